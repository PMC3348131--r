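# Shared helpers: hand-built PDB text, random rigid motions, and the
# independent brute-force oracles used against the package's fast paths.

pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                          occ = 1, b = 0, alt = "", ins = "",
                          record = "ATOM", element = substr(name, 1, 1)) {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, alt, resid, chain, resno, ins,
          x, y, z, occ, b, element)
}

tiny_pdb_text <- function(lines) paste(c(lines, "END"), collapse = "\n")

# A 3-residue, 3-atom single-chain toy.
three_atom_pdb <- function() {
  tiny_pdb_text(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0),
    pdb_atom_line(3, "CA", "SER", "A", 3, 7.6, 0, 0)
  ))
}

random_rotation <- function() {
  qr_q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(qr_q) < 0) qr_q[, 1] <- -qr_q[, 1]
  qr_q
}

rigid_motion <- function(xyz, rot = random_rotation(),
                         trans = rnorm(3, sd = 10)) {
  sweep(xyz %*% t(rot), 2, trans, "+")
}

# Brute-force site-assignment oracle: plain loops over catalog entries,
# written independently of assign_site().
oracle_assign <- function(center, catalog, auto_cutoff = 3.75,
                          new_cutoff = 10) {
  ds <- numeric(nrow(catalog))
  for (k in seq_len(nrow(catalog))) {
    ds[k] <- sqrt(sum((c(catalog$x[k], catalog$y[k], catalog$z[k]) -
                         center)^2))
  }
  inside <- catalog$label[ds <= auto_cutoff]
  if (length(inside) > 0) {
    lab <- paste(sort(inside), collapse = "_")
    return(list(label = lab, status = "assigned"))
  }
  if (min(ds) <= new_cutoff) {
    return(list(label = catalog$label[which.min(ds)], status = "ambiguous"))
  }
  list(label = "NEW", status = "new")
}

# Exhaustive docking-pick oracle: enumerate every admissible candidate set
# under the stated rule and take the best by (volume, then conformer id).
oracle_docking_pick <- function(scores, volumes, ids = seq_along(scores)) {
  cut <- sort(scores, decreasing = TRUE)[min(5, length(scores))]
  adm <- which(scores >= cut)
  best <- adm[order(-volumes[adm], ids[adm])][1]
  ids[best]
}

# Independent summation oracle for total constraint violation.
oracle_total_violation <- function(xyz, constraints) {
  s <- 0
  for (k in seq_len(nrow(constraints))) {
    d <- sqrt(sum((xyz[constraints$j[k], ] - xyz[constraints$i[k], ])^2))
    if (d < constraints$lower[k]) s <- s + constraints$lower[k] - d
    if (d > constraints$upper[k]) s <- s + d - constraints$upper[k]
  }
  s
}

# Flood-fill oracle for enclosed cavity cells: mark grid cells inside any
# van der Waals sphere as blocked, BFS from the box boundary through
# 6-connected empty cells; enclosed = empty and unreached.
oracle_cavity_cells <- function(s, spacing = 1.0, margin = 2.0) {
  xyz <- coords(s)
  radii <- ensemblepockets:::vdw_radius(s$atoms$element)
  lo <- floor((apply(xyz, 2, min) - margin) / spacing)
  hi <- ceiling((apply(xyz, 2, max) + margin) / spacing)
  nx <- hi[1] - lo[1] + 1; ny <- hi[2] - lo[2] + 1; nz <- hi[3] - lo[3] + 1
  g <- expand.grid(ix = lo[1]:hi[1], iy = lo[2]:hi[2], iz = lo[3]:hi[3])
  pts <- cbind(g$ix, g$iy, g$iz) * spacing
  blocked <- ensemblepockets:::cpp_surface_distance(pts, xyz, radii) <= 0
  arr <- array(blocked, dim = c(nx, ny, nz))
  seen <- array(FALSE, dim = c(nx, ny, nz))
  queue <- list()
  for (i in 1:nx) for (j in 1:ny) for (k in c(1, nz)) queue[[length(queue) + 1]] <- c(i, j, k)
  for (i in 1:nx) for (j in c(1, ny)) for (k in 1:nz) queue[[length(queue) + 1]] <- c(i, j, k)
  for (i in c(1, nx)) for (j in 1:ny) for (k in 1:nz) queue[[length(queue) + 1]] <- c(i, j, k)
  qm <- unique(do.call(rbind, queue))
  qm <- qm[!arr[qm], , drop = FALSE]
  seen[qm] <- TRUE
  frontier <- qm
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  while (nrow(frontier) > 0) {
    nxt <- NULL
    for (o in 1:6) {
      cand <- sweep(frontier, 2, offs[o, ], "+")
      ok <- cand[, 1] >= 1 & cand[, 1] <= nx & cand[, 2] >= 1 &
        cand[, 2] <= ny & cand[, 3] >= 1 & cand[, 3] <= nz
      cand <- cand[ok, , drop = FALSE]
      if (nrow(cand) == 0) next
      fresh <- !seen[cand] & !arr[cand]
      cand <- cand[fresh, , drop = FALSE]
      if (nrow(cand) == 0) next
      seen[cand] <- TRUE
      nxt <- rbind(nxt, cand)
    }
    frontier <- if (is.null(nxt)) matrix(numeric(0), ncol = 3) else unique(nxt)
  }
  sum(!arr & !seen)
}
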