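#' Synthetic fixture structures with known pocket ground truth
#'
#' Deterministic toy structures — a spherical shell with an interior
#' cavity and circular aperture, a flat slab, a two-cavity pair and an
#' ideal-geometry helix bundle — that make every pipeline stage testable
#' without any external structure files. Each generator returns the
#' structure together with its analytic ground truth.
#'
#' @name fixtures
NULL

make_atom_tibble <- function(xyz, atom_name, residue_name, element,
                             residue_number, chain_id = "A",
                             occupancy = 1, b_factor = 0) {
  n <- nrow(xyz)
  tibble::tibble(
    serial = seq_len(n),
    atom_name = rep_len(atom_name, n),
    residue_name = rep_len(residue_name, n),
    chain_id = rep_len(chain_id, n),
    residue_number = as.integer(rep_len(residue_number, n)),
    insertion_code = "",
    element = rep_len(element, n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = rep_len(occupancy, n),
    b_factor = rep_len(b_factor, n)
  )
}

#' @describeIn fixtures Spherical shell of apolar pseudo-atoms (Ala
#'   C-beta-like carbons) enclosing a single cavity of radius
#'   `inner_radius`, with a circular aperture of the given angular radius
#'   cut around +z. The analytic cavity volume is the sphere volume minus
#'   the spherical cap subtended by the aperture.
#' @param inner_radius Cavity radius in Angstrom.
#' @param aperture Angular radius of the aperture in degrees (0 = closed
#'   shell; must be < 180).
#' @param atom_spacing Target spacing of shell atoms in Angstrom; must be
#'   fine enough that neighbouring van der Waals spheres overlap and close
#'   the shell.
#' @param seed Integer seed (controls a small coordinate jitter so that
#'   byte-reproducibility is meaningfully exercised).
#' @param jitter Jitter scale in Angstrom.
#' @return `make_shell_cavity()`: list with `structure`, `cavity_volume`
#'   (analytic, cubic Angstrom), `center` and `params`.
#' @export
make_shell_cavity <- function(inner_radius = 6, aperture = 60,
                              atom_spacing = 1.8, seed = 1, jitter = 0.02) {
  stopifnot(inner_radius > 0, aperture >= 0, aperture < 180)
  r_vdw <- unname(.VDW_RADII["C"])
  if (atom_spacing > 2 * r_vdw) {
    stop("atom_spacing too coarse to close the shell (needs <= ",
         2 * r_vdw, " A)")
  }
  shell_r <- inner_radius + r_vdw
  n <- max(12, round(4 * pi * shell_r^2 / atom_spacing^2))
  pos <- fibonacci_sphere(n) * shell_r
  theta <- acos(pmin(1, pmax(-1, pos[, 3] / shell_r))) * 180 / pi
  pos <- pos[theta >= aperture, , drop = FALSE]
  pos <- pos + with_seed(seed, matrix(rnorm(length(pos), sd = jitter),
                                      ncol = 3))
  s <- new_structure(
    make_atom_tibble(pos, "CB", "ALA", "C", seq_len(nrow(pos))),
    source_id = sprintf("shell_cavity_r%g_a%g", inner_radius, aperture))
  ca <- aperture * pi / 180
  v <- 4 / 3 * pi * inner_radius^3 -
    pi / 3 * inner_radius^3 * (1 - cos(ca))^2 * (2 + cos(ca))
  list(structure = s, cavity_volume = v, center = c(0, 0, 0),
       params = list(inner_radius = inner_radius, aperture = aperture,
                     atom_spacing = atom_spacing, seed = seed))
}

#' @describeIn fixtures Flat rectangular slab (two stacked atom layers) of
#'   apolar carbons with no concavity anywhere: ground truth is zero
#'   pockets.
#' @param nx,ny Atoms per slab edge (at least 3).
#' @return `make_slab()`: list with `structure` and `params`.
#' @export
make_slab <- function(nx = 10, ny = 10, atom_spacing = 1.8, seed = 1,
                      jitter = 0.02) {
  stopifnot(nx >= 3, ny >= 3)
  g <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = 0:1)
  pos <- cbind((g$i - (nx + 1) / 2) * atom_spacing,
               (g$j - (ny + 1) / 2) * atom_spacing,
               -g$k * atom_spacing)
  pos <- pos + with_seed(seed, matrix(rnorm(length(pos), sd = jitter),
                                      ncol = 3))
  s <- new_structure(
    make_atom_tibble(pos, "CB", "ALA", "C", seq_len(nrow(pos))),
    source_id = sprintf("slab_%dx%d", nx, ny))
  list(structure = s, params = list(nx = nx, ny = ny,
                                    atom_spacing = atom_spacing, seed = seed))
}

#' @describeIn fixtures Two shell cavities separated along x: ground truth
#'   is exactly two pockets with known centres and volumes.
#' @param separation Centre-to-centre distance in Angstrom.
#' @return `make_two_cavity()`: list with `structure`, `cavity_volumes`,
#'   `centers` (2 x 3 matrix) and `params`.
#' @export
make_two_cavity <- function(inner_radius = 5, aperture = 50,
                            atom_spacing = 1.8, separation = 30, seed = 1) {
  a <- make_shell_cavity(inner_radius, aperture, atom_spacing, seed)
  b <- make_shell_cavity(inner_radius, aperture, atom_spacing, seed + 1)
  off <- separation / 2
  at_a <- a$structure$atoms
  at_b <- b$structure$atoms
  at_a$x <- at_a$x - off
  at_b$x <- at_b$x + off
  at_b$serial <- at_b$serial + max(at_a$serial)
  at_b$residue_number <- at_b$residue_number + max(at_a$residue_number)
  s <- new_structure(dplyr::bind_rows(at_a, at_b),
                     source_id = sprintf("two_cavity_sep%g", separation))
  list(structure = s,
       cavity_volumes = c(a$cavity_volume, b$cavity_volume),
       centers = rbind(c(-off, 0, 0), c(off, 0, 0)),
       params = list(inner_radius = inner_radius, aperture = aperture,
                     atom_spacing = atom_spacing, separation = separation,
                     seed = seed))
}

# Natural-extension (NeRF) placement: position D from A-B-C with bond
# length r (C-D), angle theta (B-C-D, degrees) and torsion phi
# (A-B-C-D, degrees).
nerf_place <- function(A, B, C, r, theta, phi) {
  theta <- theta * pi / 180
  phi <- phi * pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  C + r * (-cos(theta) * bc + sin(theta) * cos(phi) * m +
             sin(theta) * sin(phi) * n)
}

# Ideal poly-Ala alpha helix (N, CA, C, O, CB per residue) built with
# standard backbone geometry and phi/psi = -57/-47.
build_helix <- function(n_res, phi = -57, psi = -47) {
  N <- matrix(0, n_res, 3); CA <- N; C <- N; O <- N; CB <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  ang <- 111.2 * pi / 180
  C[1, ] <- CA[1, ] + 1.525 * c(-cos(ang), sin(ang), 0)
  for (i in 2:n_res) {
    N[i, ] <- nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         1.329, 116.2, psi)
    CA[i, ] <- nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ],
                          1.458, 121.7, 180)
    C[i, ] <- nerf_place(C[i - 1, ], N[i, ], CA[i, ], 1.525, 111.2, phi)
  }
  for (i in seq_len(n_res)) {
    o_torsion <- if (i < n_res) psi + 180 else psi + 180
    O[i, ] <- nerf_place(N[i, ], CA[i, ], C[i, ], 1.231, 120.8, o_torsion)
    CB[i, ] <- nerf_place(C[i, ], N[i, ], CA[i, ], 1.521, 110.4, -122.0)
  }
  list(N = N, CA = CA, C = C, O = O, CB = CB)
}

#' @describeIn fixtures Bundle of parallel ideal poly-Ala alpha helices
#'   (N, CA, C, O, CB per residue; 3 helices x 20 residues = 300 atoms by
#'   default) with realistic bond geometry, so covalent / angle / hydrogen
#'   bond constraint detection and the chirality guard are genuinely
#'   exercised.
#' @param n_helices Number of helices.
#' @param n_res Residues per helix.
#' @param helix_separation Axis-to-axis distance in Angstrom.
#' @return `make_helix_bundle()`: list with `structure` and `params`.
#' @export
make_helix_bundle <- function(n_helices = 3, n_res = 20,
                              helix_separation = 10, seed = 1,
                              jitter = 0.02) {
  stopifnot(n_helices >= 1, n_res >= 4)
  h <- build_helix(n_res)
  # rotate so the helix axis (first principal component of the CA trace)
  # lies along z, then centre it
  ca <- h$CA
  cen <- colMeans(ca)
  ax <- eigen(crossprod(sweep(ca, 2, cen)), symmetric = TRUE)$vectors
  if (det(ax) < 0) ax[, 3] <- -ax[, 3]
  rot <- ax[, c(2, 3, 1)] # principal axis last -> z
  place <- function(m) sweep(m, 2, cen) %*% rot

  offs <- cbind(helix_separation *
                  cos(2 * pi * (seq_len(n_helices) - 1) / max(n_helices, 2)),
                helix_separation *
                  sin(2 * pi * (seq_len(n_helices) - 1) / max(n_helices, 2)),
                0)
  if (n_helices == 1) offs[] <- 0

  rows <- list()
  resno0 <- 0L
  for (k in seq_len(n_helices)) {
    for (i in seq_len(n_res)) {
      xyz <- rbind(place(h$N)[i, ], place(h$CA)[i, ], place(h$C)[i, ],
                   place(h$O)[i, ], place(h$CB)[i, ])
      xyz <- sweep(xyz, 2, offs[k, ], "+")
      rows[[length(rows) + 1]] <- make_atom_tibble(
        xyz, c("N", "CA", "C", "O", "CB"), "ALA",
        c("N", "C", "C", "O", "C"), resno0 + i)
    }
    resno0 <- resno0 + n_res
  }
  at <- dplyr::bind_rows(rows)
  at$serial <- seq_len(nrow(at))
  at[, c("x", "y", "z")] <- at[, c("x", "y", "z")] +
    with_seed(seed, matrix(rnorm(3 * nrow(at), sd = jitter), ncol = 3))
  s <- new_structure(at, source_id = sprintf("helix_bundle_%dx%d",
                                             n_helices, n_res))
  list(structure = s,
       params = list(n_helices = n_helices, n_res = n_res,
                     helix_separation = helix_separation, seed = seed))
}

#' @describeIn fixtures Reference structure plus per-conformer sphere sets
#'   with exact Provar ground truth: spheres sit within the lining cutoff
#'   of the designated residues in exactly `k_present` conformers and far
#'   (> 10 Angstrom from every residue) in the rest, so the recovered
#'   propensity is `k_present / n_conformers` on the lining set and 0
#'   elsewhere. Residues are isolated C-alpha pseudo-residues on a coarse
#'   grid so no sphere can flag a neighbour by accident.
#' @param n_residues Number of residues in the reference structure.
#' @param n_conformers Ensemble size.
#' @param lining_set Integer indices of the designated lining residues.
#' @param k_present Number of conformers in which the lining spheres are
#'   present.
#' @param grid_step Residue grid spacing in Angstrom (must exceed the
#'   lining cutoff plus the sphere offset so recovery is exact).
#' @return `make_mask_ensemble()`: list with `structure`, `sphere_sets`
#'   (list of matrices), `lining_keys`, `present` (logical per conformer)
#'   and `params`.
#' @export
make_mask_ensemble <- function(n_residues = 50, n_conformers = 100,
                               lining_set = 1:5, k_present = 92, seed = 1,
                               grid_step = 10) {
  stopifnot(k_present >= 0, k_present <= n_conformers,
            all(lining_set >= 1), all(lining_set <= n_residues))
  if (grid_step <= 3.75 + 2.0) {
    stop("grid_step too small for exact recovery (placement infeasible)")
  }
  side <- ceiling(n_residues^(1 / 3))
  g <- expand.grid(i = 0:(side - 1), j = 0:(side - 1), k = 0:(side - 1))
  g <- g[seq_len(n_residues), ]
  pos <- cbind(g$i, g$j, g$k) * grid_step
  s <- new_structure(
    make_atom_tibble(pos, "CA", "GLY", "C", seq_len(n_residues)),
    source_id = sprintf("mask_ensemble_%dres", n_residues))
  keys <- residue_table(s)$key

  present <- rep(FALSE, n_conformers)
  present[with_seed(seed, sort(sample.int(n_conformers, k_present)))] <- TRUE
  far <- apply(pos, 2, max) + 50
  near_spheres <- pos[lining_set, , drop = FALSE] +
    matrix(rep(c(2, 0, 0), each = length(lining_set)), ncol = 3)
  sphere_sets <- lapply(seq_len(n_conformers), function(i) {
    if (present[i]) near_spheres else matrix(far, nrow = 1)
  })
  list(structure = s, sphere_sets = sphere_sets,
       lining_keys = keys[lining_set], present = present,
       params = list(n_residues = n_residues, n_conformers = n_conformers,
                     lining_set = lining_set, k_present = k_present,
                     seed = seed, grid_step = grid_step))
}
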