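#' Druggability score coefficients
#'
#' Linear coefficients of the two pocket scores, each of the form
#' `a_n * sqrt(min(n, 100)) + a_e * e - a_p * p'` with `n` the site-point
#' count, `e` the enclosure and `p'` the (possibly capped) hydrophilicity.
#' Defaults follow the published calibration of these scores; both sets are exposed
#' so users can recalibrate.
#'
#' @param a_n,a_e,a_p Positive coefficients (`a_p` entered as the penalty
#'   magnitude).
#' @return A `score_coefficients` list.
#' @export
score_coefficients <- function(a_n, a_e, a_p) {
  stopifnot(a_n > 0, a_e > 0, a_p > 0)
  structure(list(a_n = a_n, a_e = a_e, a_p = a_p),
            class = "score_coefficients")
}

#' @rdname score_coefficients
#' @export
sitescore_coefficients <- function() score_coefficients(0.0733, 0.6688, 0.20)

#' @rdname score_coefficients
#' @export
dscore_coefficients <- function() score_coefficients(0.094, 0.60, 0.324)

#' SiteScore of a pocket
#'
#' `a_n * sqrt(min(n, 100)) + a_e * e - a_p * min(p, 1)`: site-point count
#' capped at 100, hydrophilicity capped at 1.0. Scores of at least 0.80
#' mark drug-binding candidates; around 1.0 indicates submicromolar
#' promise.
#'
#' @param n Site-point count(s).
#' @param e Enclosure fraction(s) in `[0, 1]`.
#' @param p Hydrophilicity value(s), non-negative.
#' @param coefficients A [score_coefficients()] set.
#' @return Numeric score(s).
#' @export
site_score <- function(n, e, p, coefficients = sitescore_coefficients()) {
  stopifnot(all(n >= 0), all(e >= 0 & e <= 1), all(p >= 0))
  coefficients$a_n * sqrt(pmin(n, 100)) + coefficients$a_e * e -
    coefficients$a_p * pmin(p, 1.0)
}

#' Dscore of a pocket
#'
#' Same functional form as [site_score()] but with the hydrophilicity
#' uncapped, so highly hydrophilic (hard-to-drug) sites are penalised in
#' full.
#'
#' @inheritParams site_score
#' @return Numeric score(s).
#' @export
d_score <- function(n, e, p, coefficients = dscore_coefficients()) {
  stopifnot(all(n >= 0), all(e >= 0 & e <= 1), all(p >= 0))
  coefficients$a_n * sqrt(pmin(n, 100)) + coefficients$a_e * e -
    coefficients$a_p * p
}

#' Pocket-detection configuration
#'
#' @param spacing Grid spacing in Angstrom.
#' @param probe_reach Maximum distance from the van der Waals surface at
#'   which a grid point can still be a candidate site point (Angstrom).
#' @param enclosure_floor Minimum blocked-ray fraction for a candidate site
#'   point. A point over an infinite flat surface approaches 1/2 from
#'   below, so the floor must exceed 1/2 to exclude planar and convex
#'   surface patches; the default of 2/3 (clearly buried: blocked in at
#'   least two thirds of directions) additionally trims shallow mouth
#'   funnels and was calibrated on the shell-cavity fixture against its
#'   analytic volume.
#' @param n_rays Number of cast rays per point (fixed spherical set).
#' @param ray_range Maximum ray length in Angstrom.
#' @param min_site_points Minimum connected site points for a reported
#'   pocket.
#' @param top_n Number of top-ranked pockets retained.
#' @param druggable_cutoff SiteScore at or above which a pocket is marked a
#'   drug-binding candidate.
#' @param hydrophobic_radius,hydrophobic_min_neighbours Restrictive
#'   hydrophobicity rule: a site point is hydrophobic only if its nearest
#'   atom is an apolar side-chain carbon/sulfur and at least this many
#'   apolar atoms lie within the radius.
#' @param calibration_h,calibration_p Scale factors mapping hydrophobic /
#'   hydrophilic site-point fractions to the h and p properties.
#' @param p_floor,balance_cap Guard rails for the balance ratio h/p.
#' @param margin Bounding-box margin for grid construction (Angstrom).
#' @param sitescore_coefficients,dscore_coefficients Score coefficient sets.
#' @return A named list of settings for [detect_pockets()].
#' @export
pocket_config <- function(spacing = 1.0, probe_reach = 8.0,
                          enclosure_floor = 2/3, n_rays = 66, ray_range = 12.0,
                          min_site_points = 15, top_n = 10,
                          druggable_cutoff = 0.80,
                          hydrophobic_radius = 4.5,
                          hydrophobic_min_neighbours = 2,
                          calibration_h = 1.0, calibration_p = 1.0,
                          p_floor = 0.1, balance_cap = 10, margin = 2.0,
                          sitescore_coefficients = NULL,
                          dscore_coefficients = NULL) {
  stopifnot(spacing > 0)
  list(spacing = spacing, probe_reach = probe_reach, margin = margin,
       enclosure_floor = enclosure_floor, n_rays = n_rays,
       ray_range = ray_range, min_site_points = min_site_points,
       top_n = top_n, druggable_cutoff = druggable_cutoff,
       hydrophobic_radius = hydrophobic_radius,
       hydrophobic_min_neighbours = hydrophobic_min_neighbours,
       calibration_h = calibration_h, calibration_p = calibration_p,
       p_floor = p_floor, balance_cap = balance_cap,
       sitescore_coefficients = sitescore_coefficients %||%
         sitescore_coefficients(),
       dscore_coefficients = dscore_coefficients %||% dscore_coefficients())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical frame: centroid plus principal axes with signs fixed by the
# third central moment (ties left as computed). Anchoring the detection
# grid here makes pocket properties invariant under rigid motion of the
# input for structures with non-degenerate inertia.
canonical_frame <- function(xyz) {
  cen <- colMeans(xyz)
  xc <- sweep(xyz, 2, cen)
  ev <- eigen(crossprod(xc) / nrow(xc), symmetric = TRUE)
  A <- ev$vectors # columns: axes, decreasing variance
  for (k in 1:3) {
    m3 <- sum((xc %*% A[, k])^3)
    if (m3 < -1e-8) A[, k] <- -A[, k]
  }
  if (det(A) < 0) A[, 3] <- -A[, 3]
  list(center = cen, axes = A)
}

# Apolar atoms for hydrophobic typing: carbons/sulfurs of apolar side
# chains (backbone atoms excluded).
.APOLAR_RES <- c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET", "TRP",
                 "CYS", "GLY")
apolar_atom <- function(atoms) {
  atoms$element %in% c("C", "S") &
    atoms$residue_name %in% .APOLAR_RES &
    !(atoms$atom_name %in% c("N", "CA", "C", "O"))
}

#' Candidate site points of a structure
#'
#' Lays a regular grid (in the structure's canonical frame) over the
#' bounding box, keeps points that sit outside all van der Waals spheres
#' but within probe reach of the surface, and filters by enclosure: the
#' fraction of cast rays (fixed spherical set, fixed maximum range) blocked
#' by protein atoms must reach the configured floor. Each surviving point
#' is typed by its nearest protein atom's chemistry (donor N / acceptor O /
#' hydrophobic apolar C,S under the restrictive rule / philic-neutral).
#'
#' @param s A cleaned `mol_structure`.
#' @param config Settings from [pocket_config()].
#' @return Tibble of site points: `x`, `y`, `z` (input frame), `ix`, `iy`,
#'   `iz` (integer grid indices), `enclosure`, `character`.
#' @export
grid_sites <- function(s, config = pocket_config()) {
  if (n_atoms(s) == 0) stop("empty structure")
  xyz <- coords(s)
  radii <- vdw_radius(s$atoms$element)
  frame <- canonical_frame(xyz)
  y <- sweep(xyz, 2, frame$center) %*% frame$axes

  sp <- config$spacing
  lo <- floor((apply(y, 2, min) - config$margin %||% 2.0) / sp)
  hi <- ceiling((apply(y, 2, max) + config$margin %||% 2.0) / sp)
  idx <- expand.grid(ix = lo[1]:hi[1], iy = lo[2]:hi[2], iz = lo[3]:hi[3])
  pts <- cbind(idx$ix, idx$iy, idx$iz) * sp

  sd <- cpp_surface_distance(pts, y, radii)
  keep <- sd > 0 & sd <= config$probe_reach
  pts <- pts[keep, , drop = FALSE]
  idx <- idx[keep, , drop = FALSE]
  if (nrow(pts) == 0) return(empty_sites())

  dirs <- fibonacci_sphere(config$n_rays)
  enc <- cpp_ray_blocked(pts, y, radii, dirs, config$ray_range)
  keep <- enc >= config$enclosure_floor
  pts <- pts[keep, , drop = FALSE]
  idx <- idx[keep, , drop = FALSE]
  enc <- enc[keep]
  if (nrow(pts) == 0) return(empty_sites())

  near <- cpp_nearest_atom(pts, y)
  el <- s$atoms$element[near]
  apolar <- apolar_atom(s$atoms)
  n_apolar <- cpp_count_within(pts, y, apolar, config$hydrophobic_radius)
  chr <- rep("philic-neutral", nrow(pts))
  chr[el == "N"] <- "donor"
  chr[el == "O"] <- "acceptor"
  hydro <- apolar[near] & n_apolar >= config$hydrophobic_min_neighbours
  chr[hydro] <- "hydrophobic"

  world <- sweep(pts %*% t(frame$axes), 2, frame$center, "+")
  tibble::tibble(
    x = world[, 1], y = world[, 2], z = world[, 3],
    ix = as.integer(idx$ix), iy = as.integer(idx$iy), iz = as.integer(idx$iz),
    enclosure = enc, character = chr
  )
}

empty_sites <- function() {
  tibble::tibble(x = numeric(0), y = numeric(0), z = numeric(0),
                 ix = integer(0), iy = integer(0), iz = integer(0),
                 enclosure = numeric(0), character = character(0))
}

#' Cluster site points into pockets
#'
#' Connected components of the site-point set under 26-neighbour grid
#' adjacency; components below `min_site_points` are discarded.
#'
#' @param points Site-point tibble from [grid_sites()].
#' @param min_site_points Minimum component size kept.
#' @return Tibble with one row per surviving component: `component`, `n`
#'   and a `site_points` list-column.
#' @export
cluster_site_points <- function(points, min_site_points = 15) {
  if (nrow(points) == 0) {
    return(tibble::tibble(component = integer(0), n = integer(0),
                          site_points = list()))
  }
  key <- paste(points$ix, points$iy, points$iz)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  offs <- offs[seq_len(nrow(offs)) <= 13, ] # half-shell; edges undirected
  edges <- NULL
  for (k in seq_len(nrow(offs))) {
    nb <- paste(points$ix + offs$dx[k], points$iy + offs$dy[k],
                points$iz + offs$dz[k])
    hit <- match(nb, key)
    src <- which(!is.na(hit))
    if (length(src) > 0) edges <- rbind(edges, cbind(src, hit[src]))
  }
  g <- igraph::graph_from_edgelist(
    if (is.null(edges)) matrix(integer(0), ncol = 2) else edges,
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(points) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  keep_ids <- which(tabulate(comp) >= min_site_points)
  out <- lapply(keep_ids, function(cid) points[comp == cid, , drop = FALSE])
  tibble::tibble(component = seq_along(out),
                 n = vapply(out, nrow, integer(1)),
                 site_points = out)
}

#' Enclosure of a pocket
#'
#' Mean over its site points of the fraction of cast rays (fixed spherical
#' set, fixed maximum range) blocked by protein atoms; 1 means fully
#' buried, 0 fully open.
#'
#' @param points Site-point tibble (columns `x`, `y`, `z`).
#' @param s The `mol_structure` the pocket sits on.
#' @param n_rays,ray_range Ray-casting parameters.
#' @return Fraction in `[0, 1]`.
#' @export
enclosure <- function(points, s, n_rays = 66, ray_range = 12.0) {
  stopifnot(nrow(points) > 0)
  dirs <- fibonacci_sphere(n_rays)
  mean(cpp_ray_blocked(as.matrix(points[, c("x", "y", "z")]), coords(s),
                       vdw_radius(s$atoms$element), dirs, ray_range))
}

#' Hydrophobic / hydrophilic character of a pocket
#'
#' `h` is the calibrated fraction of hydrophobic site points, `p` the
#' calibrated fraction of polar (donor / acceptor / philic-neutral) ones;
#' `balance = h / p` with the denominator floored and the ratio capped to
#' keep the all-hydrophobic limit finite.
#'
#' @param points Site-point tibble with a `character` column.
#' @param config Settings from [pocket_config()] (calibration, floor, cap).
#' @return List with `h`, `p`, `balance`.
#' @export
hydro_character <- function(points, config = pocket_config()) {
  stopifnot(nrow(points) > 0)
  fh <- mean(points$character == "hydrophobic")
  h <- config$calibration_h * fh
  p <- config$calibration_p * (1 - fh)
  list(h = h, p = p,
       balance = min(h / max(p, config$p_floor), config$balance_cap))
}

#' Pocket volume
#'
#' One grid cell per site point: `n * spacing^3`.
#'
#' @param points Site-point tibble.
#' @param spacing Grid spacing in Angstrom.
#' @return Volume in cubic Angstrom.
#' @export
pocket_volume <- function(points, spacing = 1.0) {
  stopifnot(nrow(points) > 0)
  nrow(points) * spacing^3
}

#' Detect and score surface pockets
#'
#' Full single-conformer pipeline: grid site points, cluster into
#' connected components, compute volume, enclosure, hydrophobic /
#' hydrophilic character and both druggability scores, rank by SiteScore
#' (ties by volume, then lowest centre lexicographically) and keep the top
#' pockets. Pockets at or above the SiteScore cut-off are flagged as
#' drug-binding candidates.
#'
#' @param s A cleaned, single-chain `mol_structure`.
#' @param config Settings from [pocket_config()].
#' @return Tibble with one row per pocket, ranked: `rank`, `n`, `volume`,
#'   `enclosure`, `h`, `p`, `balance`, `site_score`, `d_score`,
#'   `druggable`, `center_x/y/z`, `lining_residues` and `site_points`
#'   list-columns.
#' @export
detect_pockets <- function(s, config = pocket_config()) {
  points <- grid_sites(s, config)
  comps <- cluster_site_points(points, config$min_site_points)
  if (nrow(comps) == 0) return(empty_pockets())
  rows <- lapply(comps$site_points, function(sp) {
    hc <- hydro_character(sp, config)
    e <- mean(sp$enclosure)
    n <- nrow(sp)
    ctr <- colMeans(as.matrix(sp[, c("x", "y", "z")]))
    lin <- lining_residues(s, as.matrix(sp[, c("x", "y", "z")]))
    tibble::tibble(
      n = n, volume = pocket_volume(sp, config$spacing), enclosure = e,
      h = hc$h, p = hc$p, balance = hc$balance,
      site_score = site_score(n, e, hc$p, config$sitescore_coefficients),
      d_score = d_score(n, e, hc$p, config$dscore_coefficients),
      center_x = ctr[1], center_y = ctr[2], center_z = ctr[3],
      lining_residues = list(lin), site_points = list(sp)
    )
  })
  out <- dplyr::bind_rows(rows)
  ord <- order(-out$site_score, -out$volume,
               out$center_x, out$center_y, out$center_z)
  out <- out[ord, , drop = FALSE]
  out <- head(out, config$top_n)
  out$rank <- seq_len(nrow(out))
  out$druggable <- out$site_score >= config$druggable_cutoff
  dplyr::relocate(out, "rank")
}

empty_pockets <- function() {
  tibble::tibble(rank = integer(0), n = integer(0), volume = numeric(0),
                 enclosure = numeric(0), h = numeric(0), p = numeric(0),
                 balance = numeric(0), site_score = numeric(0),
                 d_score = numeric(0), center_x = numeric(0),
                 center_y = numeric(0), center_z = numeric(0),
                 lining_residues = list(), site_points = list(),
                 druggable = logical(0))
}

lining_residues <- function(s, sphere_xyz, cutoff = 3.75) {
  if (nrow(sphere_xyz) == 0) return(character(0))
  d <- cpp_surface_distance(coords(s), sphere_xyz,
                            rep(0, nrow(sphere_xyz)))
  unique(atom_residue_keys(s)[d <= cutoff])
}

#' Detect pockets on every conformer of an ensemble
#'
#' @param ensemble A `conformer_ensemble`.
#' @param config Settings from [pocket_config()].
#' @return Tibble of pockets across all conformers with a `conformer_id`
#'   column prepended.
#' @export
detect_ensemble_pockets <- function(ensemble, config = pocket_config()) {
  n <- dim(ensemble$coords)[3]
  purrr::map_dfr(seq_len(n), function(i) {
    pk <- detect_pockets(conformer_structure(ensemble, i), config)
    if (nrow(pk) == 0) return(NULL)
    dplyr::mutate(pk, conformer_id = i, .before = 1)
  })
}

#' Write pocket site points as a sphere PDB
#'
#' One HETATM record per site point, residue name `SIT`, one residue per
#' pocket — the interchange format consumed by the Provar stage and by
#' external visualisation tools.
#'
#' @param pockets Pocket tibble from [detect_pockets()].
#' @param file Optional output path.
#' @return PDB-format text.
#' @export
write_pocket_spheres <- function(pockets, file = NULL) {
  if (nrow(pockets) == 0) {
    out <- "END\n"
  } else {
    xyz <- NULL
    resno <- NULL
    for (k in seq_len(nrow(pockets))) {
      sp <- pockets$site_points[[k]]
      xyz <- rbind(xyz, as.matrix(sp[, c("x", "y", "z")]))
      resno <- c(resno, rep(k, nrow(sp)))
    }
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path))
    na <- nrow(xyz)
    bio3d::write.pdb(
      pdb = NULL, file = path, xyz = as.vector(t(xyz)),
      type = rep("HETATM", na), resno = resno,
      resid = rep("SIT", na), eleno = seq_len(na),
      elety = rep("SPH", na), chain = rep("S", na),
      o = rep(1, na), b = rep(0, na), elesy = rep("O", na), end = TRUE
    )
    out <- paste0(paste(readLines(path), collapse = "\n"), "\n")
  }
  if (!is.null(file)) writeLines(sub("\n$", "", out), file)
  out
}

#' Read sphere coordinates from a pocket-sphere PDB
#'
#' Accepts the dialect written by [write_pocket_spheres()] or any
#' HETATM-only PDB produced by external pocket-detection tools.
#'
#' @param text PDB text or path.
#' @return Numeric matrix of sphere centres (one row per sphere).
#' @export
read_sphere_pdb <- function(text) {
  lines <- if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    readLines(text)
  } else if (length(text) == 1) strsplit(text, "\n")[[1]] else text
  rec <- lines[grepl("^(HETATM|ATOM )", lines)]
  if (length(rec) == 0) return(matrix(numeric(0), ncol = 3))
  cbind(as.numeric(substr(rec, 31, 38)),
        as.numeric(substr(rec, 39, 46)),
        as.numeric(substr(rec, 47, 54)))
}
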