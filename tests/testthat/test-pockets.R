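test_that("an isolated atom yields no site points", {
  s <- new_structure(tibble::tibble(
    serial = 1L, atom_name = "CB", residue_name = "ALA", chain_id = "A",
    residue_number = 1L, insertion_code = "", element = "C",
    x = 0, y = 0, z = 0, occupancy = 1, b_factor = 0))
  expect_equal(nrow(grid_sites(s)), 0)
})

test_that("shell-cavity site points agree with a flood-fill oracle", {
  sh <- make_shell_cavity(aperture = 0, seed = 1)
  pk <- detect_pockets(sh$structure)
  expect_equal(nrow(pk), 1)
  n_oracle <- oracle_cavity_cells(sh$structure, spacing = 1.0)
  expect_lte(abs(pk$n[1] - n_oracle) / n_oracle, 0.05)
})

test_that("coarser grids give fewer site points", {
  sh <- make_shell_cavity(seed = 1)
  n1 <- nrow(grid_sites(sh$structure, pocket_config(spacing = 1.0)))
  n2 <- nrow(grid_sites(sh$structure, pocket_config(spacing = 2.0)))
  expect_lt(n2, n1)
})

test_that("clustering enforces the 15-point floor inclusively", {
  mkpts <- function(n, offset = 0) {
    tibble::tibble(x = 0, y = 0, z = 0,
                   ix = as.integer(seq_len(n) + offset), iy = 0L, iz = 0L,
                   enclosure = 0.9, character = "hydrophobic")
  }
  expect_equal(nrow(cluster_site_points(mkpts(14))), 0)
  cl <- cluster_site_points(mkpts(15))
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n, 15)
  # two clusters far apart on the grid
  two <- dplyr::bind_rows(mkpts(20), mkpts(20, offset = 100))
  expect_equal(nrow(cluster_site_points(two)), 2)
})

test_that("enclosure distinguishes buried from open points and is rigid-invariant", {
  sh <- make_shell_cavity(aperture = 0, seed = 1)
  centre <- tibble::tibble(x = 0, y = 0, z = 0)
  expect_gte(enclosure(centre, sh$structure), 0.95)

  far <- tibble::tibble(x = 40, y = 0, z = 0)
  expect_lte(enclosure(far, sh$structure), 0.05)

  set.seed(3)
  rot <- random_rotation()
  tr <- c(7, -4, 11)
  moved_s <- set_coords(sh$structure,
                        rigid_motion(coords(sh$structure), rot, tr))
  moved_p <- as.data.frame(rigid_motion(as.matrix(centre), rot, tr))
  names(moved_p) <- c("x", "y", "z")
  expect_equal(enclosure(moved_p, moved_s), enclosure(centre, sh$structure),
               tolerance = 1e-9)
})

test_that("hydro character follows typed site-point counts", {
  pts <- tibble::tibble(x = 0, y = 0, z = 0, ix = 0L, iy = 0L, iz = 0L,
                        enclosure = 0.9,
                        character = c(rep("hydrophobic", 10),
                                      rep("donor", 5), rep("acceptor", 5)))
  hc <- hydro_character(pts)
  expect_equal(hc$h, 0.5)
  expect_equal(hc$p, 0.5)
  expect_equal(hc$balance, 1.0)

  all_phobic <- dplyr::mutate(pts, character = "hydrophobic")
  hc2 <- hydro_character(all_phobic)
  expect_equal(hc2$p, 0)
  expect_equal(hc2$balance, 10) # p at floor -> balance at cap

  mixed <- dplyr::mutate(pts, character = rep(c("hydrophobic", "donor",
                                                "acceptor", "philic-neutral"),
                                              each = 5))
  hc3 <- hydro_character(mixed)
  expect_equal(hc3$h, 0.25)
  expect_equal(hc3$p, 0.75)
})

test_that("pocket volume is cell count times spacing cubed", {
  pts <- tibble::tibble(x = rnorm(27), y = rnorm(27), z = rnorm(27),
                        ix = 0L, iy = 0L, iz = 0L, enclosure = 0.9,
                        character = "hydrophobic")
  expect_equal(pocket_volume(pts, 1.0), 27)
  expect_equal(pocket_volume(pts, 0.5), 27 / 8)
})

test_that("volume estimates converge toward the analytic cavity volume", {
  sh <- make_shell_cavity(seed = 1)
  v1 <- detect_pockets(sh$structure)$volume[1]
  expect_lte(abs(v1 - sh$cavity_volume) / sh$cavity_volume, 0.15)
  v05 <- detect_pockets(sh$structure,
                        pocket_config(spacing = 0.5))$volume[1]
  expect_lte(abs(v05 - sh$cavity_volume) / sh$cavity_volume, 0.25)
  expect_lte(abs(v05 - sh$cavity_volume), abs(v1 - sh$cavity_volume) + 20)
})

test_that("scores match hand arithmetic, caps and monotonicity", {
  # zero case
  expect_equal(site_score(0, 0, 0), 0)
  expect_equal(d_score(0, 0, 0), 0)

  # hand arithmetic at the defaults
  expect_equal(site_score(100, 0.76, 1.0),
               0.0733 * 10 + 0.6688 * 0.76 - 0.20 * 1.0, tolerance = 1e-12)
  expect_equal(site_score(100, 0.76, 1.0), 1.041288, tolerance = 1e-6)

  # SiteScore cap on p, and on n
  expect_equal(site_score(50, 0.5, 2.5), site_score(50, 0.5, 1.0))
  expect_equal(site_score(150, 0.5, 0.2), site_score(100, 0.5, 0.2))

  # Dscore p uncapped, strictly decreasing, with slope a_p
  expect_lt(d_score(50, 0.5, 2.5), d_score(50, 0.5, 1.0))
  expect_equal(d_score(50, 0.5, 2) - d_score(50, 0.5, 3), 0.324,
               tolerance = 1e-12)

  # both increasing in e
  expect_gt(site_score(50, 0.9, 0.5), site_score(50, 0.5, 0.5))
  expect_gt(d_score(50, 0.9, 0.5), d_score(50, 0.5, 0.5))
})

test_that("fixture ground truths: one cavity, no slab pocket, two cavities", {
  sh <- make_shell_cavity(seed = 1)
  pk <- detect_pockets(sh$structure)
  expect_equal(nrow(pk), 1)
  expect_gte(pk$enclosure[1], 0.8)

  expect_equal(nrow(detect_pockets(make_slab(seed = 1)$structure)), 0)

  tc <- make_two_cavity(seed = 1)
  pk2 <- detect_pockets(tc$structure)
  expect_equal(nrow(pk2), 2)
  expect_true(all(diff(pk2$site_score) <= 0)) # ranked by SiteScore
  # detected centres sit near the construction centres
  d <- as.matrix(dist(rbind(tc$centers,
                            as.matrix(pk2[, c("center_x", "center_y",
                                              "center_z")]))))[1:2, 3:4]
  expect_lt(min(d[1, ]), 2)
  expect_lt(min(d[2, ]), 2)
})

test_that("pocket properties are invariant under rigid motion", {
  hb <- make_two_cavity(seed = 2)
  base <- detect_pockets(hb$structure)
  set.seed(17)
  moved <- set_coords(hb$structure, rigid_motion(coords(hb$structure)))
  res <- detect_pockets(moved)
  expect_equal(nrow(res), nrow(base))
  for (col in c("n", "volume", "enclosure", "h", "p", "balance",
                "site_score", "d_score")) {
    expect_equal(res[[col]], base[[col]], tolerance = 1e-6)
  }
})

test_that("detection is deterministic and flags druggable pockets", {
  sh <- make_shell_cavity(seed = 1)
  a <- detect_pockets(sh$structure)
  b <- detect_pockets(sh$structure)
  expect_identical(a, b)
  expect_identical(a$druggable, a$site_score >= 0.80)
})

test_that("pocket sphere PDB export round-trips sphere coordinates", {
  sh <- make_shell_cavity(seed = 1)
  pk <- detect_pockets(sh$structure)
  txt <- write_pocket_spheres(pk)
  xyz <- read_sphere_pdb(txt)
  expect_equal(nrow(xyz), pk$n[1])
  orig <- as.matrix(pk$site_points[[1]][, c("x", "y", "z")])
  expect_lte(max(abs(xyz - orig)), 5e-4 + 1e-12)
})
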