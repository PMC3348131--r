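test_that("constraint library brackets observed distances by category", {
  # bonded pair observed at 1.53 A with covalent tolerance 0.05
  s <- new_structure(tibble::tibble(
    serial = 1:2, atom_name = c("C1", "C2"), residue_name = "ALA",
    chain_id = "A", residue_number = 1L, insertion_code = "",
    element = "C", x = c(0, 1.53), y = 0, z = 0, occupancy = 1, b_factor = 0))
  cs <- build_constraints(s)
  expect_equal(nrow(cs$constraints), 1)
  expect_equal(cs$constraints$category, "covalent")
  expect_equal(cs$constraints$lower, 1.48)
  expect_equal(cs$constraints$upper, 1.58)
})

test_that("a 4-atom linear chain yields 3 covalent and 2 angle constraints", {
  s <- new_structure(tibble::tibble(
    serial = 1:4, atom_name = paste0("C", 1:4), residue_name = "ALA",
    chain_id = "A", residue_number = 1L, insertion_code = "",
    element = "C", x = c(0, 1.5, 3.0, 4.5), y = 0, z = 0,
    occupancy = 1, b_factor = 0))
  cs <- build_constraints(s, constraint_policy(contact_cutoff = 4.0))
  tab <- table(cs$constraints$category)
  expect_equal(unname(tab["covalent"]), 3)
  expect_equal(unname(tab["angle-1-3"]), 2)
})

test_that("atoms beyond the contact cutoff get no constraint", {
  s <- new_structure(tibble::tibble(
    serial = 1:3, atom_name = c("C1", "C2", "C3"), residue_name = "ALA",
    chain_id = "A", residue_number = 1L, insertion_code = "",
    element = "C", x = c(0, 1.5, 50), y = 0, z = 0,
    occupancy = 1, b_factor = 0))
  cs <- build_constraints(s)
  expect_false(any(cs$constraints$i == 1 & cs$constraints$j == 3))
  expect_false(any(cs$constraints$i == 2 & cs$constraints$j == 3))
})

test_that("hydrogen-bond pairs are detected between N/O within cutoff", {
  hb <- make_helix_bundle(seed = 1)$structure
  cs <- build_constraints(hb)
  expect_true("hbond" %in% cs$constraints$category)
  hbs <- cs$constraints[cs$constraints$category == "hbond", ]
  el <- hb$atoms$element
  expect_true(all(el[hbs$i] %in% c("N", "O") & el[hbs$j] %in% c("N", "O")))
  expect_true(all(hbs$observed <= 3.5))
})

test_that("total_violation sums one-sided bound excesses", {
  s <- make_shell_cavity(seed = 1)$structure
  cs <- build_constraints(s)
  expect_equal(total_violation(coords(s), cs), 0)

  # single constraint [1.48, 1.58] with d = 1.70 -> 0.12
  s2 <- new_structure(tibble::tibble(
    serial = 1:2, atom_name = c("C1", "C2"), residue_name = "ALA",
    chain_id = "A", residue_number = 1L, insertion_code = "",
    element = "C", x = c(0, 1.53), y = 0, z = 0, occupancy = 1, b_factor = 0))
  cs2 <- build_constraints(s2)
  xyz <- coords(s2)
  xyz[2, 1] <- 1.70
  expect_equal(total_violation(xyz, cs2), 0.12)

  # random coordinates vs independently coded summation oracle
  hb <- make_helix_bundle(n_helices = 1, n_res = 4, seed = 2)$structure
  cshb <- build_constraints(hb)
  set.seed(11)
  for (i in 1:5) {
    xr <- coords(hb) + matrix(rnorm(3 * n_atoms(hb), sd = 1), ncol = 3)
    expect_equal(total_violation(xr, cshb),
                 oracle_total_violation(xr, cshb$constraints),
                 tolerance = 1e-12)
  }
  expect_error(total_violation(xyz[1, , drop = FALSE], cshb), "match")
})

test_that("conformer generation is deterministic and respects thresholds", {
  hb <- make_helix_bundle(seed = 1)$structure
  cs <- build_constraints(hb)

  # zero start perturbation: template returned untouched
  c0 <- generate_conformer(cs, seed = 5, start_magnitude = 0)
  expect_equal(c0$coordinates, coords(hb))
  expect_equal(c0$iterations_used, 0)
  expect_equal(c0$total_violation, 0)

  # same seed -> bitwise-identical coordinates
  c1 <- generate_conformer(cs, seed = 7)
  c2 <- generate_conformer(cs, seed = 7)
  expect_identical(c1$coordinates, c2$coordinates)

  # helix fixture, sigma 0.5, threshold 30: accepted
  c3 <- generate_conformer(cs, seed = 3, start_magnitude = 0.5,
                           reject_threshold = 30)
  expect_true(c3$accepted)
  expect_lte(c3$total_violation, 30)
  expect_equal(total_violation(c3$coordinates, cs), c3$total_violation,
               tolerance = 1e-9)
})

test_that("ensembles have exactly n members, all feasible, reproducibly", {
  hb <- make_helix_bundle(seed = 1)$structure
  e1 <- generate_ensemble(hb, n = 5, seed = 11)
  expect_equal(dim(e1$coords)[3], 5)
  expect_true(all(e1$info$total_violation <= 30))

  e2 <- generate_ensemble(hb, n = 5, seed = 11)
  expect_identical(e1$coords, e2$coords)
  expect_identical(tidy(e1), tidy(e2))

  # every member satisfies the violation bound against a fresh evaluation
  cs <- build_constraints(hb)
  for (i in 1:5) {
    expect_lte(total_violation(e1$coords[, , i], cs), 30)
  }
})

test_that("ensemble spread grows with the start perturbation", {
  hb <- make_helix_bundle(n_helices = 2, n_res = 10, seed = 1)$structure
  maxr <- vapply(c(0.2, 0.5, 1.0), function(sig) {
    m <- 0
    for (sd in 1:5) {
      e <- generate_ensemble(hb, n = 3, seed = sd, start_magnitude = sig)
      m <- max(m, max(e$info$ca_rmsd))
    }
    m
  }, numeric(1))
  expect_true(all(diff(maxr) > 0))
})

test_that("accepted conformers keep covalent bounds and chirality", {
  hb <- make_helix_bundle(seed = 1)$structure
  cs <- build_constraints(hb)
  cov <- cs$constraints[cs$constraints$category == "covalent", ]
  ref <- chirality_signs(hb)
  e <- generate_ensemble(hb, n = 10, seed = 2)
  for (i in 1:10) {
    x <- e$coords[, , i]
    d <- sqrt(rowSums((x[cov$j, ] - x[cov$i, ])^2))
    ok <- d >= cov$lower - 5e-4 & d <= cov$upper + 5e-4
    expect_gte(mean(ok), 0.99)
    sg <- chirality_signs(hb, x)
    expect_gte(mean(sg == ref[names(sg)]), 0.95)
  }
})

test_that("multi-model PDB output is parseable and model-consistent", {
  hb <- make_helix_bundle(n_helices = 1, n_res = 6, seed = 1)$structure
  e <- generate_ensemble(hb, n = 3, seed = 4)
  txt <- write_ensemble_pdb(e)
  lines <- strsplit(txt, "\n")[[1]]
  expect_equal(sum(grepl("^MODEL", lines)), 3)
  expect_equal(sum(grepl("^ENDMDL", lines)), 3)
  expect_equal(sum(grepl("^ATOM", lines)), 3 * n_atoms(hb))
})
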