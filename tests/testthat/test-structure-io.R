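test_that("parse_pdb transcribes atoms and selects chains", {
  s <- parse_pdb(three_atom_pdb())
  expect_equal(n_atoms(s), 3)
  expect_equal(nrow(residue_table(s)), 3)
  expect_equal(s$atoms$atom_name, c("CA", "CA", "CA"))
  expect_equal(s$atoms$residue_name, c("ALA", "GLY", "SER"))

  expect_error(parse_pdb(three_atom_pdb(), chain = "B"), "chain not found")
  expect_error(parse_pdb(tiny_pdb_text(character(0))), "parse error")

  # default chain rule: first chain with >= 50 standard residues
  big <- tiny_pdb_text(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    vapply(1:55, function(i) {
      pdb_atom_line(i + 1, "CA", "GLY", "B", i, i * 3.8, 20, 0)
    }, character(1))
  ))
  expect_equal(unique(parse_pdb(big)$atoms$chain_id), "B")
  expect_equal(unique(parse_pdb(big, chain = "A")$atoms$chain_id), "A")
})

test_that("altloc duplicates resolve to highest occupancy, first-listed tie", {
  two_alt <- tiny_pdb_text(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 1, 0, 0, occ = 0.60, alt = "A"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 2, 0, 0, occ = 0.40, alt = "B")
  ))
  s <- parse_pdb(two_alt)
  expect_equal(n_atoms(s), 1)
  expect_equal(s$atoms$occupancy, 0.6)
  expect_equal(s$atoms$x, 1)

  # order reversed: still the 0.6 copy
  rev <- tiny_pdb_text(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 2, 0, 0, occ = 0.40, alt = "B"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1, 0, 0, occ = 0.60, alt = "A")
  ))
  expect_equal(parse_pdb(rev)$atoms$x, 1)

  # tie: first occurrence wins
  tie <- tiny_pdb_text(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 5, 0, 0, occ = 0.50, alt = "A"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 6, 0, 0, occ = 0.50, alt = "B")
  ))
  expect_equal(parse_pdb(tie)$atoms$x, 5)
})

test_that("strip_heteroatoms removes waters, ligands and hydrogens", {
  mixed <- parse_pdb(tiny_pdb_text(c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.5, 0, 0),
    pdb_atom_line(3, "HA", "ALA", "A", 1, 1.5, 1, 0, element = "H"),
    pdb_atom_line(4, "C", "ALA", "A", 1, 2.2, 1.2, 0),
    pdb_atom_line(5, "O", "HOH", "A", 90, 9, 9, 9, record = "HETATM"),
    pdb_atom_line(6, "O", "HOH", "A", 91, 12, 9, 9, record = "HETATM")
  )))
  s <- strip_heteroatoms(mixed)
  expect_equal(n_atoms(s), 3)
  expect_false(any(s$atoms$element == "H"))
  expect_false(any(s$atoms$residue_name == "HOH"))

  only_water <- new_structure(tibble::tibble(
    serial = 1L, atom_name = "O", residue_name = "HOH", chain_id = "A",
    residue_number = 1L, insertion_code = "", element = "O",
    x = 0, y = 0, z = 0, occupancy = 1, b_factor = 0))
  expect_error(strip_heteroatoms(only_water), "empty structure")
})

test_that("superposition removes rigid motions and matches the bio3d oracle", {
  hb <- make_helix_bundle(seed = 3)$structure
  expect_lt(superpose(hb, hb)$rmsd, 1e-9)

  shifted <- set_coords(hb, sweep(coords(hb), 2, c(5, 0, 0), "+"))
  expect_lt(superpose(shifted, hb)$rmsd, 1e-9)

  # Gaussian noise: rmsd must equal an independently implemented fit
  set.seed(42)
  noisy <- set_coords(hb, coords(hb) + matrix(rnorm(3 * n_atoms(hb), sd = 0.5),
                                              ncol = 3))
  res <- superpose(noisy, hb)
  sel <- which(hb$atoms$atom_name == "CA")
  fit <- bio3d::fit.xyz(
    fixed = as.vector(t(coords(hb))), mobile = as.vector(t(coords(noisy))),
    fixed.inds = as.vector(rbind(3 * sel - 2, 3 * sel - 1, 3 * sel)),
    mobile.inds = as.vector(rbind(3 * sel - 2, 3 * sel - 1, 3 * sel)))
  ref_rmsd <- bio3d::rmsd(as.vector(t(coords(hb))), fit,
                          a.inds = as.vector(rbind(3 * sel - 2, 3 * sel - 1, 3 * sel)),
                          b.inds = as.vector(rbind(3 * sel - 2, 3 * sel - 1, 3 * sel)))
  expect_equal(res$rmsd, ref_rmsd, tolerance = 1e-3) # bio3d prints 3 decimals

  # idempotence
  again <- superpose(res$structure, hb)
  expect_lt(abs(again$rmsd - res$rmsd), 1e-9)

  expect_error(superpose(hb, make_slab()$structure, selection = "CB"),
               "mismatch")
  expect_error(superpose(parse_pdb(three_atom_pdb()),
                         parse_pdb(three_atom_pdb()), selection = "N"),
               "underdetermined|mismatch")
})

test_that("superposition never increases rmsd over random rigid motions", {
  s <- make_shell_cavity(seed = 5)$structure
  xyz <- coords(s)
  set.seed(7)
  for (i in 1:100) {
    moved <- set_coords(s, rigid_motion(xyz))
    sel <- s$atoms$atom_name == "CB"
    before <- sqrt(mean(rowSums((coords(moved)[sel, ] - xyz[sel, ])^2)))
    expect_lte(superpose(moved, s, selection = "CB")$rmsd, before + 1e-9)
  }
})

test_that("write_pdb annotates B-factors by residue and round-trips", {
  s <- parse_pdb(tiny_pdb_text(c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0, b = 10),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.458, 0, 0, b = 11),
    pdb_atom_line(3, "CA", "GLY", "A", 2, 5.2, 0.1, -3.3, b = 12)
  )))
  vals <- c("A:1" = 0.92, "A:2" = 0.05)
  back <- parse_pdb(write_pdb(s, residue_values = vals))
  expect_equal(back$atoms$b_factor, c(0.92, 0.92, 0.05))

  # no residue_values: original B-factors preserved
  back2 <- parse_pdb(write_pdb(s))
  expect_equal(back2$atoms$b_factor, c(10, 11, 12))

  expect_error(write_pdb(s, residue_values = c("A:9" = 1)), "unknown residue")
  expect_error(write_pdb(s, residue_values = c("A:1" = 1234)), "range")
})

test_that("parse/write round trip preserves names, keys and coordinates", {
  for (fx in list(make_helix_bundle(seed = 1)$structure,
                  make_shell_cavity(seed = 2)$structure)) {
    p1 <- parse_pdb(write_pdb(fx))
    p2 <- parse_pdb(write_pdb(p1))
    expect_equal(p1$atoms$atom_name, fx$atoms$atom_name)
    expect_equal(residue_table(p1)$key, residue_table(fx)$key)
    expect_lte(max(abs(coords(p1) - coords(fx))), 5e-4 + 1e-12)
    expect_equal(p2$atoms, p1$atoms)
  }
})
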