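test_that("synthetic PDB text parses into the expected hierarchy", {
  lines <- c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 90.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00 91.50           C",
    "ATOM      3  C   ALA A   1      10.567   5.662  -4.143  1.00 90.00           C",
    "ATOM      4  O   ALA A   1       9.480   6.240  -4.115  1.00 90.00           O",
    "ATOM      5  N   GLY A   2      10.871   4.657  -3.321  1.00 85.00           N",
    "ATOM      6  CA  GLY A   2       9.912   4.165  -2.331  1.00 85.25           C",
    "ATOM      7  C   GLY A   2      10.581   3.310  -1.261  1.00 85.00           C",
    "ATOM      8  O   GLY A   2      11.784   3.070  -1.288  1.00 85.00           O",
    "ATOM      9  N   SER A   3       9.789   2.851  -0.290  1.00 70.00           N",
    "ATOM     10  CA  SER A   3      10.282   2.022   0.819  1.00 70.75           C",
    "ATOM     11  C   SER A   3       9.215   1.932   1.897  1.00 70.00           C",
    "ATOM     12  O   SER A   3       8.018   2.090   1.613  1.00 70.00           O",
    "END"
  )
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, tf)
  st <- read_structure(tf)
  expect_s3_class(st, "ab_structure")
  expect_equal(chain_ids(st), "A")
  expect_equal(length(unique(st$atoms$resno)), 3L)
  expect_equal(st$atoms$x[1], 11.104)
  expect_equal(st$atoms$b[2], 91.50)
  expect_equal(st$atoms$resid[5:8], rep("GLY", 4))
})

test_that("model_index selects the requested MODEL and errors out of range", {
  spec <- fixture_spec(seed = 2, n_conformations = 2,
                       members_per_conformation = c(1L, 1L),
                       intra_noise_sigma = 0)
  a <- make_toy_chain(spec, 0L)$structure
  b <- make_toy_chain(spec, 1L)$structure
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(new_ensemble(list(a, b)), tf)
  m2 <- read_structure(tf, model_index = 2)
  expect_equal(m2$atoms$y, round(b$atoms$y, 3))
  expect_false(isTRUE(all.equal(m2$atoms$y, a$atoms$y)))
  expect_error(read_structure(tf, model_index = 3), "out of range")
})

test_that("write/read round-trip preserves coordinates, identities and pLDDT", {
  spec <- fixture_spec(seed = 5, n_conformations = 5,
                       members_per_conformation = rep(1L, 5),
                       intra_noise_sigma = 0.2)
  members <- lapply(0:4, function(g) make_toy_chain(spec, g)$structure)
  members[[1]]$atoms$b[members[[1]]$atoms$resno == 3] <- 81.25
  ens <- new_ensemble(members)
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(ens, tf)
  expect_equal(length(grep("^MODEL", readLines(tf))), 5L)
  back <- read_ensemble(tf)
  expect_length(back$members, 5L)
  for (i in 1:5) {
    orig <- members[[i]]$atoms
    got <- back$members[[i]]$atoms
    # PDB coordinates carry 3 decimals: absolute error at most 5e-4
    expect_lt(max(abs(got$x - orig$x)), 5.01e-4)
    expect_lt(max(abs(got$y - orig$y)), 5.01e-4)
    expect_lt(max(abs(got$z - orig$z)), 5.01e-4)
    expect_identical(paste(got$chain, got$resno, got$elety),
                     paste(orig$chain, orig$resno, orig$elety))
  }
  expect_true(all(back$members[[1]]$atoms$b[
    back$members[[1]]$atoms$resno == 3] == 81.25))
  # second round trip is exact: format precision already applied
  tf2 <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(back, tf2)
  expect_identical(grep("^ATOM", readLines(tf2), value = TRUE),
                   grep("^ATOM", readLines(tf), value = TRUE))
})

test_that("one-member ensembles write a single MODEL record", {
  spec <- fixture_spec(seed = 1, n_conformations = 1,
                       members_per_conformation = 1L, intra_noise_sigma = 0,
                       inter_conformation_shift = 1)
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(make_toy_chain(spec, 0L)$structure, tf)
  expect_equal(length(grep("^MODEL", readLines(tf))), 1L)
})

test_that("coordinate parsing agrees with bio3d on a fixture file", {
  skip_if_not_installed("bio3d")
  spec <- fixture_spec(seed = 9, n_conformations = 1,
                       members_per_conformation = 1L,
                       intra_noise_sigma = 0.3, inter_conformation_shift = 1)
  st <- make_toy_chain(spec, 0L)$structure
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_structure(st, tf)
  ours <- read_structure(tf)
  ref <- bio3d::read.pdb(tf)
  expect_equal(as.numeric(t(as.matrix(ours$atoms[, c("x", "y", "z")]))),
               as.numeric(ref$xyz), tolerance = 1e-9)
  expect_equal(ours$atoms$b, ref$atom$b)
})

test_that("altloc records reduce to the highest-occupancy conformer", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA AALA A   1       1.000   0.000   0.000  0.40 10.00           C",
    "ATOM      3  CA BALA A   1       2.000   0.000   0.000  0.60 10.00           C",
    "ATOM      4  C   ALA A   1       3.000   0.000   0.000  1.00 10.00           C",
    "ATOM      5  O   ALA A   1       4.000   0.000   0.000  1.00 10.00           O"
  )
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, tf)
  st <- read_structure(tf)
  ca <- st$atoms[st$atoms$elety == "CA", ]
  expect_equal(nrow(ca), 1L)
  expect_equal(ca$x, 2.0)   # occupancy 0.60 wins
})

test_that("backbone query returns only N, CA, C, O in fixed order", {
  spec <- fixture_spec(seed = 3, n_conformations = 1,
                       members_per_conformation = 1L, intra_noise_sigma = 0,
                       inter_conformation_shift = 1)
  st <- make_toy_chain(spec, 0L)$structure
  # shuffle atoms within residues; backbone() must restore N,CA,C,O order
  # while keeping the structure's residue order
  perm <- with(st$atoms, order(resno, elety))
  st$atoms <- st$atoms[perm, ]
  bb <- backbone(st)
  expect_true(all(bb$elety %in% c("N", "CA", "C", "O")))
  per_res <- split(bb$elety, bb$resno)
  for (e in per_res) expect_identical(e, c("N", "CA", "C", "O"))
  expect_equal(unique(bb$resno), unique(st$atoms$resno))
})

test_that("per-residue pLDDT reads CA B-factor with mean fallback", {
  atoms <- data.frame(
    eleno = 1:5, elety = c("N", "CA", "C", "N", "C"),
    resid = "ALA", chain = "A", resno = c(1, 1, 1, 2, 2),
    insert = "", x = 1:5, y = 0, z = 0, o = 1,
    b = c(50, 90, 60, 70, 80), elesy = c("N", "C", "C", "N", "C")
  )
  st <- new_structure(atoms)
  vals <- residue_plddt(st)
  expect_equal(unname(vals), c(90, 75))   # CA present; CA absent -> mean
  zero <- st; zero$atoms$b <- 0
  expect_equal(unname(residue_plddt(zero)), c(0, 0))
  expect_error(residue_plddt(st, chain = "Z"), "no atoms")
})

test_that("ensembles reject members with inconsistent residue identities", {
  spec <- fixture_spec(seed = 4, n_conformations = 1,
                       members_per_conformation = 2L, intra_noise_sigma = 0,
                       inter_conformation_shift = 1)
  a <- make_toy_chain(spec, 0L, member_id = 1L)$structure
  b <- make_toy_chain(spec, 0L, member_id = 2L)$structure
  b$atoms <- b$atoms[b$atoms$resno != 5, ]
  expect_error(new_ensemble(list(a, b)), "m002")
})
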