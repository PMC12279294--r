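test_that("kabsch recovers identity and pure translations exactly", {
  set.seed(42)
  pts <- matrix(rnorm(12), 4, 3)
  sup <- kabsch_superpose(pts, pts)
  expect_lt(sup$fit_rmsd, 1e-9)
  expect_equal(sup$rotation, diag(3), tolerance = 1e-9)

  shifted <- sweep(pts, 2, c(5, 0, 0), "+")
  sup2 <- kabsch_superpose(shifted, pts)
  expect_lt(sup2$fit_rmsd, 1e-9)
  expect_equal(sup2$translation, c(-5, 0, 0), tolerance = 1e-9)
})

test_that("kabsch matches a rotation-grid brute force on random clouds", {
  set.seed(7)
  for (rep in 1:3) {
    a <- matrix(rnorm(18), 6, 3)
    b <- matrix(rnorm(18), 6, 3)
    fit <- kabsch_superpose(a, b)$fit_rmsd
    grid <- grid_search_min_rmsd(a, b)
    expect_gte(grid, fit - 1e-9)     # grid can never beat the optimum
    expect_lt(abs(grid - fit), 1e-3)
  }
})

test_that("kabsch always returns a proper rotation, even for mirrored inputs", {
  set.seed(8)
  for (rep in 1:10) {
    a <- matrix(rnorm(15), 5, 3)
    b <- a %*% diag(c(-1, 1, 1))     # reflected copy tempts det -1
    sup <- kabsch_superpose(a, b)
    expect_equal(det(sup$rotation), 1, tolerance = 1e-6)
  }
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)),
               "degenerate")
  line <- cbind(1:5, 0, 0)
  expect_warning(kabsch_superpose(line, line), "collinear")
})

test_that("fit_rmsd never exceeds the unfitted RMSD", {
  set.seed(9)
  for (rep in 1:20) {
    a <- matrix(rnorm(24), 8, 3)
    b <- matrix(rnorm(24), 8, 3)
    expect_lte(kabsch_superpose(a, b)$fit_rmsd, rmsd(a, b) + 1e-12)
  }
})

test_that("loop_rmsd is zero on identical structures and exact on rigid loop shifts", {
  spec <- fixture_spec(seed = 21, n_conformations = 2,
                       members_per_conformation = c(1L, 1L),
                       intra_noise_sigma = 0, inter_conformation_shift = 2)
  ref <- make_toy_chain(spec, 0L)
  expect_equal(loop_rmsd(ref$structure, ref$structure, ref$regions), 0)
  # conformation 1: loop rigidly displaced 2 A perpendicular, framework fixed
  shifted <- make_toy_chain(spec, 1L)$structure
  expect_equal(loop_rmsd(shifted, ref$structure, ref$regions), 2,
               tolerance = 1e-6)
})

test_that("loop_rmsd equals an independent two-step computation", {
  skip_if_not_installed("bio3d")
  tp <- toy_regions_pair(seed = 31, sigma = 0.4)
  got <- loop_rmsd(tp$model, tp$reference, tp$regions)
  # oracle: bio3d superposition on framework + explicit RMSD formula
  fw_m <- backbone(tp$model)[in_ranges(backbone(tp$model)$resno,
                                       tp$regions$framework), ]
  fw_r <- backbone(tp$reference)[in_ranges(backbone(tp$reference)$resno,
                                           tp$regions$framework), ]
  lp_rng <- list(tp$regions$loops$H3)
  lp_m <- backbone(tp$model)[in_ranges(backbone(tp$model)$resno, lp_rng), ]
  lp_r <- backbone(tp$reference)[in_ranges(backbone(tp$reference)$resno,
                                           lp_rng), ]
  all_m <- rbind(fw_m, lp_m); all_r <- rbind(fw_r, lp_r)
  xyz_m <- as.vector(t(as.matrix(all_m[, c("x", "y", "z")])))
  xyz_r <- as.vector(t(as.matrix(all_r[, c("x", "y", "z")])))
  fit_inds <- seq_len(nrow(fw_m) * 3)
  moved <- bio3d::fit.xyz(fixed = xyz_r, mobile = xyz_m,
                          fixed.inds = fit_inds, mobile.inds = fit_inds)
  loop_inds <- seq(nrow(fw_m) * 3 + 1, length(xyz_m))
  dx <- matrix(moved[loop_inds] - xyz_r[loop_inds], ncol = 3, byrow = TRUE)
  oracle <- sqrt(mean(rowSums(dx^2)))
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("loop_rmsd is symmetric and invariant under rigid transforms", {
  tp <- toy_regions_pair(seed = 41, sigma = 0.3)
  d_ab <- loop_rmsd(tp$model, tp$reference, tp$regions)
  d_ba <- loop_rmsd(tp$reference, tp$model, tp$regions)
  expect_equal(d_ab, d_ba, tolerance = 1e-6)
  set.seed(5)
  moved <- transform_structure(tp$model, random_rotation(), rnorm(3, sd = 20))
  expect_equal(loop_rmsd(moved, tp$reference, tp$regions), d_ab,
               tolerance = 1e-6)
})

test_that("loop_rmsd errors on missing residues and unknown loops", {
  tp <- toy_regions_pair(seed = 51)
  broken <- tp$model
  loop_start <- tp$regions$loops$H3[1]
  broken$atoms <- broken$atoms[broken$atoms$resno != loop_start, ]
  expect_error(loop_rmsd(broken, tp$reference, tp$regions),
               as.character(loop_start))
  expect_error(loop_rmsd(tp$model, tp$reference, tp$regions, loop = "L1"),
               "L1")
  # missing backbone atom in a framework residue is a hard error
  noca <- tp$model
  drop_row <- which(noca$atoms$resno == 1 & noca$atoms$elety == "CA")
  noca$atoms <- noca$atoms[-drop_row, ]
  expect_error(loop_rmsd(noca, tp$reference, tp$regions), "backbone")
})

test_that("three-atom backbone variant excludes carbonyl oxygen", {
  tp <- toy_regions_pair(seed = 61, sigma = 0)
  # model = reference with only the loop O atoms displaced by 3 A
  model <- tp$reference
  sel <- model$atoms$elety == "O" &
    in_ranges(model$atoms$resno, list(tp$regions$loops$H3))
  model$atoms$z[sel] <- model$atoms$z[sel] + 3
  with_o <- loop_rmsd(model, tp$reference, tp$regions)
  without_o <- loop_rmsd(model, tp$reference, tp$regions,
                         atom_set = c("N", "CA", "C"))
  # O is 1 of 4 backbone atoms: RMSD = 3 * sqrt(1/4) = 1.5
  expect_equal(with_o, 1.5, tolerance = 1e-6)
  expect_lt(without_o, 1e-9)
})

test_that("pairwise distances are symmetric, zero-diagonal, and match per-pair calls", {
  spec <- fixture_spec(seed = 71, n_conformations = 2,
                       members_per_conformation = c(3L, 2L),
                       intra_noise_sigma = 0.25)
  gen <- make_planted_ensemble(spec)
  dm <- pairwise_loop_distances(gen$ensemble, gen$regions)
  expect_equal(dm$values, t(dm$values), tolerance = 1e-6)
  expect_equal(diag(dm$values), rep(0, 5), ignore_attr = TRUE)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(dm$values[i, j],
                 loop_rmsd(gen$ensemble$members[[i]],
                           gen$ensemble$members[[j]], gen$regions),
                 tolerance = 1e-9)
  }
  ident <- new_ensemble(rep(list(gen$ensemble$members[[1]]), 3))
  dm0 <- pairwise_loop_distances(ident, gen$regions)
  expect_equal(max(dm0$values), 0)
})

test_that("region configs round-trip through YAML", {
  tp <- toy_regions_pair(seed = 81)
  tf <- withr::local_tempfile(fileext = ".yaml")
  write_region_config(tp$regions, tf)
  back <- read_region_config(tf)
  expect_equal(back$chain, tp$regions$chain)
  expect_equal(back$framework, tp$regions$framework)
  expect_equal(back$loops, tp$regions$loops)
  expect_error(region_definition("H", list(c(1, 10)), list(H3 = c(5, 12))),
               "disjoint")
  expect_error(region_definition("H", list(c(1, 10)), list(X9 = c(12, 15))),
               "unknown loop")
})
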