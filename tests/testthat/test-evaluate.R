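test_that("kabsch superposition is exact on identical and rigid pairs", {
  set.seed(1)
  P <- matrix(rnorm(30), 10, 3)
  expect_lt(kabsch_superpose(P, P)$rmsd, 1e-12)
  R <- random_rotation()
  Q <- P %*% t(R) + matrix(c(4, -2, 7), 10, 3, byrow = TRUE)
  fit <- kabsch_superpose(Q, P)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  expect_error(kabsch_superpose(P, P[1:5, ]), "differ in length")
})

test_that("kabsch agrees with the quaternion oracle on random pairs", {
  set.seed(2)
  for (r in 1:100) {
    n <- sample(10:200, 1)
    P <- matrix(rnorm(3 * n, sd = 5), n, 3)
    Q <- P %*% t(random_rotation()) + matrix(rnorm(3), n, 3, byrow = TRUE) +
      matrix(rnorm(3 * n, sd = runif(1, 0, 2)), n, 3)
    expect_equal(kabsch_superpose(P, Q)$rmsd, quaternion_rmsd(P, Q),
                 tolerance = 1e-8)
  }
})

test_that("collinear point sets are flagged degenerate but still scored", {
  P <- cbind(1:5, 0, 0) * 1.0
  fit <- kabsch_superpose(P, P)
  expect_true(fit$degenerate)
  expect_lt(fit$rmsd, 1e-10)
})

test_that("region RMSD is zero for self and respects the fit convention", {
  b <- fx_bundle()
  regions <- evaluation_regions(b)
  rr <- region_rmsd(b, b, regions)
  expect_true(all(rr$rmsd < 1e-10))
  # ECL2 displaced rigidly: per-region fit gives 0 there, full model > 0
  co <- b$coords
  reg <- receptor_regions(b)
  for (a in dimnames(co)[[2]])
    co[reg$ECL2, a, ] <- co[reg$ECL2, a, ] + matrix(c(2, 0, 0),
                                                    length(reg$ECL2), 3,
                                                    byrow = TRUE)
  m <- receptor_entry("shifted", b$sequence, coords = co,
                      tm_segments = b$tm_segments, disulfides = b$disulfides)
  rr2 <- region_rmsd(m, b, regions)
  expect_lt(rr2$rmsd[rr2$region == "TM"], 1e-10)
  expect_lt(rr2$rmsd[rr2$region == "ECL2"], 1e-10)
  expect_gt(rr2$rmsd[rr2$region == "FullModel"], 0.1)
  # global fit sees the displacement in ECL2
  rr3 <- region_rmsd(m, b, regions, fit = "global")
  expect_gt(rr3$rmsd[rr3$region == "ECL2"], 1.5)
})

test_that("residues missing in either structure are excluded pairwise", {
  b <- fx_bundle()
  regions <- evaluation_regions(b)
  co <- b$coords
  co[10:20, , ] <- NA
  m <- receptor_entry("gappy", b$sequence, coords = co,
                      tm_segments = b$tm_segments, disulfides = b$disulfides)
  rr <- region_rmsd(m, b, regions)
  expect_equal(rr$n_atoms[rr$region == "FullModel"],
               nchar(b$sequence) - 11L)
  expect_true(all(rr$rmsd < 1e-10))
})

test_that("gaussian perturbation yields the chi-square RMSD expectation", {
  b <- fx_bundle()
  regions <- evaluation_regions(b)
  sigma <- 0.5
  set.seed(3)
  co <- b$coords
  L <- nchar(b$sequence)
  co[, "CA", ] <- co[, "CA", ] + matrix(rnorm(3 * L, sd = sigma), L, 3)
  m <- receptor_entry("noisy", b$sequence, coords = co,
                      tm_segments = b$tm_segments, disulfides = b$disulfides)
  rr <- region_rmsd(m, b, regions)
  for (rg in c("TM", "FullModel")) {
    n <- rr$n_atoms[rr$region == rg]
    # superposition removes 6 dof: RMSD^2 ~ sigma^2 chi^2_{3n-6} / n
    expv <- sigma^2 * (3 * n - 6) / n
    sdv <- sigma^2 * sqrt(2 * (3 * n - 6)) / n
    expect_lt(abs(rr$rmsd[rr$region == rg]^2 - expv), 3 * sdv)
  }
})

test_that("fold change is exactly 1 against itself and scales linearly", {
  runs <- data.frame(target = rep(c("r1", "r2", "r3"), each = 4),
                     rmsd = c(1.2, 1.4, 1.1, 1.3, 2.0, 2.2, 2.4, 1.9,
                              0.8, 0.9, 1.0, 0.7))
  fc <- fold_change(runs, runs)
  expect_true(all(fc$per_target$ratio == 1))
  expect_equal(fc$summary, 1)
  doubled <- transform(runs, rmsd = 2 * rmsd)
  fc2 <- fold_change(doubled, runs)
  expect_equal(fc2$per_target$ratio, rep(2, 3))
  expect_equal(fc2$summary, 2)
  # random tables against a direct recomputation
  set.seed(4)
  for (r in 1:20) {
    m <- data.frame(target = sample(c("a", "b"), 20, TRUE), rmsd = runif(20, 0.5, 4))
    ref <- data.frame(target = sample(c("a", "b"), 20, TRUE), rmsd = runif(20, 0.5, 4))
    fc3 <- fold_change(m, ref)
    for (tg in fc3$per_target$target) {
      expect_equal(fc3$per_target$ratio[fc3$per_target$target == tg],
                   mean(m$rmsd[m$target == tg]) / mean(ref$rmsd[ref$target == tg]))
    }
  }
  # a zero reference mean is flagged as NA
  zref <- data.frame(target = "a", rmsd = 0)
  zm <- data.frame(target = "a", rmsd = 1)
  expect_true(is.na(fold_change(zm, zref)$per_target$ratio))
})

test_that("the experiment harness emits one summary row per condition x region", {
  fam <- fx_family30()
  res <- experiment_harness(fam, template_counts = c(1, 2), n_models = 2L,
                            steps = 120L, seed = 5L, threshold_max = 100)
  expect_equal(nrow(res), 2L * 3L)
  expect_setequal(unique(res$condition), c("1", "2"))
  expect_setequal(unique(res$region), c("TM", "ECL2", "FullModel"))
  expect_true(all(res$mean >= res$min & res$mean <= res$max))
  res2 <- experiment_harness(fam, template_counts = c(1, 2), n_models = 2L,
                             steps = 120L, seed = 5L, threshold_max = 100)
  expect_identical(res, res2)
})
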