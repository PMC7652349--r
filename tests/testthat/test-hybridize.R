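test_that("score terms follow their stated formulas", {
  # two CA atoms forced 2 A apart contribute (4-2)^2 = 4 to clash
  ca <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0), c(7.6, 3.8, 0),
              c(3.8, 3.8, 0), c(2, 0.4, 0))
  # residue 6 sits 2.0 A from residue 1 (non-adjacent)
  ca[6, ] <- c(2, 0, 0)
  co <- backbone_from_ca(ca)
  d16 <- sqrt(sum((ca[1, ] - ca[6, ])^2))
  sc <- score_model(list(coords = co), list(weights = default_score_weights()))
  other_close <- as.matrix(dist(ca))
  other_close[cbind(1:5, 2:6)] <- 99; other_close[cbind(2:6, 1:5)] <- 99
  diag(other_close) <- 99
  expected_clash <- sum(pmax(0, 4 - other_close[upper.tri(other_close)])^2)
  expect_equal(sc$terms[["clash"]], expected_clash)
  expect_gte(sc$terms[["clash"]], (4 - d16)^2)
  # chainbreak on an ideal 3.8 chain is ~0
  ideal <- backbone_from_ca(cbind(3.8 * (1:6), 0, 0))
  sc2 <- score_model(list(coords = ideal), list())
  expect_lt(sc2$terms[["chainbreak"]], 1e-20)
  # satisfied disulfide scores zero; a stretched one follows max(0, d-5)^2
  cb <- backbone_from_ca(rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0),
                               c(11.4, 0, 0)))
  cb[1, "CB", ] <- c(0, 1, 0); cb[4, "CB", ] <- c(0, 5, 0)   # 4 A apart
  sc3 <- score_model(list(coords = cb), list(disulfides = cbind(1L, 4L)))
  expect_equal(sc3$terms[["disulfide"]], 0)
  cb[4, "CB", ] <- c(0, 8, 0)   # 7 A apart -> (7-5)^2
  sc4 <- score_model(list(coords = cb), list(disulfides = cbind(1L, 4L)))
  expect_equal(sc4$terms[["disulfide"]], 4)
  expect_error(score_model(list(coords = empty_coords(5)), list()),
               "incomplete")
})

test_that("the total equals an independent re-summation of weighted terms", {
  set.seed(6)
  w <- default_score_weights()
  b <- fx_bundle()
  threads <- fx_regional_threads()
  L <- nchar(b$sequence)
  cons <- b$coords[, "CA", ]
  for (r in 1:20) {
    co <- b$coords
    for (a in dimnames(co)[[2]]) co[, a, ] <- co[, a, ] + rnorm(L * 3, sd = runif(1, 0, 1.5))
    ann <- list(ss = sample(c("H", "L"), L, TRUE), disulfides = b$disulfides,
                rg_ref = runif(1, 15, 25), consensus = cons, weights = w)
    sc <- score_model(list(coords = co), ann)
    expect_equal(sc$total, sum(w[names(sc$terms)] * sc$terms))
  }
})

test_that("fragment libraries cover every position at both lengths", {
  threads <- fx_regional_threads()
  L <- nchar(fx_bundle()$sequence)
  ss <- rep("L", L)
  lib <- build_fragment_library(threads, ss)
  for (len in c(3L, 9L)) {
    for (pos in seq_len(L - len + 1L)) {
      frs <- lib[[paste0(pos, "_", len)]]
      expect_gte(length(frs), 1L)
      # the ideal fallback is always present
      expect_true(any(vapply(frs, function(f) f$tag == "frag:ideal", logical(1))))
    }
  }
  # a fully-covering template contributes its own fragments where SS agrees
  obs <- classify_ss_ca(threads[[1]]$coords[, "CA", ])
  lib2 <- build_fragment_library(threads[1], obs)
  some <- lib2[["40_9"]]
  expect_true(any(vapply(some, function(f) grepl("tz1", f$tag), logical(1))))
})

test_that("hybridization is deterministic and keeps provenance valid", {
  threads <- fx_regional_threads()
  b <- fx_bundle()
  m1 <- hybridize(threads, n_models = 2L, steps = 150L, seed = 9L,
                  constraints = b$disulfides)
  m2 <- hybridize(threads, n_models = 2L, steps = 150L, seed = 9L,
                  constraints = b$disulfides)
  expect_identical(serialize(m1, NULL), serialize(m2, NULL))
  valid <- c(paste0("tz", 1:5), NA)
  for (m in m1) {
    expect_true(all(m$provenance %in% valid | startsWith(m$provenance, "frag:")))
    expect_false(anyNA(m$coords))
  }
  expect_error(hybridize(list()), "zero templates")
})

test_that("the running best score never increases along a trajectory", {
  threads <- fx_regional_threads()
  b <- fx_bundle()
  models <- hybridize(threads, n_models = 3L, steps = 400L, seed = 4L,
                      constraints = b$disulfides)
  for (m in models) {
    expect_true(all(diff(cummin(m$trajectory)) <= 0))
    expect_lte(m$total, m$trajectory[1])
  }
})

test_that("a single complete thread survives hybridization nearly unchanged", {
  b <- fx_bundle()
  th <- partial_thread(b$sequence, b$sequence, b, target_id = b$id)
  models <- hybridize(list(th), n_models = 1L, steps = 400L, seed = 2L,
                      constraints = b$disulfides, t_hi = 0.02, t_lo = 0.01)
  best <- select_best(models)
  rr <- region_rmsd(best, b, evaluation_regions(b))
  expect_lt(rr$rmsd[rr$region == "FullModel"], 0.5)
})

test_that("select_best takes the argmin with ties to the lowest index", {
  mk <- function(tot, i) structure(list(total = tot, model_index = i),
                                   class = "hybrid_model")
  models <- list(mk(3.2, 1), mk(1.1, 2), mk(7.0, 3))
  expect_equal(select_best(models)$model_index, 2)
  ties <- list(mk(2, 1), mk(2, 2), mk(2, 3))
  expect_equal(select_best(ties)$model_index, 1)
  expect_error(select_best(list()), "empty")
  set.seed(8)
  for (r in 1:100) {
    tot <- runif(sample(2:10, 1))
    models <- lapply(seq_along(tot), function(i) mk(tot[i], i))
    expect_equal(select_best(models)$model_index, which.min(tot))
  }
})

test_that("hybridizing regionally-accurate templates beats each thread", {
  b <- fx_bundle()
  threads <- fx_regional_threads()
  regions <- evaluation_regions(b)
  thread_rmsd <- vapply(threads, function(th)
    region_rmsd(th, b, regions)$rmsd[3], numeric(1))
  models <- hybridize(threads, n_models = 3L, steps = 1500L, seed = 31L,
                      constraints = b$disulfides)
  best <- select_best(models)
  best_rmsd <- region_rmsd(best, b, regions)$rmsd[3]
  expect_lt(best_rmsd, min(thread_rmsd))
})
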