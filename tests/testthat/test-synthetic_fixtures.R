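test_that("ideal bundles have clean chain geometry and planted features", {
  b <- fx_bundle()
  ca <- b$coords[, "CA", ]
  d <- sqrt(rowSums((ca[-1, ] - ca[-nrow(ca), ])^2))
  expect_true(all(abs(d - 3.8) <= 0.2))
  expect_equal(nrow(b$tm_segments), 7L)
  expect_equal(nrow(b$disulfides), 1L)
  # disulfide partners are cysteines in contact proximity
  sq <- strsplit(b$sequence, "")[[1]]
  expect_true(all(sq[b$disulfides] == "C"))
  dss <- sqrt(sum((b$coords[b$disulfides[1, 1], "CB", ] -
                   b$coords[b$disulfides[1, 2], "CB", ])^2))
  expect_lt(dss, 5)
  # clash-free: no non-adjacent CA pair below 4 A
  dm <- as.matrix(dist(ca))
  dm[abs(row(dm) - col(dm)) <= 1] <- Inf
  expect_gt(min(dm), 4)
  # anchor motifs present (DRY around 3.50, NPxxY around 7.50)
  a <- b$tm_segments$anchor
  expect_equal(paste(sq[(a[3] - 1):(a[3] + 1)], collapse = ""), "DRY")
  expect_equal(sq[a[7]], "P")
  expect_equal(sq[a[7] + 3], "Y")
})

test_that("bundle generation is deterministic under seed", {
  b1 <- make_ideal_bundle(seed = 77)
  b2 <- make_ideal_bundle(seed = 77)
  expect_identical(serialize(b1, NULL), serialize(b2, NULL))
  b3 <- make_ideal_bundle(seed = 78)
  expect_false(identical(b1$sequence, b3$sequence))
})

test_that("helix CA traces fit the ideal rise by axis regression", {
  b <- fx_bundle()
  reg <- receptor_regions(b)
  for (h in 1:7) {
    hx <- b$coords[reg[[paste0("TM", h)]], "CA", ]
    axis <- prcomp(hx)$rotation[, 1]
    proj <- hx %*% axis
    expect_lt(abs(mean(abs(diff(proj))) - 1.5), 0.1)
  }
})

test_that("zero mutation rate reproduces the ancestor sequence", {
  fam <- evolve_family(fx_bundle(), n_members = 3, mutation_rate = 0,
                       indel_rate = 0, noise_sigma = 0, seed = 1)
  for (m in fam$members)
    expect_identical(m$sequence, fx_bundle()$sequence)
  expect_false(grepl("-", paste(fam$truth_alignment$rows, collapse = "")))
})

test_that("identity calibration lands near its target", {
  fam <- evolve_family(fx_bundle(), n_members = 10, target_identity = 30,
                       seed = 303)
  idm <- pairwise_identity(fam$truth_alignment)
  members <- setdiff(rownames(idm), fam$ancestor$id)
  sub <- idm[members, members]
  expect_lt(abs(mean(sub[lower.tri(sub)]) - 30), 10)
})

test_that("indels restricted to loops leave TM truth columns gap-free", {
  fam <- fx_family30()
  truth <- fam$truth_alignment
  mat <- do.call(rbind, strsplit(truth$rows, ""))
  tm_cols <- truth_tm_cols(truth)
  expect_false(any(mat[, tm_cols] == "-"))
})

test_that("families are deterministic and chains stay connected", {
  f1 <- evolve_family(fx_bundle(), n_members = 4, seed = 55)
  f2 <- evolve_family(fx_bundle(), n_members = 4, seed = 55)
  expect_identical(serialize(f1, NULL), serialize(f2, NULL))
  for (m in f1$members) {
    ca <- m$coords[, "CA", ]
    d <- sqrt(rowSums((ca[-1, ] - ca[-nrow(ca), ])^2))
    expect_true(all(d > 2.8 & d < 4.8))
  }
})

test_that("truth alignment rows ungap to the member sequences", {
  fam <- fx_family30()
  truth <- fam$truth_alignment
  expect_equal(length(unique(nchar(truth$rows))), 1L)
  expect_identical(ungap(truth$rows[[fam$ancestor$id]]), fam$ancestor$sequence)
  for (id in names(fam$members))
    expect_identical(ungap(truth$rows[[id]]), fam$members[[id]]$sequence)
})

test_that("overlong loops are rejected as geometrically impossible", {
  expect_error(make_ideal_bundle(loop_lengths = c(1L, 5L, 5L, 12L, 7L, 5L)))
})

test_that("identity-tied noise plants a monotone accuracy gradient", {
  b <- fx_bundle()
  pf <- length(attr(b, "protected")) / nchar(b$sequence)
  rates <- vapply(rep(c(34, 22), each = 2), mutation_rate_for_identity,
                  numeric(1), protected_frac = pf, relative_to = "ancestor")
  fam <- evolve_family(b, n_members = 4, mutation_rate = rates,
                       noise_from_identity = function(id)
                         0.3 * exp((34.5 - id) / 11.6) +
                         5 / (1 + exp((id - 19.5) / 0.8)),
                       indel_rate = 0, seed = 8)
  rms <- vapply(fam$members, function(m)
    kabsch_superpose(m$coords[, "CA", ], b$coords[, "CA", ])$rmsd, numeric(1))
  expect_gt(mean(rms[3:4]), mean(rms[1:2]))
})
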