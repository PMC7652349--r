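test_that("BW numbering is anchored at x.50 and increases with position", {
  seg <- data.frame(helix = 3, start = 110, end = 139, anchor = 120)
  entry <- receptor_entry("r", paste(rep("A", 150), collapse = ""),
                          tm_segments = data.frame(helix = 1:7,
                                                   start = c(1, 21, 110, 141, 143, 145, 147),
                                                   end = c(10, 30, 139, 141, 143, 145, 147),
                                                   anchor = c(5, 25, 120, 141, 143, 145, 147)))
  bw <- assign_bw_numbers(entry)
  expect_equal(unname(bw["120"]), "3.50")
  expect_equal(unname(bw["121"]), "3.51")
  expect_equal(unname(bw["118"]), "3.48")
  helix3 <- bw[as.character(110:139)]
  expect_equal(length(unique(helix3)), 30L)
  nums <- as.numeric(sub("3\\.", "", helix3))
  expect_true(all(diff(nums) == 1))
})

test_that("two identical entries align without gaps, anchors co-columnar", {
  b <- fx_bundle()
  b2 <- receptor_entry("copy", b$sequence, coords = b$coords,
                       tm_segments = b$tm_segments, disulfides = b$disulfides)
  tm <- align_tm_segments(list(b, b2))
  expect_true(all(vapply(tm$columns, length, integer(1)) == 2L))
  for (h in 1:7) {
    ac <- tm$columns[[tm$anchor_col[[sprintf("%d.50", h)]]]]
    expect_equal(unname(ac[1]), unname(ac[2]))
    expect_equal(unname(ac[[1]]), b$tm_segments$anchor[h])
  }
})

test_that("a planted mid-helix bulge becomes an insertion column", {
  b <- fx_bundle()
  # build a member with one extra residue bulging out of TM5
  seg <- b$tm_segments
  at <- seg$anchor[5] + 4L   # insertion point, inside TM5, past the anchor
  L <- nchar(b$sequence)
  sq <- strsplit(b$sequence, "")[[1]]
  sq2 <- c(sq[1:at], "W", sq[(at + 1):L])
  ca <- b$coords[, "CA", ]
  bulge <- (ca[at, ] + ca[at + 1, ]) / 2 + 2.6 * c(0, 0, 1)
  ca2 <- rbind(ca[1:at, ], bulge, ca[(at + 1):L, ])
  co2 <- backbone_from_ca(ca2)
  shift <- function(v) ifelse(v > at, v + 1L, v)
  seg2 <- transform(seg, start = shift(start), end = shift(end),
                    anchor = shift(anchor))
  seg2$end[5] <- seg2$end[5] + 1L   # helix 5 grew by one residue
  m <- receptor_entry("bulged", paste(sq2, collapse = ""), coords = co2,
                      tm_segments = seg2, disulfides = shift(b$disulfides))
  others <- lapply(1:3, function(k) {
    co <- b$coords
    set.seed(900 + k)
    for (a in dimnames(co)[[2]]) co[, a, ] <- co[, a, ] + rnorm(length(co[, a, ]), sd = 0.1)
    receptor_entry(paste0("o", k), b$sequence, coords = co,
                   tm_segments = b$tm_segments, disulfides = b$disulfides)
  })
  entries <- c(list(b), others, list(m))
  tm <- align_tm_segments(entries)
  # one insertion column inside TM5, containing only the bulged member
  ins <- which(tm$insert & tm$helix_of == 5L)
  expect_length(ins, 1L)
  expect_equal(names(tm$columns[[ins]]), "bulged")
  expect_equal(unname(tm$columns[[ins]][[1]]), at + 1L)
  # anchors remain co-columnar for every helix
  for (h in 1:7) {
    ac <- tm$columns[[tm$anchor_col[[sprintf("%d.50", h)]]]]
    expect_length(ac, 5L)
  }
})

test_that("loop residues of identical copies self-align with no gaps", {
  b <- fx_bundle()
  b2 <- receptor_entry("copy", b$sequence, coords = b$coords,
                       tm_segments = b$tm_segments, disulfides = b$disulfides)
  lp <- align_loops_structural(list(b, b2))
  for (ln in c("ICL1", "ECL1", "ICL2", "ECL2", "ICL3", "ECL3")) {
    expect_true(all(vapply(lp[[ln]]$columns, length, integer(1)) == 2L))
    expect_length(lp[[ln]]$unaligned, 0L)
  }
})

test_that("antiparallel CA->CB vectors refuse to share a column", {
  b <- fx_bundle()
  flip <- b$coords
  reg <- receptor_regions(b)
  for (p in reg$ICL3)   # point the CB vectors the opposite way
    flip[p, "CB", ] <- 2 * flip[p, "CA", ] - flip[p, "CB", ]
  b2 <- receptor_entry("flipped", b$sequence, coords = flip,
                       tm_segments = b$tm_segments, disulfides = b$disulfides)
  lp <- align_loops_structural(list(b, b2))
  expect_equal(sort(lp$ICL3$unaligned$flipped), reg$ICL3)
})

test_that("family MSA recovers ground-truth TM and conserved loop columns", {
  fam <- fx_family30()
  msa <- fx_msa30()
  truth <- fam$truth_alignment
  r <- alignment_recovery(msa, truth, truth_tm_cols(truth), names(truth$rows))
  expect_gte(r["recovered"] / r["total"], 0.95)
  checks <- conserved_loop_checks(fam)
  ok <- 0L; tot <- 0L
  for (ln in names(checks)) {
    r <- alignment_recovery(msa, truth, checks[[ln]]$cols, checks[[ln]]$rows)
    ok <- ok + r["recovered"]; tot <- tot + r["total"]
  }
  expect_gte(ok / tot, 0.90)
})

test_that("MSA invariants hold: equal widths, rows ungap to sources", {
  msa <- fx_msa30()
  entries <- fx_entries30()
  expect_equal(unique(nchar(msa$rows)), msa$width)
  for (id in names(entries))
    expect_identical(ungap(msa$rows[[id]]), entries[[id]]$sequence)
  masks <- unlist(msa$region_masks, use.names = FALSE)
  expect_false(anyDuplicated(masks) > 0)
})

test_that("unalignable residues pack against the nearest defined flank", {
  # row b: defined at cols 1 and 9 ('H'), two free residues closer to the
  # right flank -> packed right
  rows <- c(a = "HXXXXXXXH", b = "H---WW--H")
  msa <- new_msa(rows, aligned_cols = c(1L, 9L))
  out <- place_unalignable_residues(msa)
  expect_equal(unname(out$rows["b"]), "H-----WWH")
  # idempotent
  out2 <- place_unalignable_residues(out)
  expect_identical(out2$rows, out$rows)
  # no unaligned residues: unchanged
  msa2 <- new_msa(c(a = "HWH", b = "HWH"), aligned_cols = 1:3)
  expect_identical(place_unalignable_residues(msa2)$rows, msa2$rows)
  # tie goes to the N-terminal flank
  rows3 <- c(a = "HXXXXXH", b = "H--W--H")
  out3 <- place_unalignable_residues(new_msa(rows3, aligned_cols = c(1L, 7L)))
  expect_equal(unname(out3$rows["b"]), "HW----H")
})

test_that("packing leaves no residue separated from structure by a gap", {
  set.seed(21)
  for (r in 1:30) {
    w <- sample(10:40, 1)
    rows <- vapply(1:4, function(i) {
      ch <- sample(c("A", "C", "-", "-"), w, TRUE)
      ch[c(1, w)] <- "M"
      paste(ch, collapse = "")
    }, character(1))
    names(rows) <- paste0("s", 1:4)
    defined <- sort(unique(c(1L, w, sample(seq_len(w), 3))))
    out <- place_unalignable_residues(new_msa(rows, aligned_cols = defined))
    mat <- do.call(rbind, strsplit(out$rows, ""))
    defset <- out$aligned_cols
    for (i in 1:4) {
      occ <- which(mat[i, ] != "-")
      freeruns <- split(occ[!occ %in% defset],
                        cumsum(c(1, diff(occ[!occ %in% defset]) != 1)))
      for (run in freeruns) {
        if (!length(run)) next
        # the run must touch a defined column of this row or the MSA edge
        touch <- (min(run) - 1) %in% c(0L, occ[occ %in% defset]) ||
                 (max(run) + 1) %in% c(out$width + 1L, occ[occ %in% defset])
        expect_true(touch)
      }
    }
  }
})

test_that("pairwise identity matches hand values and the counting oracle", {
  msa <- new_msa(c(a = "ACDEF", b = "ACDFF"))
  idm <- pairwise_identity(msa)
  expect_equal(idm["a", "b"], 80)
  expect_equal(diag(idm), c(a = 100, b = 100))
  idm2 <- pairwise_identity(new_msa(c(x = "AAAA", y = "AAAA")))
  expect_equal(idm2["x", "y"], 100)
  set.seed(5)
  for (r in 1:50) {
    w <- sample(4:60, 1)
    mk <- function() paste(sample(c("A", "C", "D", "-"), w, TRUE), collapse = "")
    rows <- c(p = mk(), q = mk())
    if (any(!grepl("[^-]", rows))) next
    idm <- pairwise_identity(new_msa(rows), region_mask = seq_len(w))
    expect_equal(idm["p", "q"], identity_oracle(rows[1], rows[2]))
    expect_equal(idm["p", "q"], idm["q", "p"])
  }
})

test_that("identity matrix entries stay in [0, 100] on the family MSA", {
  idm <- pairwise_identity(fx_msa30())
  expect_true(all(idm >= 0 & idm <= 100, na.rm = TRUE))
  expect_true(isSymmetric(idm))
  expect_true(all(diag(idm) == 100))
})
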