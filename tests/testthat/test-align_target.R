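test_that("a target identical to a template adopts that template's row", {
  msa <- fx_msa30()
  fam <- fx_family30()
  tid <- names(fam$members)[1]
  out <- align_target_to_msa(fam$members[[tid]]$sequence, msa,
                             tm_predictions = fam$members[[tid]]$tm_segments,
                             target_id = "tgt")
  expect_identical(unname(out$rows["tgt"]), unname(msa$rows[[tid]]))
})

test_that("ICL3 splits at the halfway point, extra residue N-terminal", {
  expect_equal(split_loop_lengths(9L), c(5L, 4L))
  expect_equal(split_loop_lengths(8L), c(4L, 4L))
  b <- fx_bundle()
  fam <- fx_family30()
  msa <- fx_msa30()
  # mutate the target everywhere unprotected so the fast path cannot fire,
  # keeping length and annotations identical to the ancestor
  sq <- strsplit(b$sequence, "")[[1]]
  set.seed(33)
  mut <- setdiff(seq_along(sq), attr(b, "protected"))
  for (i in mut) sq[i] <- sample(setdiff(c("A", "C", "D", "E", "F", "G"), sq[i]), 1)
  tseq <- paste(sq, collapse = "")
  out <- align_target_to_msa(tseq, msa, tm_predictions = b$tm_segments,
                             target_id = "tgt")
  row <- strsplit(out$rows[["tgt"]], "")[[1]]
  expect_identical(ungap(out$rows[["tgt"]]), tseq)
  # the ICL3 pool must abut TM5's last and TM6's first target columns with
  # the gap block in the middle
  reg <- receptor_regions(b)
  icl3 <- reg$ICL3
  occ <- which(row != "-")
  pos_of <- cumsum(row != "-")
  cols <- vapply(icl3, function(p) occ[which(pos_of[occ] == p)[1]], integer(1))
  n <- length(icl3)
  nL <- ceiling(n / 2)
  expect_true(all(diff(cols[1:nL]) == 1))                   # left half contiguous
  expect_true(all(diff(cols[(nL + 1):n]) == 1))             # right half contiguous
  expect_gte(cols[nL + 1] - cols[nL], 1)    # any slack sits in the middle
  # left half adjoins the TM5 end column
  tm5_end_col <- max(which(pos_of == reg$TM5[length(reg$TM5)] & row != "-"))
  expect_equal(cols[1], tm5_end_col + 1L)
  # right half adjoins the TM6 start column
  tm6_start_col <- min(which(pos_of == reg$TM6[1] & row != "-"))
  expect_equal(cols[n], tm6_start_col - 1L)
})

test_that("a mutated family member re-aligns to its ground-truth TM columns", {
  fam <- fx_family30()
  msa_full <- fx_msa30()
  truth <- fam$truth_alignment
  tid <- names(fam$members)[2]
  # rebuild the template MSA without the target member
  entries <- fx_entries30()
  msa <- build_template_msa(entries[setdiff(names(entries), tid)])
  tgt <- fam$members[[tid]]
  out <- align_target_to_msa(tgt$sequence, msa, tm_predictions = tgt$tm_segments,
                             disulfides = tgt$disulfides, target_id = tid)
  # compare target TM columns against the ground truth through co-columns
  r <- alignment_recovery(out, truth, truth_tm_cols(truth),
                          c(fam$ancestor$id, tid))
  expect_gte(r["recovered"] / r["total"], 0.95)
})

test_that("motif fallback resolves helices and failures are named", {
  fam <- fx_family30()
  msa <- fx_msa30()
  b <- fx_bundle()
  sq <- strsplit(b$sequence, "")[[1]]
  set.seed(44)
  mut <- setdiff(seq_along(sq), attr(b, "protected"))
  for (i in mut) sq[i] <- sample(setdiff(c("H", "I", "K", "L", "M"), sq[i]), 1)
  tseq <- paste(sq, collapse = "")
  seg <- b$tm_segments
  # helix 3, 6 and 7 anchors withheld: DRY / CWxP / NPxxY must recover them
  seg$anchor[c(3, 6, 7)] <- NA_integer_
  out <- align_target_to_msa(tseq, msa, tm_predictions = seg, target_id = "tgt")
  row <- out$rows[["tgt"]]
  occ <- which(strsplit(row, "")[[1]] != "-")
  pos_of <- cumsum(strsplit(row, "")[[1]] != "-")
  for (h in c(3L, 6L, 7L)) {
    acol <- out$anchor_columns[[sprintf("%d.50", h)]]
    expect_equal(pos_of[acol], b$tm_segments$anchor[h])
  }
  # helix 1 has no default motif: withholding its anchor must fail loudly
  seg1 <- b$tm_segments
  seg1$anchor[1] <- NA_integer_
  expect_error(align_target_to_msa(tseq, msa, tm_predictions = seg1),
               "helix 1")
})

test_that("ECL2 is split at the conserved cysteine on the disulfide column", {
  fam <- fx_family30()
  msa <- fx_msa30()
  b <- fx_bundle()
  sq <- strsplit(b$sequence, "")[[1]]
  set.seed(55)
  mut <- setdiff(seq_along(sq), attr(b, "protected"))
  for (i in mut) sq[i] <- sample(setdiff(c("N", "P", "Q", "R", "S"), sq[i]), 1)
  tseq <- paste(sq, collapse = "")
  out <- align_target_to_msa(tseq, msa, tm_predictions = b$tm_segments,
                             disulfides = b$disulfides, target_id = "tgt")
  row <- strsplit(out$rows[["tgt"]], "")[[1]]
  pos_of <- cumsum(row != "-")
  ccol <- out$disulfide_columns[["ECL2"]]
  expect_equal(pos_of[ccol], unname(b$disulfides[1, 2]))
  expect_equal(row[ccol], "C")
})
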