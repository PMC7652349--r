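# Shared fixtures, built once per test run (testthat sources helpers into
# one environment for the whole directory).

.fx_cache <- new.env(parent = emptyenv())

fx_bundle <- function() {
  if (is.null(.fx_cache$bundle)) .fx_cache$bundle <- make_ideal_bundle(seed = 101L)
  .fx_cache$bundle
}

# 10-member family at ~30% identity with loop indels (the standard study
# condition for alignment recovery)
fx_family30 <- function() {
  if (is.null(.fx_cache$fam30))
    .fx_cache$fam30 <- evolve_family(fx_bundle(), n_members = 10L,
                                     target_identity = 30, indel_rate = 0.15,
                                     noise_sigma = 0.3, seed = 202L)
  .fx_cache$fam30
}

fx_entries30 <- function() {
  fam <- fx_family30()
  c(stats::setNames(list(fam$ancestor), fam$ancestor$id), fam$members)
}

fx_msa30 <- function() {
  if (is.null(.fx_cache$msa30))
    .fx_cache$msa30 <- build_template_msa(fx_entries30())
  .fx_cache$msa30
}

# five templates of the bundle, each accurate in a different region and
# noisy (sd 1.2 A) elsewhere; used for the multi-template recovery checks
fx_regional_templates <- function(seed = 42L) {
  b <- fx_bundle()
  reg <- receptor_regions(b)
  zones <- list(c(reg$TM1, reg$ICL1, reg$TM2),
                c(reg$ECL1, reg$TM3, reg$ICL2, reg$TM4),
                c(reg$ECL2, reg$TM5),
                c(reg$ICL3, reg$TM6),
                c(reg$ECL3, reg$TM7, reg$Nterm, reg$Cterm))
  set.seed(seed)
  L <- nchar(b$sequence)
  out <- list()
  for (k in seq_along(zones)) {
    co <- b$coords
    noise <- matrix(rnorm(L * 3, sd = 1.2), L, 3)
    noise[zones[[k]], ] <- matrix(rnorm(length(zones[[k]]) * 3, sd = 0.05),
                                  length(zones[[k]]), 3)
    for (a in dimnames(co)[[2]]) co[, a, ] <- co[, a, ] + noise
    id <- paste0("tz", k)
    out[[id]] <- receptor_entry(id, b$sequence, coords = co,
                                tm_segments = b$tm_segments,
                                disulfides = b$disulfides)
  }
  out
}

fx_regional_threads <- function(seed = 42L) {
  b <- fx_bundle()
  lapply(fx_regional_templates(seed), function(e)
    partial_thread(b$sequence, b$sequence, e, target_id = b$id))
}

# recovery of truth columns in a produced MSA: a truth column counts as
# recovered when every eligible row's residue lands in one shared column
alignment_recovery <- function(produced, truth, truth_cols, eligible_rows) {
  poscol <- lapply(produced$rows, function(s) which(strsplit(s, "")[[1]] != "-"))
  tmat <- do.call(rbind, strsplit(truth$rows, ""))
  rownames(tmat) <- names(truth$rows)
  tpos <- apply(tmat != "-", 1, cumsum)   # W x rows matrix
  ok <- 0L; tot <- 0L
  for (k in truth_cols) {
    rows_k <- eligible_rows[tmat[eligible_rows, k] != "-"]
    if (length(rows_k) < 2L) next
    tot <- tot + 1L
    cols <- vapply(rows_k, function(id) poscol[[id]][tpos[k, id]], integer(1))
    if (length(unique(cols)) == 1L) ok <- ok + 1L
  }
  c(recovered = ok, total = tot)
}

truth_tm_cols <- function(truth) {
  sort(unlist(truth$region_masks[paste0("TM", 1:7)], use.names = FALSE))
}

# structure-conserved loop columns and their eligible rows
conserved_loop_checks <- function(fam) {
  truth <- fam$truth_alignment
  anc <- attr(truth, "anc_pos")
  loops <- c("ICL1", "ECL1", "ICL2", "ECL2", "ICL3", "ECL3")
  out <- list()
  for (ln in loops) {
    cols <- truth$region_masks[[ln]]
    cols <- cols[!is.na(anc[cols])]
    rows <- c(fam$ancestor$id,
              names(fam$members)[fam$loop_conserved[, ln]])
    out[[ln]] <- list(cols = cols, rows = rows)
  }
  out
}
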