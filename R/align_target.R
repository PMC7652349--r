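# Alignment of a structure-less target sequence into a template MSA.
#
# TM stretches are anchored at the x.50 columns (sequence-motif fallback
# when no anchor is supplied); ICL3 is split at its halfway point and the
# halves adjoined to TM5/TM6; ECL2 is split at the conserved cysteine
# aligned to the TM3-disulfide column and each sub-loop halved onto its
# nearest fixed feature; remaining loops use motif anchors when available
# (xWxxG in ECL1) and the half-split rule otherwise. Odd-length splits
# give the extra residue to the N-terminal half.

#' Align a target sequence to a template MSA
#'
#' @param target_seq one-letter amino-acid string.
#' @param msa template alignment from [build_template_msa] (or any
#'   [new_msa] with TM region masks and anchor columns).
#' @param tm_predictions per-residue topology string over `{M, i, o}` with
#'   exactly seven membrane runs, or a data.frame with columns
#'   `helix`, `start`, `end` and optionally `anchor`.
#' @param motifs motif anchor table, see [default_motifs].
#' @param disulfides optional two-column matrix of target disulfide pairs
#'   (used to identify the conserved ECL2 cysteine).
#' @param anchors optional named integer vector ("1".."7") of x.50
#'   positions; takes precedence over motif search.
#' @param target_id row name for the target.
#' @return the MSA with the target added as the last row (columns may have
#'   been inserted to accommodate long target loops).
#' @export
align_target_to_msa <- function(target_seq, msa, tm_predictions,
                                motifs = default_motifs(),
                                disulfides = NULL, anchors = NULL,
                                target_id = "target") {
  target_seq <- toupper(target_seq)
  letters1 <- strsplit(target_seq, "")[[1L]]
  L <- length(letters1)

  # a target identical in sequence to a template adopts that template's row
  for (id in names(msa$rows)) {
    if (identical(ungap(msa$rows[[id]]), target_seq)) {
      msa$rows[target_id] <- msa$rows[[id]]
      return(msa)
    }
  }

  # --- target TM segments and anchors ---
  if (is.character(tm_predictions)) {
    sp <- topology_to_span(tm_predictions)
    if (nrow(sp$segments) != 7L)
      stop("topology must contain exactly 7 membrane runs, got ",
           nrow(sp$segments))
    seg <- data.frame(helix = 1:7, start = sp$segments[, 1L],
                      end = sp$segments[, 2L], anchor = NA_integer_)
  } else {
    seg <- as.data.frame(tm_predictions)
    if (!"anchor" %in% names(seg)) seg$anchor <- NA_integer_
  }
  anch <- stats::setNames(seg$anchor, as.character(seg$helix))
  if (!is.null(anchors)) anch[names(anchors)] <- anchors
  for (h in 1:7) {
    hc <- as.character(h)
    if (!is.na(anch[[hc]])) next
    mrow <- motifs[motifs$region == paste0("TM", h), , drop = FALSE]
    found <- NA_integer_
    if (nrow(mrow)) {
      s <- seg[seg$helix == h, ]
      lo <- max(1L, s$start - 3L); hi <- min(L, s$end + 3L)
      sub <- substr(target_seq, lo, hi)
      m <- gregexpr(motif_regex(mrow$pattern[1L]), sub)[[1L]]
      if (m[1L] != -1L) {
        cand <- lo + as.integer(m) - 1L + mrow$anchor_offset[1L] - 1L
        mid <- (s$start + s$end) / 2
        found <- cand[order(abs(cand - mid), cand)][1L]
      }
    }
    if (is.na(found))
      stop("unresolvable alignment: no x.50 anchor and no motif for helix ", h)
    anch[[hc]] <- found
  }

  # --- mutable alignment state ---
  st <- new.env(parent = emptyenv())
  st$mat <- msa_char(msa)
  st$W <- ncol(st$mat)
  st$tch <- rep("-", st$W)
  st$masks <- msa$region_masks
  st$anchor_columns <- msa$anchor_columns
  st$discols <- msa$disulfide_columns
  st$aligned <- msa$aligned_cols
  st$colins <- attr(msa, "col_insert")
  if (is.null(st$colins)) st$colins <- rep(FALSE, st$W)

  insert_cols <- function(after, n, region) {
    # n all-gap columns after column index `after` (0 = front)
    shift <- function(v) ifelse(v > after, v + n, v)
    st$mat <- cbind(st$mat[, seq_len(after), drop = FALSE],
                    matrix("-", nrow(st$mat), n),
                    if (after < st$W) st$mat[, (after + 1L):st$W, drop = FALSE])
    st$tch <- c(st$tch[seq_len(after)], rep("-", n),
                if (after < st$W) st$tch[(after + 1L):st$W])
    st$colins <- c(st$colins[seq_len(after)], rep(FALSE, n),
                   if (after < st$W) st$colins[(after + 1L):st$W])
    st$masks <- lapply(st$masks, shift)
    if (!is.null(region))
      st$masks[[region]] <- sort(c(st$masks[[region]], after + seq_len(n)))
    st$anchor_columns <- shift(st$anchor_columns)
    st$discols <- shift(st$discols)
    st$aligned <- shift(st$aligned)
    st$W <- st$W + n
  }

  put <- function(pos, cols) {
    stopifnot(length(pos) == length(cols))
    if (length(pos)) st$tch[cols] <- letters1[pos]
  }

  # pack a run of positions into a window, halves abutting the two flanks;
  # the N-terminal half gets the extra residue of an odd split
  pack_halves <- function(pool, wstart, wend, region, side = "both") {
    k <- length(pool)
    if (!k) return(invisible())
    win <- if (wstart <= wend) setdiff(wstart:wend, which(st$tch != "-")) else integer(0)
    if (k > length(win)) {
      at <- if (length(win)) win[ceiling(length(win) / 2)] else wstart - 1L
      insert_cols(at, k - length(win), region)
      wend2 <- wend + (k - length(win))
      win <- setdiff(wstart:wend2, which(st$tch != "-"))
    }
    if (side == "left") {
      put(pool, utils::head(win, k))
    } else if (side == "right") {
      put(pool, utils::tail(win, k))
    } else {
      nL <- ceiling(k / 2)
      put(pool[seq_len(nL)], utils::head(win, nL))
      if (k > nL) put(pool[(nL + 1L):k], utils::tail(win, k - nL))
    }
  }

  # --- TM placement ---
  tm_first_col <- integer(7); tm_last_col <- integer(7)
  tm_first_pos <- integer(7); tm_last_pos <- integer(7)
  for (h in 1:7) {
    cols_h <- setdiff(st$masks[[paste0("TM", h)]], which(st$colins))
    cols_h <- sort(cols_h)
    ac <- st$anchor_columns[[sprintf("%d.50", h)]]
    ai <- match(ac, cols_h)
    s <- seg[seg$helix == h, ]
    a <- anch[[as.character(h)]]
    kc <- min(s$end - a, length(cols_h) - ai)          # C-terminal reach
    kn <- min(a - s$start, ai - 1L)                    # N-terminal reach
    put((a - kn):(a + kc), cols_h[(ai - kn):(ai + kc)])
    tm_first_pos[h] <- a - kn; tm_last_pos[h] <- a + kc
    tm_first_col[h] <- cols_h[ai - kn]; tm_last_col[h] <- cols_h[ai + kc]
  }

  # --- loops (pools include any TM residues that did not fit in helix cols) ---
  loop_names <- c("ICL1", "ECL1", "ICL2", "ECL2", "ICL3", "ECL3")
  ecl2_cys_pos <- function(pool) {
    if (!is.null(disulfides) && nrow(disulfides)) {
      tm3 <- seg$start[3L]:seg$end[3L]
      for (k in seq_len(nrow(disulfides))) {
        pr <- as.integer(disulfides[k, ])
        if (pr[1L] %in% tm3 && pr[2L] %in% pool) return(pr[2L])
        if (pr[2L] %in% tm3 && pr[1L] %in% pool) return(pr[1L])
      }
    }
    cand <- pool[letters1[pool] == "C"]
    if (length(cand)) cand[1L] else NA_integer_
  }

  for (j in 1:6) {
    pool <- if (tm_last_pos[j] + 1L <= tm_first_pos[j + 1L] - 1L)
      (tm_last_pos[j] + 1L):(tm_first_pos[j + 1L] - 1L) else integer(0)
    if (!length(pool)) next
    wstart <- tm_last_col[j] + 1L; wend <- tm_first_col[j + 1L] - 1L
    lname <- loop_names[j]

    if (lname == "ECL2") {
      cys <- ecl2_cys_pos(pool)
      ccol <- if ("ECL2" %in% names(st$discols)) st$discols[["ECL2"]] else NA_integer_
      if (!is.na(cys) && !is.na(ccol) && ccol >= wstart && ccol <= wend) {
        put(cys, ccol)
        pack_halves(pool[pool < cys], wstart, ccol - 1L, lname)
        pack_halves(pool[pool > cys], ccol + 1L, wend, lname)
        next
      }
    }
    mrow <- motifs[motifs$region == lname, , drop = FALSE]
    if (nrow(mrow)) {
      pat <- mrow$pattern[1L]
      plen <- nchar(pat)
      seqstr <- paste(letters1[pool], collapse = "")
      m <- regexpr(motif_regex(pat), seqstr)
      mcols <- find_msa_motif_cols(st$mat, wstart, wend, pat)
      if (m[1L] != -1L && !is.null(mcols)) {
        q <- as.integer(m)
        put(pool[q:(q + plen - 1L)], mcols)
        pack_halves(pool[seq_len(q - 1L)], wstart, mcols[1L] - 1L, lname)
        if (q + plen <= length(pool))
          pack_halves(pool[(q + plen):length(pool)], mcols[plen] + 1L, wend, lname)
        next
      }
    }
    pack_halves(pool, wstart, wend, lname)
  }

  # --- termini, packed against the bundle ---
  if (tm_first_pos[1L] > 1L)
    pack_halves(1:(tm_first_pos[1L] - 1L), 1L, tm_first_col[1L] - 1L,
                "Nterm", side = "right")
  if (tm_last_pos[7L] < L)
    pack_halves((tm_last_pos[7L] + 1L):L, tm_last_col[7L] + 1L, st$W,
                "Cterm", side = "left")

  row <- paste(st$tch, collapse = "")
  if (!identical(ungap(row), target_seq))
    stop("internal error: target row does not reproduce the target sequence")
  # column order must respect sequence order
  stopifnot(!is.unsorted(order(which(st$tch != "-"))))

  rows <- apply(st$mat, 1L, paste, collapse = "")
  names(rows) <- names(msa$rows)
  rows[target_id] <- row
  out <- new_msa(rows, region_masks = st$masks,
                 anchor_columns = st$anchor_columns,
                 disulfide_columns = st$discols,
                 aligned_cols = st$aligned)
  attr(out, "col_insert") <- st$colins
  out
}

# Columns of the window whose template residues support the motif pattern.
# Scans contiguous column windows; the window matched by the most rows
# (non-wildcard positions only, requiring at least one matching row) wins.
find_msa_motif_cols <- function(mat, wstart, wend, pattern) {
  plen <- nchar(pattern)
  pats <- strsplit(pattern, "")[[1L]]
  if (wend - wstart + 1L < plen) return(NULL)
  best <- NULL; best_sup <- 0L
  for (s in wstart:(wend - plen + 1L)) {
    cols <- s:(s + plen - 1L)
    sup <- 0L
    for (r in seq_len(nrow(mat))) {
      chars <- mat[r, cols]
      if (any(chars == "-")) next
      okm <- TRUE
      for (q in seq_len(plen))
        if (pats[q] != "x" && chars[q] != pats[q]) { okm <- FALSE; break }
      if (okm) sup <- sup + 1L
    }
    if (sup > best_sup) { best_sup <- sup; best <- cols }
  }
  best
}

#' Half-split packing of an interior loop (utility)
#'
#' Splits `n` into the two halves used by the loop-adjoining rules: the
#' N-terminal half receives the extra residue when `n` is odd.
#'
#' @param n loop length.
#' @return integer vector `c(n_left, n_right)`.
#' @export
split_loop_lengths <- function(n) {
  nL <- ceiling(n / 2)
  c(nL, n - nL)
}
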