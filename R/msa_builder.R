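# Blended sequence/structure multiple alignment of template receptors, and
# knowledge-based alignment of a structure-less target into it.
#
# TM helices are aligned from the Ballesteros-Weinstein x.50 anchor of each
# helix outwards, with insertions and deletions placed where a residue's CA
# deviates from the column consensus after global superposition. Loops are
# aligned from CA->CB vector agreement. Residues alignable by neither rule
# are packed against the nearest flanking region of defined structure.

#' Assign Ballesteros-Weinstein numbers to the TM residues of a receptor
#'
#' The anchor residue of helix h gets label `h.50`; the residue k positions
#' C-terminal of it gets `h.(50+k)`, k positions N-terminal `h.(50-k)`,
#' within the annotated helix bounds.
#'
#' @param entry a [receptor_entry] with `tm_segments` (anchors required).
#' @return named character vector: names are residue positions (1-based),
#'   values BW labels such as "3.50".
#' @export
assign_bw_numbers <- function(entry) {
  seg <- entry$tm_segments
  if (is.null(seg) || anyNA(seg$anchor)) stop("missing TM anchor annotations")
  out <- character(0)
  for (i in seq_len(nrow(seg))) {
    pos <- seg$start[i]:seg$end[i]
    lab <- sprintf("%d.%d", seg$helix[i], 50L + pos - seg$anchor[i])
    names(lab) <- pos
    out <- c(out, lab)
  }
  out
}

# matched anchor-window CA coordinates for superposing entry onto ref
anchor_window_pairs <- function(entry, ref, window = 3L) {
  P <- NULL; Q <- NULL
  se <- entry$tm_segments; sr <- ref$tm_segments
  for (h in intersect(se$helix, sr$helix)) {
    ae <- se$anchor[se$helix == h]; ar <- sr$anchor[sr$helix == h]
    for (k in -window:window) {
      pe <- ae + k; pr <- ar + k
      if (pe >= se$start[se$helix == h] && pe <= se$end[se$helix == h] &&
          pr >= sr$start[sr$helix == h] && pr <= sr$end[sr$helix == h]) {
        P <- rbind(P, entry$coords[pe, "CA", ])
        Q <- rbind(Q, ref$coords[pr, "CA", ])
      }
    }
  }
  list(P = P, Q = Q)
}

#' Superpose a family of receptor entries into a common frame
#'
#' Each entry is rigidly superposed onto the first by a Kabsch fit of the
#' CA atoms in a window around the seven x.50 anchors.
#'
#' @param entries list of [receptor_entry] with coordinates and anchors.
#' @param window half-width (residues) of the anchor window used for the fit.
#' @return the list with transformed coordinates.
#' @export
superpose_entries <- function(entries, window = 3L) {
  stopifnot(length(entries) >= 2L)
  ref <- entries[[1L]]
  for (i in seq_along(entries)[-1L]) {
    pr <- anchor_window_pairs(entries[[i]], ref, window)
    fit <- kabsch_superpose(pr$P, pr$Q)
    co <- entries[[i]]$coords
    for (a in BACKBONE_ATOMS)
      co[, a, ] <- apply_transform(co[, a, , drop = TRUE], fit$rotation, fit$translation)
    entries[[i]]$coords <- co
  }
  entries
}

#' Structure-guided alignment of the transmembrane helices
#'
#' All x.50 anchor residues of a helix share one column. Columns are
#' extended outwards from the anchor; when a residue's CA deviates more
#' than `d_max` from the column consensus (coordinate-wise median over the
#' family after global superposition), the row either receives a gap (the
#' residue is retried at the next column; a deletion relative to the
#' family) or, if the row's following residue matches the current
#' consensus, the deviating residue is emitted as an insertion column of
#' its own (a helix bulge), with gaps in all other rows.
#'
#' @param entries list of [receptor_entry] with coordinates and 7 anchors;
#'   superposed internally via [superpose_entries].
#' @param d_max CA deviation (Angstrom) that triggers an indel.
#' @return list with `columns` (ordered list of named position vectors),
#'   `helix_of` (helix index per column), `anchor_col` (column index of
#'   each x.50, named "1.50".."7.50"), `insert` (logical per column) and
#'   `entries` (the superposed entries).
#' @export
align_tm_segments <- function(entries, d_max = 2.0) {
  stopifnot(length(entries) >= 2L)
  if (is.null(names(entries)) || any(!nzchar(names(entries))))
    names(entries) <- vapply(entries, `[[`, character(1), "id")
  entries <- superpose_entries(entries)
  columns <- list(); helix_of <- integer(0); insert_flag <- logical(0)
  anchor_col <- integer(0)

  seg_of <- function(id, h) {
    s <- entries[[id]]$tm_segments
    s[s$helix == h, , drop = FALSE]
  }
  ca_of <- function(id, pos) entries[[id]]$coords[pos, "CA", ]

  for (h in 1:7) {
    ids <- names(entries)[vapply(names(entries), function(id)
      nrow(seg_of(id, h)) == 1L, logical(1))]
    if (length(ids) < length(entries))
      warning("helix ", h, " missing in some entries; their columns are gapped")
    if (!length(ids)) next

    walk <- function(dir) {
      pos <- vapply(ids, function(id) seg_of(id, h)$anchor, integer(1))
      defer <- stats::setNames(integer(length(ids)), ids)
      out <- list()
      repeat {
        inb <- function(id, p) {
          s <- seg_of(id, h)
          p >= s$start && p <= s$end
        }
        cand <- pos + dir
        act <- ids[vapply(ids, function(id) inb(id, cand[[id]]), logical(1))]
        if (!length(act)) break
        cam <- do.call(rbind, lapply(act, function(id) ca_of(id, cand[[id]])))
        cons <- apply(cam, 2L, stats::median)
        dev <- sqrt(rowSums(sweep(cam, 2L, cons)^2))
        names(dev) <- act
        ok <- act[dev <= d_max]
        bad <- setdiff(act, ok)
        ins <- character(0)
        for (id in bad) {
          nxt <- cand[[id]] + dir
          if (inb(id, nxt) &&
              vnorm(ca_of(id, nxt) - cons) <= d_max) {
            # helix bulge: the deviating residue gets its own column
            out[[length(out) + 1L]] <- list(col = stats::setNames(cand[[id]], id),
                                            insert = TRUE)
            pos[[id]] <- cand[[id]]
            ins <- c(ins, id)
          }
        }
        forced <- setdiff(bad, ins)[defer[setdiff(bad, ins)] >= 3L]
        members <- c(ok, ins, forced)
        colv <- vapply(members, function(id) pos[[id]] + dir, integer(1))
        names(colv) <- members
        out[[length(out) + 1L]] <- list(col = colv, insert = FALSE)
        pos[members] <- colv
        defer[members] <- 0L
        rest <- setdiff(bad, c(ins, forced))
        defer[rest] <- defer[rest] + 1L
      }
      out
    }

    left <- rev(walk(-1L))
    anch <- vapply(ids, function(id) seg_of(id, h)$anchor, integer(1))
    names(anch) <- ids
    right <- walk(1L)
    cols_h <- c(left, list(list(col = anch, insert = FALSE)), right)
    anchor_col[sprintf("%d.50", h)] <- length(columns) + length(left) + 1L
    for (cc in cols_h) {
      columns[[length(columns) + 1L]] <- cc$col
      helix_of <- c(helix_of, h)
      insert_flag <- c(insert_flag, cc$insert)
    }
  }
  list(columns = columns, helix_of = helix_of, anchor_col = anchor_col,
       insert = insert_flag, entries = entries)
}

loop_range <- function(entry, j) {
  seg <- entry$tm_segments
  a <- seg$end[seg$helix == j] + 1L
  b <- seg$start[seg$helix == j + 1L] - 1L
  if (a <= b) a:b else integer(0)
}

# angle in degrees between CA->CB unit vectors of two residues
cb_angle <- function(e1, p1, e2, p2) {
  v1 <- e1$coords[p1, "CB", ] - e1$coords[p1, "CA", ]
  v2 <- e2$coords[p2, "CB", ] - e2$coords[p2, "CA", ]
  if (anyNA(v1) || anyNA(v2)) return(NA_real_)
  acos(max(-1, min(1, sum(unitv(v1) * unitv(v2))))) * 180 / pi
}

#' Structure-based alignment of the loop regions
#'
#' Loop residues of different rows share a column only when their CA atoms
#' lie within `d_loop` of each other and the angle between their CA->CB
#' vectors is at most `theta_max` degrees (after global superposition).
#' The first entry serves as the column spine; other rows are assigned to
#' spine columns greedily in sequence order (monotone). Disulfide-bonded
#' cysteines take precedence over the vector criterion, and runs of
#' secondary structure detected inside loops are kept intact (assigned to
#' consecutive columns or left unaligned as a block).
#'
#' @param entries list of [receptor_entry]; superposed internally.
#' @param d_loop CA-CA distance ceiling (Angstrom).
#' @param theta_max CA->CB angle ceiling (degrees).
#' @return list per loop region: `columns` (named position vectors, spine
#'   order) and `unaligned` (list row id -> positions); plus `entries`.
#' @export
align_loops_structural <- function(entries, d_loop = 3.0, theta_max = 60) {
  if (is.null(names(entries)) || any(!nzchar(names(entries))))
    names(entries) <- vapply(entries, `[[`, character(1), "id")
  entries <- superpose_entries(entries)
  loop_names <- c("ICL1", "ECL1", "ICL2", "ECL2", "ICL3", "ECL3")
  spine_id <- names(entries)[1L]
  spine <- entries[[spine_id]]

  ecl2_cys <- function(e) {
    # cysteine of the conserved TM3-ECL2 disulfide, if annotated
    if (!nrow(e$disulfides)) return(NA_integer_)
    seg <- e$tm_segments
    tm3 <- seg$start[seg$helix == 3L]:seg$end[seg$helix == 3L]
    for (k in seq_len(nrow(e$disulfides))) {
      pr <- e$disulfides[k, ]
      if (pr[1L] %in% tm3) return(pr[2L])
      if (pr[2L] %in% tm3) return(pr[1L])
    }
    NA_integer_
  }

  out <- list()
  for (j in 1:6) {
    lname <- loop_names[j]
    sp_pos <- loop_range(spine, j)
    cols <- lapply(sp_pos, function(p) stats::setNames(p, spine_id))
    unaligned <- list()
    sp_cys <- ecl2_cys(spine)
    cys_col <- if (lname == "ECL2" && !is.na(sp_cys)) match(sp_cys, sp_pos) else NA_integer_

    for (id in names(entries)[-1L]) {
      e <- entries[[id]]
      rp <- loop_range(e, j)
      if (!length(rp)) next
      has_coord <- !is.na(e$coords[rp, "CA", 1L])
      # secondary-structure blocks inside the loop are moved as one unit
      ssc <- classify_ss_ca(ca_matrix(e))[rp]
      blk <- integer(length(rp))   # 0 = free residue, else block id
      r <- rle(ifelse(is.na(ssc) | ssc == "L", "L", ssc))
      ends <- cumsum(r$lengths)
      bid <- 0L
      for (q in seq_along(r$values)) if (r$values[q] != "L" && r$lengths[q] >= 3L) {
        bid <- bid + 1L
        blk[(ends[q] - r$lengths[q] + 1L):ends[q]] <- bid
      }
      forced_pos <- if (lname == "ECL2" && !is.na(cys_col)) ecl2_cys(e) else NA_integer_

      assign <- rep(NA_integer_, length(rp))
      last <- 0L
      i <- 1L
      while (i <= length(rp)) {
        p <- rp[i]
        if (!is.na(forced_pos) && p == forced_pos) {
          # disulfide precedence: force the cysteine onto the spine cys column
          if (cys_col > last) { assign[i] <- cys_col; last <- cys_col }
          i <- i + 1L
          next
        }
        if (!has_coord[i]) { i <- i + 1L; next }
        if (blk[i] > 0L && (i == 1L || blk[i - 1L] != blk[i])) {
          # start of an SS block: place the whole block on consecutive columns
          len <- sum(blk == blk[i])
          best <- NA_integer_; bestd <- Inf
          c0_max <- length(cols) - len + 1L
          cand0 <- if (last + 1L <= c0_max) (last + 1L):c0_max else integer(0)
          for (c0 in cand0) {
            dsum <- 0; okb <- TRUE
            for (q in 0:(len - 1L)) {
              sc <- cols[[c0 + q]][[spine_id]]
              d <- vnorm(e$coords[rp[i + q], "CA", ] - spine$coords[sc, "CA", ])
              if (d > d_loop) { okb <- FALSE; break }
              dsum <- dsum + d
            }
            if (okb && dsum < bestd) { bestd <- dsum; best <- c0 }
          }
          if (!is.na(best)) {
            assign[i:(i + len - 1L)] <- best:(best + len - 1L)
            last <- best + len - 1L
          }
          i <- i + len
          next
        }
        # free residue: nearest compatible spine column after `last`
        cand <- if (last < length(cols)) (last + 1L):length(cols) else integer(0)
        best <- NA_integer_; bestd <- Inf
        for (cc in cand) {
          sc <- cols[[cc]][[spine_id]]
          d <- vnorm(e$coords[p, "CA", ] - spine$coords[sc, "CA", ])
          if (is.na(d) || d > d_loop) next
          ang <- cb_angle(e, p, spine, sc)
          if (is.na(ang) || ang > theta_max) next
          if (d < bestd) { bestd <- d; best <- cc }
        }
        if (!is.na(best)) { assign[i] <- best; last <- best }
        i <- i + 1L
      }
      for (i in seq_along(rp)) {
        if (!is.na(assign[i])) {
          cols[[assign[i]]][[id]] <- rp[i]
        } else {
          unaligned[[id]] <- c(unaligned[[id]], rp[i])
        }
      }
    }
    out[[lname]] <- list(columns = cols, unaligned = unaligned,
                         cys_col = cys_col)
  }
  out$entries <- entries
  out
}

#' Build the blended template MSA from structures
#'
#' Orchestrates [superpose_entries], [align_tm_segments] and
#' [align_loops_structural], assembles the global column space (termini as
#' row-local columns flanking the bundle), threads each row's unaligned
#' loop residues into provisional columns, and finishes with
#' [place_unalignable_residues].
#'
#' @param entries list of [receptor_entry] with coordinates and anchors.
#' @param d_max,d_loop,theta_max see the component aligners.
#' @return a [new_msa] with region masks, anchor columns, disulfide
#'   columns and an `insert` column attribute.
#' @export
build_template_msa <- function(entries, d_max = 2.0, d_loop = 3.0,
                               theta_max = 60) {
  if (is.null(names(entries)) || any(!nzchar(names(entries))))
    names(entries) <- vapply(entries, `[[`, character(1), "id")
  tm <- align_tm_segments(entries, d_max = d_max)
  entries <- tm$entries
  lp <- align_loops_structural(entries, d_loop = d_loop, theta_max = theta_max)
  entries <- lp$entries
  ids <- names(entries)
  loop_names <- c("ICL1", "ECL1", "ICL2", "ECL2", "ICL3", "ECL3")

  columns <- list(); region <- character(0); insert_flag <- logical(0)
  aligned <- logical(0)
  anchor_columns <- integer(0)
  disulfide_columns <- integer(0)

  emit <- function(col, reg, ins, alg) {
    columns[[length(columns) + 1L]] <<- col
    region <<- c(region, reg)
    insert_flag <<- c(insert_flag, ins)
    aligned <<- c(aligned, alg)
  }

  # N-termini: one row-local column per residue, packed just before TM1
  for (id in ids) {
    seg <- entries[[id]]$tm_segments
    first_tm <- seg$start[seg$helix == 1L]
    if (first_tm > 1L) for (p in 1:(first_tm - 1L))
      emit(stats::setNames(p, id), "Nterm", FALSE, FALSE)
  }

  for (h in 1:7) {
    sel <- which(tm$helix_of == h)
    for (k in sel) {
      if (sprintf("%d.50", h) %in% names(tm$anchor_col) &&
          tm$anchor_col[[sprintf("%d.50", h)]] == k)
        anchor_columns[sprintf("%d.50", h)] <- length(columns) + 1L
      emit(tm$columns[[k]], paste0("TM", h), tm$insert[k], TRUE)
    }
    if (h < 7L) {
      lr <- lp[[loop_names[h]]]
      # interleave each row's unaligned residues right after the column of
      # that row's preceding aligned residue (provisional placement)
      pre <- lapply(lr$unaligned, function(x) sort(x))
      spine_cols <- lr$columns
      # for each row, map: position -> spine col index (aligned residues)
      rowcol <- list()
      for (ci in seq_along(spine_cols))
        for (id in names(spine_cols[[ci]]))
          rowcol[[id]][as.character(spine_cols[[ci]][[id]])] <- ci
      # emit spine columns in order; before each, emit pending unaligned
      # residues of rows whose next aligned residue is this column
      pend <- list()
      for (id in names(pre)) for (p in pre[[id]]) {
        nxtc <- NA_integer_
        rc <- rowcol[[id]]
        if (!is.null(rc)) {
          lat <- as.integer(names(rc))
          after <- lat[lat > p]
          if (length(after)) nxtc <- rc[[as.character(min(after))]]
        }
        key <- if (is.na(nxtc)) length(spine_cols) + 1L else nxtc
        pend[[as.character(key)]] <- rbind(pend[[as.character(key)]],
                                           data.frame(id = id, p = p))
      }
      if (length(lr$cys_col) && !is.na(lr$cys_col) && loop_names[h] == "ECL2")
        disulfide_columns["ECL2"] <- length(columns) +
          lr$cys_col + {
            # account for pending singletons emitted before the cys column
            sum(vapply(seq_len(lr$cys_col), function(ci) {
              pd <- pend[[as.character(ci)]]
              if (is.null(pd)) 0L else nrow(pd)
            }, integer(1)))
          }
      for (ci in seq_along(spine_cols)) {
        pd <- pend[[as.character(ci)]]
        if (!is.null(pd)) for (q in seq_len(nrow(pd)))
          emit(stats::setNames(pd$p[q], pd$id[q]), loop_names[h], FALSE, FALSE)
        emit(spine_cols[[ci]], loop_names[h], FALSE, TRUE)
      }
      pd <- pend[[as.character(length(spine_cols) + 1L)]]
      if (!is.null(pd)) for (q in seq_len(nrow(pd)))
        emit(stats::setNames(pd$p[q], pd$id[q]), loop_names[h], FALSE, FALSE)
    }
  }

  # C-termini
  for (id in ids) {
    seg <- entries[[id]]$tm_segments
    last_tm <- seg$end[seg$helix == 7L]
    L <- nchar(entries[[id]]$sequence)
    if (last_tm < L) for (p in (last_tm + 1L):L)
      emit(stats::setNames(p, id), "Cterm", FALSE, FALSE)
  }

  # TM3 cysteine column of the conserved disulfide (for target alignment)
  spine <- entries[[1L]]
  if (nrow(spine$disulfides)) {
    seg <- spine$tm_segments
    tm3 <- seg$start[seg$helix == 3L]:seg$end[seg$helix == 3L]
    cys3 <- spine$disulfides[spine$disulfides[, 1L] %in% tm3 |
                             spine$disulfides[, 2L] %in% tm3, , drop = FALSE]
    if (nrow(cys3)) {
      p3 <- cys3[1L, which(cys3[1L, ] %in% tm3)]
      hit <- which(vapply(columns, function(cl)
        ids[1L] %in% names(cl) && cl[[ids[1L]]] == p3, logical(1)))
      if (length(hit)) disulfide_columns["TM3"] <- hit[1L]
    }
  }

  W <- length(columns)
  seqs <- lapply(entries, function(e) strsplit(e$sequence, "")[[1L]])
  rows <- vapply(ids, function(id) {
    chars <- rep("-", W)
    for (k in seq_len(W)) {
      cl <- columns[[k]]
      if (id %in% names(cl)) chars[k] <- seqs[[id]][cl[[id]]]
    }
    paste(chars, collapse = "")
  }, character(1))
  # sanity: every row must ungap to its source sequence
  for (id in ids) stopifnot(identical(ungap(rows[[id]]), entries[[id]]$sequence))

  region_masks <- split(seq_len(W), region)
  msa <- new_msa(rows, region_masks = region_masks,
                 anchor_columns = anchor_columns,
                 disulfide_columns = disulfide_columns,
                 aligned_cols = which(aligned))
  attr(msa, "col_insert") <- insert_flag
  place_unalignable_residues(msa)
}

#' Pack unalignable residues against defined structure
#'
#' In each row, every run of residues sitting in non-aligned columns
#' between two structurally defined columns is shifted to abut the nearer
#' flank (ties toward the N-terminal side); runs at the termini pack
#' against their single flank. All-gap columns left over are dropped.
#' The operation is idempotent.
#'
#' @param msa a [new_msa] with a non-empty `aligned_cols` set.
#' @return the repacked `gpcr_msa`.
#' @export
place_unalignable_residues <- function(msa) {
  if (!length(msa$aligned_cols)) return(msa)
  mat <- msa_char(msa)
  W <- ncol(mat)
  is_aligned_col <- seq_len(W) %in% msa$aligned_cols
  for (r in seq_len(nrow(mat))) {
    occ <- which(mat[r, ] != "-")
    def <- occ[is_aligned_col[occ]]
    free <- occ[!is_aligned_col[occ]]
    if (!length(free)) next
    bounds <- c(0L, def, W + 1L)
    for (b in seq_len(length(bounds) - 1L)) {
      lo <- bounds[b]; hi <- bounds[b + 1L]
      run <- free[free > lo & free < hi]
      if (!length(run)) next
      window <- setdiff((lo + 1L):(hi - 1L), def)
      k <- length(run)
      left_d <- min(run) - lo
      right_d <- hi - max(run)
      target <- if (lo == 0L) utils::tail(window, k)          # N-terminal edge
        else if (hi == W + 1L) utils::head(window, k)          # C-terminal edge
        else if (left_d <= right_d) utils::head(window, k)
        else utils::tail(window, k)
      if (!identical(target, run)) {
        chars <- mat[r, run]
        mat[r, run] <- "-"
        mat[r, target] <- chars
      }
    }
  }
  keep <- which(colSums(mat != "-") > 0L)
  mat <- mat[, keep, drop = FALSE]
  remap <- match(seq_len(W), keep)
  rows <- apply(mat, 1L, paste, collapse = "")
  names(rows) <- names(msa$rows)
  out <- new_msa(rows,
                 region_masks = lapply(msa$region_masks, function(m)
                   sort(stats::na.omit(remap[m]))),
                 anchor_columns = stats::setNames(remap[msa$anchor_columns],
                                                  names(msa$anchor_columns)),
                 disulfide_columns = stats::setNames(remap[msa$disulfide_columns],
                                                     names(msa$disulfide_columns)),
                 aligned_cols = stats::na.omit(remap[msa$aligned_cols]))
  ci <- attr(msa, "col_insert")
  if (!is.null(ci)) attr(out, "col_insert") <- ci[keep]
  out
}

#' Pairwise percent identity over masked alignment columns
#'
#' identity(i, j) = 100 x (identical residues in masked columns where both
#' rows are non-gap) / (masked columns where both are non-gap). The default
#' mask covers the TM bundle and loops plus `termini_pad` columns on either
#' side, excluding long termini.
#'
#' @param msa a [new_msa].
#' @param region_mask integer columns to score; `NULL` for the default.
#' @param termini_pad columns of terminus retained next to TM1/TM7.
#' @return symmetric matrix of percent identities (diagonal 100); `NA`
#'   where two rows share no masked non-gap column.
#' @export
pairwise_identity <- function(msa, region_mask = NULL, termini_pad = 10L) {
  mat <- msa_char(msa)
  if (is.null(region_mask)) {
    rm <- msa$region_masks
    if (length(rm) && all(c("TM1", "TM7") %in% names(rm))) {
      lo <- max(1L, min(rm$TM1) - termini_pad)
      hi <- min(ncol(mat), max(rm$TM7) + termini_pad)
      region_mask <- lo:hi
    } else region_mask <- seq_len(ncol(mat))
  }
  mat <- mat[, region_mask, drop = FALSE]
  n <- nrow(mat)
  out <- matrix(NA_real_, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n)) for (j in i:n) {
    both <- mat[i, ] != "-" & mat[j, ] != "-"
    if (!any(both)) next
    out[i, j] <- out[j, i] <- 100 * sum(mat[i, both] == mat[j, both]) / sum(both)
  }
  diag(out) <- 100
  rownames(out) <- colnames(out) <- names(msa$rows)
  out
}

#' Default sequence-motif anchor table
#'
#' Fallback motifs for helix positioning when the x.50 residue cannot be
#' identified (lowercase `x` is a wildcard): DRY at the intracellular end
#' of TM3 (R = 3.50), CWxP in TM6 (P = 6.50), NPxxY in TM7 (P = 7.50), and
#' xWxxG as the ECL1 alignment motif.
#'
#' @return data.frame with columns `region`, `pattern`, `anchor_offset`
#'   (1-based offset of the anchored residue within the pattern).
#' @export
default_motifs <- function() {
  data.frame(region = c("TM3", "TM6", "TM7", "ECL1"),
             pattern = c("DRY", "CWxP", "NPxxY", "xWxxG"),
             anchor_offset = c(2L, 4L, 2L, 2L),
             stringsAsFactors = FALSE)
}

motif_regex <- function(pattern) gsub("x", ".", pattern, fixed = TRUE)
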