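# Desk-scale multi-template recombination: Metropolis Monte Carlo that
# swaps template segments (after local superposition on flanking residues,
# holding all templates in one global frame) and inserts 3/9-residue
# backbone fragments, under an explicit lightweight composite score. The
# score is this package's own stand-in for a molecular-mechanics energy;
# it selects segments that fit locally (chain geometry, secondary
# structure) and globally (clashes, compactness, template consensus).

default_score_weights <- function() {
  c(clash = 1, chainbreak = 10, ss_agreement = 5,
    disulfide = 10, rg = 0.1, template_consensus = 1)
}

#' Composite score of a complete model state
#'
#' Terms: `clash` = sum over non-adjacent CA pairs of max(0, 4 - d)^2;
#' `chainbreak` = sum over consecutive residues of (d - 3.8)^2;
#' `ss_agreement` = fraction of residues whose CA-trace geometry class
#' disagrees with the predicted secondary structure; `disulfide` = sum
#' over restraint pairs of max(0, d(CB, CB) - 5)^2; `rg` = max(0,
#' Rg - Rg_ref)^2; `template_consensus` = sum over residues of the CA
#' deviation from the per-residue median of the superposed templates (an
#' extensive term, like the per-residue template restraints of
#' fragment-assembly programs: an intensive mean could not balance the
#' extensive chain-geometry sums). The total is the weighted sum (default
#' weights 1, 10, 5, 10, 0.1, 1).
#'
#' @param state a model (anything with a `[L, 5, 3]` `coords` array) with
#'   complete coordinates.
#' @param annotations list with `ss` (predicted H/E/L vector), `disulfides`
#'   (two-column matrix or NULL), `rg_ref`, `consensus` (`[L, 3]` CA matrix
#'   or NULL) and optional `weights`.
#' @return list with `terms` (named numeric) and `total`.
#' @export
score_model <- function(state, annotations) {
  co <- coords_of(state)
  ca <- co[, "CA", , drop = TRUE]
  if (anyNA(ca)) stop("incomplete coordinates: fill gaps before scoring")
  w <- annotations$weights
  if (is.null(w)) w <- default_score_weights()
  n <- nrow(ca)
  dvec <- stats::dist(ca)
  close <- dvec[dvec < 4]
  adj <- sqrt(rowSums((ca[-1L, , drop = FALSE] - ca[-n, , drop = FALSE])^2))
  clash <- sum((4 - close)^2) - sum(pmax(0, 4 - adj)^2)
  chainbreak <- sum((adj - 3.8)^2)
  ssa <- 0
  if (!is.null(annotations$ss)) {
    obs <- classify_ss_ca(ca)
    both <- !is.na(obs) & !is.na(annotations$ss)
    if (any(both)) ssa <- mean(obs[both] != annotations$ss[both])
  }
  dis <- 0
  pairs <- annotations$disulfides
  if (!is.null(pairs) && nrow(pairs)) {
    cb <- co[, "CB", , drop = TRUE]
    dd <- sqrt(rowSums((cb[pairs[, 1L], , drop = FALSE] -
                        cb[pairs[, 2L], , drop = FALSE])^2))
    dis <- sum(pmax(0, dd - 5)^2)
  }
  rg_term <- 0
  if (!is.null(annotations$rg_ref)) {
    rg <- sqrt(mean(rowSums(sweep(ca, 2L, colMeans(ca))^2)))
    rg_term <- max(0, rg - annotations$rg_ref)^2
  }
  cons <- 0
  if (!is.null(annotations$consensus)) {
    ok <- !is.na(annotations$consensus[, 1L])
    cons <- sum(sqrt(rowSums((ca[ok, , drop = FALSE] -
                              annotations$consensus[ok, , drop = FALSE])^2)))
  }
  terms <- c(clash = clash, chainbreak = chainbreak, ss_agreement = ssa,
             disulfide = dis, rg = rg_term, template_consensus = cons)
  list(terms = terms, total = sum(w[names(terms)] * terms))
}

# ideal-geometry CA trace for a fragment of the given SS string
ideal_fragment_ca <- function(sschars) {
  len <- length(sschars)
  ca <- matrix(NA_real_, len, 3L)
  p <- c(0, 0, 0); dir <- c(0, 0, 1)
  for (i in seq_len(len)) {
    if (identical(sschars[i], "H")) {
      th <- 100 * pi / 180 * i
      ca[i, ] <- c(2.3 * cos(th), 2.3 * sin(th), 1.5 * i)
    } else if (identical(sschars[i], "E")) {
      ca[i, ] <- c(1.1 * (-1)^i, 0, 3.4 * i)
    } else {
      ca[i, ] <- c(0.8 * sin(0.5 * i), 0.8 * (1 - cos(0.5 * i)), 3.6 * i)
    }
  }
  ca
}

#' Build the fragment library for a target
#'
#' Fragments of length 3 and 9 are harvested from every template thread at
#' windows whose geometric secondary structure matches the prediction;
#' ideal-geometry fragments (helix, strand, coil) are appended at every
#' position so that coverage is total.
#'
#' @param threads list of threaded models (template coordinate sources).
#' @param predicted_ss per-residue H/E/L vector (length of the target).
#' @param lengths fragment lengths.
#' @return object of class `fragment_library`: list keyed `"pos_len"`,
#'   each a list of fragments (`coords` `[len, 5, 3]`, `tag`).
#' @export
build_fragment_library <- function(threads, predicted_ss, lengths = c(3L, 9L)) {
  L <- length(predicted_ss)
  lib <- list()
  thread_ss <- lapply(threads, function(th) classify_ss_ca(th$coords[, "CA", ]))
  for (len in lengths) {
    for (pos in seq_len(max(L - len + 1L, 0L))) {
      key <- paste0(pos, "_", len)
      idx <- pos:(pos + len - 1L)
      frags <- list()
      for (ti in seq_along(threads)) {
        th <- threads[[ti]]
        if (anyNA(th$coords[idx, "CA", 1L])) next
        tss <- thread_ss[[ti]][idx]
        pss <- predicted_ss[idx]
        both <- !is.na(tss) & !is.na(pss)
        if (any(both) && !all(tss[both] == pss[both])) next
        frags[[length(frags) + 1L]] <-
          list(coords = th$coords[idx, , , drop = FALSE],
               tag = paste0("frag:", th$template_id))
      }
      pss <- predicted_ss[idx]
      pss[is.na(pss)] <- "L"
      frags[[length(frags) + 1L]] <-
        list(coords = backbone_from_ca(ideal_fragment_ca(pss)),
             tag = "frag:ideal")
      lib[[key]] <- frags
    }
  }
  structure(lib, class = "fragment_library", lengths = lengths, L = L)
}

# superpose fragment backbone onto the current window (CA fit) and return
# the replacement [len,5,3] block
fit_fragment <- function(frag_coords, window_ca) {
  fit <- kabsch_superpose(frag_coords[, "CA", , drop = TRUE], window_ca)
  out <- frag_coords
  for (a in BACKBONE_ATOMS)
    out[, a, ] <- apply_transform(frag_coords[, a, , drop = TRUE],
                                  fit$rotation, fit$translation)
  out
}

# fill unmodeled stretches of a thread by linear CA interpolation between
# the flanking modeled residues (straight extension at the termini)
fill_gaps <- function(coords) {
  ca <- coords[, "CA", , drop = TRUE]
  n <- nrow(ca)
  miss <- is.na(ca[, 1L])
  if (!any(miss)) return(list(coords = coords, filled = integer(0)))
  mod <- which(!miss)
  if (length(mod) < 2L) stop("thread has fewer than 2 modeled residues")
  for (i in which(miss)) {
    lo <- mod[mod < i]; hi <- mod[mod > i]
    if (length(lo) && length(hi)) {
      a <- max(lo); b <- min(hi)
      f <- (i - a) / (b - a)
      ca[i, ] <- ca[a, ] + f * (ca[b, ] - ca[a, ])
    } else if (length(hi)) {
      b <- min(hi); b2 <- min(hi[hi > b])
      step <- if (is.finite(b2)) unitv(ca[b, ] - ca[b2, ]) else c(1, 0, 0)
      ca[i, ] <- ca[b, ] + 3.8 * (b - i) * step
    } else {
      a <- max(lo); a2 <- max(lo[lo < a])
      step <- if (is.finite(a2)) unitv(ca[a, ] - ca[a2, ]) else c(1, 0, 0)
      ca[i, ] <- ca[a, ] + 3.8 * (i - a) * step
    }
  }
  bb <- backbone_from_ca(ca)
  coords[miss, , ] <- bb[miss, , , drop = FALSE]
  list(coords = coords, filled = which(miss))
}

#' Multi-template hybridization by Monte Carlo
#'
#' The highest-identity thread (the first in `threads`) seeds the state;
#' its unmodeled stretches are filled by CA interpolation followed by an
#' ideal fragment insertion. Each Monte Carlo step applies, with equal
#' probability, a template-segment swap (a contiguous region of 5-30
#' residues copied from another thread after local superposition on up to
#' three flanking residues per side) or a fragment insertion (a 3- or
#' 9-residue window's local geometry replaced from the library), accepted
#' by the Metropolis criterion under a geometric cooling schedule from
#' `t_hi` to `t_lo`. Each model runs an independent trajectory seeded
#' `seed + model index`; the best-scoring state visited is returned.
#'
#' @param threads list of [partial_thread] models of one target, highest
#'   identity first.
#' @param fragment_library optional [build_fragment_library] result
#'   (built internally when NULL).
#' @param constraints optional two-column disulfide matrix.
#' @param n_models number of models.
#' @param steps Monte Carlo steps per model.
#' @param seed base RNG seed.
#' @param weights score weights, see [score_model].
#' @param predicted_ss H/E/L vector; defaults to the per-residue majority
#'   geometry class of the threads.
#' @param t_hi,t_lo temperature schedule endpoints.
#' @return list of `hybrid_model`s sorted by ascending total score (ties
#'   by model index): `coords`, `provenance` (template id or fragment tag
#'   per residue), `score_terms`, `total`, `trajectory` (accepted total
#'   per step) and `model_index`.
#' @export
hybridize <- function(threads, fragment_library = NULL, constraints = NULL,
                      n_models = 100L, steps = 5000L, seed = 1L,
                      weights = default_score_weights(),
                      predicted_ss = NULL, t_hi = 2, t_lo = 0.25) {
  if (!length(threads)) stop("zero templates: nothing to hybridize")
  L <- nchar(threads[[1L]]$sequence)

  # hold all threads in one global frame (superpose onto the seed thread)
  ref_ca <- threads[[1L]]$coords[, "CA", , drop = TRUE]
  for (ti in seq_along(threads)[-1L]) {
    ca_i <- threads[[ti]]$coords[, "CA", , drop = TRUE]
    both <- which(!is.na(ref_ca[, 1L]) & !is.na(ca_i[, 1L]))
    if (length(both) >= 3L) {
      fit <- kabsch_superpose(ca_i[both, , drop = FALSE],
                              ref_ca[both, , drop = FALSE])
      co <- threads[[ti]]$coords
      for (a in BACKBONE_ATOMS)
        co[, a, ] <- apply_transform(co[, a, , drop = TRUE],
                                     fit$rotation, fit$translation)
      threads[[ti]]$coords <- co
    }
  }

  # per-residue median CA over covering threads
  cons <- matrix(NA_real_, L, 3L)
  cov_ca <- lapply(threads, function(th) th$coords[, "CA", , drop = TRUE])
  for (i in seq_len(L)) {
    pts <- do.call(rbind, lapply(cov_ca, function(m)
      if (!is.na(m[i, 1L])) m[i, ] else NULL))
    if (!is.null(pts)) cons[i, ] <- apply(pts, 2L, stats::median)
  }

  if (is.null(predicted_ss)) {
    ssm <- vapply(threads, function(th)
      classify_ss_ca(th$coords[, "CA", , drop = TRUE]), character(L))
    predicted_ss <- apply(matrix(ssm, nrow = L), 1L, function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) NA_character_ else names(which.max(table(v)))
    })
  }
  if (is.null(fragment_library))
    fragment_library <- build_fragment_library(threads, predicted_ss)

  seeded <- fill_gaps(threads[[1L]]$coords)
  coords0 <- seeded$coords
  prov0 <- rep(threads[[1L]]$template_id, L)
  prov0[seeded$filled] <- "frag:ideal"
  cons[is.na(cons[, 1L]), ] <- coords0[, "CA", ][is.na(cons[, 1L]), ]

  ca0 <- coords0[, "CA", , drop = TRUE]
  ann <- list(ss = predicted_ss, disulfides = constraints,
              rg_ref = sqrt(mean(rowSums(sweep(cons, 2L, colMeans(cons))^2))),
              consensus = cons, weights = weights)

  # ideal fragment insertion over the seeded gap runs
  if (length(seeded$filled)) {
    runs <- split(seeded$filled, cumsum(c(1L, diff(seeded$filled) != 1L)))
    for (r in runs) {
      len <- if (length(r) >= 9L) 9L else 3L
      pos <- min(r)
      if (pos + len - 1L > L) pos <- L - len + 1L
      key <- paste0(pos, "_", len)
      frs <- fragment_library[[key]]
      if (is.null(frs)) next
      fr <- frs[[length(frs)]]   # the ideal fragment is appended last
      idx <- pos:(pos + len - 1L)
      coords0[idx, , ] <- fit_fragment(fr$coords, coords0[idx, "CA", , drop = TRUE])
    }
  }

  modeled <- lapply(threads, function(th) !is.na(th$coords[, "CA", 1L]))
  temps <- t_hi * (t_lo / t_hi)^(seq_len(steps) / steps)
  lengths_frag <- attr(fragment_library, "lengths")

  models <- vector("list", n_models)
  for (mi in seq_len(n_models)) {
    set.seed(seed + mi)
    coords <- coords0
    prov <- prov0
    sc <- score_model(list(coords = coords), ann)
    total <- sc$total
    best <- list(coords = coords, prov = prov, terms = sc$terms,
                 total = total)
    traj <- numeric(steps)
    for (st in seq_len(steps)) {
      new_coords <- coords
      new_prov <- prov
      moved <- FALSE
      if (length(threads) >= 1L && stats::runif(1) < 0.5) {
        # template-segment swap
        ti <- if (length(threads) == 1L) 1L else sample(seq_along(threads), 1L)
        len <- sample(5:30, 1L)
        if (len < L) for (try in 1:10) {
          s <- sample(L - len + 1L, 1L)
          e <- s + len - 1L
          if (!all(modeled[[ti]][s:e])) next
          lf <- (s - 3L):(s - 1L); lf <- lf[lf >= 1L & modeled[[ti]][pmax(lf, 1L)]]
          rf <- (e + 1L):(e + 3L); rf <- rf[rf <= L & modeled[[ti]][pmin(rf, L)]]
          fl <- c(lf, rf)
          don <- threads[[ti]]$coords
          if (length(fl) < 3L) fl <- unique(c(fl, s, e))
          if (length(fl) < 3L) next
          fit <- kabsch_superpose(don[fl, "CA", , drop = TRUE],
                                  coords[fl, "CA", , drop = TRUE])
          blk <- don[s:e, , , drop = FALSE]
          for (a in BACKBONE_ATOMS)
            blk[, a, ] <- apply_transform(don[s:e, a, , drop = TRUE],
                                          fit$rotation, fit$translation)
          new_coords[s:e, , ] <- blk
          new_prov[s:e] <- threads[[ti]]$template_id
          moved <- TRUE
          break
        }
      } else {
        # fragment insertion
        len <- sample(lengths_frag, 1L)
        if (len < L) {
          pos <- sample(L - len + 1L, 1L)
          frs <- fragment_library[[paste0(pos, "_", len)]]
          if (!is.null(frs) && length(frs)) {
            fr <- frs[[sample(length(frs), 1L)]]
            idx <- pos:(pos + len - 1L)
            new_coords[idx, , ] <- fit_fragment(fr$coords,
                                                coords[idx, "CA", , drop = TRUE])
            new_prov[idx] <- fr$tag
            moved <- TRUE
          }
        }
      }
      if (moved) {
        sc_new <- score_model(list(coords = new_coords), ann)
        dlt <- sc_new$total - total
        if (dlt <= 0 || stats::runif(1) < exp(-dlt / temps[st])) {
          coords <- new_coords; prov <- new_prov
          total <- sc_new$total
          if (total < best$total)
            best <- list(coords = coords, prov = prov, terms = sc_new$terms,
                         total = total)
        }
      }
      traj[st] <- total
    }
    models[[mi]] <- structure(list(target_id = threads[[1L]]$target_id,
                                   sequence = threads[[1L]]$sequence,
                                   coords = best$coords,
                                   provenance = best$prov,
                                   score_terms = best$terms,
                                   total = best$total,
                                   trajectory = traj,
                                   model_index = mi),
                              class = "hybrid_model")
  }
  totals <- vapply(models, `[[`, numeric(1), "total")
  models[order(totals, seq_along(models))]
}

#' @export
print.hybrid_model <- function(x, ...) {
  cat(sprintf("<hybrid_model> %s #%d: total %.3f (%s)\n",
              x$target_id, x$model_index, x$total,
              paste(sprintf("%s %.2f", names(x$score_terms), x$score_terms),
                    collapse = ", ")))
  invisible(x)
}

#' Select the best-scoring model
#'
#' @param models list of scored models (each with `total`); ties are
#'   broken by the lowest model index (list order for unindexed models).
#' @return the argmin-total model.
#' @export
select_best <- function(models) {
  if (!length(models)) stop("empty model list")
  totals <- vapply(models, `[[`, numeric(1), "total")
  models[[which.min(totals)]]
}
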