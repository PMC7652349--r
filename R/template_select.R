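# Template ranking, the 40% identity ceiling, and identity binning.

#' Rank candidate templates by pairwise identity
#'
#' Templates at or above `threshold_max` percent identity are removed --
#' modeling on low-identity templates only mimics the situation faced with
#' novel targets -- and the remainder is sorted by descending identity
#' (ties broken lexicographically by id).
#'
#' @param identity_row named numeric vector of percent identities to the
#'   target (the target itself must not be included).
#' @param threshold_max removal ceiling in percent (default 40).
#' @param threshold_min optional floor; templates below it are dropped.
#' @param target_id id recorded in the ranking.
#' @return object of class `template_ranking` with `ranked`
#'   (data.frame id, identity).
#' @export
rank_templates <- function(identity_row, threshold_max = 40,
                           threshold_min = NULL, target_id = "target") {
  stopifnot(is.numeric(identity_row), !is.null(names(identity_row)))
  keep <- !is.na(identity_row) & identity_row < threshold_max
  if (!is.null(threshold_min)) keep <- keep & identity_row >= threshold_min
  pool <- identity_row[keep]
  if (!length(pool))
    stop("no templates below the ", threshold_max,
         "% identity ceiling; consider raising threshold_max")
  ord <- order(-pool, names(pool))
  structure(list(target_id = target_id,
                 ranked = data.frame(id = names(pool)[ord],
                                     identity = unname(pool[ord]),
                                     stringsAsFactors = FALSE),
                 threshold_max = threshold_max,
                 threshold_min = threshold_min),
            class = "template_ranking")
}

#' @export
print.template_ranking <- function(x, ...) {
  cat(sprintf("<template_ranking> %s: %d templates below %.0f%%\n",
              x$target_id, nrow(x$ranked), x$threshold_max))
  print(utils::head(x$ranked, 10L))
  invisible(x)
}

#' Select the top-n templates from a ranking
#'
#' Five templates is the default modeling set size.
#'
#' @param ranking a [rank_templates] result.
#' @param n number of templates (>= 1).
#' @return character vector of the first `min(n, pool)` template ids.
#' @export
select_top_n <- function(ranking, n = 5L) {
  stopifnot(inherits(ranking, "template_ranking"))
  if (n < 1L) stop("n must be >= 1")
  utils::head(ranking$ranked$id, n)
}

#' Bin templates by identity range
#'
#' Default bins 15-19, 20-24, 25-29 and 30-39 percent (inclusive on the
#' integer-truncated identity); templates outside every bin are reported
#' as unbinned.
#'
#' @param ranking a [rank_templates] result.
#' @param bins list of `c(lo, hi)` integer ranges; must not overlap.
#' @return named list of template-id vectors (one per bin, named
#'   "lo-hi") with attribute `unbinned`.
#' @export
bin_templates <- function(ranking,
                          bins = list(c(15L, 19L), c(20L, 24L),
                                      c(25L, 29L), c(30L, 39L))) {
  stopifnot(inherits(ranking, "template_ranking"))
  lo <- vapply(bins, `[`, numeric(1), 1L)
  hi <- vapply(bins, `[`, numeric(1), 2L)
  if (any(lo > hi)) stop("config error: bin with lo > hi")
  ord <- order(lo)
  if (any(utils::head(hi[ord], -1L) >= utils::tail(lo[ord], -1L)))
    stop("config error: overlapping bins")
  ids <- ranking$ranked$id
  ipct <- trunc(ranking$ranked$identity)
  out <- stats::setNames(vector("list", length(bins)),
                         sprintf("%d-%d", lo, hi))
  assigned <- rep(FALSE, length(ids))
  for (k in seq_along(bins)) {
    inb <- ipct >= lo[k] & ipct <= hi[k]
    out[[k]] <- ids[inb]
    assigned <- assigned | inb
  }
  attr(out, "unbinned") <- ids[!assigned]
  out
}
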