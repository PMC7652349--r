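# Region-specific model evaluation: CA RMSD after optimal superposition,
# per-region or with a global TM-based fit, plus benchmark statistics.

coords_of <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  if (!is.null(x$coords)) return(x$coords)
  stop("cannot extract coordinates")
}

#' Region-specific CA RMSD report
#'
#' For each region the mutual CA atoms (present in both structures) are
#' superposed and the RMSD reported. Residues unresolved in either
#' structure are excluded pairwise. `fit = "global"` instead superposes
#' once on the TM region and measures each region without refitting.
#'
#' @param model,reference structures sharing residue numbering: a
#'   [receptor_entry], threaded/hybrid model, or `[L, 5, 3]` array.
#' @param regions named list of residue-position vectors; by convention
#'   `TM` (union of the seven helices), `ECL2` and `FullModel`.
#' @param fit "region" (default) or "global".
#' @return data.frame of class `region_rmsd_report`: region, rmsd,
#'   n_atoms, fit convention; `rmsd` is NA (with reason) for regions with
#'   no mutual atoms.
#' @export
region_rmsd <- function(model, reference, regions, fit = c("region", "global")) {
  fit <- match.arg(fit)
  cm <- coords_of(model)[, "CA", , drop = TRUE]
  cr <- coords_of(reference)[, "CA", , drop = TRUE]
  n <- min(nrow(cm), nrow(cr))
  present <- !is.na(cm[seq_len(n), 1L]) & !is.na(cr[seq_len(n), 1L])
  glob <- NULL
  if (fit == "global") {
    tm <- intersect(regions[["TM"]], which(present))
    if (length(tm) < 3L) stop("global fit requires >= 3 mutual TM atoms")
    glob <- kabsch_superpose(cm[tm, , drop = FALSE], cr[tm, , drop = FALSE])
  }
  out <- data.frame(region = names(regions), rmsd = NA_real_,
                    n_atoms = 0L, fit = fit, stringsAsFactors = FALSE)
  for (k in seq_along(regions)) {
    idx <- intersect(regions[[k]], which(present))
    out$n_atoms[k] <- length(idx)
    if (length(idx) < 3L) next
    if (fit == "region") {
      out$rmsd[k] <- kabsch_superpose(cm[idx, , drop = FALSE],
                                      cr[idx, , drop = FALSE])$rmsd
    } else {
      mt <- apply_transform(cm[idx, , drop = FALSE], glob$rotation, glob$translation)
      out$rmsd[k] <- sqrt(mean(rowSums((mt - cr[idx, , drop = FALSE])^2)))
    }
  }
  class(out) <- c("region_rmsd_report", class(out))
  out
}

#' Standard evaluation regions of an annotated receptor
#'
#' @param entry a [receptor_entry] with TM segments.
#' @return list with `TM` (union TM1-7), `ECL2`, and `FullModel` (all
#'   residues).
#' @export
evaluation_regions <- function(entry) {
  r <- receptor_regions(entry)
  list(TM = sort(unlist(r[paste0("TM", 1:7)], use.names = FALSE)),
       ECL2 = r$ECL2,
       FullModel = seq_len(nchar(entry$sequence)))
}

#' Fold change of per-target average RMSD between methods
#'
#' For each target, the mean model RMSD of a method is divided by the mean
#' RMSD of the reference method; the benchmark summary is the mean of the
#' per-target ratios. A method compared with itself gives exactly 1.
#'
#' @param method_runs,reference_runs data.frames with columns `target` and
#'   `rmsd` (one row per model).
#' @return list of class `fold_change_table`: `per_target` (data.frame
#'   target, ratio) and `summary` (mean ratio).
#' @export
fold_change <- function(method_runs, reference_runs) {
  stopifnot(all(c("target", "rmsd") %in% names(method_runs)),
            all(c("target", "rmsd") %in% names(reference_runs)))
  mt <- tapply(method_runs$rmsd, method_runs$target, mean)
  rt <- tapply(reference_runs$rmsd, reference_runs$target, mean)
  targets <- intersect(names(mt), names(rt))
  if (!length(targets)) stop("no shared targets")
  ratio <- vapply(targets, function(tg) {
    if (rt[[tg]] == 0) return(NA_real_)   # undefined, flagged as NA
    unname(mt[[tg]] / rt[[tg]])
  }, numeric(1))
  structure(list(per_target = data.frame(target = targets, ratio = ratio,
                                         row.names = NULL,
                                         stringsAsFactors = FALSE),
                 summary = mean(ratio, na.rm = TRUE)),
            class = "fold_change_table")
}

#' @export
print.fold_change_table <- function(x, ...) {
  cat(sprintf("<fold_change_table> %d targets, mean ratio %.3f\n",
              nrow(x$per_target), x$summary))
  invisible(x)
}

box_stats <- function(x) {
  q <- stats::quantile(x, c(0, .25, .5, .75, 1), names = FALSE)
  data.frame(mean = mean(x), min = q[1L], q1 = q[2L], median = q[3L],
             q3 = q[4L], max = q[5L])
}

#' Template-count / identity-bin modeling experiment harness
#'
#' Runs the full select -> thread -> hybridize -> evaluate chain on a
#' synthetic family for a series of conditions -- either template counts
#' (e.g. 1, 5, 10, all available) or identity bins -- and summarises the
#' model RMSDs per region with box-plot statistics.
#'
#' @param family a [evolve_family] fixture (its ancestor is target and
#'   evaluation reference; members are the template pool).
#' @param template_counts integer vector of template-set sizes ("all" =
#'   `Inf`); mutually exclusive with `identity_bins`.
#' @param identity_bins list of `c(lo, hi)` identity ranges; each
#'   condition uses up to five templates from its bin.
#' @param n_models models generated per condition.
#' @param steps Monte Carlo steps per model.
#' @param seed base RNG seed; condition k uses `seed + 1000 k`.
#' @param threshold_max identity ceiling applied before ranking.
#' @param msa alignment used for identity and threading; by default the
#'   blended structure alignment is built from the family's structures
#'   ([build_template_msa]), so that alignment quality degrades with
#'   template quality as it does in practice. Pass
#'   `family$truth_alignment` to isolate modeling from alignment error.
#' @return data.frame (condition, region, n_templates, n_models, mean,
#'   min, q1, median, q3, max). Conditions with no eligible template are
#'   skipped and reported in the `skipped` attribute.
#' @export
experiment_harness <- function(family, template_counts = NULL,
                               identity_bins = NULL, n_models = 5L,
                               steps = 1500L, seed = 1L,
                               threshold_max = 40, msa = NULL) {
  if (is.null(template_counts) == is.null(identity_bins))
    stop("give exactly one of template_counts or identity_bins")
  if (is.null(msa)) {
    entries <- c(stats::setNames(list(family$ancestor), family$ancestor$id),
                 family$members)
    msa <- build_template_msa(entries)
  }
  target_id <- family$ancestor$id
  idm <- pairwise_identity(msa)
  row <- idm[target_id, setdiff(colnames(idm), target_id)]
  ranking <- rank_templates(row, threshold_max = threshold_max,
                            target_id = target_id)
  conditions <- list()
  if (!is.null(template_counts)) {
    for (n in template_counts) {
      lab <- if (is.infinite(n)) "all" else as.character(n)
      conditions[[lab]] <- select_top_n(ranking,
                                        if (is.infinite(n)) nrow(ranking$ranked) else n)
    }
  } else {
    binned <- bin_templates(ranking, identity_bins)
    for (lab in names(binned)) conditions[[lab]] <- utils::head(binned[[lab]], 5L)
  }
  regions <- evaluation_regions(family$ancestor)
  out <- list(); skipped <- character(0)
  ci <- 0L
  for (lab in names(conditions)) {
    ci <- ci + 1L
    ids <- conditions[[lab]]
    if (!length(ids)) { skipped <- c(skipped, lab); next }
    threads <- lapply(ids, function(id)
      partial_thread(msa$rows[[target_id]], msa$rows[[id]],
                     family$members[[id]], target_id = target_id,
                     template_id = id))
    models <- hybridize(threads, n_models = n_models, steps = steps,
                        seed = seed + 1000L * ci,
                        constraints = family$ancestor$disulfides)
    rms <- lapply(models, function(m)
      region_rmsd(m, family$ancestor, regions))
    for (rg in names(regions)) {
      vals <- vapply(rms, function(r) r$rmsd[r$region == rg], numeric(1))
      out[[length(out) + 1L]] <- cbind(
        data.frame(condition = lab, region = rg, n_templates = length(ids),
                   n_models = n_models, stringsAsFactors = FALSE),
        box_stats(vals))
    }
  }
  res <- do.call(rbind, out)
  attr(res, "skipped") <- skipped
  res
}
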