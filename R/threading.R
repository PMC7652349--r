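# Partial threading: map the target sequence onto template coordinates
# through the alignment. Columns gapped in the template leave the target
# residue unmodeled -- no coordinate is ever invented here.

#' Thread a target onto a template through the MSA
#'
#' For every column that is non-gap in both the target and the template
#' row, the target residue receives the template residue's backbone
#' (N, CA, C, O) and an ideal CB reconstructed from that backbone.
#'
#' @param target_row,template_row equal-width gapped rows from one MSA.
#' @param template_entry [receptor_entry] with the template coordinates
#'   (indexed by the template row's ungapped positions).
#' @param target_id,template_id identifiers recorded in the model.
#' @return object of class `threaded_model`: `sequence` (target),
#'   `coords` (`[L, 5, 3]`, NA rows where unmodeled), `provenance`
#'   (template position per target position, NA if unmodeled) and
#'   `coverage` (modeled fraction).
#' @export
partial_thread <- function(target_row, template_row, template_entry,
                           target_id = "target",
                           template_id = template_entry$id) {
  if (nchar(target_row) != nchar(template_row))
    stop("rows of unequal width; both must come from the same MSA")
  tg <- strsplit(target_row, "")[[1L]]
  tp <- strsplit(template_row, "")[[1L]]
  tg_pos <- cumsum(tg != "-")
  tp_pos <- cumsum(tp != "-")
  L <- sum(tg != "-")
  co <- empty_coords(L)
  prov <- rep(NA_integer_, L)
  both <- which(tg != "-" & tp != "-")
  for (k in both) {
    i <- tg_pos[k]; j <- tp_pos[k]
    bb <- template_entry$coords[j, , ]
    if (anyNA(bb["CA", ])) next
    co[i, c("N", "CA", "C", "O"), ] <- bb[c("N", "CA", "C", "O"), ]
    if (!anyNA(bb[c("N", "CA", "C"), ]))
      co[i, "CB", ] <- ideal_cb(bb["N", ], bb["CA", ], bb["C", ])
    prov[i] <- j
  }
  structure(list(target_id = target_id, template_id = template_id,
                 sequence = ungap(target_row), coords = co,
                 provenance = prov,
                 coverage = sum(!is.na(prov)) / L),
            class = "threaded_model")
}

#' @export
print.threaded_model <- function(x, ...) {
  cat(sprintf("<threaded_model> %s on %s: %d aa, coverage %.2f\n",
              x$target_id, x$template_id, nchar(x$sequence), x$coverage))
  invisible(x)
}

#' Write a disulfide restraint file for a receptor
#'
#' One `resi_a resi_b` line per annotated pair, sorted by first index. The
#' conserved TM3--ECL2 pair is emitted with any additional (e.g. ECL3)
#' pairs, unless the entry is flagged disulfide-free (some lipid receptors
#' lack the conserved bond), in which case the file is empty and a warning
#' is raised.
#'
#' @param entry a [receptor_entry] with disulfide annotations.
#' @param path output file; `NULL` returns the lines invisibly.
#' @param disulfide_free emit an empty restraint set.
#' @return character vector of lines, invisibly.
#' @export
make_disulfide_file <- function(entry, path = NULL, disulfide_free = FALSE) {
  if (disulfide_free) {
    warning("entry ", entry$id, " flagged disulfide-free; empty restraint set")
    lines <- character(0)
  } else {
    pairs <- entry$disulfides
    res <- strsplit(entry$sequence, "")[[1L]]
    if (nrow(pairs) && any(res[pairs] != "C"))
      stop("validation error: annotated disulfide residue is not a cysteine")
    if (nrow(pairs)) pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
    lines <- sprintf("%d %d", pairs[, 1L], pairs[, 2L])
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
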