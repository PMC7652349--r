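# File formats and indexing conventions.
#
# Every operation in the package indexes residues 1-based and inclusive.
# Backbone coordinates are stored as a numeric array [L, 5, 3] with atom
# slabs N, CA, C, O, CB; residues without coordinates are all-NA rows.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "CB")

empty_coords <- function(n) {
  array(NA_real_, dim = c(n, 5L, 3L),
        dimnames = list(NULL, BACKBONE_ATOMS, c("x", "y", "z")))
}

#' Construct a receptor entry
#'
#' The central record of the pipeline: one receptor sequence with optional
#' backbone coordinates, transmembrane segment annotations (with the
#' Ballesteros-Weinstein x.50 anchor of each helix), disulfide annotations
#' and a GPCR class label.
#'
#' @param id character identifier.
#' @param sequence one-letter amino-acid string, length >= 1.
#' @param coords optional `[L, 5, 3]` backbone array (atoms N, CA, C, O, CB),
#'   indexed by 1-based sequence position.
#' @param tm_segments optional data.frame with columns `helix` (1..7),
#'   `start`, `end`, `anchor` (1-based inclusive; start <= anchor <= end),
#'   ordered and non-overlapping.
#' @param disulfides integer matrix with two columns of residue indices;
#'   every referenced residue must be a cysteine.
#' @param class_label one of "A", "B", "C", "F", "unknown".
#' @return object of class `receptor_entry`.
#' @export
receptor_entry <- function(id, sequence, coords = NULL, tm_segments = NULL,
                           disulfides = NULL, class_label = "unknown") {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 1L) stop("sequence must have length >= 1")
  if (!is.null(coords)) {
    if (!is.array(coords) || length(dim(coords)) != 3L ||
        dim(coords)[1L] != n || dim(coords)[2L] != 5L || dim(coords)[3L] != 3L)
      stop("coords must be an [L, 5, 3] array matching the sequence length")
    dimnames(coords) <- list(NULL, BACKBONE_ATOMS, c("x", "y", "z"))
  }
  if (!is.null(tm_segments)) {
    tm_segments <- as.data.frame(tm_segments)
    stopifnot(all(c("helix", "start", "end", "anchor") %in% names(tm_segments)))
    tm_segments <- tm_segments[order(tm_segments$helix), , drop = FALSE]
    with(tm_segments, {
      if (any(start > anchor | anchor > end))
        stop("tm_segments must satisfy start <= anchor <= end")
      if (any(start < 1L | end > n))
        stop("tm_segments out of sequence range")
      if (nrow(tm_segments) > 1L && any(diff(start) <= 0) ||
          any(utils::head(end, -1L) >= utils::tail(start, -1L)))
        stop("tm_segments must be ordered and non-overlapping")
    })
  }
  if (!is.null(disulfides) && length(disulfides)) {
    disulfides <- matrix(as.integer(disulfides), ncol = 2L)
    res <- strsplit(sequence, "")[[1L]]
    if (any(disulfides < 1L | disulfides > n))
      stop("disulfide index out of range")
    if (any(res[disulfides] != "C"))
      stop("disulfide pair references a non-cysteine residue")
  } else disulfides <- matrix(integer(0), ncol = 2L)
  class_label <- match.arg(class_label, c("A", "B", "C", "F", "unknown"))
  structure(list(id = id, sequence = sequence, coords = coords,
                 tm_segments = tm_segments, disulfides = disulfides,
                 class_label = class_label),
            class = "receptor_entry")
}

#' @export
print.receptor_entry <- function(x, ...) {
  cat(sprintf("<receptor_entry> %s: %d aa, class %s, %s, %d TM segments, %d disulfide(s)\n",
              x$id, nchar(x$sequence), x$class_label,
              if (is.null(x$coords)) "no coordinates" else "with coordinates",
              if (is.null(x$tm_segments)) 0L else nrow(x$tm_segments),
              nrow(x$disulfides)))
  invisible(x)
}

ca_matrix <- function(x) {
  co <- if (inherits(x, "receptor_entry") || is.list(x)) x$coords else x
  if (is.null(co)) stop("no coordinates present")
  co[, "CA", , drop = TRUE]
}

#' Read a backbone subset from a PDB file
#'
#' Reads ATOM records of the first model through \pkg{bio3d}, keeps one
#' chain (by default the first chain encountered) and the first alternate
#' location, and extracts the N, CA, C, O and CB positions per residue.
#' Residues lacking a CA atom are dropped with a warning. The sequence is
#' derived from the residue names.
#'
#' @param path PDB file.
#' @param chain chain identifier; `NULL` selects the first chain encountered.
#' @return a [receptor_entry] with coordinates.
#' @export
read_pdb <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("format error: no ATOM records in ", path)
  if (is.null(chain)) chain <- at$chain[1L]
  at <- at[at$chain %in% chain, , drop = FALSE]
  # keep unlabelled atoms plus the first alternate-location label
  alt <- at$alt
  alt[is.na(alt)] <- ""
  labels <- sort(unique(alt[alt != ""]))
  keep_alt <- c("", if (length(labels)) labels[1L])
  at <- at[alt %in% keep_alt, , drop = FALSE]
  key <- paste(at$resno, at$insert)
  resk <- unique(key)
  has_ca <- vapply(resk, function(k) any(at$elety[key == k] == "CA"), logical(1))
  if (!any(has_ca)) stop("format error: no CA atoms in ", path)
  if (any(!has_ca))
    warning(sum(!has_ca), " residue(s) lacking CA dropped from ", basename(path))
  resk <- resk[has_ca]
  n <- length(resk)
  co <- empty_coords(n)
  aa3 <- character(n)
  for (i in seq_len(n)) {
    rows <- at[key == resk[i], , drop = FALSE]
    aa3[i] <- rows$resid[1L]
    for (a in BACKBONE_ATOMS) {
      j <- which(rows$elety == a)[1L]
      if (!is.na(j)) co[i, a, ] <- c(rows$x[j], rows$y[j], rows$z[j])
    }
  }
  seq1 <- bio3d::aa321(aa3)
  seq1[is.na(seq1) | seq1 == ""] <- "X"
  receptor_entry(id = sub("\\.pdb$", "", basename(path)),
                 sequence = paste(seq1, collapse = ""), coords = co)
}

#' Write a backbone model as PDB ATOM records
#'
#' Residues without coordinates are omitted entirely (no zero-filled
#' placeholder atoms), so downstream RMSD calculations can never pick up
#' fabricated positions.
#'
#' @param x a [receptor_entry], threaded model, or any list with `sequence`
#'   and a `[L, 5, 3]` `coords` array.
#' @param path output file.
#' @param chain chain identifier to write.
#' @return invisibly, the path.
#' @export
write_pdb <- function(x, path, chain = "A") {
  co <- x$coords
  if (is.null(co)) stop("no coordinates to write")
  res <- strsplit(x$sequence, "")[[1L]]
  aa3 <- vapply(res, function(a) {
    out <- bio3d::aa123(a)
    if (is.na(out)) "UNK" else out
  }, character(1))
  lines <- character(0)
  serial <- 0L
  elem <- c(N = "N", CA = "C", C = "C", O = "O", CB = "C")
  for (i in seq_along(res)) {
    for (a in BACKBONE_ATOMS) {
      xyz <- co[i, a, ]
      if (anyNA(xyz)) next
      serial <- serial + 1L
      lines[length(lines) + 1L] <- sprintf(
        "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, sprintf(" %-3s", a), " ", aa3[i], chain, i, " ",
        xyz[1L], xyz[2L], xyz[3L], 1, 0, elem[[a]])
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Convert a per-residue membrane topology string to membrane spans
#'
#' The topology alphabet is `M` (membrane), `i` (inside) and `o` (outside),
#' the information content of an Octopus-style prediction. Maximal runs of
#' `M` become membrane-spanning segments.
#'
#' @param topology character string over `{M, i, o}`.
#' @return a `span_record`: list with `segments` (two-column matrix of
#'   1-based inclusive start/end) and `total_length`.
#' @export
topology_to_span <- function(topology) {
  stopifnot(is.character(topology), length(topology) == 1L)
  if (grepl("[^Mio]", topology))
    stop("parse error: topology may contain only 'M', 'i', 'o'")
  m <- gregexpr("M+", topology)[[1L]]
  if (m[1L] == -1L) stop("no membrane-spanning segments: not a membrane protein")
  start <- as.integer(m)
  end <- start + attr(m, "match.length") - 1L
  structure(list(segments = cbind(start = start, end = end),
                 total_length = nchar(topology)),
            class = "span_record")
}

#' Write / read a membrane span file
#'
#' Default dialect: a header line `<n_segments> <total_length>` followed by
#' one `start end` pair per line. `rosetta = TRUE` switches to a
#' Rosetta-style layout (comment line, counts, `antiparallel`, `n2c`, then
#' `start end start end` rows).
#'
#' @param span a `span_record` (see [topology_to_span]).
#' @param path file path.
#' @param rosetta write the Rosetta-style variant.
#' @return `write_span` returns the path invisibly; `read_span` a
#'   `span_record`.
#' @export
write_span <- function(span, path, rosetta = FALSE) {
  seg <- span$segments
  if (rosetta) {
    lines <- c("TM region prediction",
               sprintf("%d %d", nrow(seg), span$total_length),
               "antiparallel", "n2c",
               sprintf("%6d%6d%6d%6d", seg[, 1L], seg[, 2L], seg[, 1L], seg[, 2L]))
  } else {
    lines <- c(sprintf("%d %d", nrow(seg), span$total_length),
               sprintf("%d %d", seg[, 1L], seg[, 2L]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_span
#' @export
read_span <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("format error: empty span file")
  hd <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  if (length(hd) != 2L || anyNA(hd)) stop("format error: bad span header")
  seg <- do.call(rbind, lapply(lines[-1L], function(l)
    as.integer(strsplit(trimws(l), "\\s+")[[1L]][1:2])))
  if (nrow(seg) != hd[1L]) stop("format error: segment count mismatch")
  structure(list(segments = cbind(start = seg[, 1L], end = seg[, 2L]),
                 total_length = hd[2L]),
            class = "span_record")
}

#' Construct a gapped multiple sequence alignment object
#'
#' @param rows named character vector of equal-length gapped sequences
#'   (gap character `-`).
#' @param region_masks named list of integer column vectors (TM1..TM7,
#'   ICL1..ICL3, ECL1..ECL3, Nterm, Cterm); masks must be pairwise disjoint.
#' @param anchor_columns named integer vector mapping BW anchors
#'   ("1.50".."7.50") to columns.
#' @param disulfide_columns named integer vector of disulfide cysteine
#'   columns (e.g. "TM3", "ECL2").
#' @param aligned_cols integer vector of columns considered structurally
#'   defined (used by [place_unalignable_residues]).
#' @return object of class `gpcr_msa`.
#' @export
new_msa <- function(rows, region_masks = list(), anchor_columns = integer(0),
                    disulfide_columns = integer(0), aligned_cols = integer(0)) {
  stopifnot(is.character(rows), length(rows) >= 1L, !is.null(names(rows)))
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("format error: ragged MSA rows")
  if (length(region_masks)) {
    allc <- unlist(region_masks, use.names = FALSE)
    if (anyDuplicated(allc)) stop("region masks must be disjoint")
  }
  structure(list(rows = rows, width = w, region_masks = region_masks,
                 anchor_columns = anchor_columns,
                 disulfide_columns = disulfide_columns,
                 aligned_cols = sort(unique(as.integer(aligned_cols)))),
            class = "gpcr_msa")
}

#' @export
print.gpcr_msa <- function(x, ...) {
  cat(sprintf("<gpcr_msa> %d rows x %d columns; %d region masks, %d anchors\n",
              length(x$rows), x$width, length(x$region_masks),
              length(x$anchor_columns)))
  invisible(x)
}

ungap <- function(s) gsub("-", "", s, fixed = TRUE)

msa_char <- function(msa) {
  do.call(rbind, strsplit(msa$rows, ""))
}

#' Read / write a multiple sequence alignment
#'
#' FASTA alignments go through \pkg{bio3d}; the Clustal dialect is parsed
#' by a small reader here (header line, blocks of `id  residues` lines).
#' All rows must have equal gapped length.
#'
#' @param path file path.
#' @param format "fasta" or "clustal".
#' @param msa a `gpcr_msa` (writing; region masks are not serialised).
#' @return `read_msa` returns a `gpcr_msa`.
#' @export
read_msa <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("format error: empty alignment file")
  if (format == "fasta") {
    aln <- bio3d::read.fasta(path)
    if (!length(aln$id)) stop("format error: no sequences in ", path)
    mat <- aln$ali
    mat[is.na(mat)] <- "-"
    rows <- apply(mat, 1L, paste, collapse = "")
    names(rows) <- aln$id
  } else {
    lines <- readLines(path)
    if (!length(lines) || !startsWith(lines[1L], "CLUSTAL"))
      stop("format error: not a Clustal alignment")
    lines <- lines[-1L]
    # sequence lines: identifier, whitespace, residues; skip blank and
    # conservation lines (which start with whitespace)
    keep <- nzchar(lines) & !grepl("^\\s", lines)
    parts <- regmatches(lines[keep],
                        regexec("^(\\S+)\\s+([A-Za-z.~-]+)", lines[keep]))
    rows <- character(0)
    for (p in parts) {
      if (length(p) < 3L) next
      id <- p[2L]
      rows[id] <- paste0(if (id %in% names(rows)) rows[[id]] else "",
                         toupper(p[3L]))
    }
    if (!length(rows)) stop("format error: no sequences in ", path)
  }
  if (length(unique(nchar(rows))) != 1L) stop("format error: ragged MSA rows")
  new_msa(rows)
}

#' @rdname read_msa
#' @export
write_msa <- function(msa, path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "fasta") {
    out <- character(0)
    for (id in names(msa$rows)) {
      seqs <- msa$rows[[id]]
      chunks <- substring(seqs, seq(1L, nchar(seqs), 60L),
                          pmin(seq(1L, nchar(seqs), 60L) + 59L, nchar(seqs)))
      out <- c(out, paste0(">", id), chunks)
    }
    writeLines(out, path)
  } else {
    ids <- sprintf("%-16s", names(msa$rows))
    out <- c("CLUSTAL W multiple sequence alignment", "")
    for (off in seq(1L, msa$width, 60L)) {
      blk <- substring(msa$rows, off, pmin(off + 59L, msa$width))
      out <- c(out, paste0(ids, blk), "")
    }
    writeLines(out, path)
  }
  invisible(path)
}

#' Write / read a disulfide constraint file
#'
#' One `resi_a resi_b` pair per line, 1-based residue indices.
#'
#' @param pairs two-column integer matrix.
#' @param path file path.
#' @return `read_disulfide_file` returns a two-column integer matrix.
#' @export
write_disulfide_file <- function(pairs, path) {
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (nrow(pairs)) pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  writeLines(sprintf("%d %d", pairs[, 1L], pairs[, 2L]), path)
  invisible(path)
}

#' @rdname write_disulfide_file
#' @export
read_disulfide_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(matrix(integer(0), ncol = 2L))
  out <- do.call(rbind, lapply(lines, function(l)
    as.integer(strsplit(trimws(l), "\\s+")[[1L]][1:2])))
  if (anyNA(out)) stop("format error: bad disulfide line")
  out
}

#' Read a plain FASTA sequence file
#'
#' @param path FASTA file; gaps, if any, are removed.
#' @return named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  aln <- bio3d::read.fasta(path)
  mat <- aln$ali
  mat[is.na(mat)] <- ""
  rows <- ungap(apply(mat, 1L, paste, collapse = ""))
  names(rows) <- aln$id
  rows
}
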