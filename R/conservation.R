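#' Read a multiple sequence alignment
#'
#' Reads an aligned FASTA (via Biostrings) or Stockholm file into an `msa`
#' object. All aligned strings must be of equal length. The `provenance`
#' note records upstream filtering metadata (for example the E-value cutoff
#' applied when the alignment was built); this package never computes
#' alignment statistics against a database.
#'
#' @param path alignment path.
#' @param format `"auto"` (detect by content), `"fasta"` or `"stockholm"`.
#' @param provenance free-text metadata string.
#' @return An `msa`: list with `ids`, `seqs` (uppercase aligned strings)
#'   and `provenance`.
#' @export
read_msa <- function(path, format = c("auto", "fasta", "stockholm"),
                     provenance = NA_character_) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (grepl("^# STOCKHOLM", first)) "stockholm" else "fasta"
  }
  if (format == "fasta") {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stop("Biostrings is required to read FASTA alignments")
    ss <- Biostrings::readAAStringSet(path)
    ids <- sub("\\s.*$", "", names(ss))
    seqs <- toupper(as.character(ss))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^#", lines) & !grepl("^//", lines) &
                     nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "\\s+")
    ids0 <- vapply(parts, `[[`, character(1), 1L)
    seq0 <- vapply(parts, function(p) paste(p[-1], collapse = ""), character(1))
    # multi-block Stockholm: concatenate per id, preserving first-seen order
    ids <- unique(ids0)
    seqs <- vapply(ids, function(i)
      toupper(paste(seq0[ids0 == i], collapse = "")), character(1))
  }
  seqs <- gsub("\\.", "-", seqs)
  msa(ids, unname(seqs), provenance)
}

#' Construct an MSA object
#'
#' @param ids sequence identifiers.
#' @param seqs aligned sequences (equal length, gaps as `-`).
#' @param provenance optional metadata note.
#' @return An `msa`.
#' @export
msa <- function(ids, seqs, provenance = NA_character_) {
  if (length(ids) != length(seqs)) stop("ids and seqs length mismatch")
  if (!length(seqs)) stop("empty alignment")
  if (length(unique(nchar(seqs))) != 1L)
    stop("aligned sequences must all have the same length")
  structure(list(ids = as.character(ids), seqs = toupper(seqs),
                 provenance = provenance), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences x %d columns%s\n", length(x$ids),
              nchar(x$seqs[1]),
              if (!is.na(x$provenance)) paste0(" (", x$provenance, ")") else ""))
  invisible(x)
}

#' Map BW-coded sites to alignment columns
#'
#' Walks the reference row of the alignment, skipping gap columns, and pairs
#' reference residue positions with BW codes from the annotation (ungapped
#' reference position `i` corresponds to author residue number
#' `ref_offset + i - 1` on `ref_chain`). Only annotated positions are
#' returned.
#'
#' @param x an [msa].
#' @param reference_id id of the reference sequence.
#' @param annotation a `bw_annotation`.
#' @param ref_chain chain of the reference in the annotation (default "A").
#' @param ref_offset author residue number of the first reference residue.
#' @return Named integer vector: BW code -> 1-based alignment column.
#' @export
map_columns <- function(x, reference_id, annotation, ref_chain = "A",
                        ref_offset = 1L) {
  idx <- match(reference_id, x$ids)
  if (is.na(idx)) stop("reference sequence '", reference_id, "' not in MSA")
  chars <- strsplit(x$seqs[idx], "")[[1]]
  cols <- which(chars != "-")
  out <- integer()
  for (i in seq_along(cols)) {
    hit <- bw_lookup(annotation, ref_chain, ref_offset + i - 1L)
    if (!is.null(hit) && !is.na(hit$bw)) out[hit$bw] <- cols[i]
  }
  if (anyDuplicated(out)) stop("site map is not injective")
  out
}

# characters of one alignment column
.msa_column <- function(x, col) {
  vapply(x$seqs, function(s) substr(s, col, col), character(1), USE.NAMES = FALSE)
}

#' Residue frequency at a BW-coded site
#'
#' Fraction of sequences carrying `residue` at the mapped column. Gapped
#' sequences are excluded from the denominator by default (standard
#' conservation practice); set `count_gaps = TRUE` to include them.
#'
#' @param x an [msa].
#' @param site_map map from [map_columns].
#' @param bw_code site BW code.
#' @param residue one-letter amino acid.
#' @param count_gaps include gapped sequences in the denominator.
#' @return Frequency in `[0, 1]`.
#' @export
site_conservation <- function(x, site_map, bw_code, residue,
                              count_gaps = FALSE) {
  if (!(bw_code %in% names(site_map))) stop("site ", bw_code, " not mapped")
  col <- .msa_column(x, site_map[[bw_code]])
  den <- if (count_gaps) length(col) else sum(col != "-")
  if (den == 0L) stop("undefined frequency: all sequences gapped at ", bw_code)
  sum(col == toupper(residue)) / den
}

#' Designed-motif co-occurrence in natural sequences
#'
#' Counts alignment sequences that simultaneously carry at least `min_k` of
#' the designed (site, residue) pairs, reporting the matching ids. This is
#' the check of whether combinations of designed mutations occur together
#' in natural receptors.
#'
#' @param x an [msa].
#' @param site_map map from [map_columns].
#' @param design_mutations data.frame with columns `bw` and `residue`.
#' @param min_k minimum number of designed residues carried (default 2).
#' @return list with `n` (count), `ids` (matching sequence ids) and
#'   `per_sequence` (match count per sequence).
#' @export
motif_cooccurrence <- function(x, site_map, design_mutations, min_k = 2L) {
  if (min_k < 1L) stop("min_k must be at least 1")
  unmapped <- setdiff(design_mutations$bw, names(site_map))
  if (length(unmapped))
    stop("unmapped sites: ", paste(unmapped, collapse = ", "))
  hits <- rep(0L, length(x$ids))
  for (i in seq_len(nrow(design_mutations))) {
    col <- .msa_column(x, site_map[[design_mutations$bw[i]]])
    hits <- hits + (col == toupper(design_mutations$residue[i]))
  }
  sel <- hits >= min_k
  list(n = sum(sel), ids = x$ids[sel],
       per_sequence = stats::setNames(hits, x$ids))
}

#' Conservation report over designed sites
#'
#' Per-site frequencies of the reference and designed residues, the TSV
#' report companion of [site_conservation].
#'
#' @param x an [msa].
#' @param site_map map from [map_columns].
#' @param sites data.frame with columns `bw`, `reference_aa`, `designed_aa`.
#' @return data.frame with `freq_reference` and `freq_designed` appended.
#' @export
conservation_report <- function(x, site_map, sites) {
  sites$freq_reference <- vapply(seq_len(nrow(sites)), function(i)
    site_conservation(x, site_map, sites$bw[i], sites$reference_aa[i]),
    numeric(1))
  sites$freq_designed <- vapply(seq_len(nrow(sites)), function(i)
    site_conservation(x, site_map, sites$bw[i], sites$designed_aa[i]),
    numeric(1))
  sites
}
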