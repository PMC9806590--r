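# Alignment gap-column filtering, column residue frequencies, and mapping of
# alignment columns onto an ungapped reference (motif support).

GAP_CHARS <- c("-", ".")

#' Construct an amino-acid alignment object
#'
#' A light container around a named character vector of equal-length aligned
#' sequences. Residues are uppercased on construction; `-` and `.` count as
#' gaps, letters (including `X`) do not.
#'
#' @param records Named character vector of aligned sequences, or a
#'   `Biostrings::AAStringSet`.
#' @return Object of class `aa_alignment` with attributes `n_columns`.
#' @export
aa_alignment <- function(records) {
  if (methods::is(records, "XStringSet")) {
    records <- stats::setNames(as.character(records), names(records))
  }
  stopifnot(is.character(records), length(records) >= 1L)
  if (is.null(names(records)) || anyDuplicated(names(records))) {
    stop("aligned sequences must have unique names")
  }
  records <- toupper(records)
  widths <- nchar(records)
  if (length(unique(widths)) != 1L) {
    stop("ragged alignment: sequence lengths ",
         paste(unique(widths), collapse = ", "))
  }
  structure(records, n_columns = widths[1L], class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("aa_alignment: ", length(x), " sequences x ", attr(x, "n_columns"),
      " columns\n", sep = "")
  invisible(x)
}

aln_matrix <- function(aln) {
  ncol <- attr(aln, "n_columns")
  matrix(unlist(strsplit(unclass(aln), "")), nrow = length(aln), ncol = ncol,
         byrow = TRUE, dimnames = list(names(aln), NULL))
}

#' Read / write an aligned FASTA file
#'
#' @param path File path.
#' @return `read_alignment()` returns an `aa_alignment`.
#' @export
read_alignment <- function(path) {
  aa_alignment(Biostrings::readAAStringSet(path))
}

#' @rdname read_alignment
#' @param aln An `aa_alignment`.
#' @export
write_alignment <- function(aln, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(unclass(aln)), path)
  invisible(aln)
}

column_gap_fraction <- function(aln) {
  m <- aln_matrix(aln)
  colMeans(matrix(m %in% GAP_CHARS, nrow = nrow(m)))
}

#' Remove alignment columns exceeding a gap fraction
#'
#' A column is removed iff its gap fraction (gap count / sequence count) is
#' strictly greater than `max_gap_frac`; a column at exactly the threshold is
#' kept. The default 0.40 removes columns with more than 40% gaps. All-gap
#' columns (possible in subsetted alignments) are flagged via the
#' `all_gap_removed` attribute of the result.
#'
#' @param aln An `aa_alignment`.
#' @param max_gap_frac Gap-fraction threshold in \[0, 1\].
#' @return List with `alignment` (filtered `aa_alignment`) and `kept_columns`
#'   (integer vector mapping new 1-based column indices to original ones).
#' @export
filter_gap_columns <- function(aln, max_gap_frac = 0.40) {
  stopifnot(inherits(aln, "aa_alignment"),
            max_gap_frac >= 0, max_gap_frac <= 1)
  gf <- column_gap_fraction(aln)
  kept <- which(gf <= max_gap_frac)
  m <- aln_matrix(aln)[, kept, drop = FALSE]
  recs <- stats::setNames(apply(m, 1L, paste, collapse = ""), names(aln))
  if (attr(aln, "n_columns") > 0L && length(kept) == 0L) {
    recs <- stats::setNames(rep("", length(aln)), names(aln))
  }
  out <- aa_alignment_allow_empty(recs)
  attr(out, "all_gap_removed") <- which(gf >= 1)
  list(alignment = out, kept_columns = kept)
}

# internal: aa_alignment() forbids nothing else, but zero-column alignments
# arise when every column is filtered away
aa_alignment_allow_empty <- function(records) {
  records <- toupper(records)
  widths <- unique(nchar(records))
  stopifnot(length(widths) == 1L)
  structure(records, n_columns = widths, class = "aa_alignment")
}

#' Per-column residue frequencies
#'
#' For each requested column, tabulates residue frequencies over the non-gap
#' characters (frequencies sum to 1) and reports the gap fraction separately.
#' All-gap columns yield no residue rows and are flagged.
#'
#' @param aln An `aa_alignment`.
#' @param columns 1-based column indices (default: all columns).
#' @return List with `frequencies` (data frame `column`, `residue`, `freq`),
#'   `gap_frac` (named numeric per column) and `all_gap` (logical per column).
#' @export
column_frequencies <- function(aln, columns = seq_len(attr(aln, "n_columns"))) {
  stopifnot(inherits(aln, "aa_alignment"))
  nc <- attr(aln, "n_columns")
  if (length(columns) && (min(columns) < 1L || max(columns) > nc)) {
    stop("column index out of range 1..", nc)
  }
  m <- aln_matrix(aln)
  rows <- list()
  gap_frac <- stats::setNames(numeric(length(columns)), columns)
  all_gap <- stats::setNames(logical(length(columns)), columns)
  for (k in seq_along(columns)) {
    col <- m[, columns[k]]
    is_gap <- col %in% GAP_CHARS
    gap_frac[k] <- mean(is_gap)
    res <- col[!is_gap]
    if (!length(res)) {
      all_gap[k] <- TRUE
      next
    }
    tab <- table(res)
    rows[[length(rows) + 1L]] <- data.frame(
      column = columns[k], residue = names(tab),
      freq = as.numeric(tab) / length(res), stringsAsFactors = FALSE)
  }
  freqs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(column = integer(), residue = character(), freq = double())
  rownames(freqs) <- NULL
  list(frequencies = freqs, gap_frac = gap_frac, all_gap = all_gap)
}

#' Map alignment columns to ungapped reference positions
#'
#' Motif windows (e.g. the catalytic-glutamate region or dimerisation
#' interfaces of a reference TIR domain) are usually described in ungapped
#' coordinates of one reference sequence. This returns, for every alignment
#' column, the 1-based position in the ungapped reference, or `NA` where the
#' reference carries a gap. Defined values are strictly increasing.
#'
#' @param aln An `aa_alignment`.
#' @param ref_id Name of the reference sequence in `aln`.
#' @return Integer vector of length `n_columns`.
#' @export
map_reference_columns <- function(aln, ref_id) {
  stopifnot(inherits(aln, "aa_alignment"))
  if (!ref_id %in% names(aln)) {
    stop("reference sequence not in alignment: ", ref_id)
  }
  chars <- strsplit(unclass(aln)[[ref_id]], "")[[1L]]
  non_gap <- !(chars %in% GAP_CHARS)
  out <- rep(NA_integer_, length(chars))
  out[non_gap] <- seq_len(sum(non_gap))
  out
}

#' Write a kept-column map or frequency table to TSV
#'
#' @param kept_columns Integer vector from [filter_gap_columns()].
#' @param path Output file.
#' @export
write_column_map <- function(kept_columns, path) {
  utils::write.table(
    data.frame(new = seq_along(kept_columns), old = kept_columns),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(kept_columns)
}

#' @rdname write_column_map
#' @param frequencies Data frame from [column_frequencies()].
#' @export
write_frequencies <- function(frequencies, path) {
  utils::write.table(frequencies, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(frequencies)
}
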