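# Presence-absence matrices over species and strict co-occurrence pattern
# matching (phylogenetic profiling of orthogroups and gene families).

#' Construct a presence-absence matrix
#'
#' @param m Logical matrix with unique row names (family or orthogroup ids)
#'   and unique column names (species ids).
#' @param provenance `"family_counts"` or `"orthogroups"`.
#' @return Object of class `presence_matrix` (a logical matrix).
#' @export
presence_matrix <- function(m, provenance = c("family_counts", "orthogroups")) {
  provenance <- match.arg(provenance)
  stopifnot(is.matrix(m), is.logical(m))
  # R drops character(0) dimnames on empty dimensions, so only non-empty
  # dimensions must be named
  if ((nrow(m) > 0L && is.null(rownames(m))) ||
      (ncol(m) > 0L && is.null(colnames(m)))) {
    stop("presence matrix needs row and column names")
  }
  if (anyDuplicated(rownames(m))) stop("duplicate row ids")
  if (anyDuplicated(colnames(m))) stop("duplicate species ids")
  structure(m, provenance = provenance,
            class = c("presence_matrix", "matrix", "array"))
}

#' Read an orthogroup gene-list table
#'
#' Standard orthology-inference layout: first column `Orthogroup`, one column
#' per species, cells are comma-separated gene lists (possibly empty).
#'
#' @param path TSV file path.
#' @return Data frame (character columns, first column `Orthogroup`).
#' @export
read_orthogroups <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", comment.char = "")
  if (ncol(tab) < 2L) stop("orthogroup table needs an id column plus species columns")
  names(tab)[1L] <- "Orthogroup"
  tab
}

#' Binarize an orthogroup table into species presence
#'
#' A cell is `TRUE` iff the species' gene list for that orthogroup is
#' non-empty after trimming whitespace; copy number is deliberately ignored
#' (presence is defined at the species level, >= 1 gene).
#'
#' @param og_table Data frame from [read_orthogroups()], or a file path.
#' @return A `presence_matrix` with provenance `"orthogroups"`.
#' @export
binarize_orthogroups <- function(og_table) {
  if (is.character(og_table) && length(og_table) == 1L) {
    og_table <- read_orthogroups(og_table)
  }
  ids <- og_table[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate orthogroup ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  species <- names(og_table)[-1L]
  m <- vapply(species, function(s) nzchar(trimws(og_table[[s]])),
              logical(nrow(og_table)))
  if (nrow(og_table) == 1L) m <- matrix(m, nrow = 1L)
  dimnames(m) <- list(ids, species)
  presence_matrix(m, provenance = "orthogroups")
}

#' Extract rows matching a presence/absence pattern
#'
#' Returns the ids of rows whose value equals the query at every required
#' species. Matching is strict by default (the screen for candidates
#' co-distributing with a marker family imposes an exact pattern); species
#' not named in the query are free and ignored. A small mismatch budget can
#' be allowed with `max_mismatches`.
#'
#' @param matrix A `presence_matrix`.
#' @param query Named logical vector: `TRUE` = required present, `FALSE` =
#'   required absent; names are species ids.
#' @param max_mismatches Number of required species allowed to disagree
#'   (default 0, strict).
#' @return Character vector of matching row ids, in matrix order.
#' @export
match_pattern <- function(matrix, query, max_mismatches = 0L) {
  stopifnot(inherits(matrix, "presence_matrix"), is.logical(query),
            length(query) >= 1L, max_mismatches >= 0L)
  if (is.null(names(query)) || anyDuplicated(names(query))) {
    stop("query must be a uniquely named logical vector")
  }
  unknown <- setdiff(names(query), colnames(matrix))
  if (length(unknown)) {
    stop("query species not in matrix: ", paste(unknown, collapse = ", "))
  }
  sub <- matrix[, names(query), drop = FALSE]
  mism <- rowSums(sub != matrix(query, nrow = nrow(sub), ncol = length(query),
                                byrow = TRUE))
  rownames(matrix)[mism <= max_mismatches]
}

#' Read a pattern file
#'
#' Two-column TSV (`species_id`, `0/1`), with or without header.
#'
#' @param path File path.
#' @return Named logical vector usable as a [match_pattern()] query.
#' @export
read_pattern <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("species_id", "present"))
  if (identical(tolower(tab$species_id[1L]), "species_id")) tab <- tab[-1L, ]
  stats::setNames(as.integer(tab$present) > 0L, tab$species_id)
}

#' Agreement between two presence profiles
#'
#' @param matrix A `presence_matrix`.
#' @param row_a,row_b Row ids.
#' @return Named numeric vector: `jaccard` (intersection over union of the
#'   present-species sets; 1 when both are empty) and `hamming_agreement`
#'   (fraction of species with equal value).
#' @export
profile_agreement <- function(matrix, row_a, row_b) {
  stopifnot(inherits(matrix, "presence_matrix"))
  miss <- setdiff(c(row_a, row_b), rownames(matrix))
  if (length(miss)) stop("row id(s) not in matrix: ", paste(miss, collapse = ", "))
  a <- matrix[row_a, ]; b <- matrix[row_b, ]
  uni <- sum(a | b)
  jac <- if (uni == 0L) 1 else sum(a & b) / uni
  c(jaccard = jac, hamming_agreement = mean(a == b))
}

#' Presence matrix from per-species family counts
#'
#' Combines an architecture counts table (TNL/TN/TIR-only/TNP per species)
#' with an additional family count table (e.g. EDS1/PAD4/SAG101, ADR1/NRG1)
#' into one family x species presence matrix. Presence means count >= 1.
#' Both tables must cover the same species.
#'
#' @param arch_counts Data frame from [tabulate_architectures()], or `NULL`.
#' @param family_counts Data frame with `species_id` plus one numeric column
#'   per family, or `NULL`.
#' @return A `presence_matrix` with provenance `"family_counts"`.
#' @export
family_presence_from_counts <- function(arch_counts = NULL, family_counts = NULL) {
  tabs <- Filter(Negate(is.null), list(arch_counts, family_counts))
  if (!length(tabs)) stop("need at least one count table")
  for (tab in tabs) {
    stopifnot("species_id" %in% names(tab))
    if (any(vapply(tab[setdiff(names(tab), "species_id")],
                   function(x) any(x < 0), TRUE))) {
      stop("counts must be non-negative")
    }
  }
  if (length(tabs) == 2L) {
    d1 <- setdiff(tabs[[1L]]$species_id, tabs[[2L]]$species_id)
    d2 <- setdiff(tabs[[2L]]$species_id, tabs[[1L]]$species_id)
    if (length(d1) || length(d2)) {
      stop("species missing from one table: ",
           paste(unique(c(d1, d2)), collapse = ", "))
    }
  }
  species <- tabs[[1L]]$species_id
  rows <- list()
  for (tab in tabs) {
    tab <- tab[match(species, tab$species_id), , drop = FALSE]
    for (fam in setdiff(names(tab), "species_id")) {
      rows[[fam]] <- as.numeric(tab[[fam]]) >= 1
    }
  }
  m <- do.call(rbind, rows)
  dimnames(m) <- list(names(rows), species)
  presence_matrix(m, provenance = "family_counts")
}

#' Apply a keep-list to a candidate id list
#'
#' Downstream refinement of pattern matches (e.g. reciprocal BLAST against
#' discriminatory species) is a manual external step; its outcome comes back
#' as a keep-list of ids that survived.
#'
#' @param ids Candidate ids from [match_pattern()].
#' @param keep Character vector of ids to keep, or a path to a one-id-per-line
#'   file.
#' @return The filtered ids, preserving input order.
#' @export
apply_keep_list <- function(ids, keep) {
  if (is.character(keep) && length(keep) == 1L && file.exists(keep)) {
    keep <- readLines(keep)
  }
  ids[ids %in% trimws(keep)]
}

#' Write a presence matrix to TSV
#'
#' Cells are written as 0/1; a round trip through [read_presence_matrix()]
#' reproduces the matrix.
#'
#' @param matrix A `presence_matrix`.
#' @param path Output file.
#' @export
write_presence_matrix <- function(matrix, path) {
  ints <- matrix * 1L
  df <- data.frame(id = rownames(matrix), ints, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(matrix)
}

#' @rdname write_presence_matrix
#' @param provenance Provenance tag for the reconstructed matrix.
#' @export
read_presence_matrix <- function(path, provenance = "orthogroups") {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE]) > 0
  rownames(m) <- tab[[1L]]
  presence_matrix(m, provenance = provenance)
}
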