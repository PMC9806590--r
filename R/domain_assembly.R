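# Domain-hit assembly and full-length protein architecture classification.

#' Recognised domain classes and architecture labels
#'
#' `domain_classes()` returns the domain classes used throughout the package;
#' `architecture_labels()` the full-length architecture labels. TNP is the
#' TIR-NBARC-tetratricopeptide-repeat architecture; TNL the canonical
#' TIR-NBARC-LRR immune receptor; TN a truncated TIR-NBARC protein; TIR_ONLY
#' a short (< 400 aa by default) protein whose only predicted domain is a TIR.
#'
#' @return Character vector.
#' @export
domain_classes <- function() c("TIR", "NBARC", "LRR", "TPR", "OTHER")

#' @rdname domain_classes
#' @export
architecture_labels <- function() {
  c("TNP", "TNL", "TN", "TIR_ONLY", "TIR_OTHER", "NON_TIR")
}

#' Default HMM-name to domain-class mapping
#'
#' Maps common Pfam HMM names for TIR, NB-ARC, LRR and TPR models to the
#' package's domain classes. The mapping is an ordinary data frame and is
#' meant to be extended or replaced by the user (see [read_class_map()]);
#' any HMM name not covered by the mapping is classed `OTHER`.
#'
#' @return Data frame with columns `hmm_name`, `domain_class`.
#' @export
default_class_map <- function() {
  data.frame(
    hmm_name = c(
      "TIR", "TIR_2", "TIR_3", "TIR-like",
      "NB-ARC", "NBARC",
      paste0("LRR_", 1:9),
      paste0("TPR_", 1:12)
    ),
    domain_class = c(
      rep("TIR", 4L),
      rep("NBARC", 2L),
      rep("LRR", 9L),
      rep("TPR", 12L)
    ),
    stringsAsFactors = FALSE
  )
}

#' Read an HMM-name to domain-class mapping table
#'
#' Two-column TSV (`hmm_name`, `domain_class`), with or without a header.
#'
#' @param path File path.
#' @return Data frame with columns `hmm_name`, `domain_class`.
#' @export
read_class_map <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           col.names = c("hmm_name", "domain_class"))
  if (nrow(tab) > 0L && identical(tolower(tab$hmm_name[1L]), "hmm_name")) {
    tab <- tab[-1L, , drop = FALSE]
  }
  bad <- setdiff(unique(tab$domain_class), domain_classes())
  if (length(bad)) {
    stop("unknown domain classes in mapping: ", paste(bad, collapse = ", "))
  }
  rownames(tab) <- NULL
  tab
}

map_domain_class <- function(hmm_name, class_map) {
  cls <- class_map$domain_class[match(hmm_name, class_map$hmm_name)]
  cls[is.na(cls)] <- "OTHER"
  cls
}

validate_hits <- function(hits) {
  need <- c("protein_id", "hmm_name", "domain_class", "env_start", "env_end",
            "evalue")
  miss <- setdiff(need, names(hits))
  if (length(miss)) stop("hit table lacks columns: ", paste(miss, collapse = ", "))
  if (any(hits$env_start < 1L)) stop("env_start must be >= 1")
  if (any(hits$env_end < hits$env_start)) stop("env_end must be >= env_start")
  if (any(hits$evalue < 0)) stop("evalue must be non-negative")
  invisible(hits)
}

#' Parse a domain-search hit table
#'
#' Reads per-domain hits either from HMMER3 per-domain tabular output
#' ("domtblout", whitespace-delimited with `#` comment lines) or from a plain
#' 6-column TSV (`protein_id`, `hmm_name`, `env_start`, `env_end`, `evalue`,
#' `protein_length`). Envelope coordinates are 1-based and inclusive and are
#' preserved verbatim. Hits with independent E-value above `max_evalue` are
#' dropped at parse time, mirroring an inclusion threshold applied during the
#' search itself.
#'
#' @param path File path.
#' @param class_map Data frame mapping `hmm_name` to `domain_class`; unknown
#'   names map to `OTHER`.
#' @param max_evalue Retain only hits with `evalue <= max_evalue`.
#' @param format `"auto"` (sniff), `"domtblout"` or `"tsv"`.
#' @return Data frame of hits with columns `protein_id`, `hmm_name`,
#'   `domain_class`, `env_start`, `env_end`, `evalue`, `protein_length`
#'   (`NA` when the format does not carry it).
#' @export
parse_hit_table <- function(path, class_map = default_class_map(),
                            max_evalue = 0.01,
                            format = c("auto", "domtblout", "tsv")) {
  format <- match.arg(format)
  stopifnot(max_evalue > 0)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  empty <- data.frame(protein_id = character(), hmm_name = character(),
                      domain_class = character(), env_start = integer(),
                      env_end = integer(), evalue = double(),
                      protein_length = integer(), stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  if (format == "auto") {
    nf <- length(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
    format <- if (nf >= 22L) "domtblout" else "tsv"
  }
  parse_line <- function(i) {
    f <- strsplit(trimws(lines[i]), if (format == "tsv") "\t" else "\\s+")[[1L]]
    if (format == "domtblout") {
      if (length(f) < 22L) {
        stop("malformed domtblout line ", lineno[i], ": expected >= 22 fields, got ",
             length(f))
      }
      # fields: 1 target, 3 tlen, 4 query (HMM), 13 i-Evalue, 20-21 env from/to
      out <- list(protein_id = f[1L], hmm_name = f[4L],
                  env_start = f[20L], env_end = f[21L],
                  evalue = f[13L], protein_length = f[3L])
    } else {
      if (length(f) < 5L) {
        stop("malformed TSV line ", lineno[i], ": expected >= 5 fields, got ",
             length(f))
      }
      out <- list(protein_id = f[1L], hmm_name = f[2L],
                  env_start = f[3L], env_end = f[4L], evalue = f[5L],
                  protein_length = if (length(f) >= 6L) f[6L] else NA_character_)
    }
    num <- suppressWarnings(as.numeric(out[c("env_start", "env_end", "evalue")]))
    if (anyNA(num)) stop("malformed line ", lineno[i], ": non-numeric coordinate or E-value")
    out
  }
  first <- strsplit(trimws(lines[1L]), if (format == "tsv") "\t" else "\\s+")[[1L]]
  # tolerate a TSV header row
  if (format == "tsv" && identical(tolower(first[1L]), "protein_id")) {
    lines <- lines[-1L]; lineno <- lineno[-1L]
    if (!length(lines)) return(empty)
  }
  rows <- lapply(seq_along(lines), parse_line)
  hits <- data.frame(
    protein_id = vapply(rows, `[[`, "", "protein_id"),
    hmm_name = vapply(rows, `[[`, "", "hmm_name"),
    env_start = as.integer(vapply(rows, function(r) as.numeric(r$env_start), 0)),
    env_end = as.integer(vapply(rows, function(r) as.numeric(r$env_end), 0)),
    evalue = vapply(rows, function(r) as.numeric(r$evalue), 0),
    protein_length = suppressWarnings(
      as.integer(vapply(rows, function(r) as.numeric(r$protein_length), 0))),
    stringsAsFactors = FALSE
  )
  if (any(hits$env_start < 1L | hits$env_end < 1L)) {
    stop("envelope coordinates must be positive (1-based)")
  }
  hits$domain_class <- map_domain_class(hits$hmm_name, class_map)
  hits <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  rownames(hits) <- NULL
  validate_hits(hits)
  hits[, c("protein_id", "hmm_name", "domain_class", "env_start", "env_end",
           "evalue", "protein_length")]
}

hit_overlap <- function(s1, e1, s2, e2) {
  pmin(e1, e2) - pmax(s1, s2) + 1L
}

#' Remove redundant overlapping hits within one protein
#'
#' Same-class hits whose envelopes overlap by more than `max_overlap`
#' residues are treated as redundant detections of one domain by different
#' HMMs. Redundant hits are grouped into connected components under the
#' "overlap > max_overlap" relation and exactly one representative per
#' component is retained: the hit with the lowest E-value, ties broken by the
#' longer envelope, then by lexicographic HMM name. Hits of different domain
#' classes never suppress each other. Overlap between 1-based inclusive
#' envelopes is `min(end1, end2) - max(start1, start2) + 1`.
#'
#' @param hits Data frame of hits for a single protein.
#' @param max_overlap Largest tolerated overlap in residues (default 20;
#'   overlap strictly greater than this triggers deduplication).
#' @return The retained hits, sorted by `env_start`.
#' @export
merge_overlapping_hits <- function(hits, max_overlap = 20L) {
  validate_hits(hits)
  if (nrow(hits) == 0L) return(hits)
  if (length(unique(hits$protein_id)) > 1L) {
    stop("merge_overlapping_hits expects hits for a single protein; got ",
         length(unique(hits$protein_id)))
  }
  keep <- logical(nrow(hits))
  for (cls in unique(hits$domain_class)) {
    idx <- which(hits$domain_class == cls)
    n <- length(idx)
    s <- hits$env_start[idx]; e <- hits$env_end[idx]
    # overlap graph: edges where pairwise envelope overlap exceeds the limit
    ov <- outer(e, e, pmin) - outer(s, s, pmax) + 1L
    adj <- ov > max_overlap
    comp <- integer(n); cur <- 0L
    for (i in seq_len(n)) {
      if (comp[i] > 0L) next
      cur <- cur + 1L
      comp[i] <- cur
      frontier <- i
      while (length(frontier)) {
        reach <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & comp == 0L)
        comp[reach] <- cur
        frontier <- reach
      }
    }
    for (cc in seq_len(cur)) {
      members <- idx[comp == cc]
      sub <- hits[members, , drop = FALSE]
      len <- sub$env_end - sub$env_start + 1L
      ord <- order(sub$evalue, -len, sub$hmm_name)
      keep[members[ord[1L]]] <- TRUE
    }
  }
  out <- hits[keep, , drop = FALSE]
  out <- out[order(out$env_start, out$env_end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enforce per-class minimum domain lengths
#'
#' Drops hits whose envelope length (`env_end - env_start + 1`) falls below
#' the class minimum. Defaults follow the usual screening practice for plant
#' TIR annotation: TIR domains at least 50 aa, NBARC at least 150 aa.
#' Classes without an entry in `min_len` are not filtered.
#'
#' @param hits Data frame of hits.
#' @param min_len Named integer vector, names are domain classes.
#' @return Filtered hit data frame.
#' @export
filter_domain_length <- function(hits, min_len = c(TIR = 50L, NBARC = 150L)) {
  validate_hits(hits)
  if (nrow(hits) == 0L) return(hits)
  thr <- min_len[hits$domain_class]
  thr[is.na(thr)] <- 0L
  out <- hits[(hits$env_end - hits$env_start + 1L) >= thr, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify the domain architecture of one protein
#'
#' Assigns one of the labels returned by [architecture_labels()], applying
#' the first matching rule in order: TIR+NBARC+TPR is TNP; TIR+NBARC+LRR is
#' TNL; TIR+NBARC is TN; a TIR protein shorter than `max_len_tir_only` with
#' no other predicted domain is TIR_ONLY; any other TIR protein is
#' TIR_OTHER; a protein without a TIR is NON_TIR. TNP takes precedence, so a
#' TIR+NBARC+LRR+TPR protein is TNP, and TNPs are never counted among
#' TNL/TN/TIR-only. The input hits are expected to be deduplicated
#' ([merge_overlapping_hits()]) and length-filtered ([filter_domain_length()]).
#'
#' @param protein List or one-row data frame with at least `protein_id` and
#'   `length` (full protein length in amino acids).
#' @param domains Hit data frame for that protein.
#' @param max_len_tir_only Proteins must be strictly shorter than this to be
#'   TIR_ONLY (default 400 aa).
#' @param require_tir_first If `TRUE`, TNL/TN/TNP additionally require the
#'   TIR envelope to start before every NBARC envelope. Off by default.
#' @return List of class `protein_architecture` with elements `protein_id`,
#'   `ordered_domains` (data frame sorted by `env_start`) and `label`.
#' @export
classify_architecture <- function(protein, domains,
                                  max_len_tir_only = 400L,
                                  require_tir_first = FALSE) {
  if (is.data.frame(protein)) protein <- as.list(protein[1L, ])
  stopifnot(!is.null(protein$protein_id), !is.null(protein$length))
  validate_hits(domains)
  if (nrow(domains) && !all(domains$protein_id == protein$protein_id)) {
    stop("domains do not all belong to protein ", protein$protein_id)
  }
  domains <- domains[order(domains$env_start, domains$env_end), , drop = FALSE]
  present <- unique(domains$domain_class)
  has <- function(cls) cls %in% present
  tn_core <- has("TIR") && has("NBARC")
  if (tn_core && require_tir_first) {
    tir_min <- min(domains$env_start[domains$domain_class == "TIR"])
    nb_min <- min(domains$env_start[domains$domain_class == "NBARC"])
    tn_core <- tir_min < nb_min
  }
  label <- if (tn_core && has("TPR")) {
    "TNP"
  } else if (tn_core && has("LRR")) {
    "TNL"
  } else if (tn_core) {
    "TN"
  } else if (has("TIR") && protein$length < max_len_tir_only &&
             length(setdiff(present, "TIR")) == 0L) {
    "TIR_ONLY"
  } else if (has("TIR")) {
    "TIR_OTHER"
  } else {
    "NON_TIR"
  }
  structure(
    list(protein_id = protein$protein_id,
         ordered_domains = domains[, c("domain_class", "env_start", "env_end")],
         label = label),
    class = "protein_architecture"
  )
}

#' @export
print.protein_architecture <- function(x, ...) {
  cat(x$protein_id, ": ", x$label, "  [", domain_string(x$ordered_domains),
      "]\n", sep = "")
  invisible(x)
}

domain_string <- function(domains) {
  if (nrow(domains) == 0L) return("")
  paste0(domains$domain_class, "(", domains$env_start, "-", domains$env_end, ")",
         collapse = ";")
}

#' Classify every protein of a proteome
#'
#' Runs the per-protein pipeline (deduplicate overlapping hits, enforce
#' length minima, classify) over a whole hit table.
#'
#' @param hits Hit data frame, typically from [parse_hit_table()].
#' @param proteins Data frame with `protein_id`, `species_id`, `length`;
#'   proteins absent from `hits` are classified NON_TIR.
#' @param max_overlap,min_len,max_len_tir_only,require_tir_first Passed to
#'   the underlying steps.
#' @return Data frame with one row per protein: `protein_id`, `species_id`,
#'   `length`, `label`, `domains` (compact "TIR(12-180);..." string).
#' @export
classify_proteome <- function(hits, proteins, max_overlap = 20L,
                              min_len = c(TIR = 50L, NBARC = 150L),
                              max_len_tir_only = 400L,
                              require_tir_first = FALSE) {
  stopifnot(all(c("protein_id", "species_id", "length") %in% names(proteins)))
  validate_hits(hits)
  split_hits <- split(hits, hits$protein_id)
  res <- lapply(seq_len(nrow(proteins)), function(i) {
    p <- proteins[i, ]
    h <- split_hits[[p$protein_id]]
    if (is.null(h)) h <- hits[0L, , drop = FALSE]
    h <- filter_domain_length(merge_overlapping_hits(h, max_overlap), min_len)
    arch <- classify_architecture(p, h, max_len_tir_only, require_tir_first)
    data.frame(protein_id = p$protein_id, species_id = p$species_id,
               length = p$length, label = arch$label,
               domains = domain_string(arch$ordered_domains),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Tabulate architecture counts per species
#'
#' Counts TNL, TN, TIR-only and TNP proteins per species. TNPs contribute
#' only to their own column, never to TNL/TN/TIR-only, so the four columns
#' sum to the number of TIR-positive proteins excluding the residual
#' TIR_OTHER class.
#'
#' @param architectures Data frame as returned by [classify_proteome()].
#' @param taxonomy Data frame with at least `species_id`; defines the row set
#'   (species without proteins get zero rows).
#' @return Data frame: `species_id`, `TNL`, `TN`, `TIR_ONLY`, `TNP`.
#' @export
tabulate_architectures <- function(architectures, taxonomy) {
  stopifnot("species_id" %in% names(taxonomy))
  species <- unique(taxonomy$species_id)
  unknown <- setdiff(unique(architectures$species_id), species)
  if (length(unknown)) {
    stop("species not in taxonomy: ", paste(unknown, collapse = ", "))
  }
  cols <- c("TNL", "TN", "TIR_ONLY", "TNP")
  out <- data.frame(species_id = species, stringsAsFactors = FALSE)
  for (cl in cols) {
    out[[cl]] <- vapply(species, function(s) {
      sum(architectures$species_id == s & architectures$label == cl)
    }, 0L)
  }
  rownames(out) <- NULL
  out
}

#' Write per-protein architectures / per-species counts to TSV
#'
#' @param architectures,counts Data frames from [classify_proteome()] /
#'   [tabulate_architectures()].
#' @param path Output file.
#' @return The input, invisibly.
#' @export
write_architectures <- function(architectures, path) {
  utils::write.table(architectures, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(architectures)
}

#' @rdname write_architectures
#' @export
write_arch_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts)
}
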