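# Pipeline orchestration: shared threshold set, config validation, and an
# end-to-end runner producing a reproducible run report.

#' The shared threshold configuration
#'
#' Central definition of every numeric threshold used across the pipeline,
#' with the strictness convention each module honours: hits are kept at
#' `evalue <= max_evalue`; same-class hits are redundant at overlap
#' `> max_overlap_aa` (exactly 20 residues of overlap is tolerated); TIR
#' domains need `>= min_len_tir` residues and NBARC `>= min_len_nbarc`;
#' TIR-only proteins are strictly shorter than `max_len_tir_only`; alignment
#' columns are removed at gap fraction `> max_gap_frac` (exactly 40% is
#' kept); clades qualify at ultrafast bootstrap `> min_ufboot` and SH-aLRT
#' `> min_sh_alrt`; genes count as expressed at tpm `> tpm_threshold`; stars
#' use strict comparisons against `star_alphas`.
#'
#' @param ... Named overrides of the defaults.
#' @return Object of class `threshold_config` (a named list).
#' @export
threshold_config <- function(...) {
  cfg <- list(
    max_evalue = 0.01,
    max_overlap_aa = 20L,
    min_len_tir = 50L,
    min_len_nbarc = 150L,
    max_len_tir_only = 400L,
    max_gap_frac = 0.40,
    min_ufboot = 90,
    min_sh_alrt = 80,
    min_lineages = 2L,
    tpm_threshold = 0,
    star_alphas = c(0.05, 0.01, 0.001)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown threshold(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  structure(cfg, class = "threshold_config")
}

#' @export
print.threshold_config <- function(x, ...) {
  cat("threshold_config:\n")
  for (k in names(x)) cat("  ", k, " = ", paste(x[[k]], collapse = ", "),
                          "\n", sep = "")
  invisible(x)
}

threshold_ranges <- function() {
  list(max_evalue = c(0, Inf), max_overlap_aa = c(0, Inf),
       min_len_tir = c(1, Inf), min_len_nbarc = c(1, Inf),
       max_len_tir_only = c(1, Inf), max_gap_frac = c(0, 1),
       min_ufboot = c(0, 100), min_sh_alrt = c(0, 100),
       min_lineages = c(1, Inf), tpm_threshold = c(0, Inf),
       star_alphas = c(0, 1))
}

#' Validate a pipeline configuration
#'
#' Checks a configuration (a list, or a YAML file path) for unknown keys,
#' out-of-range thresholds, and dangling input file paths. Findings are
#' returned, not thrown; `level` distinguishes `"error"`, `"warning"` and
#' `"info"` (the latter marks thresholds overridden from their defaults).
#'
#' @param config Named list or YAML file path; see [run_pipeline()] for the
#'   layout.
#' @return Data frame with columns `level`, `key`, `message` (zero rows when
#'   nothing is noteworthy).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  findings <- list()
  note <- function(level, key, message) {
    findings[[length(findings) + 1L]] <<- data.frame(
      level = level, key = key, message = message, stringsAsFactors = FALSE)
  }
  known_top <- c("out_dir", "seed", "thresholds", "stages")
  for (k in setdiff(names(config), known_top)) {
    note("error", k, "unknown configuration key")
  }
  defaults <- threshold_config()
  ranges <- threshold_ranges()
  thr <- config$thresholds
  for (k in names(thr)) {
    if (!k %in% names(defaults)) {
      note("error", k, "unknown threshold")
      next
    }
    r <- ranges[[k]]
    if (any(thr[[k]] < r[1L] | thr[[k]] > r[2L])) {
      note("error", k, sprintf("value %s outside [%s, %s]",
                               paste(thr[[k]], collapse = ","), r[1L], r[2L]))
    } else if (!isTRUE(all.equal(as.numeric(thr[[k]]),
                                 as.numeric(defaults[[k]])))) {
      note("info", k, sprintf("overridden from default %s",
                              paste(defaults[[k]], collapse = ",")))
    }
  }
  known_stages <- c("classify", "filter_msa", "shared_clades", "cooccur",
                    "expr_assoc")
  for (st in names(config$stages)) {
    if (!st %in% known_stages) {
      note("error", st, "unknown stage")
      next
    }
    for (k in names(config$stages[[st]])) {
      v <- config$stages[[st]][[k]]
      if (is.character(v) && length(v) == 1L && grepl("[/.]", v) &&
          !file.exists(v)) {
        note("error", paste(st, k, sep = "."),
             sprintf("input file does not exist: %s", v))
      }
    }
  }
  if (!length(findings)) {
    return(data.frame(level = character(), key = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, findings)
  rownames(out) <- NULL
  out
}

#' Run the pipeline end-to-end
#'
#' Executes the enabled stages in dependency order: `classify` (hit table ->
#' architectures -> per-species counts), `filter_msa`, `shared_clades`
#' (tree -> clade groups -> per-species presence), `cooccur` (orthogroups ->
#' pattern matches), `expr_assoc` (tpm + metadata -> association results).
#' All enabled-stage inputs are checked before any stage runs. Outputs are
#' written under `out_dir` together with a `manifest.json` recording input
#' MD5 hashes, the thresholds in force, per-stage row counts and output
#' paths, so a run is reproducible from its manifest and seed.
#'
#' Config layout (list or YAML): top-level `out_dir`, `seed`, `thresholds`
#' (overrides of [threshold_config()]), and `stages`, a named list where each
#' enabled stage maps its input files, e.g. `stages$classify` has `hits`,
#' `proteins` (TSV: protein_id, species_id, length), `taxonomy`, optional
#' `class_map`; `stages$filter_msa` has `alignment`; `stages$shared_clades`
#' has `tree`, `dialect`, `taxonomy`; `stages$cooccur` has `orthogroups`,
#' `pattern`, optional `keep_list`; `stages$expr_assoc` has `tpm`,
#' `metadata`, optional `genes` (one id per line).
#'
#' @param config Named list or YAML file path.
#' @return The run report (list), invisibly written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  findings <- validate_config(config)
  errs <- findings[findings$level == "error", , drop = FALSE]
  if (nrow(errs)) {
    stop("configuration errors:\n",
         paste(sprintf("  %s: %s", errs$key, errs$message), collapse = "\n"))
  }
  out_dir <- config$out_dir %||% stop("config needs out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  thr <- do.call(threshold_config, as.list(config$thresholds))
  stages <- config$stages %||% list()
  input_files <- unlist(lapply(stages, function(s) {
    Filter(function(v) is.character(v) && length(v) == 1L && file.exists(v), s)
  }), use.names = TRUE)
  report <- list(seed = seed, thresholds = unclass(thr),
                 input_hashes = as.list(tools::md5sum(unname(input_files))),
                 stages = list())
  add_stage <- function(name, n_rows, outputs, notes = NULL) {
    # outputs recorded relative to out_dir so reports compare across runs
    report$stages[[name]] <<- list(n_rows = n_rows,
                                   outputs = basename(outputs), notes = notes)
  }
  min_len <- c(TIR = thr$min_len_tir, NBARC = thr$min_len_nbarc)

  if (!is.null(stages$classify)) {
    st <- stages$classify
    class_map <- if (!is.null(st$class_map)) read_class_map(st$class_map)
    else default_class_map()
    hits <- parse_hit_table(st$hits, class_map, thr$max_evalue)
    proteins <- utils::read.table(st$proteins, sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE)
    taxonomy <- utils::read.table(st$taxonomy, sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE)
    arch <- classify_proteome(hits, proteins, thr$max_overlap_aa, min_len,
                              thr$max_len_tir_only)
    counts <- tabulate_architectures(arch, taxonomy)
    p1 <- file.path(out_dir, "architectures.tsv")
    p2 <- file.path(out_dir, "architecture_counts.tsv")
    write_architectures(arch, p1)
    write_arch_counts(counts, p2)
    add_stage("classify", nrow(arch), c(p1, p2))
  }
  if (!is.null(stages$filter_msa)) {
    st <- stages$filter_msa
    aln <- read_alignment(st$alignment)
    flt <- filter_gap_columns(aln, thr$max_gap_frac)
    p1 <- file.path(out_dir, "alignment_filtered.fasta")
    p2 <- file.path(out_dir, "kept_columns.tsv")
    write_alignment(flt$alignment, p1)
    write_column_map(flt$kept_columns, p2)
    add_stage("filter_msa", length(flt$kept_columns), c(p1, p2),
              notes = sprintf("%d of %d columns kept",
                              length(flt$kept_columns),
                              attr(aln, "n_columns")))
  }
  if (!is.null(stages$shared_clades)) {
    st <- stages$shared_clades
    taxonomy <- utils::read.table(st$taxonomy, sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE)
    atree <- parse_newick_with_support(st$tree,
                                       dialect = st$dialect %||% "dual",
                                       taxonomy = taxonomy)
    groups <- find_shared_clades(atree, thr$min_ufboot,
                                 if (identical(st$dialect, "single")) NULL
                                 else thr$min_sh_alrt,
                                 thr$min_lineages)
    p1 <- file.path(out_dir, "clade_groups.tsv")
    p2 <- file.path(out_dir, "clade_presence.tsv")
    write_clade_groups(groups, p1)
    write_presence_matrix(lineage_presence_from_clades(groups, taxonomy), p2)
    add_stage("shared_clades", nrow(groups$groups), c(p1, p2),
              notes = sprintf("dialect=%s", st$dialect %||% "dual"))
  }
  if (!is.null(stages$cooccur)) {
    st <- stages$cooccur
    pm <- binarize_orthogroups(st$orthogroups)
    query <- read_pattern(st$pattern)
    ids <- match_pattern(pm, query)
    if (!is.null(st$keep_list)) ids <- apply_keep_list(ids, st$keep_list)
    p1 <- file.path(out_dir, "og_matches.tsv")
    utils::write.table(data.frame(orthogroup = ids), p1, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    add_stage("cooccur", length(ids), p1)
  }
  if (!is.null(stages$expr_assoc)) {
    st <- stages$expr_assoc
    study <- read_expression(st$tpm, st$metadata,
                             species_id = st$species_id %||% "unknown")
    genes <- if (!is.null(st$genes)) readLines(st$genes)
    else rownames(study$tpm)
    res <- run_association(study, genes, threshold = thr$tpm_threshold,
                           alphas = thr$star_alphas)
    p1 <- file.path(out_dir, "association.tsv")
    p2 <- file.path(out_dir, "zscores.tsv")
    write_association(res, p1)
    z <- zscore_per_sample(study$tpm[genes, , drop = FALSE])
    utils::write.table(data.frame(gene_id = rownames(z), z,
                                  check.names = FALSE),
                       p2, sep = "\t", quote = FALSE, row.names = FALSE)
    add_stage("expr_assoc", nrow(res), c(p1, p2))
  }
  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(report, manifest, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
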