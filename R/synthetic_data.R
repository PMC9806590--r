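# Seeded generators producing synthetic inputs with planted ground truth for
# every pipeline stage: proteome hit tables, support-annotated trees,
# orthogroup matrices, and immune-expression studies. Every generator is a
# pure function of its parameters and the seed.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(len) paste(sample(AA20, len, replace = TRUE),
                                      collapse = "")

rand_evalue <- function(n, lo = 5, hi = 40) 10^(-stats::runif(n, lo, hi))

#' Default lineage assignment for synthetic species
#'
#' Distributes `n_species` synthetic species round-robin over four flowering
#' plant lineages (Rosids, Asterids, monocots, magnoliids), the taxonomic
#' rank at which clade sharing is assessed.
#'
#' @param n_species Number of species.
#' @return Data frame `species_id`, `lineage_id`.
#' @export
default_lineages <- function(n_species = 10L) {
  lineages <- c("Rosids", "Asterids", "monocots", "magnoliids")
  data.frame(
    species_id = sprintf("sp%02d", seq_len(n_species)),
    lineage_id = rep_len(lineages, n_species),
    stringsAsFactors = FALSE)
}

# Lay out planted domains for one protein of a given architecture.
# Returns list(length, hits = data.frame(hmm_name, domain_class, start, end)).
plant_architecture <- function(label) {
  seg <- function(hmm, cls, start, len) {
    data.frame(hmm_name = hmm, domain_class = cls,
               env_start = start, env_end = start + len - 1L,
               stringsAsFactors = FALSE)
  }
  if (label == "TNL") {
    tir_len <- sample(130:200, 1L); nb_len <- sample(250:350, 1L)
    tir <- seg("TIR", "TIR", sample(5:20, 1L), tir_len)
    nb <- seg("NB-ARC", "NBARC", tir$env_end + sample(20:60, 1L), nb_len)
    lrr1 <- seg("LRR_1", "LRR", nb$env_end + sample(20:40, 1L), sample(60:90, 1L))
    lrr2 <- seg("LRR_4", "LRR", lrr1$env_end + sample(25:50, 1L), sample(60:90, 1L))
    hits <- rbind(tir, nb, lrr1, lrr2)
  } else if (label == "TN") {
    tir <- seg("TIR", "TIR", sample(5:20, 1L), sample(130:200, 1L))
    nb <- seg("NB-ARC", "NBARC", tir$env_end + sample(20:60, 1L),
              sample(250:350, 1L))
    hits <- rbind(tir, nb)
  } else if (label == "TIR_ONLY") {
    tir <- seg("TIR", "TIR", sample(3:15, 1L), sample(130:180, 1L))
    hits <- tir
  } else if (label == "TNP") {
    tir <- seg("TIR_2", "TIR", sample(5:20, 1L), sample(130:200, 1L))
    nb <- seg("NB-ARC", "NBARC", tir$env_end + sample(20:60, 1L),
              sample(250:350, 1L))
    tpr1 <- seg("TPR_1", "TPR", nb$env_end + sample(20:40, 1L), 34L)
    tpr2 <- seg("TPR_2", "TPR", tpr1$env_end + sample(25:45, 1L), 34L)
    hits <- rbind(tir, nb, tpr1, tpr2)
  } else { # NON_TIR: half with a lone LRR hit, half with no hits at all
    hits <- if (stats::runif(1) < 0.5) {
      seg("LRR_1", "LRR", sample(10:60, 1L), sample(60:90, 1L))
    } else {
      data.frame(hmm_name = character(), domain_class = character(),
                 env_start = integer(), env_end = integer(),
                 stringsAsFactors = FALSE)
    }
  }
  tail_len <- if (label == "TIR_ONLY") sample(10:40, 1L) else sample(20:80, 1L)
  len <- (if (nrow(hits)) max(hits$env_end) else sample(200:500, 1L)) + tail_len
  if (label == "TIR_ONLY") len <- min(len, 399L)
  list(length = as.integer(len), hits = hits)
}

#' Simulate a proteome with planted domain architectures
#'
#' Generates, per species, proteins with planted TNL / TN / TIR-only / TNP /
#' non-TIR architectures and the corresponding domain-search hit table.
#' Planted TIR domains are at least 50 aa, NBARCs at least 150 aa, and
#' TIR-only proteins shorter than 400 aa, so the noise-free truth survives
#' every downstream filter. With probability `spurious_rate` per clean
#' protein, filterable noise is injected: hits with E-value above the 0.01
#' cutoff, sub-threshold domain lengths, and redundant same-class hits
#' overlapping a planted hit by more than 20 aa at a worse E-value. The
#' generator is a pure function of its parameters and `seed`.
#'
#' @param n_species Number of species.
#' @param counts Named integer vector of per-species architecture counts
#'   (names among TNL, TN, TIR_ONLY, TNP, NON_TIR).
#' @param spurious_rate Per-protein probability of injecting one noise hit of
#'   each filterable kind.
#' @param lineages Data frame `species_id`, `lineage_id`; defaults to
#'   [default_lineages()].
#' @param seed Integer seed.
#' @param out_dir If non-`NULL`, writes `proteome.fasta`, `hits.tsv` (6-column
#'   dialect) and `truth.tsv` there.
#' @return List with `hits` (data frame in the 6-column hit-table layout),
#'   `proteins` (`protein_id`, `species_id`, `length`), `sequences` (named
#'   character vector), `truth` (`protein_id`, `species_id`, `label`),
#'   `taxonomy`, and `noise` (data frame of injected noise hits with a
#'   `noise_type` column).
#' @export
simulate_proteome_hits <- function(n_species = 10L,
                                   counts = c(TNL = 5L, TN = 3L, TIR_ONLY = 2L,
                                              TNP = 1L, NON_TIR = 9L),
                                   spurious_rate = 0.25,
                                   lineages = default_lineages(n_species),
                                   seed = 1L, out_dir = NULL) {
  stopifnot(all(names(counts) %in% architecture_labels()), all(counts >= 0))
  withr::with_seed(seed, {
    hit_rows <- list(); prot_rows <- list(); truth_rows <- list()
    seqs <- character(); noise_rows <- list()
    for (s in lineages$species_id[seq_len(n_species)]) {
      labels <- rep(names(counts), counts)
      for (k in seq_along(labels)) {
        pid <- sprintf("%s_p%03d", s, k)
        arch <- plant_architecture(labels[k])
        seqs[pid] <- random_protein(arch$length)
        prot_rows[[pid]] <- data.frame(protein_id = pid, species_id = s,
                                       length = arch$length,
                                       stringsAsFactors = FALSE)
        truth_rows[[pid]] <- data.frame(protein_id = pid, species_id = s,
                                        label = labels[k],
                                        stringsAsFactors = FALSE)
        h <- arch$hits
        if (nrow(h)) {
          h$protein_id <- pid
          h$evalue <- rand_evalue(nrow(h))
          h$protein_length <- arch$length
          hit_rows[[pid]] <- h
        }
        if (stats::runif(1) < spurious_rate) {
          noise_rows[[pid]] <- inject_noise(pid, list(length = arch$length,
                                                      hits = h))
        }
      }
    }
    hits <- do.call(rbind, c(hit_rows, lapply(noise_rows, function(x) {
      x[, setdiff(names(x), "noise_type"), drop = FALSE]
    })))
    if (is.null(hits)) {
      hits <- data.frame(protein_id = character(), hmm_name = character(),
                         domain_class = character(), env_start = integer(),
                         env_end = integer(), evalue = double(),
                         protein_length = integer(), stringsAsFactors = FALSE)
    }
    cols <- c("protein_id", "hmm_name", "env_start", "env_end", "evalue",
              "protein_length")
    hits <- hits[order(hits$protein_id, hits$env_start), cols, drop = FALSE]
    rownames(hits) <- NULL
    noise <- if (length(noise_rows)) do.call(rbind, noise_rows) else
      data.frame(protein_id = character(), noise_type = character())
    rownames(noise) <- NULL
    out <- list(hits = hits,
                proteins = do.call(rbind, prot_rows),
                sequences = seqs,
                truth = do.call(rbind, truth_rows),
                taxonomy = lineages[seq_len(n_species), , drop = FALSE],
                noise = noise)
    rownames(out$proteins) <- rownames(out$truth) <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs),
                                  file.path(out_dir, "proteome.fasta"))
      utils::write.table(hits, file.path(out_dir, "hits.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(out$truth, file.path(out_dir, "truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(out$taxonomy, file.path(out_dir, "taxonomy.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    out
  })
}

# One noise hit of each filterable kind for a protein: above-cutoff E-value,
# sub-threshold length, and (when a planted TIR exists) a redundant
# overlapping same-class hit at worse E-value. `arch$hits` carries the final
# planted hits including E-values. Noise that could overlap a planted hit is
# always given a strictly worse E-value so it never displaces truth at the
# merge step; halving the log10 E-value keeps it below the 0.01 parse cutoff.
inject_noise <- function(pid, arch) {
  len <- arch$length
  worse_e <- if (nrow(arch$hits)) 10^(log10(min(arch$hits$evalue)) / 2)
  else rand_evalue(1)
  rows <- list()
  rows$evalue <- data.frame(
    protein_id = pid, hmm_name = "TIR_3", domain_class = "TIR",
    env_start = 1L, env_end = min(len, 120L),
    evalue = stats::runif(1, 0.02, 0.9), protein_length = len,
    noise_type = "evalue", stringsAsFactors = FALSE)
  # sub-threshold NBARC (< 150 aa) near the N-terminus: planted NBARCs start
  # beyond residue 150, so this is removed by the length filter, never by the
  # merge step, keeping merge removals equal to the redundant injections
  rows$short <- data.frame(
    protein_id = pid, hmm_name = "NB-ARC", domain_class = "NBARC",
    env_start = 1L, env_end = sample(60:min(149L, len - 1L), 1L),
    evalue = worse_e, protein_length = len,
    noise_type = "short", stringsAsFactors = FALSE)
  tir <- arch$hits[arch$hits$domain_class == "TIR", , drop = FALSE]
  if (nrow(tir)) {
    t1 <- tir[1L, ]
    start <- max(1L, t1$env_start + sample(5:20, 1L))
    end <- max(start + 59L, t1$env_end - sample(0:5, 1L))
    rows$redundant <- data.frame(
      protein_id = pid, hmm_name = "TIR-like", domain_class = "TIR",
      env_start = start, env_end = end,
      evalue = worse_e, protein_length = len,
      noise_type = "redundant", stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# --- tree simulation ---------------------------------------------------------

# Random binary join of newick fragments; label_fun(n_leaves) supplies the
# internal label applied at each join.
random_join <- function(items, label_fun, n_leaves) {
  stopifnot(length(items) >= 1L)
  while (length(items) > 1L) {
    pick <- sample(length(items), 2L)
    a <- items[[pick[1L]]]; b <- items[[pick[2L]]]
    nl <- n_leaves[pick[1L]] + n_leaves[pick[2L]]
    joined <- sprintf("(%s:%.4f,%s:%.4f)%s",
                      a, stats::rexp(1, 10) + 0.01,
                      b, stats::rexp(1, 10) + 0.01, label_fun(nl))
    items <- c(items[-pick], joined)
    n_leaves <- c(n_leaves[-pick], nl)
  }
  items[[1L]]
}

#' Simulate a support-annotated phylogeny with planted shared clades
#'
#' Builds a random-join topology containing `n_planted` planted clades whose
#' leaves span at least two lineages and whose root supports exceed the
#' detection thresholds (ultrafast bootstrap in \[93, 99\], SH-aLRT in
#' \[85, 99\]), plus decoy clades that fail detection either taxonomically
#' (single-lineage, high support) or by support (multi-lineage, ultrafast
#' bootstrap in \[30, 88\], SH-aLRT in \[30, 78\]), plus background leaves.
#' All non-planted internal nodes receive sub-threshold supports, so the
#' planted clades are exactly the maximal qualifying clades. Supports are
#' specification, not inference: the clade detector consumes labelled
#' topologies, so no sequence evolution is simulated.
#'
#' @param n_leaves Total number of leaves.
#' @param n_planted Number of planted qualifying clades.
#' @param n_decoys Number of decoy clades (alternating taxonomic/support
#'   decoys).
#' @param planted_size,decoy_size Leaves per planted / decoy clade.
#' @param lineages Data frame `species_id`, `lineage_id` (>= 2 lineages).
#' @param dialect `"dual"` writes `SH-aLRT/UFboot` labels, `"single"` only
#'   the ultrafast bootstrap.
#' @param seed Integer seed.
#' @param out_dir If non-`NULL`, writes `tree.nwk`, `leaf_taxonomy.tsv`,
#'   `truth.tsv` there.
#' @return List with `newick` (string), `taxonomy` (leaf_id, species_id,
#'   lineage_id), `planted` (named list of leaf-id sets), `decoys` (named
#'   list).
#' @export
simulate_tree <- function(n_leaves = 200L, n_planted = 4L, n_decoys = 10L,
                          planted_size = 12L, decoy_size = 6L,
                          lineages = default_lineages(12L),
                          dialect = c("dual", "single"), seed = 1L,
                          out_dir = NULL) {
  dialect <- match.arg(dialect)
  n_lineage <- length(unique(lineages$lineage_id))
  if (n_lineage < 2L) stop("need at least two lineages to plant shared clades")
  n_clade_leaves <- n_planted * planted_size + n_decoys * decoy_size
  if (n_clade_leaves + 2L > n_leaves) {
    stop("n_leaves too small for the requested clades: need > ", n_clade_leaves)
  }
  withr::with_seed(seed, {
    by_lineage <- split(lineages$species_id, lineages$lineage_id)
    leaf_count <- 0L
    tax_rows <- list()
    new_leaf <- function(species) {
      leaf_count <<- leaf_count + 1L
      id <- sprintf("t%04d_%s", leaf_count, species)
      tax_rows[[id]] <<- data.frame(
        leaf_id = id, species_id = species,
        lineage_id = lineages$lineage_id[match(species, lineages$species_id)],
        stringsAsFactors = FALSE)
      id
    }
    fmt <- function(sh, uf) {
      if (dialect == "dual") sprintf("%d/%d", round(sh), round(uf))
      else sprintf("%d", round(uf))
    }
    low_label <- function(nl) fmt(stats::runif(1, 30, 78), stats::runif(1, 30, 88))
    make_clade <- function(size, lin_pool, root_label) {
      # guarantee coverage of every lineage in lin_pool, then random fill
      lin_seq <- c(lin_pool, sample(lin_pool, size - length(lin_pool),
                                    replace = TRUE))
      leaves <- vapply(lin_seq, function(ln) {
        new_leaf(sample(by_lineage[[ln]], 1L))
      }, "")
      sub <- random_join(as.list(leaves), low_label, rep(1L, length(leaves)))
      # overwrite the outermost label with the clade-root label
      sub <- sub_root_label(sub, root_label)
      list(newick = sub, leaves = unname(leaves))
    }
    planted <- list(); decoys <- list(); frags <- list(); frag_n <- integer()
    for (i in seq_len(n_planted)) {
      lin_pool <- sample(unique(lineages$lineage_id),
                         sample(2:min(3L, n_lineage), 1L))
      cl <- make_clade(planted_size, lin_pool,
                       fmt(stats::runif(1, 85, 99), stats::runif(1, 93, 99)))
      planted[[paste0("planted_", i)]] <- cl$leaves
      frags <- c(frags, cl$newick); frag_n <- c(frag_n, planted_size)
    }
    for (i in seq_len(n_decoys)) {
      if (i %% 2L == 0L) {
        # taxonomic decoy: one lineage only, support above thresholds
        cl <- make_clade(decoy_size, sample(unique(lineages$lineage_id), 1L),
                         fmt(stats::runif(1, 85, 99), stats::runif(1, 93, 99)))
      } else {
        # support decoy: several lineages, support below thresholds
        lin_pool <- sample(unique(lineages$lineage_id), 2L)
        cl <- make_clade(decoy_size, lin_pool, low_label(decoy_size))
      }
      decoys[[paste0("decoy_", i)]] <- cl$leaves
      frags <- c(frags, cl$newick); frag_n <- c(frag_n, decoy_size)
    }
    n_bg <- n_leaves - n_clade_leaves
    for (i in seq_len(n_bg)) {
      frags <- c(frags, new_leaf(sample(lineages$species_id, 1L)))
      frag_n <- c(frag_n, 1L)
    }
    newick <- paste0(random_join(frags, low_label, frag_n), ";")
    taxonomy <- do.call(rbind, tax_rows)
    rownames(taxonomy) <- NULL
    out <- list(newick = newick, taxonomy = taxonomy, planted = planted,
                decoys = decoys)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      writeLines(newick, file.path(out_dir, "tree.nwk"))
      utils::write.table(taxonomy, file.path(out_dir, "leaf_taxonomy.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      truth <- data.frame(
        clade = rep(names(planted), lengths(planted)),
        leaf_id = unlist(planted, use.names = FALSE))
      utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    out
  })
}

# replace the label directly after the final ')' of a subtree fragment
sub_root_label <- function(frag, label) {
  if (!grepl("\\)", frag)) return(frag)  # single leaf: no root to label
  pos <- max(gregexpr(")", frag, fixed = TRUE)[[1L]])
  old_tail <- substring(frag, pos + 1L)
  # the outermost join appended a label after ')'; strip it up to ':' or end
  old_tail <- sub("^[^:,()]*", "", old_tail)
  paste0(substring(frag, 1L, pos), label, old_tail)
}

# --- orthogroup simulation ---------------------------------------------------

#' Simulate an orthogroup presence table with planted pattern rows
#'
#' Generates an orthogroup x species gene-list table in the standard
#' orthology-inference layout. `n_planted` rows exactly follow `pattern`;
#' background rows draw presence i.i.d. per species with probability
#' `bg_presence`, re-drawing (up to `max_retries` per row) any background row
#' that would accidentally match the pattern, so the planted rows are the
#' unique matches. Present cells carry 1-3 synthetic gene ids, exercising the
#' copy-number-blind binarization.
#'
#' @param n_og Number of orthogroups.
#' @param species Species ids (default 10 species).
#' @param pattern Named logical over (a subset of) `species`; default: first
#'   five species required present, last five required absent.
#' @param n_planted Number of rows planted to match.
#' @param bg_presence Background presence probability.
#' @param seed Integer seed.
#' @param max_retries Rejection-sampling budget per background row.
#' @param out_dir If non-`NULL`, writes `Orthogroups.tsv`, `pattern.tsv`,
#'   `truth.tsv` there.
#' @return List with `og_table` (data frame), `pattern`, `planted_ids`.
#' @export
simulate_og_matrix <- function(n_og = 1000L,
                               species = sprintf("sp%02d", 1:10),
                               pattern = NULL, n_planted = 7L,
                               bg_presence = 0.35, seed = 1L,
                               max_retries = 100L, out_dir = NULL) {
  if (is.null(pattern)) {
    pattern <- stats::setNames(rep(c(TRUE, FALSE), each = 5L)[seq_along(species)],
                               species)
  }
  stopifnot(all(names(pattern) %in% species), n_planted <= n_og)
  withr::with_seed(seed, {
    ids <- sprintf("OG%07d", seq_len(n_og))
    planted_ids <- sort(sample(ids, n_planted))
    m <- matrix(FALSE, n_og, length(species), dimnames = list(ids, species))
    req_idx <- match(names(pattern), species)
    for (i in seq_len(n_og)) {
      if (ids[i] %in% planted_ids) {
        row <- stats::runif(length(species)) < bg_presence
        row[req_idx] <- pattern
      } else {
        ok <- FALSE
        for (try in seq_len(max_retries)) {
          row <- stats::runif(length(species)) < bg_presence
          if (!all(row[req_idx] == pattern)) { ok <- TRUE; break }
        }
        if (!ok) {
          stop("could not draw a non-matching background row after ",
               max_retries, " tries; use more species or a longer pattern")
        }
      }
      m[i, ] <- row
    }
    cells <- matrix("", n_og, length(species))
    n_genes <- matrix(sample(1:3, n_og * length(species), replace = TRUE),
                      n_og)
    for (j in seq_along(species)) {
      present <- which(m[, j])
      cells[present, j] <- vapply(present, function(i) {
        paste0(ids[i], "_", species[j], "_g", seq_len(n_genes[i, j]),
               collapse = ", ")
      }, "")
    }
    og_table <- data.frame(Orthogroup = ids, cells, stringsAsFactors = FALSE,
                           check.names = FALSE)
    names(og_table) <- c("Orthogroup", species)
    out <- list(og_table = og_table, pattern = pattern,
                planted_ids = planted_ids)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.table(og_table, file.path(out_dir, "Orthogroups.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(species_id = names(pattern), present = as.integer(pattern)),
        file.path(out_dir, "pattern.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
      writeLines(planted_ids, file.path(out_dir, "truth.tsv"))
    }
    out
  })
}

# --- expression simulation ---------------------------------------------------

#' Simulate an immune-expression study with planted responsive genes
#'
#' Responsive genes have tpm 0 in control samples (except with probability
#' `leak`) and are detected (tpm > 0) in triggered samples with probability
#' `detection`; non-responsive genes are expressed independently of trigger
#' status with probability `base_expr`. Positive tpm magnitudes are
#' lognormal(meanlog 2, sdlog 1): only exceedance of the 0 threshold matters
#' for the association test, so magnitudes are display-level realism.
#'
#' @param n_genes Total genes.
#' @param n_responsive Number of planted trigger-responsive genes (first
#'   `n_responsive` gene ids).
#' @param n_triggered,n_control Sample counts per group.
#' @param detection Detection probability in triggered samples for responsive
#'   genes.
#' @param leak Background-leak probability in control samples for responsive
#'   genes.
#' @param base_expr Expression probability for non-responsive genes.
#' @param meanlog,sdlog Lognormal parameters for positive tpm values.
#' @param species_id Species label for the study.
#' @param seed Integer seed.
#' @param out_dir If non-`NULL`, writes `tpm.tsv`, `metadata.tsv`,
#'   `truth.tsv` there.
#' @return List with `study` (an [expression_study()]), `responsive`
#'   (character vector of planted gene ids).
#' @export
simulate_expression <- function(n_genes = 50L, n_responsive = 6L,
                                n_triggered = 5L, n_control = 5L,
                                detection = 1, leak = 0, base_expr = 0.5,
                                meanlog = 2, sdlog = 1,
                                species_id = "synthetic", seed = 1L,
                                out_dir = NULL) {
  stopifnot(n_triggered >= 1L, n_control >= 1L, n_responsive <= n_genes,
            detection >= 0, detection <= 1, leak >= 0, leak <= 1)
  withr::with_seed(seed, {
    genes <- sprintf("gene%04d", seq_len(n_genes))
    responsive <- genes[seq_len(n_responsive)]
    samples <- c(sprintf("trig%02d", seq_len(n_triggered)),
                 sprintf("ctrl%02d", seq_len(n_control)))
    trig <- stats::setNames(rep(c(TRUE, FALSE), c(n_triggered, n_control)),
                            samples)
    expressed <- matrix(FALSE, n_genes, length(samples),
                        dimnames = list(genes, samples))
    for (g in genes) {
      p <- if (g %in% responsive) ifelse(trig, detection, leak)
      else rep(base_expr, length(samples))
      expressed[g, ] <- stats::runif(length(samples)) < p
    }
    tpm <- matrix(0, n_genes, length(samples), dimnames = dimnames(expressed))
    n_pos <- sum(expressed)
    tpm[expressed] <- stats::rlnorm(n_pos, meanlog, sdlog)
    study <- expression_study(tpm, trig, species_id)
    out <- list(study = study, responsive = responsive)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.table(
        data.frame(gene_id = genes, tpm, check.names = FALSE),
        file.path(out_dir, "tpm.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      utils::write.table(
        data.frame(sample_id = samples, triggered = as.integer(trig),
                   study_id = "study1"),
        file.path(out_dir, "metadata.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      writeLines(responsive, file.path(out_dir, "truth.tsv"))
    }
    out
  })
}
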