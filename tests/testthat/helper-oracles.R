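# Independent oracles used to cross-check the implementation. These stay
# deliberately naive: quadratic loops, Warshall transitive closure, exhaustive
# enumeration — different algorithms from the code paths they verify.

# O(n^2) cluster-and-select oracle for overlapping-hit deduplication:
# per class, build the over-overlap relation, close it transitively with
# Floyd-Warshall, then pick one representative per cluster by
# (E-value, longer envelope, lexicographic hmm name).
oracle_merge <- function(hits, max_overlap = 20L) {
  keep <- logical(nrow(hits))
  for (cls in unique(hits$domain_class)) {
    idx <- which(hits$domain_class == cls)
    n <- length(idx)
    rel <- diag(n) > 0
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        ov <- min(hits$env_end[idx[i]], hits$env_end[idx[j]]) -
          max(hits$env_start[idx[i]], hits$env_start[idx[j]]) + 1L
        if (ov > max_overlap) rel[i, j] <- TRUE
      }
    }
    for (k in seq_len(n)) {
      for (i in seq_len(n)) {
        for (j in seq_len(n)) {
          if (rel[i, k] && rel[k, j]) rel[i, j] <- TRUE
        }
      }
    }
    seen <- logical(n)
    for (i in seq_len(n)) {
      if (seen[i]) next
      cluster <- which(rel[i, ])
      seen[cluster] <- TRUE
      sub <- hits[idx[cluster], , drop = FALSE]
      len <- sub$env_end - sub$env_start + 1L
      best <- cluster[order(sub$evalue, -len, sub$hmm_name)[1L]]
      keep[idx[best]] <- TRUE
    }
  }
  out <- hits[keep, , drop = FALSE]
  out <- out[order(out$env_start, out$env_end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# random hit set on one protein for merge property tests
random_hits <- function(n, classes = c("TIR", "NBARC", "LRR")) {
  start <- sample(1:500, n, replace = TRUE)
  len <- sample(10:200, n, replace = TRUE)
  data.frame(
    protein_id = "p1",
    hmm_name = sample(c("TIR", "TIR_2", "TIR-like", "NB-ARC", "LRR_1"), n,
                      replace = TRUE),
    domain_class = sample(classes, n, replace = TRUE),
    env_start = start, env_end = start + len - 1L,
    evalue = signif(10^(-sample(2:30, n, replace = TRUE)), 3),
    stringsAsFactors = FALSE)
}

# exhaustive-enumeration oracle for the one-sided Fisher test: sum the exact
# hypergeometric point masses (choose() arithmetic) over all tables with the
# observed margins and first cell >= a
oracle_fisher_greater <- function(a, b, cc, d) {
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  mass <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n, c1)
  sum(mass[ks >= a])
}

# brute-force per-node clade oracle: evaluate the qualification predicate on
# every internal node, then keep the maximal qualifying leaf-sets by pairwise
# subset comparison (independent of the implementation's ancestor walk)
oracle_shared_clades <- function(atree, min_ufboot, min_sh_alrt, min_lineages) {
  phylo <- atree$phylo
  ntip <- length(phylo$tip.label)
  lin <- setNames(atree$taxonomy$lineage_id, atree$taxonomy$leaf_id)
  sets <- list()
  for (i in seq_len(phylo$Nnode)) {
    tips <- phylo$tip.label[unlist(phangorn::Descendants(phylo, ntip + i, "tips"))]
    uf <- atree$support$ufboot[i]; sh <- atree$support$sh_alrt[i]
    if (is.na(uf) || uf <= min_ufboot) next
    if (!is.null(min_sh_alrt) && (is.na(sh) || sh <= min_sh_alrt)) next
    if (length(unique(lin[tips])) < min_lineages) next
    sets[[length(sets) + 1L]] <- sort(tips)
  }
  if (!length(sets)) return(list())
  maximal <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i != j && all(sets[[i]] %in% sets[[j]]) &&
          length(sets[[i]]) < length(sets[[j]])) {
        maximal[i] <- FALSE
      }
    }
  }
  sets[maximal]
}

# naive full-scan pattern oracle
oracle_match_pattern <- function(m, query) {
  hits <- character()
  for (r in rownames(m)) {
    ok <- TRUE
    for (s in names(query)) if (m[r, s] != query[[s]]) { ok <- FALSE; break }
    if (ok) hits <- c(hits, r)
  }
  hits
}

leafset_key <- function(x) paste(sort(x), collapse = "|")

# small alignment constructor for msa tests
make_aln <- function(...) aa_alignment(c(...))
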