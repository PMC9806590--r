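# Support-label parsing, shared-clade detection, representative selection.

tax4 <- function(leaves, species, lineages) {
  data.frame(leaf_id = leaves, species_id = species, lineage_id = lineages,
             stringsAsFactors = FALSE)
}

test_that("support labels parse in both dialects", {
  at <- parse_newick_with_support(text = "((A:1,B:1)95:1,C:2):0;",
                                  dialect = "single")
  expect_true(95 %in% at$support$ufboot)
  expect_true(all(is.na(at$support$sh_alrt)))

  at <- parse_newick_with_support(text = "((A:1,B:1)80/95:1,C:2):0;",
                                  dialect = "dual")
  i <- which(!is.na(at$support$ufboot))
  expect_identical(at$support$sh_alrt[i], 80)
  expect_identical(at$support$ufboot[i], 95)

  # unlabeled nodes get absent support, not an error
  at <- parse_newick_with_support(text = "((A:1,B:1):1,C:2):0;",
                                  dialect = "dual")
  expect_true(all(is.na(at$support$ufboot)))

  expect_error(
    parse_newick_with_support(text = "((A:1,B:1)banana:1,C:2):0;",
                              dialect = "dual"),
    "node")
  expect_error(
    parse_newick_with_support(text = "((A:1,B:1)150:1,C:2):0;",
                              dialect = "single"),
    "\\[0, 100\\]")
})

test_that("unrooted trees are midpoint-rooted with supports kept on branches", {
  nwk <- "((A:1,B:1)85/96:1,(C:1,D:1)70/60:1,E:4);"
  tax <- tax4(LETTERS[1:5], paste0("sp", 1:5),
              c("Rosids", "Asterids", "Rosids", "Rosids", "monocots"))
  at <- parse_newick_with_support(text = nwk, dialect = "dual", taxonomy = tax)
  expect_true(ape::is.rooted(at$phylo))
  g <- find_shared_clades(at, min_ufboot = 90, min_sh_alrt = 80)
  expect_identical(length(g$members), 1L)
  expect_identical(sort(g$members[[1]]), c("A", "B"))
})

planted_small_tree <- function() {
  # clade AB: 95 support, two lineages; clade CD: 85 support, two lineages
  nwk <- "(((A:1,B:1)95:1,(C:1,D:1)85:1)50:1,(E:1,F:1)40:2):0;"
  tax <- tax4(LETTERS[1:6], paste0("sp", 1:6),
              c("Rosids", "Asterids", "Rosids", "Asterids",
                "monocots", "monocots"))
  parse_newick_with_support(text = nwk, dialect = "single", taxonomy = tax)
}

test_that("find_shared_clades applies strict thresholds and lineage spans", {
  at <- planted_small_tree()
  g <- find_shared_clades(at, min_ufboot = 90, min_lineages = 2)
  expect_identical(length(g$members), 1L)
  expect_identical(sort(g$members$group_1), c("A", "B"))
  # support exactly at the threshold does not qualify
  g <- find_shared_clades(at, min_ufboot = 95)
  expect_identical(length(g$members), 0L)
  # single-lineage clade EF never qualifies even with high support
  tax1 <- at$taxonomy
  tax1$lineage_id <- "Rosids"
  at1 <- annotate_taxonomy(at, tax1)
  expect_identical(nrow(find_shared_clades(at1, 90)$groups), 0L)
})

test_that("maximality suppresses nested qualifying clades unless requested", {
  nwk <- "(((A:1,B:1)97:1,C:1)96:1,(D:1,E:1)40:2):0;"
  tax <- tax4(LETTERS[1:5], paste0("sp", 1:5),
              c("Rosids", "Asterids", "monocots", "Rosids", "Rosids"))
  at <- parse_newick_with_support(text = nwk, dialect = "single",
                                  taxonomy = tax)
  g <- find_shared_clades(at, 90)
  expect_identical(length(g$members), 1L)
  expect_identical(sort(g$members$group_1), c("A", "B", "C"))
  g2 <- find_shared_clades(at, 90, include_nested = TRUE)
  expect_identical(length(g2$members), 2L)
  # returned maximal groups are pairwise non-nested on simulated trees
  sim <- simulate_tree(n_leaves = 80, n_planted = 3, n_decoys = 4, seed = 21)
  at <- parse_newick_with_support(text = sim$newick, dialect = "dual",
                                  taxonomy = sim$taxonomy)
  gg <- find_shared_clades(at, 90, 80)$members
  for (i in seq_along(gg)) {
    for (j in seq_along(gg)) {
      if (i != j) expect_false(all(gg[[i]] %in% gg[[j]]))
    }
  }
})

test_that("detection agrees with the per-node brute-force oracle", {
  for (seed in 1:6) {
    sim <- simulate_tree(n_leaves = 60, n_planted = 2, n_decoys = 3,
                         planted_size = 8, decoy_size = 5, seed = seed)
    at <- parse_newick_with_support(text = sim$newick, dialect = "dual",
                                    taxonomy = sim$taxonomy)
    got <- lapply(find_shared_clades(at, 90, 80)$members, sort)
    want <- oracle_shared_clades(at, 90, 80, 2)
    expect_setequal(unname(vapply(got, leafset_key, "")),
                    vapply(want, leafset_key, ""))
  }
})

test_that("raising the bootstrap threshold never adds qualifying clades", {
  # counted over all qualifying clades: the maximal-group count can jump when
  # a high ancestor splits into several descendants, but the qualifying set
  # itself only shrinks as the threshold rises
  sim <- simulate_tree(n_leaves = 120, seed = 5)
  at <- parse_newick_with_support(text = sim$newick, dialect = "dual",
                                  taxonomy = sim$taxonomy)
  n <- vapply(c(0, 50, 80, 90, 95, 99),
              function(t) nrow(find_shared_clades(at, t, NULL,
                                                  include_nested = TRUE)$groups),
              0L)
  expect_true(all(diff(n) <= 0))
})

test_that("re-rooting does not change qualifying leaf-sets away from the root", {
  sim <- simulate_tree(n_leaves = 60, n_planted = 2, n_decoys = 3,
                       planted_size = 8, decoy_size = 5, seed = 9)
  at <- parse_newick_with_support(text = sim$newick, dialect = "dual",
                                  taxonomy = sim$taxonomy)
  base <- sort(vapply(find_shared_clades(at, 90, 80)$members, leafset_key, ""))
  # re-root on the branch above an arbitrary background leaf
  re <- ape::root(at$phylo, outgroup = setdiff(at$phylo$tip.label,
                                               unlist(sim$planted))[1],
                  resolve.root = TRUE, edgelabel = TRUE)
  at2 <- parse_newick_with_support(text = ape::write.tree(re),
                                   dialect = "dual", taxonomy = sim$taxonomy)
  re_found <- sort(vapply(find_shared_clades(at2, 90, 80)$members,
                          leafset_key, ""))
  expect_identical(re_found, base)
})

test_that("representative selection is seeded, bounded, and lineage-stratified", {
  sim <- simulate_tree(n_leaves = 120, seed = 2)
  at <- parse_newick_with_support(text = sim$newick, dialect = "dual",
                                  taxonomy = sim$taxonomy)
  g <- find_shared_clades(at, 90, 80)
  expect_identical(select_representatives(at, g, per_group = 3, seed = 7),
                   select_representatives(at, g, per_group = 3, seed = 7))
  # per_group beyond every group size returns the union of members
  all_sel <- select_representatives(at, g, per_group = 1000, seed = 1)
  expect_setequal(all_sel, unlist(g$members))
  # stratification: with quota 3 every lineage present in a group contributes
  sel <- select_representatives(at, g, per_group = 3, seed = 3)
  lin <- setNames(at$taxonomy$lineage_id, at$taxonomy$leaf_id)
  for (grp in g$members) {
    picked <- intersect(sel, grp)
    expect_lte(length(picked), 3L)
    n_lin <- length(unique(lin[grp]))
    expect_identical(length(unique(lin[picked])), min(3L, n_lin, length(grp)))
  }
  expect_identical(select_representatives(at, structure(
    list(groups = data.frame(), members = list()), class = "clade_groups"),
    per_group = 3, seed = 1), character())
})

test_that("clade groups convert to species presence rows", {
  at <- planted_small_tree()
  g <- find_shared_clades(at, 90)
  pm <- lineage_presence_from_clades(g, at$taxonomy)
  expect_true(pm["group_1", "sp1"] && pm["group_1", "sp2"])
  expect_false(any(pm["group_1", c("sp3", "sp4", "sp5", "sp6")]))
  empty <- structure(list(groups = data.frame(), members = list()),
                     class = "clade_groups")
  expect_identical(nrow(lineage_presence_from_clades(empty, at$taxonomy)), 0L)
})

test_that("simulated trees round-trip and honour lineage assignments", {
  sim <- simulate_tree(n_leaves = 80, n_planted = 3, n_decoys = 4, seed = 4)
  at <- parse_newick_with_support(text = sim$newick, dialect = "dual",
                                  taxonomy = sim$taxonomy)
  expect_identical(length(at$phylo$tip.label), 80L)
  expect_setequal(at$phylo$tip.label, sim$taxonomy$leaf_id)
  # single-dialect output parses too
  sim1 <- simulate_tree(n_leaves = 60, n_planted = 2, n_decoys = 3,
                        planted_size = 8, decoy_size = 5,
                        dialect = "single", seed = 4)
  at1 <- parse_newick_with_support(text = sim1$newick, dialect = "single",
                                   taxonomy = sim1$taxonomy)
  got <- lapply(find_shared_clades(at1, 90, NULL)$members, sort)
  expect_setequal(unname(vapply(got, leafset_key, "")),
                  unname(vapply(sim1$planted, function(x) leafset_key(x), "")))
})
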