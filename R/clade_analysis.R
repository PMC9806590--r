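# Detection of taxonomically shared, well-supported clades on phylogenies
# annotated with SH-aLRT / ultrafast-bootstrap support.

#' Parse a Newick tree with branch-support labels
#'
#' Reads a Newick file whose internal-node labels carry branch support in one
#' of two dialects produced by ML tree inference: `single` (one number, taken
#' as ultrafast bootstrap, e.g. `"95"`) or `dual` (`"SH-aLRT/UFboot"`, e.g.
#' `"80/95"`). Unlabeled nodes get absent (`NA`) support. Unrooted trees are
#' midpoint-rooted, keeping support labels attached to the branches they
#' describe.
#'
#' @param path Newick file path (or use `text`).
#' @param dialect `"single"` or `"dual"`.
#' @param taxonomy Optional data frame (`leaf_id`, `species_id`, `lineage_id`)
#'   annotating every leaf; see [annotate_taxonomy()].
#' @param text Newick string, as an alternative to `path`.
#' @return Object of class `annotated_tree`: list with `phylo` (an
#'   `ape::phylo`), `support` (data frame `node`, `sh_alrt`, `ufboot`) and
#'   `taxonomy` (or `NULL`).
#' @export
parse_newick_with_support <- function(path = NULL, dialect = c("single", "dual"),
                                      taxonomy = NULL, text = NULL) {
  dialect <- match.arg(dialect)
  tree <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse Newick input")
  if (!ape::is.rooted(tree)) {
    if (is.null(tree$edge.length)) {
      stop("unrooted tree without branch lengths cannot be midpoint-rooted")
    }
    tree <- phangorn::midpoint(tree, node.labels = "support")
  }
  labs <- tree$node.label
  n_internal <- tree$Nnode
  if (is.null(labs)) labs <- rep("", n_internal)
  sh <- rep(NA_real_, n_internal)
  uf <- rep(NA_real_, n_internal)
  for (i in seq_len(n_internal)) {
    lab <- labs[i]
    if (is.na(lab) || !nzchar(lab)) next
    # the root (first internal node) often carries a textual label such as
    # "Root" after re-rooting; treat it as absent support rather than erroring
    if (i == 1L && !grepl("^[0-9.]+(/[0-9.]+)?$", lab)) next
    if (dialect == "dual") {
      parts <- strsplit(lab, "/", fixed = TRUE)[[1L]]
      if (length(parts) != 2L) {
        stop("node ", i + length(tree$tip.label),
             ": label '", lab, "' is not 'SH-aLRT/UFboot'")
      }
      vals <- suppressWarnings(as.numeric(parts))
      if (anyNA(vals)) {
        stop("node ", i + length(tree$tip.label),
             ": non-numeric support label '", lab, "'")
      }
      sh[i] <- vals[1L]; uf[i] <- vals[2L]
    } else {
      val <- suppressWarnings(as.numeric(lab))
      if (is.na(val)) {
        stop("node ", i + length(tree$tip.label),
             ": non-numeric support label '", lab, "'")
      }
      uf[i] <- val
    }
  }
  ok <- function(x) all(is.na(x) | (x >= 0 & x <= 100))
  if (!ok(sh) || !ok(uf)) stop("support values must lie in [0, 100]")
  at <- structure(
    list(phylo = tree,
         support = data.frame(node = length(tree$tip.label) + seq_len(n_internal),
                              sh_alrt = sh, ufboot = uf),
         taxonomy = NULL),
    class = "annotated_tree")
  if (!is.null(taxonomy)) at <- annotate_taxonomy(at, taxonomy) else at
}

#' Attach leaf taxonomy to an annotated tree
#'
#' @param atree An `annotated_tree`.
#' @param taxonomy Data frame with columns `leaf_id`, `species_id`,
#'   `lineage_id` covering every leaf of the tree.
#' @return The tree with `taxonomy` filled in.
#' @export
annotate_taxonomy <- function(atree, taxonomy) {
  stopifnot(inherits(atree, "annotated_tree"),
            all(c("leaf_id", "species_id", "lineage_id") %in% names(taxonomy)))
  if (anyDuplicated(taxonomy$leaf_id)) stop("duplicate leaf_ids in taxonomy")
  miss <- setdiff(atree$phylo$tip.label, taxonomy$leaf_id)
  if (length(miss)) {
    stop("leaves missing from taxonomy: ", paste(utils::head(miss, 5L),
                                                 collapse = ", "))
  }
  atree$taxonomy <- taxonomy[match(atree$phylo$tip.label, taxonomy$leaf_id), ,
                             drop = FALSE]
  rownames(atree$taxonomy) <- NULL
  atree
}

#' @export
print.annotated_tree <- function(x, ...) {
  cat("annotated_tree: ", length(x$phylo$tip.label), " leaves, ",
      x$phylo$Nnode, " internal nodes",
      if (!is.null(x$taxonomy)) paste0(", ",
        length(unique(x$taxonomy$lineage_id)), " lineages"), "\n", sep = "")
  invisible(x)
}

node_leaf_sets <- function(phylo) {
  ntip <- length(phylo$tip.label)
  desc <- phangorn::Descendants(phylo, (ntip + 1L):(ntip + phylo$Nnode), "tips")
  lapply(desc, function(i) phylo$tip.label[i])
}

#' Find taxonomically shared, well-supported clades
#'
#' Scans every internal node and returns the clades whose ultrafast
#' bootstrap support is strictly above `min_ufboot`, whose SH-aLRT support
#' is strictly above `min_sh_alrt` (when that threshold is given), and whose
#' leaves span at least `min_lineages` distinct lineages. Nodes lacking a
#' required support value fail the test rather than erroring, since tree
#' inference leaves some nodes (e.g. the root) unlabeled. By default only
#' maximal qualifying clades are returned: a qualifying clade nested inside
#' another qualifying clade is suppressed unless `include_nested = TRUE`.
#' Groups are labelled `group_1 ... group_k` in decreasing size order;
#' biological names are assigned by the user afterwards.
#'
#' @param atree An `annotated_tree` with taxonomy attached.
#' @param min_ufboot Strict lower bound on ultrafast bootstrap (default 90).
#' @param min_sh_alrt Strict lower bound on SH-aLRT, or `NULL` to ignore.
#' @param min_lineages Minimum number of distinct lineages spanned (default 2).
#' @param include_nested Return nested qualifying clades too.
#' @return Object of class `clade_groups`: list with `groups` (data frame
#'   `group_label`, `node`, `ufboot`, `sh_alrt`, `n_leaves`, `n_lineages`,
#'   `lineages`) and `members` (named list of leaf-id vectors).
#' @export
find_shared_clades <- function(atree, min_ufboot = 90, min_sh_alrt = NULL,
                               min_lineages = 2L, include_nested = FALSE) {
  stopifnot(inherits(atree, "annotated_tree"))
  if (is.null(atree$taxonomy)) stop("tree has no taxonomy; see annotate_taxonomy()")
  stopifnot(min_ufboot >= 0, min_ufboot <= 100,
            is.null(min_sh_alrt) || (min_sh_alrt >= 0 && min_sh_alrt <= 100))
  phylo <- atree$phylo
  ntip <- length(phylo$tip.label)
  leaf_sets <- node_leaf_sets(phylo)
  lin_of <- stats::setNames(atree$taxonomy$lineage_id, atree$taxonomy$leaf_id)
  sup <- atree$support
  qual <- logical(phylo$Nnode)
  for (i in seq_len(phylo$Nnode)) {
    uf <- sup$ufboot[i]; sh <- sup$sh_alrt[i]
    if (is.na(uf) || uf <= min_ufboot) next
    if (!is.null(min_sh_alrt) && (is.na(sh) || sh <= min_sh_alrt)) next
    if (length(unique(lin_of[leaf_sets[[i]]])) < min_lineages) next
    qual[i] <- TRUE
  }
  keep <- which(qual)
  if (!include_nested && length(keep) > 1L) {
    # drop qualifying clades with a qualifying strict ancestor
    anc <- phangorn::Ancestors(phylo, keep + ntip, "all")
    if (!is.list(anc)) anc <- list(anc)
    has_qual_anc <- vapply(anc, function(a) {
      a <- a[a > ntip] - ntip
      any(qual[a])
    }, TRUE)
    keep <- keep[!has_qual_anc]
  }
  sizes <- vapply(keep, function(i) length(leaf_sets[[i]]), 0L)
  keep <- keep[order(-sizes)]
  groups <- data.frame(
    group_label = if (length(keep)) paste0("group_", seq_along(keep)) else character(),
    node = keep + ntip,
    ufboot = sup$ufboot[keep],
    sh_alrt = sup$sh_alrt[keep],
    n_leaves = vapply(keep, function(i) length(leaf_sets[[i]]), 0L),
    n_lineages = vapply(keep, function(i)
      length(unique(lin_of[leaf_sets[[i]]])), 0L),
    lineages = vapply(keep, function(i)
      paste(sort(unique(lin_of[leaf_sets[[i]]])), collapse = ","), ""),
    stringsAsFactors = FALSE)
  rownames(groups) <- NULL
  members <- stats::setNames(lapply(keep, function(i) leaf_sets[[i]]),
                             groups$group_label)
  structure(list(groups = groups, members = members), class = "clade_groups")
}

#' @export
print.clade_groups <- function(x, ...) {
  cat("clade_groups: ", nrow(x$groups), " group(s)\n", sep = "")
  if (nrow(x$groups)) print(x$groups, ...)
  invisible(x)
}

#' Select representative leaves from clade groups
#'
#' Picks up to `per_group` leaves from each group to build a reduced tree
#' (smaller alignments avoid an excess of sequences over alignment patterns).
#' Selection is stratified by lineage: lineages are cycled in random order,
#' one random member at a time, until the quota is filled, so every lineage
#' present in a group is represented whenever the quota allows. Deterministic
#' under a fixed seed.
#'
#' @param atree An `annotated_tree` with taxonomy.
#' @param groups A `clade_groups` object.
#' @param per_group Maximum leaves per group (>= 1).
#' @param seed Integer seed.
#' @return Character vector of selected leaf ids.
#' @export
select_representatives <- function(atree, groups, per_group, seed) {
  stopifnot(inherits(groups, "clade_groups"), per_group >= 1L)
  if (!length(groups$members)) return(character())
  lin_of <- stats::setNames(atree$taxonomy$lineage_id, atree$taxonomy$leaf_id)
  withr::with_seed(seed, {
    sel <- lapply(groups$members, function(leaves) {
      if (length(leaves) <= per_group) return(sort(leaves))
      by_lin <- split(leaves, lin_of[leaves])
      by_lin <- lapply(by_lin, sample)        # random order within lineage
      order_lin <- sample(names(by_lin))      # random lineage rotation
      picked <- character()
      while (length(picked) < per_group && length(by_lin)) {
        for (ln in order_lin) {
          if (length(picked) >= per_group) break
          pool <- by_lin[[ln]]
          if (is.null(pool) || !length(pool)) next
          picked <- c(picked, pool[1L])
          by_lin[[ln]] <- pool[-1L]
        }
        order_lin <- order_lin[vapply(by_lin[order_lin], length, 0L) > 0L]
        if (!length(order_lin)) break
      }
      sort(picked)
    })
    unique(unlist(sel, use.names = FALSE))
  })
}

#' Species presence rows from clade groups
#'
#' Converts clade groups into a group x species presence matrix: a cell is
#' `TRUE` iff the group contains at least one leaf from that species. Feeds
#' the co-occurrence module.
#'
#' @param groups A `clade_groups` object.
#' @param taxonomy Data frame with `leaf_id`, `species_id` covering all
#'   member leaves.
#' @return A `presence_matrix` (logical, groups x species).
#' @export
lineage_presence_from_clades <- function(groups, taxonomy) {
  stopifnot(inherits(groups, "clade_groups"),
            all(c("leaf_id", "species_id") %in% names(taxonomy)))
  species <- unique(taxonomy$species_id)
  sp_of <- stats::setNames(taxonomy$species_id, taxonomy$leaf_id)
  row_ids <- names(groups$members)
  if (is.null(row_ids)) row_ids <- character()
  m <- matrix(FALSE, nrow = length(groups$members), ncol = length(species),
              dimnames = list(row_ids, species))
  for (g in names(groups$members)) {
    leaves <- groups$members[[g]]
    miss <- setdiff(leaves, names(sp_of))
    if (length(miss)) {
      stop("member leaves missing from taxonomy: ",
           paste(utils::head(miss, 5L), collapse = ", "))
    }
    m[g, unique(sp_of[leaves])] <- TRUE
  }
  presence_matrix(m, provenance = "family_counts")
}

#' Write clade groups to TSV
#'
#' @param groups A `clade_groups` object.
#' @param path Output file.
#' @export
write_clade_groups <- function(groups, path) {
  df <- groups$groups
  df$leaves <- vapply(groups$members, paste, "", collapse = ",")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(groups)
}
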