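# Hit-table parsing, overlap deduplication, length filtering, and
# architecture classification.

write_hits_tsv <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}

test_that("parse_hit_table reads the TSV dialect and applies the E-value cutoff", {
  expect_identical(nrow(parse_hit_table(write_hits_tsv(character()))), 0L)

  # one hit below and one above the 0.01 inclusion threshold
  tf <- write_hits_tsv(c("p1\tTIR\t10\t150\t0.005\t300",
                         "p1\tTIR_2\t200\t280\t0.02\t300"))
  hits <- parse_hit_table(tf, max_evalue = 0.01)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$evalue, 0.005)

  # field-by-field agreement with an independent line-level parse
  rows <- c("pA\tTIR\t12\t180\t1e-30\t500",
            "pB\tNB-ARC\t210\t520\t1e-25\t900",
            "pC\tUnknownHMM\t5\t80\t1e-04\t120")
  hits <- parse_hit_table(write_hits_tsv(rows))
  manual <- do.call(rbind, lapply(strsplit(rows, "\t"), function(f) {
    data.frame(protein_id = f[1], hmm_name = f[2],
               env_start = as.integer(f[3]), env_end = as.integer(f[4]),
               evalue = as.numeric(f[5]), protein_length = as.integer(f[6]),
               stringsAsFactors = FALSE)
  }))
  expect_identical(hits[names(manual)], manual)
  expect_identical(hits$domain_class, c("TIR", "NBARC", "OTHER"))
})

test_that("parse_hit_table reads HMMER3 domtblout lines", {
  # 23 whitespace-separated fields as emitted by hmmsearch --domtblout
  line <- paste("prot1 - 600 TIR PF01582.20 175 1.2e-40 140.1 0.1 1 2",
                "3.1e-42 2.5e-38 130.2 0.1 2 170 15 180 10 190 0.95 desc")
  tf <- write_hits_tsv(c("# comment line", line))
  hits <- parse_hit_table(tf, format = "domtblout")
  expect_identical(hits$protein_id, "prot1")
  expect_identical(hits$hmm_name, "TIR")
  expect_identical(hits$env_start, 10L)
  expect_identical(hits$env_end, 190L)
  expect_equal(hits$evalue, 2.5e-38)
  expect_identical(hits$protein_length, 600L)
})

test_that("parse_hit_table rejects malformed input with a line number", {
  tf <- write_hits_tsv(c("p1\tTIR\t10\t150\t0.005\t300", "p2\tbroken"))
  expect_error(parse_hit_table(tf), "line 2")
  tf <- write_hits_tsv("p1\tTIR\tnot_a_number\t150\t0.005\t300")
  expect_error(parse_hit_table(tf), "line 1")
  tf <- write_hits_tsv("p1\tTIR\t-5\t150\t0.005\t300")
  expect_error(parse_hit_table(tf), "positive")
})

mk_hits <- function(starts, ends, evalues, hmm = NULL, class = "TIR",
                    protein = "p1") {
  data.frame(protein_id = rep_len(protein, length(starts)),
             hmm_name = if (is.null(hmm)) sprintf("h%d", seq_along(starts)) else hmm,
             domain_class = rep_len(class, length(starts)),
             env_start = as.integer(starts), env_end = as.integer(ends),
             evalue = evalues, stringsAsFactors = FALSE)
}

test_that("merge_overlapping_hits honours the strict 20-residue overlap rule", {
  # disjoint: both kept
  h <- mk_hits(c(1, 130), c(120, 200), c(1e-10, 1e-5))
  expect_identical(nrow(merge_overlapping_hits(h)), 2L)

  # overlap 21 (> 20): lower E-value wins
  h <- mk_hits(c(1, 100), c(120, 200), c(1e-10, 1e-5))
  kept <- merge_overlapping_hits(h)
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$env_start, 1L)

  # overlap exactly 20: tolerated, both kept
  h <- mk_hits(c(1, 101), c(120, 200), c(1e-10, 1e-5))
  expect_identical(nrow(merge_overlapping_hits(h)), 2L)

  # different classes never suppress each other even at full overlap
  h <- mk_hits(c(1, 1), c(120, 120), c(1e-10, 1e-5), class = c("TIR", "NBARC"))
  expect_identical(nrow(merge_overlapping_hits(h)), 2L)

  expect_error(
    merge_overlapping_hits(mk_hits(1, 120, 1e-5, protein = c("p1"))[c(1, 1), ] |>
                             transform(protein_id = c("p1", "p2"))),
    "single protein")
})

test_that("merge tie-breaking is deterministic: longer envelope, then hmm name", {
  h <- mk_hits(c(1, 1), c(100, 120), c(1e-5, 1e-5), hmm = c("b_hmm", "a_hmm"))
  expect_identical(merge_overlapping_hits(h)$hmm_name, "a_hmm")  # longer
  h <- mk_hits(c(1, 1), c(120, 120), c(1e-5, 1e-5), hmm = c("b_hmm", "a_hmm"))
  expect_identical(merge_overlapping_hits(h)$hmm_name, "a_hmm")  # lexicographic
})

test_that("merge agrees with the O(n^2) oracle and is idempotent", {
  for (seed in 1:25) {
    set.seed(seed)
    h <- random_hits(sample(1:50, 1))
    got <- merge_overlapping_hits(h)
    expect_identical(got, oracle_merge(h), info = paste("seed", seed))
    expect_identical(merge_overlapping_hits(got), got)
  }
})

test_that("transitive overlap chains keep exactly one representative", {
  # a-b overlap > 20, b-c overlap > 20, a-c disjoint: one survivor
  h <- mk_hits(c(1, 80, 160), c(110, 190, 260), c(1e-8, 1e-12, 1e-6))
  kept <- merge_overlapping_hits(h)
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$env_start, 80L)  # lowest E-value in the chain
})

test_that("filter_domain_length applies per-class minima at the boundary", {
  h <- mk_hits(c(1, 1, 1, 1), c(49, 50, 149, 150), rep(1e-9, 4),
               class = c("TIR", "TIR", "NBARC", "NBARC"), protein = "p1")
  kept <- filter_domain_length(h)
  expect_identical(kept$env_end, c(50L, 150L))
  # unlisted class passes at any length
  h <- mk_hits(1, 10, 1e-9, class = "LRR")
  expect_identical(nrow(filter_domain_length(h)), 1L)
})

arch_label <- function(length, classes, starts = NULL, ...) {
  n <- length(classes)
  if (is.null(starts)) starts <- seq(1, by = 300, length.out = n)
  domains <- mk_hits(starts, starts + 199L, rep(1e-9, n), class = classes)
  classify_architecture(list(protein_id = "p1", length = length), domains, ...)$label
}

test_that("classify_architecture applies the rules in precedence order", {
  expect_identical(arch_label(1200, c("TIR", "NBARC", "TPR")), "TNP")
  expect_identical(arch_label(1300, c("TIR", "NBARC", "LRR", "TPR")), "TNP")
  expect_identical(arch_label(1200, c("TIR", "NBARC", "LRR")), "TNL")
  expect_identical(arch_label(700, c("TIR", "NBARC")), "TN")
  expect_identical(arch_label(200, "TIR"), "TIR_ONLY")
  expect_identical(arch_label(450, "TIR"), "TIR_OTHER")   # length rule
  expect_identical(arch_label(200, c("TIR", "OTHER")), "TIR_OTHER")
  expect_identical(arch_label(300, "LRR"), "NON_TIR")
  expect_identical(
    classify_architecture(list(protein_id = "p", length = 100),
                          mk_hits(integer(), integer(), double()))$label,
    "NON_TIR")
})

test_that("classification is total and order-invariant", {
  set.seed(42)
  for (i in 1:30) {
    n <- sample(0:5, 1)
    classes <- sample(domain_classes(), n, replace = TRUE)
    starts <- sample(1:1000, max(n, 1))[seq_len(n)]
    d <- mk_hits(starts, starts + 199L, rep(1e-9, n), class = classes)
    p <- list(protein_id = "p1", length = sample(100:1500, 1))
    lab <- classify_architecture(p, d)$label
    expect_true(lab %in% architecture_labels())
    perm <- d[sample(nrow(d)), , drop = FALSE]
    expect_identical(classify_architecture(p, perm)$label, lab)
  }
})

test_that("optional domain-order flag demotes NBARC-before-TIR proteins", {
  lab <- arch_label(700, c("NBARC", "TIR"), starts = c(1, 400),
                    require_tir_first = TRUE)
  expect_identical(lab, "TIR_OTHER")
  expect_identical(arch_label(700, c("NBARC", "TIR"), starts = c(1, 400)), "TN")
})

test_that("tabulate_architectures counts TNP separately and validates species", {
  tax <- data.frame(species_id = c("s1", "s2"))
  empty <- classify_proteome(
    mk_hits(integer(), integer(), double()),
    data.frame(protein_id = character(), species_id = character(),
               length = integer()))
  tab <- tabulate_architectures(empty, tax)
  expect_identical(dim(tab), c(2L, 5L))
  expect_true(all(tab[, -1] == 0L))

  arch <- data.frame(
    protein_id = paste0("p", 1:4), species_id = "s1",
    length = 1000L, label = c("TNP", "TNL", "TIR_OTHER", "TN"),
    domains = "", stringsAsFactors = FALSE)
  tab <- tabulate_architectures(arch, tax)
  r1 <- tab[tab$species_id == "s1", ]
  expect_identical(unlist(r1[c("TNL", "TN", "TIR_ONLY", "TNP")], use.names = FALSE),
                   c(1L, 1L, 0L, 1L))
  # TIR_OTHER excluded from all four columns; TNP only in its own
  expect_identical(sum(r1[-1]), 3L)

  arch$species_id <- "unknown_sp"
  expect_error(tabulate_architectures(arch, tax), "unknown_sp")
})

test_that("classify_proteome recovers planted architectures end-to-end", {
  sim <- simulate_proteome_hits(n_species = 3L, seed = 11L)
  tf <- tempfile()
  utils::write.table(sim$hits, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  hits <- parse_hit_table(tf)
  arch <- classify_proteome(hits, sim$proteins)
  expect_identical(
    arch$label[match(sim$truth$protein_id, arch$protein_id)],
    sim$truth$label)
})
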