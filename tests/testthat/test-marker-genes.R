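gene_tab <- function(counts, lengths, families = NULL) {
  n <- length(counts)
  data.frame(gene_id = paste0("g", seq_len(n)), orf_length = lengths,
             read_count = counts, taxon_label = "Bacteria",
             gene_family = families %||% rep("other", n),
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("TPM is length-normalized and sums to a million", {
  one <- tpm(gene_tab(50, 900))
  expect_equal(one$tpm, 1e6)
  two <- tpm(gene_tab(c(10, 10), c(100, 200)))
  expect_equal(two$tpm, c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  set.seed(12)
  big <- tpm(gene_tab(rpois(200, 40), sample(300:3000, 200)))
  expect_equal(sum(big$tpm), 1e6, tolerance = 1e-6)
  expect_error(tpm(gene_tab(c(0, 0), c(100, 100))), "undefined TPM")
})

test_that("TPM is scale-invariant in counts and halves with doubled length", {
  tab <- gene_tab(c(30, 70, 120), c(500, 1000, 1500))
  expect_equal(tpm(tab)$tpm, tpm(transform(tab, read_count = read_count * 9))$tpm,
               tolerance = 1e-12)
  tab2 <- tab; tab2$orf_length[1] <- 2 * tab$orf_length[1]
  r1 <- tpm(tab)$tpm; r2 <- tpm(tab2)$tpm
  # doubling gene 1's length halves its rate contribution
  expect_equal(r2[1] / r2[2], (r1[1] / r1[2]) / 2, tolerance = 1e-12)
})

test_that("phnJ abundance is the recA-normalized length-corrected ratio", {
  tab <- gene_tab(c(50, 1000), c(750, 1060), c("phnJ", "recA"))
  expect_equal(phnj_relative_abundance(tab),
               100 * (50 / 750) / (1000 / 1060), tolerance = 1e-12)
  expect_equal(round(phnj_relative_abundance(tab), 2), 7.07)
  equal <- gene_tab(c(100, 100), c(1000, 1000), c("phnJ", "recA"))
  expect_equal(phnj_relative_abundance(equal), 100)
  none <- gene_tab(c(100, 0), c(1000, 1000), c("phnJ", "recA"))
  expect_error(phnj_relative_abundance(none), "no recA signal")
})

test_that("identity filter is strict at 80% and aggregates per gene", {
  hits <- data.frame(gene_id = c("a", "a", "b"),
                     orf_length = c(900, 900, 1200),
                     percent_identity = c(80.0, 80.1, 95),
                     read_count = c(5, 7, 3),
                     taxon_label = "x", gene_family = "phnJ",
                     stringsAsFactors = FALSE)
  out <- identity_filter(hits)
  expect_identical(nrow(out), 2L)
  expect_equal(out$read_count[out$gene_id == "a"], 7)  # 80.0 dropped
  expect_equal(out$read_count[out$gene_id == "b"], 3)
  empty <- identity_filter(hits[0, ])
  expect_identical(nrow(empty), 0L)
  expect_error(identity_filter(transform(hits, percent_identity = 101)),
               "\\[0, 100\\]")
})

test_that("simulated count tables converge to their configured answers", {
  set.seed(77)
  panel <- default_gene_panel(phnj_percent = 14.71)
  tab <- simulate_count_table(panel, total_reads = 1e6)
  truth <- attr(tab, "truth")
  expect_equal(truth$phnj_percent, 14.71, tolerance = 1e-12)
  expect_equal(phnj_relative_abundance(tab), 14.71, tolerance = 0.05)
  est <- tpm(tab)
  expect_equal(est$tpm, truth$tpm, tolerance = 0.02)
  # two genes, equal rates and lengths: TPM near 500k each
  set.seed(78)
  two <- simulate_count_table(
    data.frame(gene_id = c("a", "b"), orf_length = c(1000, 1000),
               gene_family = "other", rel_rate = c(1, 1)), 1e5)
  expect_equal(tpm(two)$tpm, c(5e5, 5e5), tolerance = 0.01)
  # zero phnJ rate gives exactly zero percent
  set.seed(79)
  zero <- simulate_count_table(
    data.frame(gene_id = c("r", "p"), orf_length = c(1060, 750),
               gene_family = c("recA", "phnJ"), rel_rate = c(1, 0)), 1e4)
  expect_equal(phnj_relative_abundance(zero), 0)
})

test_that("gene count tables round-trip through TSV", {
  tab <- gene_tab(c(5, 9), c(700, 1100), c("phnJ", "recA"))
  path <- tempfile(fileext = ".tsv")
  write_tsv(tab, path)
  back <- read_gene_counts(path)
  expect_equal(back$read_count, tab$read_count)
  expect_equal(back$gene_family, tab$gene_family)
})
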