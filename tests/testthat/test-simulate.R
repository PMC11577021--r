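test_that("config validation lists every violation at once", {
  expect_error(simulation_config(n_genes = 0, depth = -1,
                                 frac_release_genes = 2),
               "n_genes.*\n.*depth.*\n.*frac_release_genes")
  expect_s3_class(simulation_config(n_genes = 10), "simulation_config")
})

test_that("seeded simulations are bit-reproducible", {
  cfg <- simulation_config(n_genes = 25, guides_per_gene = 3, seed = 123)
  s1 <- simulate_screen(cfg)
  s2 <- simulate_screen(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$reference, s2$reference)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_screen(simulation_config(n_genes = 25, guides_per_gene = 3,
                                          seed = 124))
  expect_false(identical(s1$counts, s3$counts))
})

test_that("spacers are unique, key-free and of the configured length", {
  s <- simulate_screen(simulation_config(n_genes = 120, guides_per_gene = 5,
                                         seed = 6))
  expect_false(any(duplicated(s$reference$spacer)))
  expect_false(any(grepl("GTTTAAGA", s$reference$spacer, fixed = TRUE)))
  expect_true(all(nchar(s$reference$spacer) == 17L))
  # ids parse back to the generated gene/spacer/sublibrary
  parsed <- parse_barcode_ids(s$reference$barcode_id)
  expect_equal(parsed$gene, s$reference$gene)
  expect_equal(parsed$spacer, s$reference$spacer)
  expect_equal(parsed$sublibrary, s$reference$sublibrary)
})

test_that("per-sample totals follow the multinomial design", {
  cfg <- simulation_config(n_genes = 40, guides_per_gene = 5, depth = 200,
                           sublibraries = 2L, seed = 11)
  s <- simulate_screen(cfg)
  for (sl in unique(s$reference$sublibrary)) {
    rows <- s$reference$sublibrary == sl
    expect_equal(unname(colSums(s$counts[rows, ])),
                 rep(200 * sum(rows), 4L))
  }
})

test_that("FASTQ synthesis round-trips through the counter exactly", {
  s <- simulate_screen(simulation_config(n_genes = 50, guides_per_gene = 4,
                                         depth = 100, seed = 41))
  fq <- simulate_fastq(s, "sevs_plus", seed = 17)
  res <- count_reads(fq$reads, s$reference)
  expect_identical(res$counts, fq$ledger)
  expect_identical(fq$ledger[rownames(s$counts)], s$counts[, "sevs_plus"])
  expect_equal(res$stats$assigned_reads, nrow(fq$reads))

  # explicit ledger, including zero entries
  led <- c(3L, 0L)
  names(led) <- s$reference$barcode_id[1:2]
  fq2 <- simulate_fastq(s, ledger = led, seed = 2)
  expect_equal(nrow(fq2$reads), 3L)
  res2 <- count_reads(fq2$reads, s$reference)
  expect_equal(unname(res2$counts[names(led)[1]]), 3L)
  expect_equal(sum(res2$counts), 3L)

  # empty ledger -> empty FASTQ
  fq3 <- simulate_fastq(s, ledger = setNames(integer(0), character(0)),
                        seed = 2)
  expect_equal(nrow(fq3$reads), 0L)

  expect_error(simulate_fastq(s, "cells_plus", read_length = 20L),
               "too short")
})

test_that("FASTQ files written to disk read back identically", {
  s <- simulate_screen(simulation_config(n_genes = 10, guides_per_gene = 3,
                                         depth = 30, seed = 15))
  path <- withr::local_tempfile(fileext = ".fastq.gz")
  out <- simulate_fastq(s, "cells_minus", path = path, seed = 4)
  fq <- read_fastq(path)
  res <- count_reads(fq, s$reference)
  expect_identical(res$counts, out$ledger)
})

test_that("recovery improves with depth and guides per gene", {
  recover <- function(depth, m) {
    cfg <- simulation_config(n_genes = 100, guides_per_gene = m,
                             depth = depth, frac_release_genes = 0.2,
                             effect_sd_release = 1.5, seed = 99)
    s <- simulate_screen(cfg)
    sc <- score_screen(s$counts, s$manifest, s$reference)
    tr <- dplyr::inner_join(sc$genes, s$truth, by = c("gene", "sublibrary"))
    rel <- tr[tr$rho != 0, ]
    cor(rel$rho, rel$z_re, method = "spearman")
  }
  lo <- recover(100, 3)
  hi <- recover(2000, 10)
  expect_gt(hi, lo - 0.05)  # Monte-Carlo slack
  expect_gt(hi, 0.9)
})
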