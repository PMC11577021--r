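test_that("fold changes follow the log2 Cas9+/Cas9- definition", {
  nrc <- matrix(c(2, 1, 4, 1,
                  3, 3, 3, 3,
                  0.5, 1, 1, 1), 3, 4, byrow = TRUE,
                dimnames = list(c("b1", "b2", "b3"),
                                c("cells_plus", "cells_minus",
                                  "sevs_plus", "sevs_minus")))
  samples <- c(cells_plus = "cells_plus", cells_minus = "cells_minus",
               sevs_plus = "sevs_plus", sevs_minus = "sevs_minus")
  fc <- compute_fold_changes(nrc, samples)
  expect_equal(fc$fc_cells, c(1, 0, -1))
  expect_equal(fc$fc_sevs, c(2, 0, 0))

  nrc[1, 1] <- 0
  expect_error(compute_fold_changes(nrc, samples), "nonpositive")
})

test_that("fit_line equals the closed-form normal-equation solution", {
  # exact line
  x <- c(-2, -1, 0, 1, 2)
  f <- fit_line(x, 2 * x + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r, 1)

  # symmetric cross: zero slope, zero correlation
  f0 <- fit_line(c(-1, 1, 0, 0), c(0, 0, 1, -1))
  expect_equal(f0$slope, 0)
  expect_equal(f0$intercept, 0)
  expect_equal(f0$r, 0)

  # random points vs normal equations
  set.seed(5)
  x <- rnorm(50); y <- 0.7 * x + rnorm(50, 0, 0.4)
  f <- fit_line(x, y)
  n <- length(x)
  slope <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  expect_equal(f$slope, slope)
  expect_equal(f$intercept, mean(y) - slope * mean(x))

  expect_error(fit_line(c(1, 1, 1), c(1, 2, 3)), "distinct x")
})

test_that("two-pass trimming recovers an offset gene against a null bulk", {
  set.seed(9)
  # many null genes lying on y = x, one gene shifted upward by +1
  n_null <- 60
  null_x <- rnorm(n_null * 5)
  guides <- tibble::tibble(
    barcode_id = sprintf("b%03d", seq_len(n_null * 5 + 5)),
    gene = c(rep(sprintf("N%02d", seq_len(n_null)), each = 5), rep("UP", 5)),
    fc_cells = c(null_x, rnorm(5)),
    fc_sevs = NA_real_
  )
  guides$fc_sevs <- guides$fc_cells + c(rep(0, n_null * 5), rep(1, 5)) +
    rnorm(nrow(guides), 0, 0.02)
  res <- compute_re(guides)
  up <- res$guides[res$guides$gene == "UP", ]
  null <- res$guides[res$guides$gene != "UP", ]
  expect_equal(mean(up$re), 1, tolerance = 0.05)
  expect_equal(mean(null$re), 0, tolerance = 0.02)
  # exactly one max and one min guide trimmed per gene
  trims <- tapply(res$guides$trimmed, res$guides$gene, sum)
  expect_true(all(trims == 2))
  # pass-2 residuals sum to zero over the untrimmed set
  expect_equal(sum(res$guides$re[!res$guides$trimmed]), 0, tolerance = 1e-9)
})

test_that("collinear guides give zero residuals in both passes", {
  guides <- tibble::tibble(
    barcode_id = sprintf("b%d", 1:9),
    gene = rep(c("A", "B", "C"), each = 3),
    fc_cells = seq(-2, 2, length.out = 9)
  )
  guides$fc_sevs <- 1.3 * guides$fc_cells - 0.2
  res <- compute_re(guides)
  expect_equal(res$guides$re, rep(0, 9), tolerance = 1e-12)
  expect_equal(res$fit2$slope, 1.3)
  expect_equal(res$fit2$intercept, -0.2)
})

test_that("a 3-guide gene keeps only its middle guide in the refit but all REs are reported", {
  set.seed(2)
  filler <- tibble::tibble(
    barcode_id = sprintf("f%02d", 1:20),
    gene = rep(sprintf("F%d", 1:4), each = 5),
    fc_cells = rnorm(20)
  )
  filler$fc_sevs <- filler$fc_cells + rnorm(20, 0, 0.1)
  g3 <- tibble::tibble(barcode_id = c("g1", "g2", "g3"), gene = "G3",
                       fc_cells = c(-1, 0, 1),
                       fc_sevs = c(-1.5, 0, 1.5))
  res <- compute_re(dplyr::bind_rows(filler, g3))
  sub <- res$guides[res$guides$gene == "G3", ]
  expect_equal(sum(sub$trimmed), 2L)
  expect_false(sub$trimmed[sub$barcode_id == "g2"])
  expect_true(all(is.finite(sub$re)))
})

test_that("gene RE is the median over all retained guides, trimmed included", {
  guides <- tibble::tibble(gene = "G", sublibrary = "L",
                           re = c(1, 2, 10), trimmed = c(FALSE, FALSE, TRUE))
  expect_equal(gene_scores(guides)$re_gene, 2)
  expect_equal(gene_scores(guides, include_trimmed = FALSE)$re_gene, 1.5)
  # even count: mean of the two middle values
  g4 <- tibble::tibble(gene = "G", re = 1:4, trimmed = FALSE)
  expect_equal(gene_scores(g4)$re_gene, 2.5)
  g1 <- tibble::tibble(gene = "G", re = 3.14, trimmed = FALSE)
  expect_equal(gene_scores(g1)$re_gene, 3.14)
})

test_that("z-normalization is per sublibrary with the sample SD", {
  genes <- tibble::tibble(gene = c("a", "b", "c"), sublibrary = "L",
                          re_gene = c(-1, 0, 1))
  expect_equal(z_normalize(genes)$z_re, c(-1, 0, 1))
  # location invariance
  shifted <- genes; shifted$re_gene <- shifted$re_gene + 100
  expect_equal(z_normalize(shifted)$z_re, c(-1, 0, 1))
  # population SD variant
  zp <- z_normalize(genes, sd_type = "population")$z_re
  expect_equal(zp, c(-1, 0, 1) * sqrt(3 / 2))
  # each sublibrary standardized on its own
  two <- dplyr::bind_rows(genes,
                          tibble::tibble(gene = c("d", "e"),
                                         sublibrary = "M",
                                         re_gene = c(0, 50)))
  z2 <- z_normalize(two)
  for (sl in c("L", "M")) {
    zz <- z2$z_re[z2$sublibrary == sl]
    expect_equal(mean(zz), 0, tolerance = 1e-9)
    expect_equal(sd(zz), 1, tolerance = 1e-9)
  }
  expect_error(z_normalize(tibble::tibble(gene = c("a", "b"),
                                          re_gene = c(1, 1))), "zero")
  expect_error(z_normalize(tibble::tibble(gene = "a", re_gene = 1)),
               "at least 2 genes")
})

test_that("score_screen matches the brute-force oracle on small screens", {
  set.seed(31)
  for (rep in 1:3) {
    cfg <- simulation_config(n_genes = 20, guides_per_gene = 5,
                             depth = 400, frac_viability_genes = 0.2,
                             frac_release_genes = 0.2, seed = 100 + rep)
    s <- simulate_screen(cfg)
    sc <- score_screen(s$counts, s$manifest, s$reference)
    or <- oracle_score(s$counts, s$reference)
    expect_equal(sc$guides$re[match(or$guides$barcode_id,
                                    sc$guides$barcode_id)],
                 or$guides$re, tolerance = 1e-9)
    expect_equal(sc$genes$z_re[match(or$genes$gene, sc$genes$gene)],
                 or$genes$z_re, tolerance = 1e-9)
  }
})

test_that("scoring is invariant to sequencing depth and barcode order", {
  cfg <- simulation_config(n_genes = 30, guides_per_gene = 4,
                           depth = 300, seed = 77)
  s <- simulate_screen(cfg)
  sc <- score_screen(s$counts, s$manifest, s$reference)

  doubled <- s$counts * 2L
  sc2 <- score_screen(doubled, s$manifest, s$reference)
  expect_equal(sc2$genes$z_re, sc$genes$z_re, tolerance = 1e-12)

  perm <- sample(nrow(s$counts))
  sc3 <- score_screen(s$counts[perm, ], s$manifest, s$reference)
  expect_equal(sc3$genes[order(sc3$genes$gene), ]$z_re,
               sc$genes[order(sc$genes$gene), ]$z_re, tolerance = 1e-12)
})

test_that("a perfectly proportional screen hits the zero-SD error path", {
  # 2 genes x 4 guides; sEV counts identical to cellular counts, so
  # FC_sEVs = FC_cells exactly: every residual is 0 and all gene REs tie
  set.seed(55)
  spacers <- unique(replicate(20, paste(
    sample(c("A", "C", "G", "T"), 17, replace = TRUE), collapse = "")))[1:8]
  genes <- rep(c("GENEA", "GENEB"), each = 4L)
  ref <- parse_barcode_ids(sprintf("%s_%s_%d_LIBX", genes, spacers,
                                   rep(1:4, 2)))
  base <- c(100L, 200L, 300L, 400L, 500L, 600L, 700L, 800L)
  plus <- c(200L, 100L, 300L, 800L, 250L, 600L, 1400L, 400L)
  counts <- cbind(cells_minus = base, cells_plus = plus,
                  sevs_minus = base, sevs_plus = plus)
  rownames(counts) <- ref$barcode_id
  res <- tryCatch(
    score_screen(counts, four_sample_manifest(), ref,
                 min_guides_per_gene = 3L),
    error = function(e) e)
  if (inherits(res, "error")) {
    # exact ties between gene REs hit the guarded zero-SD path
    expect_match(conditionMessage(res), "zero standard deviation")
  } else {
    # floating-point residue only: every guide RE vanishes
    expect_lt(max(abs(res$guides$re)), 1e-9)
  }
  # exact ties always error rather than dividing by zero
  expect_error(z_normalize(tibble::tibble(gene = c("GENEA", "GENEB"),
                                          re_gene = c(0, 0))),
               "zero standard deviation")
})
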