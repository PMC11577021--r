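# Small in-code fixtures shared across test files.

# a tiny reference with two genes x three guides in one sublibrary
tiny_reference <- function() {
  spacers <- c("GAAAGTCAGAAACCCGA", "ACGTACGTACGTACGTA", "TTTTCCCCAAAAGGGGT",
               "ACACACACACACACACA", "TGTGTGTGTGTGTGTGT", "GGGGAAAATTTTCCCCA")
  genes <- rep(c("GENEA", "GENEB"), each = 3L)
  tibble::tibble(
    barcode_id = sprintf("%s_%s_%d_LIBX", genes, spacers, rep(1:3, 2)),
    gene = genes, spacer = spacers, sublibrary = "LIBX"
  )
}

four_sample_manifest <- function() {
  tibble::tibble(
    sample_id = c("cells_minus", "cells_plus", "sevs_minus", "sevs_plus"),
    fraction = c("cells", "cells", "sevs", "sevs"),
    cas9 = c("minus", "plus", "minus", "plus"),
    screen = "TEST", sublibrary = "all", source = NA_character_
  )
}

# Independent brute-force transcription of the scoring procedure, written
# step by step with closed-form normal-equation OLS (no lm, no package
# scoring code). Serves as the oracle for compute_re / score_screen.
oracle_score <- function(counts, reference, min_nrc = 0.05, min_guides = 3) {
  ols <- function(x, y) {
    sx <- sum(x); sy <- sum(y); n <- length(x)
    b <- (n * sum(x * y) - sx * sy) / (n * sum(x * x) - sx^2)
    a <- (sy - b * sx) / n
    c(intercept = a, slope = b)
  }
  out_guides <- NULL
  out_genes <- NULL
  for (sl in unique(reference$sublibrary)) {
    ref <- reference[reference$sublibrary == sl, ]
    cts <- counts[ref$barcode_id, , drop = FALSE]
    nrc <- apply(cts, 2, function(col) col / sum(col) * nrow(ref))
    rownames(nrc) <- ref$barcode_id
    keep_bc <- apply(nrc, 1, function(r) all(r >= min_nrc))
    ref <- ref[keep_bc, ]
    nrc <- nrc[keep_bc, , drop = FALSE]
    tab <- table(ref$gene)
    keep_gene <- names(tab)[tab >= min_guides]
    sel <- ref$gene %in% keep_gene
    ref <- ref[sel, ]
    nrc <- nrc[sel, , drop = FALSE]
    fc_cells <- log2(nrc[, "cells_plus"] / nrc[, "cells_minus"])
    fc_sevs <- log2(nrc[, "sevs_plus"] / nrc[, "sevs_minus"])
    f1 <- ols(fc_cells, fc_sevs)
    re1 <- fc_sevs - (f1["slope"] * fc_cells + f1["intercept"])
    trimmed <- rep(FALSE, nrow(ref))
    for (gn in unique(ref$gene)) {
      i <- which(ref$gene == gn)
      trimmed[i[which.max(re1[i])]] <- TRUE
      trimmed[i[which.min(re1[i])]] <- TRUE
    }
    f2 <- ols(fc_cells[!trimmed], fc_sevs[!trimmed])
    re <- fc_sevs - (f2["slope"] * fc_cells + f2["intercept"])
    gene_re <- tapply(re, ref$gene, stats::median)
    z <- (gene_re - mean(gene_re)) / stats::sd(gene_re)
    out_guides <- rbind(out_guides,
                        data.frame(barcode_id = ref$barcode_id, re = re,
                                   trimmed = trimmed))
    out_genes <- rbind(out_genes,
                       data.frame(gene = names(gene_re),
                                  sublibrary = sl,
                                  re_gene = as.numeric(gene_re),
                                  z_re = as.numeric(z)))
  }
  list(guides = out_guides, genes = out_genes)
}
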