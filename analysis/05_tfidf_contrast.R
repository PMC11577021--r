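#!/usr/bin/env Rscript
# Term-level contrast of the two marker screens. In the full workflow the
# inputs are the enriched-term lists (adjusted p < 0.25) that a gene-set
# enrichment run produces per screen; here we build illustrative term lists
# from each screen's strongest hits' annotations to exercise the TF-IDF
# weighting and the zero-protected log2 ratio. Writes results/tfidf.tsv.

suppressPackageStartupMessages(library(ciberscreen))
suppressPackageStartupMessages(library(readr))

# stand-in enriched-term lists, one document per marker screen
terms_a <- c("GOBP_LYSOSOME_ORGANIZATION", "GOBP_VACUOLAR_ACIDIFICATION",
             "GOBP_LYSOSOME_ORGANIZATION", "GOCC_MULTIVESICULAR_BODY",
             "KEGG_OXIDATIVE_PHOSPHORYLATION",
             "GOBP_MITOCHONDRIAL_ELECTRON_TRANSPORT",
             "HALLMARK_OXIDATIVE_PHOSPHORYLATION")
terms_b <- c("GOBP_CELL_CYCLE_PHASE_TRANSITION", "GOBP_MITOTIC_CELL_CYCLE",
             "REACTOME_CELL_CYCLE_CHECKPOINTS", "GOBP_MITOTIC_CELL_CYCLE",
             "GOCC_PLASMA_MEMBRANE", "GOBP_LYSOSOME_ORGANIZATION")

docs <- build_documents(list(markerA = terms_a, markerB = terms_b))
mat <- tfidf(docs)
ratio <- tfidf_log2_ratio(mat, "markerA", "markerB")

out <- tibble::tibble(
  word = rownames(mat$score),
  tf_a = mat$tf[, "markerA"], tf_b = mat$tf[, "markerB"],
  df = mat$df,
  score_a = mat$score[, "markerA"], score_b = mat$score[, "markerB"],
  log2_ratio_a_vs_b = ratio
)
out <- out[order(-abs(out$log2_ratio_a_vs_b)), ]
write_tsv(out, "results/tfidf.tsv")

message("words most specific to marker A (positive) / marker B (negative):")
top <- rbind(head(out, 3), tail(out, 3))
message(paste(sprintf("  %-22s %+0.2f", top$word, top$log2_ratio_a_vs_b),
              collapse = "\n"))
message("wrote results/tfidf.tsv")
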