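#!/usr/bin/env Rscript
# Simulate the study conditions: two marker screens (A and B) over the same
# gene universe that share half of their true release regulators, plus a
# null screen for calibration. Writes reference, manifest, counts and
# ground truth under results/sim/.

suppressPackageStartupMessages(library(ciberscreen))
suppressPackageStartupMessages(library(readr))

outdir <- "results/sim"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
seed <- 20260921

cfg <- simulation_config(n_genes = 1000L, guides_per_gene = 5L, depth = 500,
                         frac_viability_genes = 0.10,
                         effect_sd_viability = 1.5,
                         frac_release_genes = 0.10,
                         effect_sd_release = 1.5, seed = seed)

screen_a <- simulate_screen(cfg)

# screen B: same library, same viability landscape; keep half of A's release
# effects (common regulators of both sEV subpopulations) and redraw the rest
truth_b <- screen_a$truth
rel <- which(truth_b$rho != 0)
set.seed(seed + 1)
redraw <- sample(rel, length(rel) %/% 2)
truth_b$rho[redraw] <- 0
fresh <- sample(which(truth_b$rho == 0 & !(seq_len(nrow(truth_b)) %in% rel)),
                length(redraw))
truth_b$rho[fresh] <- rnorm(length(fresh), 0, cfg$effect_sd_release)
cfg_b <- simulation_config(n_genes = 1000L, guides_per_gene = 5L,
                           depth = 500, frac_viability_genes = 0.10,
                           effect_sd_viability = 1.5,
                           frac_release_genes = 0.10,
                           effect_sd_release = 1.5, seed = seed + 2)
screen_b <- simulate_screen(cfg_b, truth = truth_b)

cfg_null <- simulation_config(n_genes = 2000L, guides_per_gene = 5L,
                              depth = 500, frac_viability_genes = 0,
                              frac_release_genes = 0, seed = seed + 3)
screen_null <- simulate_screen(cfg_null)

save_screen <- function(screen, label) {
  write_barcode_reference(screen$reference,
                          file.path(outdir, paste0(label, "_reference.tsv")))
  write_tsv(screen$manifest, file.path(outdir, paste0(label, "_manifest.tsv")))
  write_count_table(screen$counts,
                    file.path(outdir, paste0(label, "_counts.tsv")))
  write_tsv(screen$truth, file.path(outdir, paste0(label, "_truth.tsv")))
  message(sprintf("%s: %d genes x %d guides, %s total reads", label,
                  screen$config$n_genes, screen$config$guides_per_gene,
                  format(sum(screen$counts), big.mark = ",")))
}
save_screen(screen_a, "markerA")
save_screen(screen_b, "markerB")
save_screen(screen_null, "null")

shared <- sum(screen_a$truth$rho != 0 & truth_b$rho != 0)
message(sprintf("marker screens share %d of %d/%d release regulators",
                shared, sum(screen_a$truth$rho != 0),
                sum(truth_b$rho != 0)))
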