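#!/usr/bin/env Rscript
# Read-level check of the counting stage: synthesize FASTQ reads for one
# sample of the marker-A screen (prefix + 17-nt spacer + GTTTAAGA scaffold
# key + tail), count them back by scaffold-key anchoring, and report
# library QC (coverage, skew ratio). Writes results/counting_stats.json.

suppressPackageStartupMessages(library(ciberscreen))

dir.create("results", showWarnings = FALSE)
seed <- 20260921

reference <- read_barcode_reference("results/sim/markerA_reference.tsv")
counts <- read_count_table("results/sim/markerA_counts.tsv", reference)

# regenerate the screen container for its spacers, then emit reads for the
# cellular Cas9- sample against the stored per-barcode ledger
screen <- local({
  cfg <- simulation_config(n_genes = 1000L, guides_per_gene = 5L,
                           depth = 500, frac_viability_genes = 0.10,
                           effect_sd_viability = 1.5,
                           frac_release_genes = 0.10,
                           effect_sd_release = 1.5, seed = seed)
  simulate_screen(cfg)
})
stopifnot(identical(screen$counts, counts))

fastq_path <- file.path(tempdir(), "markerA_cells_minus.fastq.gz")
fq <- simulate_fastq(screen, "cells_minus", path = fastq_path, seed = seed)
reads <- read_fastq(fastq_path)
res <- count_reads(reads, reference)

exact <- identical(res$counts, fq$ledger)
message(sprintf("counted %s reads; round-trip exact: %s",
                format(res$stats$total_reads, big.mark = ","), exact))
message(sprintf("coverage %.4f, skew ratio (P90/P10) %.2f",
                res$stats$coverage, res$stats$skew_ratio))
stopifnot(exact)

jsonlite::write_json(
  list(total_reads = res$stats$total_reads,
       assigned_reads = res$stats$assigned_reads,
       key_found_reads = res$stats$key_found_reads,
       coverage = res$stats$coverage,
       skew_ratio = res$stats$skew_ratio,
       roundtrip_exact = exact),
  "results/counting_stats.json", auto_unbox = TRUE, digits = NA)
message("wrote results/counting_stats.json")
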