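---
title: "Scoring sEV release regulators from gRNA-barcoded screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring sEV release regulators from gRNA-barcoded screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciberscreen)
```

## The measurement and its confound

In a gRNA-barcoded sEV release screen, knockout cells carrying a pooled
CRISPR library release small extracellular vesicles (sEVs) whose gRNA content
is loaded by a marker--dCas9 fusion (e.g. CD63--dCas9 or CD9--dCas9). Each
guide's abundance is sequenced in four samples: the cellular and sEV
fractions of Cas9+ (knockout) and Cas9- (control) cultures. The quantity of
interest is how a gene's knockout changes sEV release — but a knockout also
changes the guide's *cellular* abundance (viability, proliferation, barcode
transcription), and that change propagates into the sEV fraction. The
scoring model in this package separates the two.

Write, per guide,

- `nRC(b, s)`: the normalized read count — raw count divided by the sample
  total within the guide's sublibrary, times the number of gRNAs in that
  sublibrary, so the per-sample mean is 1;
- `FC_cells = log2(nRC[cells, Cas9+] / nRC[cells, Cas9-])` and
  `FC_sEVs` analogously for the sEV fraction.

Empirically `FC_sEVs` depends almost linearly on `FC_cells`; knockouts that
only change cellular abundance move *along* that line. The **release effect
(RE)** of a guide is its residual from the line — the part of the sEV change
not explained by the cellular change. Gene-level RE is the median of its
guides' REs, and genes are compared on the **z-RE**: gene REs z-normalized
within each sublibrary (subpool). Genes with `z-RE > 1.65` are upper hits
(knockout increases release of the tagged sEV subpopulation), `z-RE < -1.65`
lower hits; under a normal null these are the 95th/5th percentiles.

## The procedure, step by step

`score_screen()` composes the stages; each is exported on its own.

1. **Normalization** (`normalize_counts()`): nRC per sublibrary, as above.
   nRC is computed once on the full library and *not* recomputed after
   filtering — re-normalizing on the filtered subset would silently shift
   every fold change.
2. **Filters** (`apply_filters()`): a barcode is excluded when its nRC is
   *strictly below* 0.05 in at least one of the four samples; afterwards any
   gene with fewer than 3 retained barcodes is excluded. The positivity this
   guarantees is why no pseudocounts appear anywhere downstream.
3. **Fold changes** (`compute_fold_changes()`): the two log2 ratios per
   retained barcode.
4. **Two-pass trimmed regression** (`compute_re()`): an OLS line of
   `FC_sEVs` on `FC_cells` over all retained guides gives tentative
   residuals; within every gene the single highest- and single
   lowest-residual guides are removed *from the fit* (not from the results);
   the line is refit on the untrimmed guides, and the final RE of **every**
   retained guide — trimmed ones included — is its residual from the second
   line. The trim makes the line robust to genes with genuine release
   effects, which would otherwise drag the fit toward themselves.
5. **Gene scores** (`gene_scores()`, `z_normalize()`): median RE per gene,
   then z-normalization within each sublibrary. Scoring per subpool keeps
   independently transduced, independently sequenced pools on their own
   scale.
6. **Hits and comparison** (`call_hits()`, `compare_screens()`): strict
   thresholding at |z-RE| > 1.65; two screens are compared on their gene
   intersection via the per-gene difference `d = z_A - z_B`, a
   `mean(d) ± 2·SD(d)` band whose outliers are the marker-specific genes,
   Pearson correlation, and upper/lower hit-set overlaps.

### Interpretation choices that were genuinely open

Several details are not forced by the procedure's verbal description; the
package fixes them as follows and, where noted, offers the alternative
behind a flag.

- **Trimming is one pass.** The trim-and-refit is done exactly once, not
  iterated to convergence: the procedure reads as a single robustification
  step, and iterating would re-trim against an already-robust line.
- **Exactly one max and one min guide per gene** are trimmed; ties break to
  the lowest barcode index so results are deterministic. A gene whose single
  guide is simultaneously max and min is trimmed once.
- **Trimmed guides count toward the gene median** (default
  `include_trimmed = TRUE`). Trimming removes a guide from the *scatter
  plot*, i.e. the regression fit; the gene-level RE is defined over the
  barcodes targeting the gene, without exclusion. This is the single most
  consequential interpretation in the pipeline — excluding the extremes from
  a 3-guide gene's median would reduce it to one guide — and the alternative
  is available via `include_trimmed = FALSE`.
- **The regression is fit within each sublibrary**, matching the per-subpool
  z-normalization; subpools are separately transduced and sequenced, so
  their FC scatters need not share a line.
- **Sample SD** (n − 1) is the z-normalization default;
  `sd_type = "population"` switches to n.
- **Even-count medians** are the mean of the two middle values (R's
  default).
- **The reported correlation** (`fits$…$pass1$r`) is the Pearson r of the
  full pass-1 scatter, the screen-quality figure of merit.

### Numerical and degenerate-input behavior

- Zero-total samples, all-identical `FC_cells`, fewer than two untrimmed
  guides, fewer than two genes in a subpool, and a zero SD of gene REs are
  all hard errors with named culprits — never silent NaNs. The zero-SD error
  is reachable in principle when `FC_sEVs` is exactly proportional to
  `FC_cells` (all gene REs tie); in floating point such screens instead
  yield REs at rounding-error scale.
- z-REs within each sublibrary have mean 0 and SD 1 to 1e-9; pass-2
  residuals sum to 0 over the untrimmed set to the same tolerance.
- The pipeline is exactly invariant to per-sample depth scaling and to
  barcode order.

## Barcode counting from reads

Reads are amplified so that the 17-nt spacer sits immediately 5' of a
constant 8-nt scaffold sequence, the KEY (`GTTTAAGA`). `count_reads()`
assigns a read to a barcode iff the key occurs with at least 17 nt upstream
and those 17 nt exactly equal a library spacer. Matching is exact — no
mismatches, no indels — and the first qualifying key occurrence wins. A key
occurrence with insufficient upstream context is skipped and the scan
continues downstream; this permissive reading is a deliberate choice (the
strict alternative would discard the read outright) and is the one the
synthetic generator also assumes. Reads are upper-cased; `N` never matches;
reads are assumed sense-oriented by the nested amplification design, with
reverse-complement rescue available via `counting_config(revcomp = TRUE)`.

QC statistics follow pooled-library practice: coverage is the fraction of
reference barcodes seen at least once; the skew ratio is the P90/P10 of
per-barcode counts (the term is standard but has no canonical formula; the
90/10 percentile ratio is the common convention, reported as `Inf` when the
10th percentile is 0).

## The TF-IDF term contrast

To contrast what two screens' enrichment results are *about*, each screen's
enriched terms (e.g. `GOBP_LYSOSOME_ORGANIZATION`, adjusted p < 0.25 in a
gene-set enrichment run — producing those lists is outside this package)
become one document: underscores to spaces, ontology prefix dropped, words
lower-cased and pooled. Scores are
`TF(t, d) × (log10(D / DF(t)) + 1)` with `D` the number of documents (the
constant reads as 2 in a pairwise contrast, and generalizes to D here), and
the per-word contrast is `log2(score_A / score_B)` after replacing zero
scores with half the document's minimal positive score. Lower-casing is a
convention choice; no stemming or stop-word removal is applied.

## What the synthetic generator emulates — and what it does not

`simulate_screen()` generates screens from the same structural assumptions
the scoring model makes, with ground truth recorded:

| parameter | default | meaning |
|---|---|---|
| `depth` | 500 | expected reads per guide per sample; matches the coverage the assay maintains (500 cells/gRNA) |
| `slope` | 1 | slope of the latent FC_sEVs-on-FC_cells line |
| `sd_baseline` | 0.5 | log-normal sigma of guide baseline abundance (gives P90/P10 skew ≈ 3.6, a well-made library) |
| `sd_guide_noise` | 0.3 | SD (log2) of per-guide noise on each fold change and of the shared sEV-loading deviation |
| `frac_viability_genes`, `effect_sd_viability` | 0.1, 1 | genes whose knockout shifts cellular abundance (beta) |
| `frac_release_genes`, `effect_sd_release` | 0.05, 1 | genes with a true additive release effect (rho) |

Per-sample counts are a single multinomial draw at `depth × n_guides` per
sublibrary, modeling competitive sequencing of a pool. The defaults are
order-of-magnitude choices where the assay description gives none (no
empirical dispersion estimates exist for sEV-fraction counts); they are
fixed once, not tuned. `simulate_fastq()` additionally emits reads
(key-free random prefix + spacer + KEY + key-free tail) whose per-barcode
numbers equal a ledger exactly, with spacers rejection-sampled to be unique
and key-free — so counting round-trips are exact by construction and any
discrepancy is a counting bug, not simulation noise.

Because generator and scorer share the linear-plus-residual structure,
passing tests show that the pipeline recovers the model's parameters and
cancels viability confounds *under that model*. They do not show robustness
to features real screens have and the generator omits: sequencing errors and
chimeric reads, guide-efficacy differences, overdispersion beyond
multinomial, clonal drift between the four cultures, or nonlinearity of the
FC relationship. A negative-binomial per-guide sampling mode would probe the
overdispersion axis and is a natural extension.

## Problem sizes used in the shipped analyses

The numbered scripts under `analysis/` use 1,000 genes × 5 guides (2,000 ×
5 for the null screen) at depth 500 — large enough that the null tail
fractions and recovery correlations are stable at the percent level, while
the whole workflow runs in well under a minute. The test suite uses the
same null size and 50 replicates of 400-gene screens for the
confounder-cancellation check; the read-level round-trip uses 10^5+ reads.

## Known limitations

- Replicate screens are scored independently; there is no replicate-aware
  variance model and no p-value/FDR machinery (hits are z-threshold calls
  by design).
- Gene symbols containing underscores cannot be represented in the barcode
  id convention.
- The trailing-token sublibrary heuristic (all-uppercase token of length
  at least 2) can misread an id whose last info token looks like a pool
  label; an explicit `sublibrary` column in the reference overrides it.
- Exact matching forfeits reads with any sequencing error in the spacer or
  key; at typical error rates this costs sensitivity, not specificity.
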