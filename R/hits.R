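#' Call upper/lower hits from z-RE scores
#'
#' Genes with `z_re` strictly greater than `threshold` are upper hits and
#' strictly below `-threshold` lower hits; genes exactly at the threshold
#' are not significant. Under a normal null, 1.65 corresponds to the 95th /
#' 5th percentiles.
#'
#' @param genes Gene-score tibble with `gene` and `z_re` (e.g.
#'   `score_screen()$genes`).
#' @param threshold Hit threshold on |z-RE| (default 1.65).
#' @return `genes` with a `hit_class` factor (`lower`, `NS`, `upper`).
#' @export
call_hits <- function(genes, threshold = 1.65) {
  stopifnot(threshold > 0)
  cls <- ifelse(genes$z_re > threshold, "upper",
                ifelse(genes$z_re < -threshold, "lower", "NS"))
  genes$hit_class <- factor(cls, levels = c("lower", "NS", "upper"))
  genes
}

#' Compare two scored screens gene by gene
#'
#' Restricted to the gene intersection of the two screens. Computes the
#' per-gene z-RE difference `d = z_A - z_B`, the difference band
#' `mean(d) +/- band_k * sd(d)` whose outliers are marker-specific genes,
#' the Pearson correlation of the two z-RE profiles, and the overlap of
#' upper/lower hit sets at `threshold`.
#'
#' @param genes_a,genes_b Gene-score tibbles (`gene`, `z_re`).
#' @param threshold Hit threshold (default 1.65).
#' @param band_k Band half-width in SD units (default 2).
#' @return A list of class `screen_comparison`: `genes` (gene, z_re_a,
#'   z_re_b, d, in_band), `band_center`, `band_halfwidth`, `specific_to_a`,
#'   `specific_to_b`, `pearson_r`, `overlap_upper`, `overlap_lower`,
#'   `n_common`, `dropped_a`, `dropped_b`.
#' @export
compare_screens <- function(genes_a, genes_b, threshold = 1.65, band_k = 2) {
  common <- intersect(genes_a$gene, genes_b$gene)
  if (length(common) == 0L) {
    stop("the two screens share no genes", call. = FALSE)
  }
  za <- genes_a$z_re[match(common, genes_a$gene)]
  zb <- genes_b$z_re[match(common, genes_b$gene)]
  d <- za - zb
  center <- mean(d)
  halfwidth <- band_k * stats::sd(d)
  in_band <- abs(d - center) <= halfwidth

  hits_a <- call_hits(genes_a[genes_a$gene %in% common, ], threshold)
  hits_b <- call_hits(genes_b[genes_b$gene %in% common, ], threshold)
  upper_a <- hits_a$gene[hits_a$hit_class == "upper"]
  upper_b <- hits_b$gene[hits_b$hit_class == "upper"]
  lower_a <- hits_a$gene[hits_a$hit_class == "lower"]
  lower_b <- hits_b$gene[hits_b$hit_class == "lower"]

  structure(list(
    genes = tibble::tibble(gene = common, z_re_a = za, z_re_b = zb, d = d,
                           in_band = in_band),
    band_center = center,
    band_halfwidth = halfwidth,
    specific_to_a = common[d - center > halfwidth],
    specific_to_b = common[d - center < -halfwidth],
    pearson_r = stats::cor(za, zb),
    overlap_upper = length(intersect(upper_a, upper_b)),
    overlap_lower = length(intersect(lower_a, lower_b)),
    n_common = length(common),
    dropped_a = setdiff(genes_a$gene, common),
    dropped_b = setdiff(genes_b$gene, common)
  ), class = "screen_comparison")
}

#' @export
print.screen_comparison <- function(x, ...) {
  cat(sprintf(
    "Screen comparison over %d common genes\n  Pearson R = %.3f\n  band: %.3f +/- %.3f (%d specific to A, %d to B)\n  hit overlap: %d upper, %d lower\n",
    x$n_common, x$pearson_r, x$band_center, x$band_halfwidth,
    length(x$specific_to_a), length(x$specific_to_b),
    x$overlap_upper, x$overlap_lower))
  invisible(x)
}
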