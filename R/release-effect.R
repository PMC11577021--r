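#' Per-guide fold changes between Cas9+ and Cas9- samples
#'
#' `fc_cells = log2(nRC[cells, Cas9+] / nRC[cells, Cas9-])` and likewise for
#' the sEV fraction. The abundance filter guarantees positive nRC for every
#' retained barcode, so no pseudocounts are used.
#'
#' @param nrc nRC matrix restricted to retained barcodes.
#' @param samples Named character vector (or list) with entries
#'   `cells_plus`, `cells_minus`, `sevs_plus`, `sevs_minus` giving the
#'   column names of the four samples.
#' @return A tibble with `barcode_id`, `fc_cells`, `fc_sevs`.
#' @export
compute_fold_changes <- function(nrc, samples) {
  need <- c("cells_plus", "cells_minus", "sevs_plus", "sevs_minus")
  samples <- unlist(samples)
  missing <- setdiff(need, names(samples))
  if (length(missing) > 0L) {
    stop("samples must name: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sub <- nrc[, samples[need], drop = FALSE]
  if (any(sub <= 0)) {
    stop("nonpositive nRC encountered; apply the abundance filter first",
         call. = FALSE)
  }
  tibble::tibble(
    barcode_id = rownames(nrc),
    fc_cells = unname(log2(sub[, 1L] / sub[, 2L])),
    fc_sevs = unname(log2(sub[, 3L] / sub[, 4L]))
  )
}

#' Ordinary least-squares line with Pearson correlation
#'
#' @param x,y Numeric vectors (here `fc_cells` and `fc_sevs`).
#' @return A list of class `regression_fit` with `slope`, `intercept`, `r`
#'   and `n_points`.
#' @export
fit_line <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(unique(x)) < 2L) {
    stop("need at least 2 distinct x values for a regression line",
         call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  structure(list(slope = unname(fit$coefficients[2L]),
                 intercept = unname(fit$coefficients[1L]),
                 r = stats::cor(x, y),
                 n_points = length(x)),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("OLS fit: y = %.4f x + %.4f  (R = %.3f, n = %d)\n",
              x$slope, x$intercept, x$r, x$n_points))
  invisible(x)
}

#' Release effects from a two-pass trimmed regression
#'
#' Pass 1 fits FC_sEVs on FC_cells over all retained guides and computes
#' tentative residuals. Within every gene, the single guide with the highest
#' and the single guide with the lowest tentative residual are removed from
#' the scatter (ties broken by lowest barcode index; a gene's only guide is
#' trimmed once, not twice). Pass 2 refits on the untrimmed guides, and the
#' final release effect (RE) of every retained guide -- trimmed guides
#' included -- is its residual from the pass-2 line.
#'
#' @param guides Tibble with `barcode_id`, `gene`, `fc_cells`, `fc_sevs`.
#' @return A list with `guides` (input plus `re` and `trimmed`), `fit1` and
#'   `fit2` ([fit_line()] objects for the two passes).
#' @export
compute_re <- function(guides) {
  stopifnot(all(c("barcode_id", "gene", "fc_cells", "fc_sevs") %in%
                  names(guides)))
  fit1 <- fit_line(guides$fc_cells, guides$fc_sevs)
  re1 <- guides$fc_sevs - (fit1$slope * guides$fc_cells + fit1$intercept)

  trimmed <- logical(nrow(guides))
  for (idx in split(seq_len(nrow(guides)), guides$gene)) {
    hi <- idx[which.max(re1[idx])]
    lo <- idx[which.min(re1[idx])]
    trimmed[c(hi, lo)] <- TRUE
  }
  keep <- !trimmed
  if (sum(keep) < 2L) {
    stop("fewer than 2 untrimmed guides; cannot refit", call. = FALSE)
  }
  fit2 <- fit_line(guides$fc_cells[keep], guides$fc_sevs[keep])
  re <- guides$fc_sevs - (fit2$slope * guides$fc_cells + fit2$intercept)

  guides$re <- re
  guides$trimmed <- trimmed
  list(guides = guides, fit1 = fit1, fit2 = fit2)
}

#' Gene-level release effect
#'
#' The gene-level RE is the median of the REs of the barcodes targeting the
#' gene. Guides trimmed from the regression scatter still carry an RE and are
#' included in the median by default (trimming removes them only from the
#' line fit).
#'
#' @param guides Tibble with `gene`, `re`, `trimmed` (and optionally
#'   `sublibrary`).
#' @param include_trimmed Include trimmed guides in the median (default
#'   `TRUE`).
#' @return A tibble with `gene`, `sublibrary` (if present), `re_gene`,
#'   `n_guides`.
#' @export
gene_scores <- function(guides, include_trimmed = TRUE) {
  used <- if (include_trimmed) guides else
    guides[!guides$trimmed, , drop = FALSE]
  keys <- intersect(c("gene", "sublibrary"), names(used))
  dplyr::summarise(
    dplyr::group_by(used, dplyr::across(dplyr::all_of(keys))),
    re_gene = stats::median(.data$re),
    n_guides = dplyr::n(),
    .groups = "drop"
  )
}

#' z-normalize gene-level release effects within sublibraries
#'
#' `z_re = (re_gene - mean) / sd`, computed within each sublibrary (subpool)
#' and concatenated. The sample standard deviation (n - 1 denominator) is
#' the default.
#'
#' @param genes Tibble with `gene`, `re_gene` and (optionally) `sublibrary`.
#' @param sd_type `"sample"` (n - 1) or `"population"` (n).
#' @return `genes` with a `z_re` column appended.
#' @export
z_normalize <- function(genes, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (!"sublibrary" %in% names(genes)) genes$sublibrary <- "all"
  zfun <- function(x) {
    if (length(x) < 2L) {
      stop("need at least 2 genes per sublibrary to z-normalize",
           call. = FALSE)
    }
    s <- stats::sd(x)
    if (sd_type == "population") s <- s * sqrt((length(x) - 1) / length(x))
    if (!is.finite(s) || s == 0) {
      stop("zero standard deviation of gene-level REs in a sublibrary",
           call. = FALSE)
    }
    (x - mean(x)) / s
  }
  dplyr::mutate(dplyr::group_by(genes, .data$sublibrary),
                z_re = zfun(.data$re_gene)) |>
    dplyr::ungroup()
}

# Resolve the four (fraction x cas9) sample columns for one sublibrary from
# a manifest; samples labeled sublibrary == "all" serve every sublibrary.
screen_samples <- function(manifest, sublib) {
  man <- manifest[manifest$sublibrary %in% c(sublib, "all"), , drop = FALSE]
  pick <- function(fr, cs) {
    hit <- man$sample_id[man$fraction == fr & man$cas9 == cs]
    if (length(hit) != 1L) {
      stop("sublibrary ", sublib, ": expected exactly one ", fr, "/Cas9-",
           cs, " sample, found ", length(hit), call. = FALSE)
    }
    hit
  }
  c(cells_plus = pick("cells", "plus"),
    cells_minus = pick("cells", "minus"),
    sevs_plus = pick("sevs", "plus"),
    sevs_minus = pick("sevs", "minus"))
}

#' Score a screen from raw counts to z-RE
#'
#' Full deterministic composition: nRC normalization (per sublibrary), the
#' abundance filters, per-guide fold changes, the two-pass trimmed regression
#' release effects (fit within each sublibrary), gene-level medians, and
#' per-sublibrary z-normalization.
#'
#' @param counts Integer matrix (barcode x sample).
#' @param manifest Manifest tibble for one screen (four samples per
#'   sublibrary, or four samples labeled `"all"`).
#' @param reference Reference tibble.
#' @param min_nrc,min_guides_per_gene Filter thresholds (see
#'   [apply_filters()]).
#' @param sd_type Standard-deviation convention for [z_normalize()].
#' @param library_size,per_sublibrary Passed to [normalize_counts()].
#' @param include_trimmed Passed to [gene_scores()].
#' @return A list of class `scored_screen`: `guides` (barcode_id, gene,
#'   sublibrary, fc_cells, fc_sevs, re, trimmed), `genes` (gene, sublibrary,
#'   n_guides, re_gene, z_re), `fits` (per sublibrary, pass-1 and pass-2
#'   [fit_line()] objects) and `exclusions`.
#' @export
score_screen <- function(counts, manifest, reference,
                         min_nrc = 0.05, min_guides_per_gene = 3L,
                         sd_type = "sample", library_size = NULL,
                         per_sublibrary = TRUE, include_trimmed = TRUE) {
  manifest <- normalize_manifest(manifest)
  nrc <- normalize_counts(counts, reference, library_size = library_size,
                          per_sublibrary = per_sublibrary)

  guides_all <- list()
  fits <- list()
  exclusions <- list()
  for (sl in unique(reference$sublibrary)) {
    ref_sl <- reference[reference$sublibrary == sl, , drop = FALSE]
    samples <- screen_samples(manifest, sl)
    nrc_sl <- nrc[ref_sl$barcode_id, samples, drop = FALSE]
    flt <- apply_filters(nrc_sl, ref_sl, min_nrc = min_nrc,
                         min_guides_per_gene = min_guides_per_gene)
    exclusions[[sl]] <- flt$exclusions
    ref_keep <- ref_sl[ref_sl$barcode_id %in% flt$barcodes, , drop = FALSE]
    if (nrow(ref_keep) == 0L) {
      stop("no barcodes retained in sublibrary ", sl, call. = FALSE)
    }
    fc <- compute_fold_changes(nrc[ref_keep$barcode_id, , drop = FALSE],
                               samples)
    fc$gene <- ref_keep$gene
    fc$sublibrary <- sl
    res <- compute_re(fc)
    fits[[sl]] <- list(pass1 = res$fit1, pass2 = res$fit2)
    guides_all[[sl]] <- res$guides
  }
  guides <- dplyr::bind_rows(guides_all)
  genes <- z_normalize(gene_scores(guides, include_trimmed = include_trimmed),
                       sd_type = sd_type)
  structure(list(
    guides = guides[, c("barcode_id", "gene", "sublibrary", "fc_cells",
                        "fc_sevs", "re", "trimmed")],
    genes = genes[, c("gene", "sublibrary", "n_guides", "re_gene", "z_re")],
    fits = fits,
    exclusions = dplyr::bind_rows(exclusions, .id = "sublibrary")
  ), class = "scored_screen")
}

#' @export
print.scored_screen <- function(x, ...) {
  cat("Scored screen:", nrow(x$genes), "genes,", nrow(x$guides),
      "guides across", length(x$fits), "sublibrary(ies)\n")
  for (sl in names(x$fits)) {
    f <- x$fits[[sl]]$pass1
    cat(sprintf("  %s: pass-1 R = %.3f (n = %d)\n", sl, f$r, f$n_points))
  }
  invisible(x)
}
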