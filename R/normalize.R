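#' Normalize raw counts to normalized read counts (nRC)
#'
#' Within each sublibrary, each sample's counts are divided by the sample's
#' total over that sublibrary and multiplied by the number of gRNAs in the
#' sublibrary, so that the per-sample mean nRC over the sublibrary is 1.
#' nRC is therefore invariant to per-sample sequencing depth.
#'
#' @param counts Integer matrix (barcode x sample), rows covering the full
#'   reference.
#' @param reference Reference tibble; provides each barcode's sublibrary.
#' @param library_size Optional named vector of scaling constants per
#'   sublibrary (number of gRNAs); defaults to the number of reference
#'   barcodes in each sublibrary.
#' @param per_sublibrary If `FALSE`, the whole library is treated as a single
#'   pool (single-pool data).
#' @return Numeric matrix of nRC values, same dimnames as `counts`.
#' @export
normalize_counts <- function(counts, reference, library_size = NULL,
                             per_sublibrary = TRUE) {
  stopifnot(is.matrix(counts))
  missing <- setdiff(reference$barcode_id, rownames(counts))
  if (length(missing) > 0L) {
    stop("counts lack reference barcode(s), e.g. ", missing[1L],
         call. = FALSE)
  }
  counts <- counts[reference$barcode_id, , drop = FALSE]
  sublib <- if (per_sublibrary) reference$sublibrary else
    rep("all", nrow(reference))
  nrc <- matrix(NA_real_, nrow(counts), ncol(counts),
                dimnames = dimnames(counts))
  for (sl in unique(sublib)) {
    rows <- sublib == sl
    n <- if (!is.null(library_size)) {
      if (!sl %in% names(library_size) && length(library_size) == 1L &&
          is.null(names(library_size))) {
        as.numeric(library_size)
      } else {
        as.numeric(library_size[[sl]])
      }
    } else {
      sum(rows)
    }
    totals <- colSums(counts[rows, , drop = FALSE])
    zero <- totals == 0
    if (any(zero)) {
      stop("sample(s) with zero total count in sublibrary ", sl, ": ",
           paste(colnames(counts)[zero], collapse = ", "), call. = FALSE)
    }
    nrc[rows, ] <- sweep(counts[rows, , drop = FALSE], 2L, totals, "/") * n
  }
  nrc
}

#' Barcode- and gene-level abundance filters
#'
#' A barcode is excluded when its nRC is below `min_nrc` in at least one of
#' the screen's samples (strict comparison); after that exclusion, any gene
#' left with fewer than `min_guides_per_gene` barcodes is excluded. nRC is
#' not recomputed after filtering.
#'
#' @param nrc Numeric nRC matrix (barcode x sample), typically the four
#'   samples of one screen.
#' @param reference Reference tibble mapping barcodes to genes.
#' @param min_nrc Exclusion threshold on nRC (default 0.05).
#' @param min_guides_per_gene Minimum retained barcodes per gene (default 3).
#' @return A list with `barcodes` (retained barcode ids), `genes` (retained
#'   gene symbols) and `exclusions` (tibble of `id`, `level`, `reason`).
#' @export
apply_filters <- function(nrc, reference, min_nrc = 0.05,
                          min_guides_per_gene = 3L) {
  stopifnot(min_nrc >= 0, min_guides_per_gene >= 1L)
  nrc <- nrc[reference$barcode_id, , drop = FALSE]
  low <- apply(nrc < min_nrc, 1L, any)
  excl_bc <- tibble::tibble(id = reference$barcode_id[low],
                            level = "barcode", reason = "low_nrc")
  kept <- reference[!low, , drop = FALSE]
  n_guides <- table(kept$gene)
  few <- names(n_guides)[n_guides < min_guides_per_gene]
  # genes whose every barcode was removed are also gone, with the same cause
  all_gone <- setdiff(unique(reference$gene), unique(kept$gene))
  excl_gene <- tibble::tibble(id = c(few, all_gone), level = "gene",
                              reason = "few_guides")
  kept <- kept[!kept$gene %in% few, , drop = FALSE]
  list(barcodes = kept$barcode_id,
       genes = unique(kept$gene),
       exclusions = dplyr::bind_rows(excl_bc, excl_gene))
}
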