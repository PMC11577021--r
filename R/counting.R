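#' Configuration for scaffold-key barcode counting
#'
#' Reads are assigned by locating the constant scaffold sequence (the KEY,
#' `GTTTAAGA` by default) that sits immediately 3' of the spacer in the
#' amplicon, and matching the `spacer_length` nucleotides upstream of it
#' exactly against the library spacers.
#'
#' @param key Scaffold anchor sequence (ACGT only).
#' @param spacer_length Spacer length in nucleotides.
#' @param search_window Optional maximum read prefix length scanned for the
#'   key; `NULL` scans the whole read.
#' @param revcomp If `TRUE`, reads failing assignment are retried on their
#'   reverse complement. Off by default: the nested amplification fixes read
#'   orientation.
#' @return A list of class `counting_config`.
#' @export
counting_config <- function(key = "GTTTAAGA", spacer_length = 17L,
                            search_window = NULL, revcomp = FALSE) {
  key <- toupper(key)
  if (nchar(key) == 0L || grepl("[^ACGT]", key)) {
    stop("key must be a non-empty ACGT string", call. = FALSE)
  }
  if (spacer_length < 1L) stop("spacer_length must be >= 1", call. = FALSE)
  structure(list(key = key, spacer_length = as.integer(spacer_length),
                 search_window = search_window, revcomp = isTRUE(revcomp)),
            class = "counting_config")
}

reverse_complement <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s) {
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
         }, character(1), USE.NAMES = FALSE))
}

# First key occurrence with a full spacer's worth of upstream sequence.
# Occurrences starting at position <= spacer_length are skipped and the scan
# continues downstream. Returns 1-based key start positions (NA if none).
key_positions <- function(seqs, config) {
  scan <- seqs
  if (!is.null(config$search_window)) {
    scan <- substr(scan, 1L, config$search_window + nchar(config$key))
  }
  pos <- as.integer(regexpr(config$key, scan, fixed = TRUE))
  pos[pos < 0L] <- NA_integer_
  # reads whose first occurrence lacks upstream context: scan all occurrences
  early <- which(!is.na(pos) & pos <= config$spacer_length)
  for (i in early) {
    all_pos <- gregexpr(config$key, scan[i], fixed = TRUE)[[1]]
    ok <- all_pos[all_pos > config$spacer_length]
    pos[i] <- if (length(ok) > 0L) ok[1L] else NA_integer_
  }
  pos
}

#' Assign reads to library barcodes
#'
#' Implements the exact-match counting rule: a read is assigned to a barcode
#' iff the scaffold key occurs with at least `spacer_length` nucleotides
#' upstream and those nucleotides equal one of the library spacers. No
#' mismatches or indels are tolerated; the first qualifying key occurrence
#' wins; unassignable reads are a counted outcome, not an error.
#'
#' @param sequences Character vector of read sequences.
#' @param spacer_index Named character vector mapping spacer -> barcode_id.
#' @param config A [counting_config()].
#' @return Character vector of barcode ids (`NA` = unassigned) with a logical
#'   attribute `key_found` marking reads containing the key anywhere.
#' @export
assign_reads <- function(sequences, spacer_index,
                         config = counting_config()) {
  seqs <- toupper(sequences)
  key_found <- grepl(config$key, seqs, fixed = TRUE)
  pos <- key_positions(seqs, config)
  spacer <- ifelse(is.na(pos), NA_character_,
                   substr(seqs, pos - config$spacer_length, pos - 1L))
  barcode <- unname(spacer_index[spacer])
  if (config$revcomp) {
    miss <- which(is.na(barcode))
    if (length(miss) > 0L) {
      rc <- reverse_complement(seqs[miss])
      pos_rc <- key_positions(rc, config)
      sp_rc <- ifelse(is.na(pos_rc), NA_character_,
                      substr(rc, pos_rc - config$spacer_length, pos_rc - 1L))
      barcode[miss] <- unname(spacer_index[sp_rc])
      key_found[miss] <- key_found[miss] | grepl(config$key, rc, fixed = TRUE)
    }
  }
  structure(barcode, key_found = key_found)
}

#' Count reads per library barcode
#'
#' @param reads Character vector of read sequences, or a tibble from
#'   [read_fastq()].
#' @param reference Reference tibble from [read_barcode_reference()].
#' @param config A [counting_config()].
#' @return A list with `counts` (named integer vector over all reference
#'   barcodes, zeros included) and `stats` (a [counting_stats()] list).
#' @export
count_reads <- function(reads, reference, config = counting_config()) {
  if (is.data.frame(reads)) reads <- reads$sequence
  if (nrow(reference) == 0L) stop("empty barcode reference", call. = FALSE)
  if (anyDuplicated(reference$spacer)) {
    stop("reference spacers must be unique", call. = FALSE)
  }
  spacer_index <- stats::setNames(reference$barcode_id, reference$spacer)
  assigned <- assign_reads(reads, spacer_index, config)
  counts <- table(factor(assigned, levels = reference$barcode_id))
  counts <- stats::setNames(as.integer(counts), reference$barcode_id)
  stats <- counting_stats(
    total_reads = length(reads),
    key_found_reads = sum(attr(assigned, "key_found")),
    assigned_reads = sum(!is.na(assigned)),
    counts = counts
  )
  list(counts = counts, stats = stats)
}

#' Counting QC statistics
#'
#' @param total_reads,key_found_reads,assigned_reads Read tallies from
#'   counting (`assigned <= key_found <= total`).
#' @param counts Named per-barcode count vector over the full reference.
#' @return A list of class `counting_stats` with the tallies plus `coverage`
#'   and `skew_ratio` (see [coverage_and_skew()]).
#' @export
counting_stats <- function(total_reads, key_found_reads, assigned_reads,
                           counts) {
  stopifnot(assigned_reads <= key_found_reads,
            key_found_reads <= total_reads)
  qc <- coverage_and_skew(counts)
  structure(list(total_reads = total_reads,
                 key_found_reads = key_found_reads,
                 assigned_reads = assigned_reads,
                 coverage = qc$coverage,
                 skew_ratio = qc$skew_ratio),
            class = "counting_stats")
}

#' Library coverage and skew ratio
#'
#' Coverage is the fraction of reference barcodes observed at least once.
#' The skew ratio is the standard pooled-library dispersion QC: the ratio of
#' the 90th to the 10th percentile of per-barcode counts; when the 10th
#' percentile is zero it is reported as `Inf`.
#'
#' @param counts Per-barcode count vector over the full reference.
#' @return List with `coverage` and `skew_ratio`.
#' @export
coverage_and_skew <- function(counts) {
  counts <- as.numeric(counts)
  q <- stats::quantile(counts, c(0.1, 0.9), names = FALSE)
  list(coverage = mean(counts > 0),
       skew_ratio = if (q[1] > 0) q[2] / q[1] else Inf)
}
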