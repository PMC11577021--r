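#' Parse barcode ids into gene, spacer and sublibrary
#'
#' Barcode ids follow the convention
#' `{target gene}_{spacer sequence}_{additional information}`: splitting on
#' underscore, the first token is the gene symbol and the second the spacer.
#' Gene symbols containing underscores are therefore unsupported. When the
#' trailing token is purely alphabetic (e.g. a sublibrary label such as
#' `DTKP`) it is taken as the sublibrary; otherwise `default_sublibrary`
#' is used.
#'
#' @param ids Character vector of barcode ids.
#' @param spacer_length Required spacer length in nucleotides.
#' @param default_sublibrary Label used when no trailing sublibrary token is
#'   present.
#' @return A tibble with columns `barcode_id`, `gene`, `spacer`, `sublibrary`.
#' @export
parse_barcode_ids <- function(ids, spacer_length = 17L,
                              default_sublibrary = "default") {
  stopifnot(is.character(ids))
  tokens <- strsplit(ids, "_", fixed = TRUE)
  n_tok <- lengths(tokens)
  bad <- which(n_tok < 2L)
  if (length(bad) > 0L) {
    stop("malformed barcode id (fewer than 2 underscore-separated tokens) ",
         "at row(s) ", paste(bad, collapse = ", "), ": ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  gene <- vapply(tokens, `[[`, character(1), 1L)
  spacer <- toupper(vapply(tokens, `[[`, character(1), 2L))

  bad_len <- which(nchar(spacer) != spacer_length)
  if (length(bad_len) > 0L) {
    stop("spacer of wrong length (expected ", spacer_length, " nt) at row(s) ",
         paste(bad_len, collapse = ", "), call. = FALSE)
  }
  bad_nt <- which(grepl("[^ACGT]", spacer))
  if (length(bad_nt) > 0L) {
    stop("spacer with non-ACGT characters at row(s) ",
         paste(bad_nt, collapse = ", "), call. = FALSE)
  }

  # a trailing pool label (e.g. DTKP, PROT) is all-uppercase, >= 2 chars;
  # other trailing info tokens (weights like "2832.7", indices) are not
  last_tok <- vapply(tokens, function(t) t[[length(t)]], character(1))
  sublibrary <- ifelse(n_tok >= 3L & grepl("^[A-Z][A-Z0-9]+$", last_tok),
                       last_tok, default_sublibrary)

  dup_id <- which(duplicated(ids))
  if (length(dup_id) > 0L) {
    stop("duplicate barcode id(s): ",
         paste(unique(ids[dup_id]), collapse = ", "), call. = FALSE)
  }
  dup_sp <- which(duplicated(spacer))
  if (length(dup_sp) > 0L) {
    first <- ids[match(spacer[dup_sp], spacer)]
    stop("duplicate spacer shared by ids: ",
         paste(paste(first, ids[dup_sp], sep = " / "), collapse = "; "),
         call. = FALSE)
  }

  tibble::tibble(barcode_id = ids, gene = gene, spacer = spacer,
                 sublibrary = sublibrary)
}

#' Read a barcode reference table
#'
#' Accepts the xlsx convention (one barcode id per row under a header named
#' `id`) or a plain TSV/CSV with the same column. Gene, spacer and sublibrary
#' are recovered from the id string; a `sublibrary` column, when present,
#' overrides the id-derived label.
#'
#' @param path Path to a `.xlsx`/`.xls`, `.csv` or tab-separated file.
#' @param id_column Name of the column holding barcode ids.
#' @param spacer_length Expected spacer length in nucleotides.
#' @return A tibble with columns `barcode_id`, `gene`, `spacer`, `sublibrary`.
#' @export
read_barcode_reference <- function(path, id_column = "id",
                                   spacer_length = 17L) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  tab <- switch(
    ext,
    xlsx = ,
    xls = readxl::read_excel(path),
    csv = readr::read_csv(path, show_col_types = FALSE),
    readr::read_tsv(path, show_col_types = FALSE)
  )
  if (!id_column %in% names(tab)) {
    stop("reference file has no column named '", id_column, "'", call. = FALSE)
  }
  ref <- parse_barcode_ids(as.character(tab[[id_column]]),
                           spacer_length = spacer_length)
  if ("sublibrary" %in% names(tab)) {
    ref$sublibrary <- as.character(tab$sublibrary)
  }
  ref
}

#' Write a barcode reference table as TSV
#'
#' @param reference Tibble as returned by [read_barcode_reference()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_barcode_reference <- function(reference, path) {
  readr::write_tsv(tibble::tibble(id = reference$barcode_id,
                                  sublibrary = reference$sublibrary),
                   path)
  invisible(path)
}

#' Read a sample manifest
#'
#' A manifest maps sequencing samples to their screen design slot: `fraction`
#' (`cells` or `sEVs`), `cas9` (`plus`/`minus`, `+`/`-` accepted), the screen
#' (marker) label and the sublibrary the sample covers (`all` for a sample
#' spanning every sublibrary).
#'
#' @param path Tab-separated file with columns `sample_id`, `fraction`,
#'   `cas9`, `screen`, `sublibrary` and optionally `source`.
#' @return A tibble with normalized `fraction` and `cas9` columns.
#' @export
read_sample_manifest <- function(path) {
  man <- readr::read_tsv(path, show_col_types = FALSE)
  required <- c("sample_id", "fraction", "cas9", "screen", "sublibrary")
  missing <- setdiff(required, names(man))
  if (length(missing) > 0L) {
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  normalize_manifest(man)
}

normalize_manifest <- function(man) {
  fr <- tolower(as.character(man$fraction))
  fr[fr %in% c("sev", "sevs", "ev", "evs")] <- "sevs"
  if (!all(fr %in% c("cells", "sevs"))) {
    stop("fraction must be 'cells' or 'sEVs'", call. = FALSE)
  }
  cs <- tolower(as.character(man$cas9))
  cs[cs %in% c("+", "pos", "positive", "true")] <- "plus"
  cs[cs %in% c("-", "−", "neg", "negative", "false")] <- "minus"
  if (!all(cs %in% c("plus", "minus"))) {
    stop("cas9 must be 'plus'/'minus' (or '+'/'-')", call. = FALSE)
  }
  man$fraction <- fr
  man$cas9 <- cs
  man
}

#' Stream a FASTQ file into read ids and sequences
#'
#' Reads plain or gzip-compressed FASTQ (4-line records). Quality lines are
#' parsed for record integrity but otherwise ignored.
#'
#' @param path Path to a FASTQ file, optionally `.gz`.
#' @return A tibble with columns `read_id` and `sequence`, in file order.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L) {
    stop("truncated FASTQ record at record index ", n %/% 4L + 1L,
         " (file has ", n, " lines, not a multiple of 4)", call. = FALSE)
  }
  if (n == 0L) {
    return(tibble::tibble(read_id = character(), sequence = character()))
  }
  heads <- lines[seq(1L, n, by = 4L)]
  if (any(substr(heads, 1L, 1L) != "@")) {
    bad <- which(substr(heads, 1L, 1L) != "@")[1L]
    stop("malformed FASTQ header at record index ", bad, call. = FALSE)
  }
  tibble::tibble(
    read_id = sub("^@", "", sub("\\s.*$", "", heads)),
    sequence = toupper(lines[seq(2L, n, by = 4L)])
  )
}

#' Read a count table
#'
#' Tab-separated, first column `barcode_id`, one integer column per sample.
#' When a reference is supplied, barcodes absent from the file are inserted
#' with zero counts (with a warning) so that the row set always equals the
#' reference set, and unknown barcodes are an error.
#'
#' @param path Path to the TSV.
#' @param reference Optional reference tibble; enforces the dense row set.
#' @return An integer matrix (barcode x sample) with dimnames.
#' @export
read_count_table <- function(path, reference = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(tab)[1L] != "barcode_id") {
    stop("first column of a count table must be 'barcode_id'", call. = FALSE)
  }
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(mat) <- tab$barcode_id
  if (any(is.na(mat))) stop("missing values in count table", call. = FALSE)
  if (any(mat < 0)) stop("negative count in count table", call. = FALSE)
  if (any(mat != round(mat))) {
    stop("non-integer count in count table", call. = FALSE)
  }
  storage.mode(mat) <- "integer"
  if (!is.null(reference)) {
    unknown <- setdiff(rownames(mat), reference$barcode_id)
    if (length(unknown) > 0L) {
      stop("count table contains barcode(s) absent from the reference: ",
           paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
    }
    missing <- setdiff(reference$barcode_id, rownames(mat))
    if (length(missing) > 0L) {
      warning(length(missing),
              " reference barcode(s) missing from count table; ",
              "inserted with zero counts", call. = FALSE)
      zero <- matrix(0L, nrow = length(missing), ncol = ncol(mat),
                     dimnames = list(missing, colnames(mat)))
      mat <- rbind(mat, zero)
    }
    mat <- mat[reference$barcode_id, , drop = FALSE]
  }
  mat
}

#' Write a count table as TSV
#'
#' @param counts Integer matrix (barcode x sample) with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  tab <- tibble::as_tibble(counts)
  tab <- tibble::add_column(tab, barcode_id = rownames(counts), .before = 1L)
  readr::write_tsv(tab, path)
  invisible(path)
}
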