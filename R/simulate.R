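#' Configuration of a synthetic screen
#'
#' The generator emulates the statistical structure the scoring model
#' assumes: each gene's knockout shifts its guides' cellular log2 fold change
#' by a viability effect `beta`, and the sEV fold change follows the cellular
#' one linearly (slope `k`) plus an additive gene-level release effect `rho`
#' -- the quantity the screen is designed to recover. Guide baseline
#' abundances are log-normal (library skew), and each sample's counts are a
#' multinomial draw at a fixed sequencing depth.
#'
#' @param n_genes Number of genes.
#' @param guides_per_gene Guides (barcodes) per gene.
#' @param sublibraries Either a number of equally sized subpools, or a
#'   character vector of length `n_genes` assigning each gene a subpool.
#' @param depth Expected reads per guide per sample (default 500, the
#'   coverage the assay design maintains per gRNA).
#' @param slope Slope `k` of the FC_sEVs-on-FC_cells dependence (default 1).
#' @param sd_baseline Log-normal sigma of guide baseline abundance
#'   (default 0.5).
#' @param sd_guide_noise SD (log2 units) of per-guide noise on both fold
#'   changes and of the shared sEV-loading deviation (default 0.3).
#' @param frac_viability_genes,effect_sd_viability Fraction of genes with a
#'   nonzero viability effect `beta`, and the SD of those effects.
#' @param frac_release_genes,effect_sd_release Fraction of genes with a
#'   nonzero release effect `rho`, and the SD of those effects.
#' @param spacer_length Spacer length in nucleotides.
#' @param key Scaffold key the spacers must avoid (so counting round-trips
#'   exactly).
#' @param seed Integer seed; seeded runs are bit-reproducible, and each
#'   generation stage draws from its own derived stream.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000L, guides_per_gene = 5L,
                              sublibraries = 1L, depth = 500,
                              slope = 1, sd_baseline = 0.5,
                              sd_guide_noise = 0.3,
                              frac_viability_genes = 0.1,
                              effect_sd_viability = 1,
                              frac_release_genes = 0.05,
                              effect_sd_release = 1,
                              spacer_length = 17L, key = "GTTTAAGA",
                              seed = 1L) {
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(n_genes >= 1, "n_genes must be >= 1")
  chk(guides_per_gene >= 1, "guides_per_gene must be >= 1")
  chk(depth > 0, "depth must be > 0")
  chk(sd_baseline >= 0, "sd_baseline must be >= 0")
  chk(sd_guide_noise >= 0, "sd_guide_noise must be >= 0")
  chk(frac_viability_genes >= 0 && frac_viability_genes <= 1,
      "frac_viability_genes must be in [0, 1]")
  chk(frac_release_genes >= 0 && frac_release_genes <= 1,
      "frac_release_genes must be in [0, 1]")
  chk(effect_sd_viability >= 0, "effect_sd_viability must be >= 0")
  chk(effect_sd_release >= 0, "effect_sd_release must be >= 0")
  chk(spacer_length >= 1, "spacer_length must be >= 1")
  chk(!grepl("[^ACGT]", key) && nchar(key) > 0,
      "key must be a non-empty ACGT string")
  chk(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
      "seed must be a single integer")
  if (length(problems) > 0L) {
    stop("invalid simulation config:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  if (is.numeric(sublibraries) && length(sublibraries) == 1L) {
    k <- as.integer(sublibraries)
    sublibraries <- sprintf("SUB%02d", rep_len(seq_len(k), n_genes))
    sublibraries <- sort(sublibraries)
  } else if (length(sublibraries) != n_genes) {
    stop("sublibraries must be a count or one label per gene", call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes),
                 guides_per_gene = as.integer(guides_per_gene),
                 sublibraries = as.character(sublibraries),
                 depth = depth, slope = slope, sd_baseline = sd_baseline,
                 sd_guide_noise = sd_guide_noise,
                 frac_viability_genes = frac_viability_genes,
                 effect_sd_viability = effect_sd_viability,
                 frac_release_genes = frac_release_genes,
                 effect_sd_release = effect_sd_release,
                 spacer_length = as.integer(spacer_length), key = key,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# One derived stream per generation stage, so individual stages can be
# re-drawn reproducibly from the single user-facing seed.
stage_seed <- function(seed, stage) {
  (as.double(seed) * 7919 + stage * 1000003) %% 2147483629
}

random_dna <- function(n, len) {
  if (n == 0L) return(character())
  cols <- lapply(seq_len(len), function(i) {
    sample(c("A", "C", "G", "T"), n, replace = TRUE)
  })
  do.call(paste0, cols)
}

# random variable-length key-free strings, vectorized by grouping lengths
key_free_dna_varlen <- function(lens, key) {
  out <- character(length(lens))
  for (len in unique(lens)) {
    if (len == 0L) next
    i <- which(lens == len)
    out[i] <- key_free_dna(length(i), len, key)
  }
  out
}

# random fixed-length DNA strings containing no occurrence of `key`
key_free_dna <- function(n, len, key) {
  out <- random_dna(n, len)
  bad <- grepl(key, out, fixed = TRUE)
  while (any(bad)) {
    out[bad] <- random_dna(sum(bad), len)
    bad <- grepl(key, out, fixed = TRUE)
  }
  out
}

#' Simulate a gRNA-barcoded release screen with known ground truth
#'
#' Per guide `i` of gene `g`: baseline `a_i ~ LogNormal(0, sd_baseline)`;
#' latent `fc_cells_i = beta_g + eps_i` and
#' `fc_sevs_i = k * fc_cells_i + rho_g + eps'_i` with
#' `eps, eps' ~ N(0, sd_guide_noise)`. Expected abundances per sample are
#' `cells/Cas9-: a_i`, `cells/Cas9+: a_i * 2^fc_cells_i`,
#' `sEVs/Cas9-: a_i * 2^u_i`, `sEVs/Cas9+: a_i * 2^(u_i + fc_sevs_i)` with a
#' shared sEV-loading deviation `u_i ~ N(0, sd_guide_noise)`. Each sample's
#' counts are a multinomial draw of size `depth * n_guides` (per
#' sublibrary, modeling competitive sequencing of each pool).
#'
#' @param config A [simulation_config()].
#' @param truth Optional tibble with one row per gene and columns `beta`
#'   and `rho`, overriding the randomly drawn gene effects (e.g. to share
#'   effects between two simulated marker screens).
#' @return A list of class `simulated_screen` with `reference`, `truth`
#'   (gene, sublibrary, beta, rho), `counts` (barcode x 4 sample matrix),
#'   `manifest`, `expected` (latent per-guide fold changes) and `config`.
#' @export
simulate_screen <- function(config = simulation_config(), truth = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  g <- config$n_genes
  m <- config$guides_per_gene
  n <- g * m
  gene <- sprintf("G%05d", seq_len(g))
  sublib <- config$sublibraries

  set.seed(stage_seed(config$seed, 1))
  spacers <- key_free_dna(n, config$spacer_length, config$key)
  while (anyDuplicated(spacers)) {
    dup <- duplicated(spacers)
    spacers[dup] <- key_free_dna(sum(dup), config$spacer_length, config$key)
  }

  if (!is.null(truth)) {
    stopifnot(nrow(truth) == g, all(c("beta", "rho") %in% names(truth)))
    beta <- truth$beta
    rho <- truth$rho
  } else {
    set.seed(stage_seed(config$seed, 2))
    beta <- rho <- numeric(g)
    n_via <- round(config$frac_viability_genes * g)
    n_rel <- round(config$frac_release_genes * g)
    via_genes <- sample.int(g, n_via)
    rel_genes <- sample.int(g, n_rel)
    beta[via_genes] <- stats::rnorm(n_via, 0, config$effect_sd_viability)
    rho[rel_genes] <- stats::rnorm(n_rel, 0, config$effect_sd_release)
  }

  set.seed(stage_seed(config$seed, 3))
  gi <- rep(seq_len(g), each = m)
  a <- stats::rlnorm(n, 0, config$sd_baseline)
  eps_c <- stats::rnorm(n, 0, config$sd_guide_noise)
  eps_s <- stats::rnorm(n, 0, config$sd_guide_noise)
  u <- stats::rnorm(n, 0, config$sd_guide_noise)
  fc_cells <- beta[gi] + eps_c
  fc_sevs <- config$slope * fc_cells + rho[gi] + eps_s

  weights <- cbind(
    cells_minus = a,
    cells_plus = a * 2^fc_cells,
    sevs_minus = a * 2^u,
    sevs_plus = a * 2^(u + fc_sevs)
  )

  barcode_id <- sprintf("%s_%s_%d_%s", gene[gi], spacers,
                        rep(seq_len(m), times = g), sublib[gi])
  set.seed(stage_seed(config$seed, 4))
  counts <- matrix(0L, n, 4L,
                   dimnames = list(barcode_id, colnames(weights)))
  for (sl in unique(sublib)) {
    rows <- sublib[gi] == sl
    size <- round(config$depth * sum(rows))
    for (s in colnames(weights)) {
      counts[rows, s] <- as.integer(
        stats::rmultinom(1L, size, weights[rows, s]))
    }
  }

  reference <- tibble::tibble(barcode_id = barcode_id, gene = gene[gi],
                              spacer = spacers, sublibrary = sublib[gi])
  truth <- tibble::tibble(gene = gene, sublibrary = sublib,
                          beta = beta, rho = rho)
  manifest <- tibble::tibble(
    sample_id = colnames(weights),
    fraction = c("cells", "cells", "sevs", "sevs"),
    cas9 = c("minus", "plus", "minus", "plus"),
    screen = "SIM", sublibrary = "all",
    source = NA_character_
  )
  structure(list(reference = reference, truth = truth, counts = counts,
                 manifest = manifest,
                 expected = tibble::tibble(barcode_id = barcode_id,
                                           gene = gene[gi],
                                           fc_cells = fc_cells,
                                           fc_sevs = fc_sevs),
                 config = config),
            class = "simulated_screen")
}

#' @export
print.simulated_screen <- function(x, ...) {
  cat("Simulated screen:", x$config$n_genes, "genes x",
      x$config$guides_per_gene, "guides,",
      length(unique(x$reference$sublibrary)), "sublibrary(ies), depth",
      x$config$depth, "\n")
  invisible(x)
}

#' Synthesize FASTQ reads for one sample of a simulated screen
#'
#' Each read is a random key-free ACGT prefix, the guide's spacer, the
#' scaffold key, and a random key-free tail, truncated to `read_length`.
#' Reads are generated to guarantee that the counting rule assigns each one
#' to its intended barcode (no spurious earlier key occurrence with full
#' upstream context), so counting round-trips the ledger exactly.
#'
#' @param screen A [simulate_screen()] result (used for spacers and, when
#'   `ledger` is `NULL`, per-barcode read numbers).
#' @param sample Sample name (column of `screen$counts`); ignored when a
#'   `ledger` is given.
#' @param path Output FASTQ path (`.gz` supported); `NULL` returns the read
#'   tibble instead of writing.
#' @param read_length Total read length (default 50).
#' @param max_prefix Maximum random prefix length (default 8).
#' @param seed Seed for the read-level randomness.
#' @param ledger Optional named vector of read counts per barcode id.
#' @return A list with `ledger` (named integer vector actually emitted) and
#'   either `path` or `reads` (tibble `read_id`, `sequence`).
#' @export
simulate_fastq <- function(screen, sample = "cells_minus", path = NULL,
                           read_length = 50L, max_prefix = 8L, seed = 1L,
                           ledger = NULL) {
  stopifnot(inherits(screen, "simulated_screen"))
  key <- screen$config$key
  spacer_len <- screen$config$spacer_length
  if (read_length < max_prefix + spacer_len + nchar(key)) {
    stop("read_length too short for prefix + spacer + key", call. = FALSE)
  }
  if (is.null(ledger)) {
    ledger <- screen$counts[, sample]
  }
  ledger <- ledger[ledger > 0]
  spacer_of <- stats::setNames(screen$reference$spacer,
                               screen$reference$barcode_id)
  unknown <- setdiff(names(ledger), names(spacer_of))
  if (length(unknown) > 0L) {
    stop("ledger names unknown barcode(s): ", unknown[1L], call. = FALSE)
  }
  n_reads <- sum(ledger)
  set.seed(stage_seed(seed, 5))
  barcode <- rep(names(ledger), times = ledger)
  spacer <- unname(spacer_of[barcode])
  pre_len <- sample.int(max_prefix + 1L, n_reads, replace = TRUE) - 1L
  prefix <- key_free_dna_varlen(pre_len, key)
  core <- paste0(prefix, spacer, key)
  # reject prefixes creating an earlier key occurrence with full upstream
  # context (occurrences without spacer_len upstream are skipped by the
  # counter and are harmless)
  repeat {
    first_ok <- key_positions(core, counting_config(key, spacer_len))
    intended <- pre_len + spacer_len + 1L
    bad <- which(first_ok != intended)
    if (length(bad) == 0L) break
    prefix[bad] <- key_free_dna_varlen(pre_len[bad], key)
    core <- paste0(prefix, spacer, key)
  }
  tail_len <- pmax(read_length - nchar(core), 0L)
  tl <- key_free_dna_varlen(tail_len, key)
  seqs <- substr(paste0(core, tl), 1L, read_length)
  ord <- sample.int(n_reads)
  seqs <- seqs[ord]
  ids <- sprintf("read%06d", seq_len(n_reads))

  emitted <- stats::setNames(rep(0L, nrow(screen$reference)),
                             screen$reference$barcode_id)
  emitted[names(ledger)] <- as.integer(ledger)

  if (is.null(path)) {
    return(list(ledger = emitted,
                reads = tibble::tibble(read_id = ids, sequence = seqs)))
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  qual <- strrep("I", read_length)
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), con)
  list(ledger = emitted, path = path)
}
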