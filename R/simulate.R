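#' Simulation configuration for a synthetic activation cohort
#'
#' The generator emulates the design of a single-nucleus activation study:
#' two FOS immunostain groups (default 36 FOS+ vs 43 FOS-), a latent
#' activation pseudotime t in \[0,1\] driving a multiplicative program of
#' immediate-early-gene-like genes, negative-binomial counts with logistic
#' dropout, TPM derived from counts, ERCC spike-ins at known
#' concentrations, and label noise creating "pseudo-FOS+" nuclei whose
#' transcriptomes have not yet responded.
#'
#' Baseline gene means are log-normal (`mean_log_expression`,
#' `sd_log_expression` on the log scale). Program genes are amplified by
#' `effect_size^t`, so `effect_size` is the fold-change reached at
#' pseudotime 1. Dropout zeroes a count with probability
#' `plogis(dropout_midpoint - dropout_slope * log(mu))`; set
#' `dropout_midpoint = -Inf` to disable it. Defaults are calibrated so a
#' nucleus detects roughly 6,000 of the 8,000 genes at TPM > 1.
#'
#' @param n_fos_pos,n_fos_neg group sizes (nuclei).
#' @param n_genes total genes; `n_program_genes` of them form the
#'   activation program.
#' @param n_program_genes number of activation-program genes.
#' @param mean_log_expression,sd_log_expression log-normal parameters of
#'   baseline gene means (natural-log scale).
#' @param dispersion negative-binomial dispersion phi (> 0); variance is
#'   `mu + phi * mu^2`.
#' @param dropout_midpoint,dropout_slope logistic dropout parameters on
#'   the log mean.
#' @param effect_size program fold-change at pseudotime 1 (1 = null).
#' @param label_noise probability that a mid-pseudotime FOS- nucleus is
#'   relabelled FOS+ (the pseudo-FOS+ analogue).
#' @param ercc_n number of ERCC spike-in species.
#' @param library_size_mean,library_size_cv mean and coefficient of
#'   variation of per-nucleus gene-mapped reads.
#' @param seed integer seed; the whole cohort is deterministic given it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_fos_pos = 36, n_fos_neg = 43, n_genes = 8000,
                       n_program_genes = 500, mean_log_expression = 1,
                       sd_log_expression = 1.6, dispersion = 0.3,
                       dropout_midpoint = -2.5, dropout_slope = 0.8,
                       effect_size = 4, label_noise = 0.1, ercc_n = 92,
                       library_size_mean = 120000, library_size_cv = 0.15,
                       seed = 1) {
  cfg <- list(
    n_fos_pos = n_fos_pos, n_fos_neg = n_fos_neg, n_genes = n_genes,
    n_program_genes = n_program_genes,
    mean_log_expression = mean_log_expression,
    sd_log_expression = sd_log_expression, dispersion = dispersion,
    dropout_midpoint = dropout_midpoint, dropout_slope = dropout_slope,
    effect_size = effect_size, label_noise = label_noise, ercc_n = ercc_n,
    library_size_mean = library_size_mean,
    library_size_cv = library_size_cv, seed = seed
  )
  for (f in c("n_fos_pos", "n_fos_neg", "n_genes", "n_program_genes",
              "ercc_n")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 1 ||
        cfg[[f]] != round(cfg[[f]])) {
      abort(sprintf("%s must be a positive integer", f))
    }
  }
  if (cfg$n_program_genes > cfg$n_genes) {
    abort("n_program_genes cannot exceed n_genes")
  }
  if (cfg$dispersion <= 0) abort("dispersion must be > 0")
  if (cfg$label_noise < 0 || cfg$label_noise > 1) {
    abort("label_noise must be in [0, 1]")
  }
  if (cfg$effect_size <= 0) abort("effect_size must be > 0")
  if (cfg$library_size_mean <= 0) abort("library_size_mean must be > 0")
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic single-nucleus activation cohort
#'
#' Draws a latent activation pseudotime t ~ U(0,1) per nucleus, assigns
#' FOS+ stain to the nuclei with the highest t (matching `n_fos_pos`),
#' relabels a `label_noise` fraction of mid-pseudotime FOS- nuclei as
#' FOS+ (pseudo-FOS+ analogue), then draws NB counts with mean
#' `baseline * effect_size^t` for program genes, thins them by logistic
#' dropout, and converts to TPM by per-sample scaling to 1e6.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_cohort` with elements `counts` and `tpm`
#'   (gene x sample matrices), `metadata` (tibble, see
#'   [sample_metadata()]), and `truth` (list with per-sample `samples`
#'   tibble: latent `t`, `stain_true`, `relabelled`; and per-gene `genes`
#'   tibble: `program`, `fold_change`).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_fos_pos + cfg$n_fos_neg
  sample_ids <- sprintf("nucleus_%03d", seq_len(n))
  gene_ids <- sprintf("gene_%05d", seq_len(cfg$n_genes))

  # bimodal activation continuum: a resting and an activated state,
  # bridged by intermediate nuclei
  low <- runif(n) < cfg$n_fos_neg / n
  t <- stats::rbeta(n, ifelse(low, 2, 8), ifelse(low, 8, 2))
  pos_cut <- sort(t, decreasing = TRUE)[cfg$n_fos_pos]
  stain_true <- ifelse(t >= pos_cut, "FOS_POS", "FOS_NEG")
  # mid-pseudotime FOS- nuclei (upper half of the FOS- range) may carry
  # FOS protein before the transcriptome responds
  neg_idx <- which(stain_true == "FOS_NEG")
  mid <- neg_idx[t[neg_idx] > median(t[neg_idx])]
  relabelled <- rep(FALSE, n)
  relabelled[mid] <- runif(length(mid)) < cfg$label_noise
  stain <- ifelse(relabelled, "FOS_POS", stain_true)

  baseline <- rlnorm(cfg$n_genes, cfg$mean_log_expression,
                     cfg$sd_log_expression)
  program <- sort(sample.int(cfg$n_genes, cfg$n_program_genes))
  fold_change <- rep(1, cfg$n_genes)
  fold_change[program] <- cfg$effect_size

  # gene x sample expected relative expression, then scale to library size
  fc_mat <- outer(log(fold_change), t)          # log FC(t) = t * log(FC)
  mean_rel <- baseline * exp(fc_mat)
  lib <- rlnorm(n, log(cfg$library_size_mean) -
                  log(1 + cfg$library_size_cv^2) / 2,
                sqrt(log(1 + cfg$library_size_cv^2)))
  mu <- sweep(mean_rel, 2, lib / colSums(mean_rel), `*`)

  counts <- matrix(
    rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
    nrow = cfg$n_genes,
    dimnames = list(gene_ids, sample_ids)
  )
  if (is.finite(cfg$dropout_midpoint)) {
    p_drop <- plogis(cfg$dropout_midpoint - cfg$dropout_slope * log(mu))
    counts <- counts * (matrix(runif(length(mu)), nrow = cfg$n_genes) >=
                          p_drop)
  }

  tot <- colSums(counts)
  if (any(tot == 0)) abort("simulated sample with zero total counts")
  tpm <- sweep(counts, 2, 1e6 / tot, `*`)

  meta <- sample_metadata(sample_ids, condition = "NE", stain = stain,
                          mapped_reads = tot)
  truth <- list(
    samples = tibble(sample_id = sample_ids, t = t,
                     stain_true = stain_true, stain = stain,
                     relabelled = relabelled),
    genes = tibble(gene_id = gene_ids,
                   program = seq_len(cfg$n_genes) %in% program,
                   fold_change = fold_change)
  )
  structure(list(counts = counts, tpm = tpm, metadata = meta,
                 truth = truth, config = cfg),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic cohort: %d genes x %d nuclei (%d FOS+, %d FOS-), seed %d\n",
    nrow(x$counts), ncol(x$counts), sum(x$metadata$stain == "FOS_POS"),
    sum(x$metadata$stain == "FOS_NEG"), x$config$seed
  ))
  invisible(x)
}

#' Generate ERCC spike-in concentrations and observed TPM
#'
#' Expected concentrations are log-spaced over five orders of magnitude.
#' Observed TPM per sample is `concentration * efficiency` times
#' log-normal noise; a configurable fraction of samples get their spike
#' values randomly shuffled, emulating failed libraries whose ERCC signal
#' no longer tracks input concentration.
#'
#' @param cfg a [sim_config()]; `ercc_n` must be at least 2.
#' @param n_samples number of samples (defaults to the cohort size).
#' @param efficiency TPM produced per concentration unit.
#' @param noise_sd standard deviation of the log-normal measurement noise
#'   (natural-log scale).
#' @param shuffle_frac fraction of samples whose spike values are
#'   shuffled across species.
#' @param seed integer seed.
#' @return list with `expected` (tibble: `spike_id`, `concentration`),
#'   `observed` (spike x sample TPM matrix) and `shuffled` (sample ids).
#' @export
simulate_ercc <- function(cfg = sim_config(), n_samples = NULL,
                          efficiency = 10, noise_sd = 0.3,
                          shuffle_frac = 0, seed = cfg$seed + 1) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$ercc_n < 2) abort("ercc_n must be at least 2")
  n_samples <- n_samples %||% (cfg$n_fos_pos + cfg$n_fos_neg)
  set.seed(seed)
  spike_ids <- sprintf("ERCC-%04d", seq_len(cfg$ercc_n))
  conc <- 10^seq(-2, 3, length.out = cfg$ercc_n)
  sample_ids <- sprintf("nucleus_%03d", seq_len(n_samples))
  observed <- matrix(
    conc * efficiency *
      exp(rnorm(cfg$ercc_n * n_samples, 0, noise_sd)),
    nrow = cfg$ercc_n, dimnames = list(spike_ids, sample_ids)
  )
  shuffled <- character(0)
  if (shuffle_frac > 0) {
    k <- min(n_samples, ceiling(shuffle_frac * n_samples))
    idx <- sort(sample.int(n_samples, k))
    for (j in idx) observed[, j] <- observed[sample.int(cfg$ercc_n), j]
    shuffled <- sample_ids[idx]
  }
  list(expected = tibble(spike_id = spike_ids, concentration = conc),
       observed = observed, shuffled = shuffled)
}

#' Generate a synthetic retrotransposon consensus library
#'
#' Random nucleotide consensus sequences standing in for a RepeatMasker
#' style library; purely synthetic, for fixtures and simulation.
#'
#' @param n_elements number of consensus elements.
#' @param length consensus length in nt (>= 50).
#' @param seed integer seed.
#' @return named character vector of A/C/G/T sequences.
#' @export
simulate_te_library <- function(n_elements = 5, length = 200, seed = 1) {
  if (length < 50) abort("consensus length must be >= 50 nt")
  set.seed(seed)
  setNames(
    vapply(seq_len(n_elements), function(i) {
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
            collapse = "")
    }, character(1)),
    sprintf("TE%02d", seq_len(n_elements))
  )
}

#' Default template-switch oligo used by the read generator
#'
#' A documented 30-nt example sequence (the DNA portion of a common
#' template-switching oligo). The scanner itself takes the oligo as an
#' explicit argument; this constant only parameterizes fixtures.
#' @export
EXAMPLE_TSO <- "AAGCAGTGGTATCAACGCAGAGTACATGGG"

#' Generate reads with known TSO-adjacency structure
#'
#' Emits three read classes with known per-element counts:
#' (a) TSO followed immediately by the consensus start (the
#' promoter-driven class the scanner must count), (b) TSO followed by an
#' internal consensus fragment, and (c) consensus fragments without TSO.
#' The truth table records the class-(a) counts.
#'
#' @param library named character vector of consensus sequences
#'   (each >= 50 nt).
#' @param tso template-switch oligo sequence (>= 10 nt).
#' @param n_start,n_internal,n_background per-element read counts for
#'   classes (a), (b), (c); scalars are recycled.
#' @param read_length read length in nt.
#' @param seed integer seed.
#' @return list with `reads` (named [Biostrings::DNAStringSet]) and
#'   `truth` (tibble: `element`, `tso_adjacent_true`, `total_true`).
#' @export
simulate_te_reads <- function(library, tso = EXAMPLE_TSO, n_start = 20,
                              n_internal = 10, n_background = 15,
                              read_length = 60, seed = 1) {
  if (length(library) == 0) abort("empty consensus library")
  if (any(nchar(library) < 50)) abort("consensus sequences must be >= 50 nt")
  if (nchar(tso) < 10) abort("tso must be >= 10 nt")
  set.seed(seed)
  elems <- names(library)
  n_start <- rep_len(n_start, length(library))
  n_internal <- rep_len(n_internal, length(library))
  n_background <- rep_len(n_background, length(library))
  frag <- read_length - nchar(tso)
  reads <- character(0)
  labels <- character(0)
  for (i in seq_along(library)) {
    cons <- library[[i]]
    len <- nchar(cons)
    if (n_start[i] > 0) {
      r <- paste0(tso, substr(cons, 1, frag))
      reads <- c(reads, rep(r, n_start[i]))
      labels <- c(labels, sprintf("%s_a_%d", elems[i], seq_len(n_start[i])))
    }
    if (n_internal[i] > 0) {
      starts <- sample(seq(20, max(20, len - frag)), n_internal[i],
                       replace = TRUE)
      r <- paste0(tso, substr(rep(cons, n_internal[i]), starts,
                              starts + frag - 1))
      reads <- c(reads, r)
      labels <- c(labels,
                  sprintf("%s_b_%d", elems[i], seq_len(n_internal[i])))
    }
    if (n_background[i] > 0) {
      starts <- sample(seq(1, max(1, len - read_length)), n_background[i],
                       replace = TRUE)
      r <- substr(rep(cons, n_background[i]), starts,
                  starts + read_length - 1)
      reads <- c(reads, r)
      labels <- c(labels,
                  sprintf("%s_c_%d", elems[i], seq_len(n_background[i])))
    }
  }
  ord <- sample(length(reads))   # shuffle so counting is order-blind
  reads <- Biostrings::DNAStringSet(setNames(reads[ord], labels[ord]))
  truth <- tibble(
    element = elems,
    tso_adjacent_true = n_start,
    total_true = n_start + n_internal + n_background
  )
  list(reads = reads, truth = truth, tso = tso)
}

#' Write reads as FASTQ
#'
#' @param reads named [Biostrings::DNAStringSet].
#' @param path output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  quals <- Biostrings::BStringSet(
    vapply(Biostrings::width(reads),
           function(w) strrep("I", w), character(1))
  )
  Biostrings::writeXStringSet(reads, path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

#' Read a FASTQ file as a DNAStringSet
#'
#' @param path FASTQ path (optionally gzipped).
#' @return named [Biostrings::DNAStringSet].
#' @export
read_fastq <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}
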