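#' Read a retrotransposon consensus library
#'
#' FASTA file of consensus sequences (RepeatMasker style); names must be
#' unique and sequences at least 50 nt.
#'
#' @param path FASTA path, or a named character vector / DNAStringSet.
#' @return named character vector of upper-case consensus sequences.
#' @export
read_consensus_library <- function(path) {
  seqs <- if (inherits(path, "DNAStringSet")) {
    setNames(as.character(path), names(path))
  } else if (is.character(path) && length(path) == 1 && file.exists(path)) {
    ss <- Biostrings::readDNAStringSet(path)
    setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  } else if (is.character(path) && !is.null(names(path))) {
    path
  } else {
    abort("provide a FASTA path, a named character vector, or a DNAStringSet")
  }
  if (length(seqs) == 0) abort("empty consensus library")
  if (anyDuplicated(names(seqs))) abort("consensus names must be unique")
  if (any(nchar(seqs) < 50)) abort("consensus sequences must be >= 50 nt")
  toupper(seqs)
}

#' Count TSO-adjacent reads per consensus element
#'
#' A read supports promoter-driven expression of element E when (a) it
#' contains the template-switch oligo (exact forward-orientation match)
#' and (b) the `prefix_len` bases immediately after the oligo match a
#' window of E's consensus starting within the first `start_window`
#' bases, with at most `max_mismatch` mismatches. A read matching
#' several elements is assigned to the one with the fewest mismatches
#' (ties: alphabetically first element, recorded in the tie flag).
#'
#' @param reads named [Biostrings::DNAStringSet], a character vector of
#'   read sequences, or a FASTQ path.
#' @param library consensus library (see [read_consensus_library()]).
#' @param tso template-switch oligo sequence (>= 10 nt; required, the
#'   study oligo is a protocol parameter).
#' @param prefix_len bases compared after the oligo.
#' @param max_mismatch maximum mismatches allowed in the prefix.
#' @param start_window consensus window (1-based) in which the match may
#'   begin.
#' @return list with `counts` (tibble: `element`,
#'   `tso_adjacent_count`), `assignments` (tibble: `read`, `element`,
#'   `mismatches`, `tie`) and `n_skipped` (reads too short to
#'   evaluate).
#' @export
scan_tso_adjacent <- function(reads, library, tso, prefix_len = 20,
                              max_mismatch = 2, start_window = 5) {
  library <- read_consensus_library(library)
  if (nchar(tso) < 10) abort("tso must be >= 10 nt")
  if (inherits(reads, "DNAStringSet")) {
    reads <- setNames(as.character(reads), names(reads))
  } else if (is.character(reads) && length(reads) == 1 &&
             file.exists(reads)) {
    rr <- read_fastq(reads)
    reads <- setNames(as.character(rr), names(rr))
  }
  if (is.null(names(reads))) {
    names(reads) <- sprintf("read_%d", seq_along(reads))
  }
  reads <- toupper(reads)
  tso <- toupper(tso)

  pos <- regexpr(tso, reads, fixed = TRUE)
  has_tso <- pos > 0
  after <- pos + nchar(tso)
  long_enough <- nchar(reads) - after + 1 >= prefix_len
  n_skipped <- sum(has_tso & !long_enough)
  use <- has_tso & long_enough
  counts0 <- tibble(element = sort(names(library)),
                    tso_adjacent_count = 0L)
  if (!any(use)) {
    return(list(counts = counts0,
                assignments = tibble(read = character(0),
                                     element = character(0),
                                     mismatches = integer(0),
                                     tie = logical(0)),
                n_skipped = n_skipped))
  }

  prefixes <- substr(reads[use], after[use], after[use] + prefix_len - 1)
  pref_mat <- matrix(unlist(strsplit(prefixes, "")), ncol = prefix_len,
                     byrow = TRUE)
  elems <- sort(names(library))
  best_mm <- matrix(Inf, nrow = length(prefixes), ncol = length(elems),
                    dimnames = list(NULL, elems))
  for (e in elems) {
    cons <- library[[e]]
    for (off in seq_len(start_window)) {
      if (off + prefix_len - 1 > nchar(cons)) break
      win <- strsplit(substr(cons, off, off + prefix_len - 1), "")[[1]]
      mm <- rowSums(pref_mat != matrix(win, nrow(pref_mat), prefix_len,
                                       byrow = TRUE))
      best_mm[, e] <- pmin(best_mm[, e], mm)
    }
  }
  hit <- best_mm <= max_mismatch
  any_hit <- rowSums(hit) > 0
  assignments <- purrr::map(which(any_hit), function(i) {
    mm <- best_mm[i, ]
    cand <- elems[mm == min(mm) & hit[i, ]]
    tibble(read = names(prefixes)[i], element = cand[1],
           mismatches = as.integer(min(mm)), tie = length(cand) > 1)
  }) |> bind_rows()
  if (nrow(assignments) == 0) {
    assignments <- tibble(read = character(0), element = character(0),
                          mismatches = integer(0), tie = logical(0))
  }
  counts <- counts0 |>
    left_join(assignments |> count(.data$element), by = "element") |>
    mutate(tso_adjacent_count = as.integer(dplyr::coalesce(.data$n, 0L))) |>
    select("element", "tso_adjacent_count")
  list(counts = counts, assignments = assignments, n_skipped = n_skipped)
}

#' Naive total alignment counts per consensus
#'
#' Fixture-scale stand-in for a full aligner: a read counts towards
#' element E when, after stripping a leading template-switch oligo if
#' present, its first `k` bases occur exactly in E's consensus. Intended
#' for synthetic reads that are genuine consensus substrings; real data
#' should supply totals from an external aligner.
#'
#' @param reads as in [scan_tso_adjacent()].
#' @param library consensus library.
#' @param tso oligo to strip when present (`NULL` to skip).
#' @param k seed length for the exact match.
#' @return tibble: `element`, `total_count`.
#' @export
count_total_alignments <- function(reads, library, tso = NULL, k = 25) {
  library <- read_consensus_library(library)
  if (inherits(reads, "DNAStringSet")) reads <- as.character(reads)
  reads <- toupper(unname(reads))
  if (!is.null(tso)) {
    tso <- toupper(tso)
    pos <- regexpr(tso, reads, fixed = TRUE)
    strip <- pos > 0
    reads[strip] <- substr(reads[strip], pos[strip] + nchar(tso),
                           nchar(reads[strip]))
  }
  seeds <- substr(reads, 1, k)
  ok <- nchar(seeds) == k
  elems <- sort(names(library))
  totals <- vapply(elems, function(e) {
    sum(ok & vapply(seeds, function(s) {
      grepl(s, library[[e]], fixed = TRUE)
    }, logical(1)))
  }, numeric(1))
  tibble(element = elems, total_count = as.integer(totals))
}

#' Promoter-normalized retrotransposon counts
#'
#' Joins TSO-adjacent counts with total per-consensus alignment counts
#' and reports their ratio (the promoter-normalized count): the fraction
#' of an element's expression attributable to transcription initiated at
#' its own promoter. Elements without coverage get ratio 0 and a
#' zero-coverage flag.
#'
#' @param tso_counts tibble with `element`, `tso_adjacent_count` (from
#'   [scan_tso_adjacent()]).
#' @param total_counts tibble with `element`, `total_count`.
#' @return tibble: `element`, `tso_adjacent_count`, `total_count`,
#'   `promoter_normalized`, `zero_coverage`.
#' @export
promoter_normalized_counts <- function(tso_counts, total_counts) {
  out <- dplyr::full_join(tso_counts, total_counts, by = "element") |>
    mutate(
      tso_adjacent_count = dplyr::coalesce(.data$tso_adjacent_count, 0L),
      total_count = dplyr::coalesce(.data$total_count, 0L)
    )
  if (any(out$tso_adjacent_count > out$total_count)) {
    abort("tso_adjacent_count exceeds total_count: inconsistent inputs")
  }
  out |>
    mutate(
      promoter_normalized = ifelse(.data$total_count > 0,
                                   .data$tso_adjacent_count /
                                     .data$total_count, 0),
      zero_coverage = .data$total_count == 0
    ) |>
    arrange(.data$element)
}
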