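test_that("consensus libraries are validated on load", {
  lib <- simulate_te_library(n_elements = 2, length = 120, seed = 1)
  fa <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(lib), fa)
  expect_identical(read_consensus_library(fa), lib)
  expect_error(read_consensus_library(setNames("ACGT", "x")), ">= 50")
  expect_error(read_consensus_library(character(0)), "empty|provide")
})

test_that("TSO-adjacent scanning counts exactly the promoter-proximal reads", {
  lib <- simulate_te_library(n_elements = 3, length = 150, seed = 2)
  tso <- EXAMPLE_TSO

  start_read <- paste0(tso, substr(lib[[1]], 1, 30))
  set.seed(77)
  random_tail <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                       collapse = "")
  random_read <- paste0(tso, random_tail)
  no_tso_read <- substr(lib[[1]], 1, 60)

  res <- scan_tso_adjacent(c(r1 = start_read, r2 = random_read,
                             r3 = no_tso_read), lib, tso)
  counts <- setNames(res$counts$tso_adjacent_count, res$counts$element)
  expect_equal(unname(counts[names(lib)[1]]), 1)
  expect_equal(sum(counts), 1)
  expect_identical(res$assignments$read, "r1")
})

test_that("scanner counts match the generator truth exactly on mixed reads", {
  lib <- simulate_te_library(n_elements = 4, length = 200, seed = 3)
  rr <- simulate_te_reads(lib, n_start = c(7, 0, 3, 12), n_internal = 5,
                          n_background = 6, seed = 3)
  res <- scan_tso_adjacent(rr$reads, lib, rr$tso)
  got <- setNames(res$counts$tso_adjacent_count, res$counts$element)
  expect_equal(unname(got[rr$truth$element]), rr$truth$tso_adjacent_true)

  # precision and recall are both 1 on class-(a)-only reads
  only_a <- simulate_te_reads(lib, n_start = 10, n_internal = 0,
                              n_background = 0, seed = 4)
  res_a <- scan_tso_adjacent(only_a$reads, lib, only_a$tso)
  expect_equal(setNames(res_a$counts$tso_adjacent_count,
                        res_a$counts$element)[only_a$truth$element],
               setNames(only_a$truth$tso_adjacent_true,
                        only_a$truth$element))
  expect_false(any(res_a$assignments$tie))

  # classes (b) and (c) alone contribute nothing
  only_bc <- simulate_te_reads(lib, n_start = 0, n_internal = 5,
                               n_background = 5, seed = 5)
  res_bc <- scan_tso_adjacent(only_bc$reads, lib, only_bc$tso)
  expect_true(all(res_bc$counts$tso_adjacent_count == 0))
})

test_that("scanning is order-independent and strictly forward-oriented", {
  lib <- simulate_te_library(n_elements = 3, length = 150, seed = 6)
  rr <- simulate_te_reads(lib, seed = 6)
  fwd <- scan_tso_adjacent(rr$reads, lib, rr$tso)
  shuf <- scan_tso_adjacent(rev(rr$reads), lib, rr$tso)
  expect_equal(fwd$counts, shuf$counts)

  rc <- Biostrings::reverseComplement(rr$reads)
  expect_true(all(scan_tso_adjacent(rc, lib, rr$tso)$counts$
                    tso_adjacent_count == 0))
})

test_that("FASTQ round-trips preserve the reads the scanner sees", {
  lib <- simulate_te_library(n_elements = 2, length = 120, seed = 7)
  rr <- simulate_te_reads(lib, n_start = 4, n_internal = 2,
                          n_background = 2, seed = 7)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(rr$reads, fq)
  res <- scan_tso_adjacent(fq, lib, rr$tso)
  expect_equal(setNames(res$counts$tso_adjacent_count,
                        res$counts$element)[rr$truth$element],
               setNames(rr$truth$tso_adjacent_true, rr$truth$element))
})

test_that("ambiguous reads break ties alphabetically and are flagged", {
  shared <- paste(rep("ACGT", 30), collapse = "")
  lib <- c(zeta = shared, alpha = shared)
  read <- paste0(EXAMPLE_TSO, substr(shared, 1, 40))
  res <- scan_tso_adjacent(c(r1 = read), lib, EXAMPLE_TSO)
  expect_identical(res$assignments$element, "alpha")
  expect_true(res$assignments$tie)
})

test_that("promoter normalization is the TSO fraction with guarded inputs", {
  tso_counts <- tibble::tibble(element = c("L1", "B2", "ERV"),
                               tso_adjacent_count = c(10L, 0L, 3L))
  totals <- tibble::tibble(element = c("L1", "B2", "ERV", "ID"),
                           total_count = c(10L, 100L, 12L, 0L))
  rec <- promoter_normalized_counts(tso_counts, totals)
  got <- setNames(rec$promoter_normalized, rec$element)
  expect_equal(unname(got[c("L1", "B2", "ERV", "ID")]),
               c(1, 0, 0.25, 0))
  expect_true(rec$zero_coverage[rec$element == "ID"])
  bad <- tibble::tibble(element = "L1", tso_adjacent_count = 11L)
  expect_error(promoter_normalized_counts(
    bad, tibble::tibble(element = "L1", total_count = 10L)
  ), "exceeds")
})

test_that("the naive total counter reproduces generator totals", {
  lib <- simulate_te_library(n_elements = 3, length = 200, seed = 8)
  rr <- simulate_te_reads(lib, n_start = 5, n_internal = 4,
                          n_background = 6, seed = 8)
  totals <- count_total_alignments(rr$reads, lib, tso = rr$tso)
  expect_equal(setNames(totals$total_count, totals$element)[
    rr$truth$element], setNames(rr$truth$total_true, rr$truth$element))
})
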