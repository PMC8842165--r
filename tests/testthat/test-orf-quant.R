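test_that("k-mer index separates disjoint ORFs and flags shared ones", {
  ref <- orf_reference(c("a", "b"), c(strrep("A", 40), strrep("C", 40)), k = 5)
  idx <- index_reference(ref)
  expect_false(any(idx == mamthscreen:::AMBIGUOUS))
  # identical sequences: every k-mer ambiguous
  ref2 <- orf_reference(c("a", "b"), rep(strrep("ACGT", 10), 2), k = 5)
  idx2 <- index_reference(ref2)
  expect_true(all(idx2 == mamthscreen:::AMBIGUOUS))
  expect_error(orf_reference(c("a", "a"), c(strrep("A", 40), strrep("C", 40))),
               "duplicate")
})

test_that("ambiguous k-mer set matches the brute-force all-pairs scan", {
  seqs <- rand_dna(50, 500, seed = 21)
  # plant a shared 40-mer into two ORFs so ambiguity actually occurs
  shared <- substr(seqs[1], 101, 140)
  substr(seqs[2], 201, 240) <- shared
  ref <- orf_reference(sprintf("orf%02d", 1:50), seqs, k = 31)
  idx <- index_reference(ref)
  amb_pkg <- sort(names(idx)[idx == mamthscreen:::AMBIGUOUS])
  amb_brute <- sort(brute_ambiguous_kmers(seqs, 31))
  expect_identical(amb_pkg, amb_brute)
  expect_gt(length(amb_pkg), 0)
})

test_that("read assignment follows the all-unambiguous-kmers rule", {
  seqs <- c(a = paste0(strrep("A", 35), "CGTCGATTGCA", strrep("G", 35)),
            b = paste0(strrep("T", 35), "CGTCGATTGCA", strrep("C", 35)))
  ref <- orf_reference(names(seqs), unname(seqs), k = 7)
  idx <- index_reference(ref)
  # verbatim unique substring -> one count
  r1 <- assign_reads(substr(seqs["a"], 1, 20), idx)
  expect_equal(unname(r1$counts["a"]), 1)
  # read fully inside the shared region -> ambiguous, discarded
  r2 <- assign_reads("CGTCGATTGCA", idx)
  expect_equal(sum(r2$counts), 0)
  expect_equal(unname(r2$discarded["ambiguous"]), 1)
  # read shorter than k -> short tally, not an error
  r3 <- assign_reads("ACG", idx)
  expect_equal(unname(r3$discarded["short"]), 1)
  # read matching nothing -> unmatched
  r4 <- assign_reads(strrep("AC", 10), idx)
  expect_equal(unname(r4$discarded["unmatched"]), 1)
})

test_that("assignment recovers simulator truth exactly on a clean reference", {
  cfg <- screen_sim_config(n_orfs = 40, n_true_interactors = 5, n_fliers = 0,
                           base_mean = 5, orf_length = 300, read_length = 100,
                           seed = 31)
  sim <- simulate_screen(cfg, "b")
  idx <- index_reference(sim$reference)
  # random ORFs of length 300 share no 31-mers (checked, not assumed)
  expect_false(any(idx == mamthscreen:::AMBIGUOUS))
  for (r in 1:2) {
    asn <- assign_reads(sim$reads[[r]], idx)
    expect_equal(asn$counts, setNames(as.integer(sim$table$counts[, r]),
                                      sim$truth$orf_id),
                 ignore_attr = FALSE)
    expect_equal(sum(asn$discarded), 0)
  }
})

test_that("assignment is read-order invariant and conserves reads", {
  seqs <- rand_dna(10, 200, seed = 41)
  ref <- orf_reference(sprintf("o%d", 1:10), seqs, k = 31)
  idx <- index_reference(ref)
  set.seed(42)
  starts <- sample.int(150, 500, replace = TRUE)
  orf <- sample.int(10, 500, replace = TRUE)
  body_reads <- substring(seqs[orf], starts, starts + 50)
  reads <- c(body_reads, "ACGT", strrep("AT", 30))  # a short and an unmatched read
  a <- assign_reads(reads, idx)
  b <- assign_reads(rev(reads), idx)
  expect_identical(a$counts, b$counts)
  expect_identical(a$discarded, b$discarded)
  expect_equal(sum(a$counts) + sum(a$discarded), length(reads))
  # equivalence with naive substring search on a k-mer-disjoint reference
  expect_equal(assign_reads(body_reads, idx)$counts,
               brute_substring_counts(body_reads, sprintf("o%d", 1:10), seqs))
})

test_that("CPM arithmetic, conservation and degenerate columns", {
  ct <- count_table(matrix(c(1, 1, 2, 0, 0, 0), ncol = 2,
                           dimnames = list(c("a", "b", "c"), NULL)))
  expect_warning(ct <- counts_to_cpm(ct), "zero library size")
  expect_equal(unname(ct$cpm[, 1]), c(250000, 250000, 500000))
  expect_equal(unname(ct$cpm[, 2]), c(0, 0, 0))
  set.seed(8)
  m <- matrix(rpois(200, 10), 100, 2, dimnames = list(sprintf("g%d", 1:100), NULL))
  cpm <- counts_to_cpm(count_table(m))$cpm
  expect_equal(colSums(cpm), c(rep1 = 1e6, rep2 = 1e6))
})

test_that("FASTA/FASTQ round trip through quantify_screen", {
  cfg <- screen_sim_config(n_orfs = 15, n_true_interactors = 3, n_fliers = 0,
                           base_mean = 4, orf_length = 200, read_length = 80,
                           seed = 51)
  sim <- simulate_screen(cfg, "b")
  tmp <- withr::local_tempdir()
  fa <- file.path(tmp, "ref.fa")
  write_orf_reference(sim$reference, fa)
  fqs <- vapply(1:2, function(r) {
    p <- file.path(tmp, sprintf("r%d.fq", r))
    reads <- Biostrings::DNAStringSet(sim$reads[[r]])
    names(reads) <- sprintf("read%d", seq_along(reads))
    Biostrings::writeXStringSet(reads, p, format = "fastq")
    p
  }, character(1))
  q <- quantify_screen(read_orf_reference(fa), fqs)
  expect_equal(q$table$counts, sim$table$counts)
  expect_equal(colSums(q$table$cpm), c(rep1 = 1e6, rep2 = 1e6))
})
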