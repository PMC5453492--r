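test_that("candidate periods include the true period of an exact repeat", {
  cand <- find_candidate_periods(strrep("ACGT", 20), k = 4)
  expect_true(4 %in% cand$period)
  expect_equal(cand$period[which.max(cand$support)], 4)
})

test_that("candidate support matches the brute-force count", {
  set.seed(17)
  seqs <- c(strrep("ACGT", 15),
            paste0(strrep(random_seq(9), 8), random_seq(30)),
            random_seq(200))
  for (s in seqs) {
    brute <- period_support_oracle(s, 4, min(100, nchar(s) - 4))
    fast <- satseeker:::period_support_cpp(s, 4L, min(100L, nchar(s) - 4L))
    expect_equal(fast, brute)
  }
})

test_that("random sequence yields no candidates after the support filter", {
  set.seed(23)
  for (i in 1:5) {
    expect_equal(nrow(find_candidate_periods(random_seq(200), k = 4)), 0)
  }
})

test_that("candidates never exceed the maximum period", {
  s <- strrep(generate_monomer(30, 0.5, 3), 80) # 2400 bp
  cand <- find_candidate_periods(s, k = 4, max_period = 2000)
  expect_true(all(cand$period <= 2000))
})

test_that("wraparound scores follow the stated weights exactly", {
  s <- strrep("ACGT", 10)
  expect_equal(wraparound_align(s, "ACGT", alignment = FALSE), 80)
  s1 <- paste0(substr(s, 1, 20), "C", substr(s, 22, 40)) # one substitution
  expect_equal(wraparound_align(s1, "ACGT", alignment = FALSE),
               2 * 39 - 7)
  expect_error(wraparound_align("", "ACGT"), "non-empty")
})

test_that("wraparound equals the exhaustive DP oracle on random pairs", {
  set.seed(42)
  params <- scoring_params()
  for (i in 1:400) {
    s <- random_seq(sample(2:24, 1))
    m <- random_seq(sample(1:8, 1))
    expect_equal(wraparound_align(s, m, params, alignment = FALSE),
                 wdp_oracle(s, m))
  }
})

test_that("wraparound alignment columns walk the monomer cyclically", {
  aln <- wraparound_align(strrep("ACGT", 3), "ACGT")
  expect_equal(aln$score, 24)
  expect_equal(aln$columns, rep(1:4, 3))
})

test_that("consensus recovers the monomer under scattered substitutions", {
  expect_equal(consensus_monomer(strrep("ACGT", 12), 4), "ACGT")
  set.seed(5)
  mono <- generate_monomer(40, 0.5, 77)
  copies <- rep(mono, 5)
  substr(copies[3], 11, 11) <- setdiff(c("A", "C", "G", "T"),
                                       substr(mono, 11, 11))[1]
  arr <- paste(copies, collapse = "")
  expect_equal(consensus_monomer(arr, 40), mono)
  expect_equal(consensus_monomer(arr, 40), consensus_oracle(arr, 40))
  expect_error(consensus_monomer("ACGTACG", 4), "half")
})

test_that("consensus ties break to the alphabetically first base", {
  # two copies disagreeing in one column, no majority
  arr <- paste0("AAGG", "AATG") # column 3: G vs T -> G
  expect_equal(consensus_monomer(arr, 4), "AAGG")
})

test_that("detection annotates exact arrays and enforces the score floor", {
  ann <- detect_tandem_repeats(strrep("ACGT", 12))
  expect_equal(nrow(ann), 1)
  expect_equal(ann$period, 4)
  expect_equal(ann$score, 96)
  expect_equal(ann$copy_number, 12)
  expect_equal(ann$consensus, "ACGT")
  # 24 bp perfect array scores 48 < 50: rejected
  expect_equal(nrow(detect_tandem_repeats(strrep("ACGT", 6))), 0)
})

test_that("perfect arrays score 2x length; < 25 bp can never pass", {
  set.seed(8)
  for (p in c(5, 12, 51)) {
    mono <- generate_monomer(p, 0.5, p)
    for (copies in c(3, 6)) {
      arr <- strrep(mono, copies)
      expect_equal(wraparound_align(arr, mono, alignment = FALSE),
                   2 * nchar(arr))
    }
  }
  # score floor: 2 * 25 = 50 is the detection boundary
  expect_lt(2 * 24, 50)
  for (p in 2:12) {
    arr <- strrep(generate_monomer(p, 0.5, p), max(2, 24 %/% p))
    arr <- substr(arr, 1, 24)
    expect_equal(nrow(detect_tandem_repeats(arr)), 0)
  }
})

test_that("planted mutated arrays are recovered with the right period", {
  set.seed(184)
  hits <- 0
  n_rep <- 20
  for (i in seq_len(n_rep)) {
    spec <- repeat_family_spec("u", monomer_length = 184, n_arrays = 1,
                               copies_per_array = 10,
                               per_copy_mutation_rate = 0.01)
    built <- build_genome(genome_spec(3000, gc = 0.45, families = list(spec),
                                      seed = 7000 + i))
    ints <- built$truth$intervals
    arr <- substr(built$genome, ints$start[1] + 1, ints$end[1])
    ann <- detect_tandem_repeats(arr)
    if (nrow(ann) >= 1 &&
        abs(ann$period[1] - 184) <= 1 &&
        monomer_edit_distance(ann$consensus[1],
                              built$truth$families$monomer) <= 2) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 0.95 * n_rep)
})

test_that("random contigs are discarded; tandem contigs are kept", {
  set.seed(99)
  contigs <- tibble::tibble(
    id = c("t1", "r1", "r2"),
    seq = c(strrep(generate_monomer(60, 0.5, 4), 8),
            random_seq(400), random_seq(700)))
  out <- filter_tandem_contigs(contigs, quiet = TRUE)
  expect_equal(out$tandem$id, "t1")
  expect_equal(sort(out$discarded$id), c("r1", "r2"))
  expect_equal(nrow(out$tandem) + nrow(out$discarded), nrow(contigs))
  # empty input
  empty <- filter_tandem_contigs(contigs[0, ], quiet = TRUE)
  expect_equal(nrow(empty$tandem), 0)
  expect_equal(nrow(empty$discarded), 0)
})

test_that("canonical monomer is rotation- and strand-invariant", {
  expect_equal(canonical_monomer("CGTA"), "ACGT")
  set.seed(12)
  for (i in 1:20) {
    x <- random_seq(sample(5:60, 1))
    expect_equal(canonical_monomer(x), canonical_monomer(revcomp(x)))
    rot <- sample(nchar(x) - 1, 1)
    rotated <- paste0(substr(x, rot + 1, nchar(x)), substr(x, 1, rot))
    expect_equal(canonical_monomer(x), canonical_monomer(rotated))
    expect_equal(canonical_monomer(canonical_monomer(x)),
                 canonical_monomer(x))
  }
})
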