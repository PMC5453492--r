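test_that("generate_monomer returns primitive sequences of the right length", {
  for (len in c(4, 180, 350)) {
    m <- generate_monomer(len, gc = 0.46, seed = 5)
    expect_equal(nchar(m), len)
    # no perfect sub-period
    for (p in seq_len(len - 1)) {
      if (len %% p == 0) expect_false(strrep(substr(m, 1, p), len / p) == m)
    }
  }
  expect_identical(generate_monomer(50, 0.5, 9), generate_monomer(50, 0.5, 9))
  expect_error(generate_monomer(1), "\\[2, 2000\\]")
  expect_error(generate_monomer(2001), "\\[2, 2000\\]")
})

test_that("build_genome plants families at the exact specified fractions", {
  spec <- genome_spec(
    length = 100000, gc = 0.5, seed = 3,
    families = list(
      repeat_family_spec("famA", monomer_length = 100, n_arrays = 2,
                         copies_per_array = 50))) # 10,000 bases
  built <- build_genome(spec)
  expect_equal(nchar(built$genome), 100000)
  tf <- built$truth$families
  expect_equal(tf$planted_bases, 10000)
  expect_equal(tf$true_fraction, 0.10)
  expect_equal(built$truth$total_tandem_fraction, 0.10)
  # intervals really contain the planted (possibly reverse-complemented) arrays
  ints <- built$truth$intervals
  expect_equal(sum(ints$end - ints$start), 10000)
  mono <- tf$monomer
  for (i in seq_len(nrow(ints))) {
    arr <- substr(built$genome, ints$start[i] + 1, ints$end[i])
    if (ints$strand[i] == "-") arr <- revcomp(arr)
    expect_equal(arr, strrep(mono, 50))
  }
})

test_that("three planted families appear verbatim in the truth table", {
  spec <- genome_spec(
    length = 500000, gc = 0.5, seed = 8,
    families = list(
      repeat_family_spec("a", monomer_length = 100, n_arrays = 1,
                         copies_per_array = 500),  # 0.10
      repeat_family_spec("b", monomer_length = 250, n_arrays = 1,
                         copies_per_array = 100),  # 0.05
      repeat_family_spec("c", monomer_length = 100, n_arrays = 1,
                         copies_per_array = 50))) # 0.01
  truth <- build_genome(spec)$truth
  expect_equal(truth$families$true_fraction, c(0.10, 0.05, 0.01))
  expect_equal(truth$total_tandem_fraction, 0.16)
  expect_true(all(truth$families$canonical_monomer ==
                    canonical_monomer(truth$families$monomer)))
})

test_that("a repeat-free genome has zero tandem truth", {
  built <- build_genome(genome_spec(length = 10000, seed = 2))
  expect_equal(built$truth$total_tandem_fraction, 0)
  expect_equal(nrow(built$truth$families), 0)
  expect_equal(nchar(built$genome), 10000)
})

test_that("genome building is deterministic and rejects infeasible packing", {
  spec <- genome_spec(length = 50000, seed = 4, families = list(
    repeat_family_spec("x", monomer_length = 150, n_arrays = 2,
                       copies_per_array = 20)))
  expect_identical(build_genome(spec)$genome, build_genome(spec)$genome)
  expect_error(
    genome_spec(length = 1000, families = list(
      repeat_family_spec("x", monomer_length = 150, n_arrays = 2,
                         copies_per_array = 20))),
    "exceed")
})

test_that("shotgun read count follows the coverage arithmetic", {
  g <- random_seq(10000)
  expect_equal(nrow(shotgun_reads(g, 0.05, 150, seed = 1)),
               ceiling(0.05 * 10000 / 150))
  # the survey design's numbers: 1 Mb at 0.05X with 150 bp reads -> 334
  expect_equal(ceiling(0.05 * 1e6 / 150), 334)
  expect_error(shotgun_reads(g, 0), "coverage")
  expect_error(shotgun_reads(g, 0.1, read_length = 20000), "exceeds")
})

test_that("error-free reads are exact genome substrings (either strand)", {
  g <- random_seq(5000)
  reads <- shotgun_reads(g, 1, 100, error_rate = 0, seed = 7)
  grc <- revcomp(g)
  hit <- vapply(reads$seq, function(s) {
    grepl(s, g, fixed = TRUE) || grepl(s, grc, fixed = TRUE)
  }, logical(1))
  expect_true(all(hit))
  expect_true(all(nchar(reads$seq) == 100))
  # determinism
  again <- shotgun_reads(g, 1, 100, error_rate = 0, seed = 7)
  expect_identical(reads$seq, again$seq)
})

test_that("read sampling of planted arrays is unbiased over seeds", {
  spec <- genome_spec(
    length = 200000, gc = 0.5, seed = 21,
    families = list(repeat_family_spec("a", monomer_length = 180,
                                       n_arrays = 2,
                                       copies_per_array = 111))) # ~0.1998
  built <- build_genome(spec)
  truth_frac <- built$truth$total_tandem_fraction
  ints <- built$truth$intervals
  n_reads_total <- 0
  n_inside <- 0
  for (s in 1:20) {
    reads <- shotgun_reads(built$genome, 0.5, 150, seed = 100 + s)
    starts <- attr(reads, "layout")$start
    n_reads_total <- n_reads_total + length(starts)
    n_inside <- n_inside +
      sum(vapply(starts, function(x) any(x >= ints$start & x < ints$end),
                 logical(1)))
  }
  p_hat <- n_inside / n_reads_total
  sd3 <- 3 * sqrt(truth_frac * (1 - truth_frac) / n_reads_total)
  expect_lt(abs(p_hat - truth_frac), sd3)
})

test_that("substitution errors hit at about the requested rate", {
  g <- random_seq(5000)
  reads <- shotgun_reads(g, 2, 100, error_rate = 0.02, seed = 3)
  layout <- attr(reads, "layout")
  originals <- substring(g, layout$start + 1, layout$start + 100)
  rc <- layout$strand == "-"
  originals[rc] <- revcomp(originals[rc])
  mism <- sum(mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, reads$seq, originals))
  total <- sum(nchar(reads$seq))
  expect_gt(mism / total, 0.013)
  expect_lt(mism / total, 0.027)
})
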