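# small end-to-end fixture shared by the extraction tests
extraction_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    spec <- genome_spec(
      length = 300000, gc = 0.46, seed = 301,
      families = list(
        repeat_family_spec("big", monomer_length = 150, n_arrays = 2,
                           copies_per_array = 100),  # 10%
        repeat_family_spec("mid", monomer_length = 220, n_arrays = 1,
                           copies_per_array = 68),   # ~5%
        repeat_family_spec("small", monomer_length = 90, n_arrays = 1,
                           copies_per_array = 33)))  # ~1%
    built <- build_genome(spec)
    reads <- shotgun_reads(built$genome, 7.5, 150, seed = 302)
    ctg <- assemble_contigs(reads$seq, quiet = TRUE)
    det <- filter_tandem_contigs(ctg, quiet = TRUE)
    rec <- recruit_reads(reads$seq, det$tandem, quiet = TRUE)
    cache <<- list(truth = built$truth, reads = reads, det = det, rec = rec)
    cache
  }
})

test_that("homologs are found through rotation and strand", {
  set.seed(30)
  mono <- generate_monomer(180, 0.5, 31)
  rot <- paste0(substr(mono, 61, 180), substr(mono, 1, 60))
  contigs <- tibble::tibble(
    id = c("exact", "rotated", "rc", "random"),
    seq = c(strrep(mono, 3), strrep(rot, 3), revcomp(strrep(mono, 3)),
            random_seq(540)))
  homs <- find_homologs(mono, contigs)
  expect_true(all(c("exact", "rotated", "rc") %in% homs))
  expect_false("random" %in% homs)
  detail <- attr(homs, "detail")
  expect_true(all(detail$evalue[detail$homolog] <= 0.1))
})

test_that("random contigs are almost never called homologous", {
  set.seed(33)
  contigs <- tibble::tibble(id = sprintf("r%03d", 1:100),
                            seq = replicate(100, random_seq(500)))
  homs <- find_homologs(random_seq(180), contigs)
  expect_lte(length(homs), 1) # >= 99 of 100 non-homologs
})

test_that("one planted family collapses to a single family", {
  spec <- genome_spec(
    length = 100000, gc = 0.46, seed = 41,
    families = list(repeat_family_spec("only", monomer_length = 160,
                                       n_arrays = 2, copies_per_array = 40)))
  built <- build_genome(spec)
  reads <- shotgun_reads(built$genome, 7.5, 150, seed = 42)
  ctg <- assemble_contigs(reads$seq, quiet = TRUE)
  det <- filter_tandem_contigs(ctg, quiet = TRUE)
  rec <- recruit_reads(reads$seq, det$tandem, quiet = TRUE)
  fams <- extract_top_families(det$tandem, det$annotations, rec,
                               n_families = 4, quiet = TRUE)
  expect_equal(nrow(fams), 1) # iterations 2..4 find an empty pool
  expect_setequal(fams$members[[1]], det$tandem$id)
  expect_lte(monomer_edit_distance(fams$seed_monomer[1],
                                   built$truth$families$monomer[1]), 2)
})

test_that("extraction recovers planted rank order with disjoint members", {
  fx <- extraction_fixture()
  fams <- extract_top_families(fx$det$tandem, fx$det$annotations, fx$rec,
                               quiet = TRUE)
  expect_equal(nrow(fams), 3)
  # greedy consistency: family 1 seeds on the max-count eligible contig
  expect_equal(fams$seed_contig_id[1],
               names(which.max(fx$rec$counts)))
  # rank order matches planted abundance order
  truth_order <- fx$truth$families$name[
    order(-fx$truth$families$true_fraction)]
  matched <- vapply(seq_len(3), function(i) {
    d <- utils::adist(fams$canonical_monomer[i],
                      fx$truth$families$canonical_monomer)
    fx$truth$families$name[which.min(d)]
  }, character(1))
  expect_equal(matched, truth_order)
  # disjoint membership
  all_members <- unlist(fams$members)
  expect_equal(anyDuplicated(all_members), 0)
})

test_that("family composition is close to truth and bounded by the total", {
  fx <- extraction_fixture()
  fams <- extract_top_families(fx$det$tandem, fx$det$annotations, fx$rec,
                               quiet = TRUE)
  total <- total_tandem_fraction(fx$rec)
  fracs <- vapply(seq_len(nrow(fams)), function(i) {
    family_composition(fams[i, ], fx$reads$seq, fx$det$tandem)$fraction
  }, numeric(1))
  n <- fx$rec$total_reads
  for (i in seq_len(nrow(fams))) {
    d <- utils::adist(fams$canonical_monomer[i],
                      fx$truth$families$canonical_monomer)
    tf <- fx$truth$families$true_fraction[which.min(d)]
    expect_lt(abs(fracs[i] - tf), 3 * sqrt(tf * (1 - tf) / n))
  }
  expect_gte(total, max(fracs))
  expect_lte(sum(fracs),
             total + 3 * sqrt(total * (1 - total) / n))
})

test_that("a doubled-monomer reference removes fragment-length bias", {
  fx <- extraction_fixture()
  fams <- extract_top_families(fx$det$tandem, fx$det$annotations, fx$rec,
                               quiet = TRUE)
  fam <- fams[1, ]
  full <- family_composition(fam, fx$reads$seq, fx$det$tandem)$fraction
  # monomer-only (doubled) reference, no member contigs
  alone <- fam
  alone$members <- list(character())
  mono_only <- family_composition(alone, fx$reads$seq,
                                  fx$det$tandem)$fraction
  n <- fx$rec$total_reads
  expect_lt(abs(full - mono_only), sqrt(full * (1 - full) / n))
})

test_that("empty pools and zero recruits are handled", {
  fx <- extraction_fixture()
  empty_fams <- extract_top_families(fx$det$tandem[0, ],
                                     fx$det$annotations[0, ], fx$rec,
                                     quiet = TRUE)
  expect_equal(nrow(empty_fams), 0)
  fams <- extract_top_families(fx$det$tandem, fx$det$annotations, fx$rec,
                               quiet = TRUE)
  off_target <- family_composition(fams[1, ],
                                   replicate(50, random_seq(150)),
                                   fx$det$tandem)
  expect_equal(off_target$fraction, 0)
})

test_that("the top repeat is classified against a known library", {
  fx <- extraction_fixture()
  fams <- extract_top_families(fx$det$tandem, fx$det$annotations, fx$rec,
                               quiet = TRUE)
  fam <- fams[1, ]
  # exact match
  known <- tibble::tibble(name = c("centromeric_rep", "other"),
                          monomer = c(fam$seed_monomer, random_seq(300)))
  hit <- classify_top_repeat(fam, known)
  expect_true(hit$matched)
  expect_equal(hit$name, "centromeric_rep")
  expect_equal(hit$length_diff, 0L)
  # empty library
  expect_false(classify_top_repeat(fam, known[0, ])$matched)
  # 5% diverged entry still matches at E <= 0.1
  set.seed(61)
  ch <- strsplit(fam$seed_monomer, "")[[1]]
  idx <- sample(length(ch), round(0.05 * length(ch)))
  ch[idx] <- vapply(ch[idx], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  known2 <- tibble::tibble(name = "diverged", monomer = paste(ch, collapse = ""))
  expect_true(classify_top_repeat(fam, known2)$matched)
})
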