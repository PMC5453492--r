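make_contigs <- function(seqs, ids = sprintf("c%d", seq_along(seqs))) {
  tibble::tibble(id = ids, seq = seqs, length = nchar(seqs),
                 n_reads = NA_integer_, is_cycle = FALSE,
                 cycle_period = NA_integer_)
}

test_that("an exact substring read hits its contig at identity 1", {
  set.seed(3)
  contig <- random_seq(600)
  read <- substr(contig, 101, 250)
  res <- recruit_reads(read, make_contigs(contig), quiet = TRUE)
  expect_equal(unname(res$counts), 1)
  expect_equal(res$hits$identity, 1)
  # reverse-complement placement also found
  res2 <- recruit_reads(revcomp(read), make_contigs(contig), quiet = TRUE)
  expect_equal(unname(res2$counts), 1)
})

test_that("multi-mapping reads count per contig but once toward the total", {
  set.seed(4)
  c1 <- random_seq(500)
  c2 <- paste0(random_seq(100), substr(c1, 51, 450), random_seq(100))
  read <- substr(c1, 151, 300)
  res <- recruit_reads(read, make_contigs(c(c1, c2)), quiet = TRUE)
  expect_equal(unname(res$counts), c(1, 1))
  expect_equal(res$total_tandem_reads, 1)
  expect_equal(nrow(res$hits), 2)
})

test_that("random reads never hit unrelated contigs", {
  set.seed(5)
  contigs <- make_contigs(replicate(5, random_seq(800)))
  reads <- replicate(1000, random_seq(150))
  res <- recruit_reads(reads, contigs, min_identity = 0.9, quiet = TRUE)
  expect_equal(sum(res$counts), 0)
  expect_equal(res$total_tandem_reads, 0)
  expect_equal(total_tandem_fraction(res), 0)
  # independent check on a subsample with a full local aligner
  sub <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(reads[1:20]),
    Biostrings::DNAString(contigs$seq[1]), type = "local")
  cov_ok <- Biostrings::nchar(Biostrings::pattern(sub)) >= 120
  ident_ok <- Biostrings::pid(sub) >= 90
  expect_equal(sum(cov_ok & ident_ok), 0)
})

test_that("partial overlaps at contig ends obey the 80% coverage rule", {
  set.seed(6)
  contig <- random_seq(400)
  lead <- random_seq(60)
  # 90 bp overlap (60%): rejected; 130 bp overlap (87%): accepted
  r_low <- paste0(lead, substr(contig, 1, 90))
  r_hi <- paste0(substr(lead, 41, 60), substr(contig, 1, 130))
  res <- recruit_reads(c(r_low, r_hi), make_contigs(contig), quiet = TRUE)
  expect_equal(unname(res$counts), 1)
  expect_equal(res$hits$read_id, "read_000002")
})

test_that("lowering min_identity never loses hits", {
  set.seed(8)
  contig <- random_seq(500)
  reads <- vapply(1:50, function(i) {
    s <- sample(300, 1)
    r <- substr(contig, s, s + 149)
    # up to ~10% scattered substitutions
    n_mut <- sample(0:15, 1)
    if (n_mut > 0) {
      ch <- strsplit(r, "")[[1]]
      idx <- sample(150, n_mut)
      ch[idx] <- vapply(ch[idx], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      r <- paste(ch, collapse = "")
    }
    r
  }, character(1))
  cts <- make_contigs(contig)
  strict <- recruit_reads(reads, cts, min_identity = 0.95, quiet = TRUE)
  loose <- recruit_reads(reads, cts, min_identity = 0.85, quiet = TRUE)
  expect_gte(unname(loose$counts), unname(strict$counts))
  expect_gt(unname(loose$counts), 0)
})

test_that("hit-union conservation holds", {
  set.seed(9)
  c1 <- random_seq(400)
  c2 <- random_seq(400)
  reads <- c(substr(c1, 1, 150), substr(c1, 100, 249), substr(c2, 50, 199),
             random_seq(150))
  res <- recruit_reads(reads, make_contigs(c(c1, c2)), quiet = TRUE)
  expect_equal(res$total_tandem_reads, length(unique(res$hits$read_id)))
  expect_lte(res$total_tandem_reads, res$total_reads)
})

test_that("contig ranking orders by count, then length, then id", {
  res <- structure(list(
    counts = c(A = 100, B = 50, C = 50, D = 120),
    contig_lengths = c(A = 500, B = 300, C = 400, D = 250),
    total_reads = 1000, total_tandem_reads = 320,
    hits = NULL), class = "recruitment_result")
  ann <- tibble::tibble(contig_id = c("A", "B", "C", "D"),
                        start = 0L, end = 100L,
                        period = c(170L, 60L, 60L, 20L),
                        consensus = "X", score = c(90L, 80L, 80L, 70L),
                        copy_number = 2)
  ranked <- rank_contigs(res, ann)
  # D has the top count but a 20 bp monomer: not eligible to lead
  expect_equal(as.character(ranked), c("A", "C", "B", "D"))
  expect_false(attr(ranked, "eligible")[4])
  expect_error(rank_contigs(res, ann[-1, ]), "annotation")
})

test_that("total fraction spans its boundary cases", {
  set.seed(10)
  contig <- random_seq(500)
  inside <- vapply(1:20, function(i) {
    s <- sample(350, 1); substr(contig, s, s + 149)
  }, character(1))
  res_all <- recruit_reads(inside, make_contigs(contig), quiet = TRUE)
  expect_equal(total_tandem_fraction(res_all), 1)
  res_none <- recruit_reads(replicate(20, random_seq(150)),
                            make_contigs(contig), quiet = TRUE)
  expect_equal(total_tandem_fraction(res_none), 0)
  res_none$total_reads <- 0
  expect_error(total_tandem_fraction(res_none), "no reads")
})

test_that("recruited fraction tracks a planted fraction within 3 SD", {
  spec <- genome_spec(
    length = 200000, gc = 0.46, seed = 77,
    families = list(repeat_family_spec("a", monomer_length = 180,
                                       n_arrays = 2,
                                       copies_per_array = 72))) # 12.96%
  built <- build_genome(spec)
  truth <- built$truth$total_tandem_fraction
  reads <- shotgun_reads(built$genome, 7.5, 150, seed = 78)
  ctg <- assemble_contigs(reads$seq, quiet = TRUE)
  det <- filter_tandem_contigs(ctg, quiet = TRUE)
  expect_gte(nrow(det$tandem), 1)
  res <- recruit_reads(reads$seq, det$tandem, quiet = TRUE)
  est <- total_tandem_fraction(res)
  sd3 <- 3 * sqrt(truth * (1 - truth) / res$total_reads)
  expect_lt(abs(est - truth), sd3)
})
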