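#' K-mer multiplicity noise threshold
#'
#' Minimum canonical k-mer multiplicity retained by the assembler. Singleton
#' k-mers are overwhelmingly sequencing-error artifacts at survey coverage,
#' so the floor is 2; at high coverage the threshold scales with the mean
#' retained multiplicity (monotone non-decreasing in total read count for a
#' fixed genome).
#'
#' @param reads tibble of reads (`id`, `seq`) or character vector.
#' @param k k-mer size.
#' @return integer threshold (>= 2).
#' @export
kmer_noise_threshold <- function(reads, k) {
  seqs <- read_seqs(reads)
  if (length(seqs) == 0) stop("empty read set", call. = FALSE)
  s <- kmer_count_summary_cpp(seqs, as.integer(k))
  max(2L, as.integer(s$mean / 10))
}

#' Canonical k-mer counts of a read set
#'
#' @param reads tibble of reads or character vector of sequences.
#' @param k k-mer size (<= 32).
#' @return tibble with columns `kmer`, `count` (canonical k-mers).
#' @export
kmer_counts <- function(reads, k) {
  as_tibble(kmer_count_table_cpp(read_seqs(reads), as.integer(k)))
}

#' @noRd
read_seqs <- function(reads) {
  if (is.data.frame(reads)) reads$seq else as.character(reads)
}

#' Assemble shotgun reads into repeat-tolerant contigs
#'
#' A de Bruijn graph assembler tuned for high-copy repeats at survey
#' coverage. Canonical k-mers below the noise threshold are removed, tandem
#' arrays (which collapse to short cycles in the graph) are recovered by a
#' count-dominant cycle search and unrolled to 3 monomer periods so the
#' tandem detector sees multiple copies, and the remaining graph is reduced
#' to maximal non-branching paths with conservative truncation at branches.
#' Contigs shorter than `min_contig_length` are discarded ("unassembled
#' reads" at this length floor never survive).
#'
#' @param reads tibble of reads (`id`, `seq`) or character vector.
#' @param k odd k-mer size, `11 <= k < read_length`.
#' @param min_contig_length minimum retained contig length (default 200).
#' @param min_kmer_count k-mer noise threshold; `NULL` (default) uses
#'   [kmer_noise_threshold()].
#' @param max_period largest tandem period of interest; bounds the cycle
#'   search (default 2000).
#' @param quiet suppress progress logging.
#' @return tibble of contigs: `id`, `seq`, `length`, `n_reads` (reads
#'   sharing a k-mer with the contig), `is_cycle`, `cycle_period`.
#' @export
assemble_contigs <- function(reads, k = 31L, min_contig_length = 200L,
                             min_kmer_count = NULL, max_period = 2000L,
                             quiet = getOption("satseeker.quiet", FALSE)) {
  seqs <- read_seqs(reads)
  if (length(seqs) == 0) {
    return(empty_contigs())
  }
  k <- as.integer(k)
  read_len <- max(nchar(seqs))
  if (k %% 2 == 0) stop("k must be odd", call. = FALSE)
  if (k < 11) stop("k must be >= 11", call. = FALSE)
  if (k >= read_len) stop("k must be smaller than the read length",
                          call. = FALSE)
  if (min_contig_length < k) stop("min_contig_length must be >= k",
                                  call. = FALSE)
  if (is.null(min_kmer_count)) min_kmer_count <- kmer_noise_threshold(seqs, k)
  res <- assemble_cpp(seqs, k, as.integer(min_kmer_count),
                      as.integer(min_contig_length), as.integer(max_period))
  n <- length(res$seq)
  out <- tibble(
    id = sprintf("contig_%05d", seq_len(n)),
    seq = as.character(res$seq),
    length = nchar(as.character(res$seq)),
    n_reads = res$n_reads,
    is_cycle = res$is_cycle,
    cycle_period = res$period
  )
  ss_log(sprintf("assembled %d reads -> %d contigs (%d cyclic) at k=%d, min count %d",
                 length(seqs), n, sum(out$is_cycle), k, min_kmer_count),
         quiet = quiet)
  out
}

#' @noRd
empty_contigs <- function() {
  tibble(id = character(), seq = character(), length = integer(),
         n_reads = integer(), is_cycle = logical(), cycle_period = integer())
}

#' Write contigs to FASTA
#'
#' The description line records the supporting read count
#' (`>id n_reads=<n>`).
#'
#' @param contigs contig tibble from [assemble_contigs()].
#' @param path output FASTA path.
#' @export
write_contigs <- function(contigs, path) {
  recs <- tibble(id = sprintf("%s n_reads=%d", contigs$id, contigs$n_reads),
                 seq = contigs$seq, qual = NA_character_)
  write_sequences(recs, path, "fasta")
}
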