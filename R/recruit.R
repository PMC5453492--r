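#' Recruit reads to contigs (multi-mapping aware)
#'
#' A read hits a contig iff a shared `seed_k`-mer (either strand) lies on a
#' diagonal whose maximal ungapped segment covers at least `min_read_cov`
#' of the read at identity at least `min_identity`. A read counts once per
#' contig regardless of how many placements it has there, and counts toward
#' every contig it hits; the total tandem read count is the union (a read
#' recruited by several contigs is counted once toward the total). Reads
#' aligning across a contig end are scored on the overlapping part only.
#'
#' @param reads tibble of reads (`id`, `seq`) or character vector.
#' @param contigs contig tibble (`id`, `seq`); must be non-empty.
#' @param seed_k seed k-mer size (default 15).
#' @param min_identity minimum alignment identity in \[0.5, 1\] (default 0.85).
#' @param min_read_cov minimum fraction of the read covered (default 0.80).
#' @param quiet suppress logging.
#' @return a `recruitment_result`: `counts` (named per-contig read counts),
#'   `hits` (tibble `read_id`, `contig_id`, `identity`), `total_reads`,
#'   `total_tandem_reads`, `contig_lengths`.
#' @export
recruit_reads <- function(reads, contigs, seed_k = 15L, min_identity = 0.85,
                          min_read_cov = 0.80,
                          quiet = getOption("satseeker.quiet", FALSE)) {
  if (nrow(contigs) == 0) stop("contigs must be non-empty", call. = FALSE)
  stopifnot(min_identity >= 0.5, min_identity <= 1)
  seqs <- read_seqs(reads)
  ids <- if (is.data.frame(reads)) reads$id else
    sprintf("read_%06d", seq_along(seqs))
  hits <- if (length(seqs) == 0) {
    tibble(read = integer(), contig = integer(), identity = numeric())
  } else {
    as_tibble(recruit_cpp(seqs, contigs$seq, as.integer(seed_k),
                          min_identity, min_read_cov))
  }
  counts <- tabulate(hits$contig, nbins = nrow(contigs))
  names(counts) <- contigs$id
  res <- structure(
    list(counts = counts,
         hits = tibble(read_id = ids[hits$read],
                       contig_id = contigs$id[hits$contig],
                       identity = hits$identity),
         total_reads = length(seqs),
         total_tandem_reads = length(unique(hits$read)),
         contig_lengths = stats::setNames(nchar(contigs$seq), contigs$id)),
    class = "recruitment_result")
  ss_log(sprintf("recruited %d/%d reads to %d contigs",
                 res$total_tandem_reads, res$total_reads, nrow(contigs)),
         quiet = quiet)
  res
}

#' @export
print.recruitment_result <- function(x, ...) {
  cat(sprintf("recruitment: %d/%d reads hit %d contigs\n",
              x$total_tandem_reads, x$total_reads, length(x$counts)))
  invisible(x)
}

#' Rank contigs by recruited reads
#'
#' Contigs are ordered by recruited read count (descending), ties broken by
#' longer contig, then lexicographic id. Contigs whose representative
#' monomer (highest-scoring annotation) is shorter than
#' `min_monomer_length` are not eligible to lead the ranking: eligible
#' contigs are ranked first and ineligible ones appended, so the top-ranked
#' contig is always a valid family seed.
#'
#' @param result a `recruitment_result`.
#' @param annotations annotation tibble ([filter_tandem_contigs()]); every
#'   ranked contig must carry at least one annotation.
#' @param min_monomer_length seed monomer length floor (default 30).
#' @return character vector of contig ids in rank order, with attribute
#'   `eligible` (logical, same order).
#' @export
rank_contigs <- function(result, annotations, min_monomer_length = 30L) {
  ids <- names(result$counts)
  missing <- setdiff(ids, annotations$contig_id)
  if (length(missing)) {
    stop("contig without tandem annotation: ", missing[1], call. = FALSE)
  }
  rep_ann <- representative_annotations(annotations)
  monomer_len <- stats::setNames(rep_ann$period, rep_ann$contig_id)[ids]
  ord <- order(-result$counts, -result$contig_lengths[ids], ids)
  ids <- ids[ord]
  eligible <- monomer_len[ord] >= min_monomer_length
  ranked <- c(ids[eligible], ids[!eligible])
  structure(ranked, eligible = c(eligible[eligible], eligible[!eligible]))
}

#' Total tandem-repeat genomic fraction
#'
#' The proportion of all reads mapping to any tandem contig — the survey
#' estimate of total tandem repeat content.
#'
#' @param result a `recruitment_result`.
#' @return fraction in \[0, 1\].
#' @export
total_tandem_fraction <- function(result) {
  if (result$total_reads == 0) stop("no reads", call. = FALSE)
  result$total_tandem_reads / result$total_reads
}
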