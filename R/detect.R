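#' Tandem repeat scoring parameters
#'
#' The classic tandem-repeat-finder weights: match +2, mismatch -7,
#' indel -7 (per indel base, no affine gaps), minimum reported score 50,
#' maximum period 2000. `pm` is the target per-base match probability that
#' parameterises the deterministic period-candidate filter; `pi` (target
#' indel probability) is carried for completeness but unused under a
#' substitution-only error model.
#'
#' @param match,mismatch,indel alignment weights (`match > 0 > mismatch, indel`).
#' @param min_score minimum wraparound alignment score reported.
#' @param max_period largest period searched, `2 <= max_period <= 2000`.
#' @param pm target match probability for the candidate filter (default 0.80).
#' @param pi target indel probability (reserved; default 0.10).
#' @return a `scoring_params` list.
#' @export
scoring_params <- function(match = 2L, mismatch = -7L, indel = -7L,
                           min_score = 50L, max_period = 2000L,
                           pm = 0.80, pi = 0.10) {
  stopifnot(match > 0, mismatch < 0, indel < 0, min_score > 0,
            max_period >= 2, max_period <= 2000, pm > 0, pm <= 1)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 indel = as.integer(indel), min_score = as.integer(min_score),
                 max_period = as.integer(max_period), pm = pm, pi = pi),
            class = "scoring_params")
}

#' Find candidate tandem periods by k-mer recurrence
#'
#' For each distance `d <= max_period`, support is the number of positions
#' `i` with identical `k`-mers at `i` and `i + d`. Candidates must reach
#' `ceiling(pm * (nchar(seq) - d - k))` support — a deterministic analogue
#' of probabilistic k-tuple seeding at match probability `pm`.
#'
#' @param seq DNA string with `nchar(seq) >= 2 * k`.
#' @param k probe k-mer size (default 4).
#' @param max_period largest period considered.
#' @param pm target per-base match probability (default 0.80).
#' @return tibble (`period`, `support`) sorted by support (desc), period (asc).
#' @export
find_candidate_periods <- function(seq, k = 4L, max_period = 2000L,
                                   pm = 0.80) {
  L <- nchar(seq)
  if (L < 2 * k) stop("sequence shorter than 2k", call. = FALSE)
  maxd <- min(as.integer(max_period), L - k)
  if (maxd < 1) {
    return(tibble(period = integer(), support = integer()))
  }
  support <- period_support_cpp(seq, as.integer(k), maxd)
  period <- seq_len(maxd)
  need <- ceiling(pm * (L - period - k))
  keep <- support >= pmax(need, 1)
  out <- tibble(period = period[keep], support = support[keep])
  arrange(out, desc(.data$support), .data$period)
}

#' Wraparound alignment of a sequence against a cyclic monomer
#'
#' Maximum-scoring global alignment of `seq` against an unbounded cyclic
#' concatenation of `monomer`, with free start and end phase. A perfect
#' c-copy array of a monomer of length p scores `2 * c * p` under the
#' default weights. The per-base column assignment maps each sequence base
#' to a monomer column (1-based) or 0 for an insertion.
#'
#' @param seq DNA string (non-empty).
#' @param monomer monomer string, `1 <= nchar(monomer) <= max_period`.
#' @param params a [scoring_params()].
#' @param alignment return the per-column assignment as well?
#' @return if `alignment`, `list(score =, columns =)`; otherwise the score.
#' @export
wraparound_align <- function(seq, monomer, params = scoring_params(),
                             alignment = TRUE) {
  if (!nzchar(seq) || !nzchar(monomer)) {
    stop("seq and monomer must be non-empty", call. = FALSE)
  }
  if (nchar(monomer) > params$max_period) {
    stop("monomer longer than max_period", call. = FALSE)
  }
  if (alignment) {
    wraparound_align_cpp(seq, monomer, params$match, params$mismatch,
                         params$indel)
  } else {
    wraparound_score_cpp(seq, monomer, params$match, params$mismatch,
                         params$indel)
  }
}

#' Consensus monomer of a period-phased array
#'
#' Per-phase majority vote over the columns of the array read at the given
#' period, refined once by re-voting along a wraparound alignment to the
#' initial consensus. Ties are broken by the alphabetically first base.
#'
#' @param seq array sequence, `nchar(seq) >= 2 * period`.
#' @param period repeat period in bases.
#' @param params a [scoring_params()] (used for the refinement alignment).
#' @return consensus monomer of length `period`.
#' @export
consensus_monomer <- function(seq, period, params = scoring_params()) {
  n <- nchar(seq)
  if (period > n / 2) stop("period exceeds half the sequence", call. = FALSE)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  cols <- ((seq_len(n) - 1L) %% period) + 1L
  cons0 <- vote_columns(chars, cols, period)
  aln <- wraparound_align(seq, cons0, params, alignment = TRUE)
  keep <- aln$columns > 0
  cons1 <- vote_columns(chars[keep], aln$columns[keep], period,
                        fallback = cons0)
  cons1
}

# majority vote per column; ties -> alphabetically first base; empty
# columns fall back to the previous consensus (or "A")
#' @noRd
vote_columns <- function(chars, cols, period, fallback = NULL) {
  fb <- if (is.null(fallback)) rep("A", period) else
    strsplit(fallback, "", fixed = TRUE)[[1]]
  tab <- table(factor(cols, levels = seq_len(period)),
               factor(chars, levels = BASES))
  counts <- matrix(tab, nrow = period)
  best <- max.col(counts, ties.method = "first") # first = alphabetical tie
  out <- BASES[best]
  empty <- rowSums(counts) == 0
  out[empty] <- fb[empty]
  paste(out, collapse = "")
}

#' Detect tandem repeats in a contig
#'
#' Generates candidate periods by k-mer recurrence, derives per-candidate
#' spans and consensus monomers, and scores each span by wraparound
#' alignment. Annotations scoring below `min_score`, with period above
#' `max_period`, or with fewer than 2 copies are discarded. Perfect
#' multiples of an accepted period are suppressed in favour of the
#' primitive period, and overlapping annotations are resolved to the
#' highest score (ties: smaller period). Spans are 0-based half-open.
#'
#' @param contig one contig: a single-row tibble (`id`, `seq`) or a string.
#' @param params a [scoring_params()].
#' @param probe_k candidate-generation k-mer size (default 4).
#' @return tibble: `contig_id`, `start`, `end`, `period`, `consensus`,
#'   `score`, `copy_number`, sorted by `start`.
#' @export
detect_tandem_repeats <- function(contig, params = scoring_params(),
                                  probe_k = 4L) {
  if (is.data.frame(contig)) {
    stopifnot(nrow(contig) == 1)
    id <- contig$id
    seq <- contig$seq
  } else {
    id <- "contig"
    seq <- as.character(contig)
  }
  empty <- tibble(contig_id = character(), start = integer(), end = integer(),
                  period = integer(), consensus = character(),
                  score = integer(), copy_number = numeric())
  L <- nchar(seq)
  if (L < 2 * probe_k) return(empty)
  cand <- find_candidate_periods(seq, k = probe_k,
                                 max_period = params$max_period,
                                 pm = params$pm)
  if (nrow(cand) == 0) return(empty)
  anns <- list()
  for (d in sort(cand$period)) {
    # suppress perfect multiples of an already-accepted primitive period
    skip <- FALSE
    for (a in anns) {
      if (d %% a$period == 0 && d > a$period) skip <- TRUE
    }
    if (skip) next
    pos <- period_positions_cpp(seq, as.integer(probe_k), as.integer(d))
    if (length(pos) == 0) next
    blocks <- split_blocks(pos, gap = d)
    for (b in blocks) {
      start <- b[1]
      end <- min(b[2] + d + probe_k, L)
      if ((end - start) / d < 2) next
      span <- substr(seq, start + 1, end)
      cons <- consensus_monomer(span, d, params)
      score <- wraparound_align(span, cons, params, alignment = FALSE)
      if (score < params$min_score) next
      anns[[length(anns) + 1]] <- list(start = start, end = end, period = d,
                                       consensus = cons, score = score)
    }
  }
  if (length(anns) == 0) return(empty)
  tab <- bind_rows(lapply(anns, function(a) {
    tibble(contig_id = id, start = a$start, end = a$end, period = a$period,
           consensus = a$consensus, score = a$score,
           copy_number = (a$end - a$start) / a$period)
  }))
  resolve_overlaps(arrange(tab, desc(.data$score), .data$period, .data$start))
}

# merge support positions into blocks; a new block starts when the gap to
# the previous support position exceeds the period
#' @noRd
split_blocks <- function(pos, gap) {
  pos <- sort(pos)
  breaks <- which(diff(pos) > gap)
  starts <- c(1, breaks + 1)
  ends <- c(breaks, length(pos))
  lapply(seq_along(starts), function(i) c(pos[starts[i]], pos[ends[i]]))
}

# greedy: keep the best-scoring annotation of each overlapping cluster
#' @noRd
resolve_overlaps <- function(tab) {
  keep <- logical(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (tab$start[i] < tab$end[j] && tab$end[i] > tab$start[j]) {
        ok <- FALSE
        break
      }
    }
    keep[i] <- ok
  }
  arrange(tab[keep, ], .data$start)
}

#' Partition contigs into tandem-containing and tandem-free
#'
#' A contig is retained iff it carries at least one tandem annotation; only
#' retained contigs take part in all downstream analyses. Each retained
#' contig's representative monomer is its highest-scoring annotation.
#'
#' @param contigs contig tibble ([assemble_contigs()]).
#' @param params a [scoring_params()].
#' @param probe_k candidate probe k-mer size.
#' @param quiet suppress logging.
#' @return `list(tandem = <contigs>, annotations = <tibble>,
#'   discarded = <contigs>)`.
#' @export
filter_tandem_contigs <- function(contigs, params = scoring_params(),
                                  probe_k = 4L,
                                  quiet = getOption("satseeker.quiet", FALSE)) {
  anns <- list()
  for (i in seq_len(nrow(contigs))) {
    a <- detect_tandem_repeats(contigs[i, c("id", "seq")], params, probe_k)
    if (nrow(a) > 0) anns[[length(anns) + 1]] <- a
  }
  annotations <- if (length(anns)) bind_rows(anns) else
    tibble(contig_id = character(), start = integer(), end = integer(),
           period = integer(), consensus = character(), score = integer(),
           copy_number = numeric())
  tandem_ids <- unique(annotations$contig_id)
  tandem <- contigs[contigs$id %in% tandem_ids, ]
  discarded <- contigs[!contigs$id %in% tandem_ids, ]
  ss_log(sprintf("tandem detection: %d/%d contigs retained", nrow(tandem),
                 nrow(contigs)), quiet = quiet)
  list(tandem = tandem, annotations = annotations, discarded = discarded)
}

#' @noRd
representative_annotations <- function(annotations) {
  if (nrow(annotations) == 0) return(annotations)
  ord <- arrange(annotations, .data$contig_id, desc(.data$score),
                 .data$period)
  ord[!duplicated(ord$contig_id), ]
}

#' Canonical form of a cyclic monomer
#'
#' The lexicographically least string among all rotations of the monomer
#' and all rotations of its reverse complement. Canonical forms make
#' monomers comparable across contigs and strands; the map is idempotent.
#'
#' @param monomer non-empty DNA string.
#' @return canonical monomer string.
#' @export
canonical_monomer <- function(monomer) {
  stopifnot(nzchar(monomer))
  vapply(monomer, function(m) {
    n <- nchar(m)
    dbl <- paste0(m, m)
    rots <- substring(dbl, seq_len(n), seq_len(n) + n - 1L)
    rc <- revcomp(m)
    dblrc <- paste0(rc, rc)
    rots_rc <- substring(dblrc, seq_len(n), seq_len(n) + n - 1L)
    min(c(rots, rots_rc))
  }, character(1), USE.NAMES = FALSE)
}
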