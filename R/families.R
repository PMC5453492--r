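#' Homology search parameters
#'
#' Ungapped seeded local alignment with Karlin-Altschul E-values:
#' `E = K * m * n * exp(-lambda * S)` where `m` is the (undoubled) query
#' monomer length, `n` the total length of the searched contig pool, and
#' `S` the best seeded ungapped segment score. `lambda` is solved from the
#' match/mismatch weights at equal base frequencies; `K` defaults to the
#' standard tabulated value for +1/-2.
#'
#' @param evalue_max homology threshold (default 0.1).
#' @param word_size exact-word seed length (default 11).
#' @param match,mismatch ungapped alignment weights (default +1/-2).
#' @param lambda Karlin-Altschul lambda; `NULL` (default) solves it from
#'   the weights.
#' @param K Karlin-Altschul K (default 0.621).
#' @param search_space override for `m * n`; `NULL` computes it per search.
#' @return a `homology_params` list.
#' @export
homology_params <- function(evalue_max = 0.1, word_size = 11L, match = 1L,
                            mismatch = -2L, lambda = NULL, K = 0.621,
                            search_space = NULL) {
  stopifnot(evalue_max > 0, word_size >= 4, match > 0, mismatch < 0)
  if (is.null(lambda)) lambda <- karlin_lambda(match, mismatch)
  structure(list(evalue_max = evalue_max, word_size = as.integer(word_size),
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 lambda = lambda, K = K, search_space = search_space),
            class = "homology_params")
}

#' Karlin-Altschul lambda for match/mismatch weights
#'
#' Solves `sum_ij p_i p_j exp(lambda * s_ij) = 1` at equal base frequencies,
#' i.e. `exp(lambda * match) / 4 + 3 * exp(lambda * mismatch) / 4 = 1`.
#'
#' @param match,mismatch integer weights, `match > 0 > mismatch`.
#' @return lambda (positive real).
#' @export
karlin_lambda <- function(match, mismatch) {
  f <- function(l) exp(l * match) / 4 + 3 * exp(l * mismatch) / 4 - 1
  stats::uniroot(f, c(1e-6, 10), tol = 1e-10)$root
}

#' @noRd
evalue_of <- function(score, m, n, params) {
  space <- if (is.null(params$search_space)) m * n else params$search_space
  params$K * space * exp(-params$lambda * score)
}

#' Find contigs homologous to a seed monomer
#'
#' The seed monomer is doubled before searching so rotated copies in other
#' contigs are found (cyclic identity is real for tandem monomers); the
#' E-value search space still uses the undoubled monomer length. A contig
#' is a homolog iff its best seeded ungapped segment reaches
#' `E <= evalue_max`. The seed's own contig, when named, is always included.
#'
#' @param seed_monomer monomer string.
#' @param contigs contig tibble (`id`, `seq`).
#' @param params a [homology_params()].
#' @param seed_contig_id id of the contig the seed came from (always kept).
#' @return character vector of homolog contig ids, with attribute `detail`
#'   (tibble `contig_id`, `score`, `evalue`, `homolog`).
#' @export
find_homologs <- function(seed_monomer, contigs, params = homology_params(),
                          seed_contig_id = NULL) {
  stopifnot(nzchar(seed_monomer))
  if (nrow(contigs) == 0) {
    return(structure(character(),
                     detail = tibble(contig_id = character(),
                                     score = integer(), evalue = numeric(),
                                     homolog = logical())))
  }
  doubled <- paste0(seed_monomer, seed_monomer)
  scores <- seeded_ungapped_best_cpp(doubled, contigs$seq, params$word_size,
                                     params$match, params$mismatch)
  m <- nchar(seed_monomer)
  n <- sum(nchar(contigs$seq))
  ev <- evalue_of(scores, m, n, params)
  hom <- ev <= params$evalue_max
  if (!is.null(seed_contig_id)) hom <- hom | contigs$id == seed_contig_id
  detail <- tibble(contig_id = contigs$id, score = as.integer(scores),
                   evalue = ev, homolog = hom)
  structure(contigs$id[hom], detail = detail)
}

#' Extract the top tandem-repeat families by seed-and-remove clustering
#'
#' Iterates up to `n_families` times: rank the remaining tandem contigs by
#' recruited reads (seeds need a monomer of at least `min_monomer_length`),
#' take the top contig's consensus monomer as the family seed, absorb all
#' contigs with homology to the (doubled) seed at `E <= evalue_max`, record
#' the family, and remove its members from the pool. Stops early when the
#' pool empties or no eligible seed remains. Families are mutually disjoint
#' over contigs by construction.
#'
#' @param contigs tandem contig tibble ([filter_tandem_contigs()]`$tandem`).
#' @param annotations matching annotation tibble.
#' @param recruitment `recruitment_result` over the same contigs.
#' @param n_families maximum families to extract (default 4; abundance is
#'   typically negligible after the 4th).
#' @param min_monomer_length seed monomer floor (default 30); homolog
#'   members have no length floor.
#' @param params a [homology_params()].
#' @param quiet suppress logging.
#' @return tibble of families: `rank`, `seed_contig_id`, `seed_monomer`
#'   (as detected), `canonical_monomer`, `monomer_length`, `members`
#'   (list-column of contig ids), `n_members`, `seed_reads`.
#' @export
extract_top_families <- function(contigs, annotations, recruitment,
                                 n_families = 4L, min_monomer_length = 30L,
                                 params = homology_params(),
                                 quiet = getOption("satseeker.quiet", FALSE)) {
  stopifnot(n_families >= 1)
  empty <- tibble(rank = integer(), seed_contig_id = character(),
                  seed_monomer = character(), canonical_monomer = character(),
                  monomer_length = integer(), members = list(),
                  n_members = integer(), seed_reads = integer())
  pool <- contigs
  rep_ann <- representative_annotations(annotations)
  out <- list()
  for (i in seq_len(n_families)) {
    if (nrow(pool) == 0) {
      ss_log(sprintf("family extraction stopped early: pool empty after %d famil%s",
                     length(out), if (length(out) == 1) "y" else "ies"),
             quiet = quiet)
      break
    }
    sub <- recruitment
    sub$counts <- recruitment$counts[pool$id]
    ranked <- rank_contigs(sub, annotations[annotations$contig_id %in% pool$id, ],
                           min_monomer_length)
    if (!attr(ranked, "eligible")[1]) {
      ss_log("family extraction stopped: no contig with an eligible seed monomer",
             quiet = quiet)
      break
    }
    top <- ranked[1]
    seed <- rep_ann$consensus[rep_ann$contig_id == top]
    members <- find_homologs(seed, pool, params, seed_contig_id = top)
    out[[i]] <- tibble(
      rank = i, seed_contig_id = top, seed_monomer = seed,
      canonical_monomer = canonical_monomer(seed),
      monomer_length = nchar(seed), members = list(as.character(members)),
      n_members = length(members),
      seed_reads = unname(recruitment$counts[top]))
    pool <- pool[!pool$id %in% members, ]
  }
  if (length(out) == 0) return(empty)
  bind_rows(out)
}

#' Genomic fraction of one repeat family
#'
#' Builds the family reference — the seed monomer (doubled, so any read
#' phase aligns contiguously and fragment-length bias cannot depress the
#' estimate) plus every member contig — recruits all reads against it, and
#' returns the recruited fraction. Reads recruited by two families count
#' toward both: families are disjoint over contigs, not over reads.
#'
#' @param family one row of the [extract_top_families()] tibble.
#' @param reads read tibble or character vector.
#' @param contigs contig tibble holding the member sequences.
#' @param seed_k,min_identity,min_read_cov recruitment thresholds
#'   ([recruit_reads()]).
#' @return `list(fraction =, recruited_reads =, total_reads =)`.
#' @export
family_composition <- function(family, reads, contigs, seed_k = 15L,
                               min_identity = 0.85, min_read_cov = 0.80) {
  stopifnot(nrow(family) == 1)
  member_ids <- family$members[[1]]
  ref <- bind_rows(
    tibble(id = "__seed_monomer__",
           seq = paste0(family$seed_monomer, family$seed_monomer)),
    contigs[contigs$id %in% member_ids, c("id", "seq")])
  res <- recruit_reads(reads, ref, seed_k = seed_k,
                       min_identity = min_identity,
                       min_read_cov = min_read_cov, quiet = TRUE)
  if (res$total_reads == 0) stop("no reads", call. = FALSE)
  list(fraction = res$total_tandem_reads / res$total_reads,
       recruited_reads = res$total_tandem_reads,
       total_reads = res$total_reads)
}

#' Classify a family seed against known repeats
#'
#' Reports the known repeat monomer with the lowest E-value against the
#' family seed (same machinery as [find_homologs()]) together with the
#' monomer-length difference, or no match if nothing reaches
#' `E <= evalue_max`.
#'
#' @param family one row of the [extract_top_families()] tibble.
#' @param known_repeats tibble (`name`, `monomer`); may be empty.
#' @param params a [homology_params()].
#' @return single-row tibble `name`, `evalue`, `length_diff`, `matched`;
#'   `matched = FALSE` (and `name = NA`) when there is no hit.
#' @export
classify_top_repeat <- function(family, known_repeats,
                                params = homology_params()) {
  stopifnot(nrow(family) == 1)
  no_match <- tibble(name = NA_character_, evalue = NA_real_,
                     length_diff = NA_integer_, matched = FALSE)
  if (is.null(known_repeats) || nrow(known_repeats) == 0) return(no_match)
  doubled <- paste0(family$seed_monomer, family$seed_monomer)
  scores <- seeded_ungapped_best_cpp(doubled, known_repeats$monomer,
                                     params$word_size, params$match,
                                     params$mismatch)
  m <- nchar(family$seed_monomer)
  n <- sum(nchar(known_repeats$monomer))
  ev <- evalue_of(scores, m, n, params)
  best <- which.min(ev)
  if (ev[best] > params$evalue_max) return(no_match)
  tibble(name = known_repeats$name[best], evalue = ev[best],
         length_diff = abs(nchar(known_repeats$monomer[best]) - m),
         matched = TRUE)
}
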