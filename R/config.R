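#' Pipeline configuration
#'
#' All thresholds of the discovery pipeline in one place, defaulting to the
#' standard survey-sequencing values: tandem-repeat scoring match +2 /
#' mismatch -7 / indel -7, minimum score 50, maximum period 2000; minimum
#' contig length 200; seed monomers at least 30 bp; homology grouping at
#' E <= 0.1; 4 families extracted.
#'
#' @param ... named overrides of the defaults listed below.
#' @return a named list of class `satseeker_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    # assembly
    k = 31L,                  # de Bruijn k-mer size (odd, 11 <= k < read length)
    min_kmer_count = NULL,    # NULL = kmer_noise_threshold() (default 2)
    min_contig_length = 200L, # minimum contig length retained
    # tandem detection
    match = 2L, mismatch = -7L, indel = -7L,
    min_score = 50L, max_period = 2000L,
    pm = 0.80, pi = 0.10,
    probe_k = 4L,             # k-mer size for period-candidate generation
    # read recruitment
    seed_k = 15L,             # recruitment seed k-mer
    min_identity = 0.85,      # alignment identity floor
    min_read_cov = 0.80,      # fraction of the read the alignment must cover
    # family extraction
    min_monomer_length = 30L, # seed monomers below this are not rank-1 eligible
    n_families = 4L,
    evalue_max = 0.1,
    word_size = 11L,          # homology seed word
    hom_match = 1L, hom_mismatch = -2L,
    ka_K = 0.621,             # Karlin-Altschul K for +1/-2, uniform bases
    # simulation
    read_length = 150L,
    coverage = 0.05,
    error_rate = 0,
    quiet = FALSE
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  structure(cfg, class = "satseeker_config")
}

#' Load configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; unspecified keys keep
#' their defaults.
#'
#' @param path YAML file.
#' @return a `satseeker_config` list.
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(pipeline_config, vals)
}

#' @export
print.satseeker_config <- function(x, ...) {
  cat("satseeker pipeline configuration:\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-18s %s\n", k, if (is.null(v)) "auto" else format(v)))
  }
  invisible(x)
}

#' @noRd
scoring_from_config <- function(cfg) {
  scoring_params(match = cfg$match, mismatch = cfg$mismatch,
                 indel = cfg$indel, min_score = cfg$min_score,
                 max_period = cfg$max_period, pm = cfg$pm, pi = cfg$pi)
}

#' @noRd
homology_from_config <- function(cfg) {
  homology_params(evalue_max = cfg$evalue_max, word_size = cfg$word_size,
                  match = cfg$hom_match, mismatch = cfg$hom_mismatch,
                  K = cfg$ka_K)
}
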