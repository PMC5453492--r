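#' Run the full tandem-repeat discovery pipeline
#'
#' Reads -> repeat-tolerant assembly -> tandem detection and filtering ->
#' read recruitment and ranking -> seed-and-remove family extraction ->
#' per-family composition -> report. Every stage is deterministic given the
#' input reads; `threads` is accepted for interface stability and results
#' are independent of it (the implementation is single-threaded).
#'
#' @param reads read tibble (`id`, `seq`) or character vector of sequences.
#' @param config a [pipeline_config()].
#' @param truth optional `simulation_truth` joined into the report.
#' @param known_repeats optional tibble (`name`, `monomer`) for classifying
#'   the top family.
#' @param out_dir if given, tables and FASTAs are written there
#'   (see [write_pipeline_tables()]).
#' @param threads ignored; results do not depend on it.
#' @return list: `contigs`, `tandem`, `annotations`, `recruitment`,
#'   `families`, `total_tandem_fraction`, `report`, `classification`.
#' @export
run_pipeline <- function(reads, config = pipeline_config(), truth = NULL,
                         known_repeats = NULL, out_dir = NULL, threads = 1L) {
  quiet <- isTRUE(config$quiet)
  if (is.character(reads)) reads <- tibble(
    id = sprintf("read_%06d", seq_along(reads)), seq = reads,
    qual = NA_character_)

  contigs <- assemble_contigs(
    reads, k = config$k, min_contig_length = config$min_contig_length,
    min_kmer_count = config$min_kmer_count, max_period = config$max_period,
    quiet = quiet)

  sp <- scoring_from_config(config)
  det <- filter_tandem_contigs(contigs, sp, probe_k = config$probe_k,
                               quiet = quiet)

  if (nrow(det$tandem) == 0) {
    ss_log("no tandem contigs: empty family set, zero tandem fraction",
           quiet = quiet)
    families <- empty_families()
    total <- 0
    recruitment <- NULL
  } else {
    recruitment <- recruit_reads(reads, det$tandem, seed_k = config$seed_k,
                                 min_identity = config$min_identity,
                                 min_read_cov = config$min_read_cov,
                                 quiet = quiet)
    total <- total_tandem_fraction(recruitment)
    hp <- homology_from_config(config)
    families <- extract_top_families(
      det$tandem, det$annotations, recruitment,
      n_families = config$n_families,
      min_monomer_length = config$min_monomer_length, params = hp,
      quiet = quiet)
    if (nrow(families) > 0) {
      comp <- lapply(seq_len(nrow(families)), function(i) {
        family_composition(families[i, ], reads, det$tandem,
                           seed_k = config$seed_k,
                           min_identity = config$min_identity,
                           min_read_cov = config$min_read_cov)
      })
      families$recruited_reads <- vapply(comp, `[[`, numeric(1),
                                         "recruited_reads")
      families$genomic_fraction <- vapply(comp, `[[`, numeric(1), "fraction")
    } else {
      families <- empty_families()
    }
  }

  report <- composition_report(families, total, truth)
  classification <- if (!is.null(known_repeats) && nrow(families) > 0) {
    classify_top_repeat(families[1, ], known_repeats)
  } else NULL

  out <- list(contigs = contigs, tandem = det$tandem,
              annotations = det$annotations, recruitment = recruitment,
              families = families, total_tandem_fraction = total,
              report = report, classification = classification)
  if (!is.null(out_dir)) write_pipeline_tables(out, out_dir)
  out
}

#' @noRd
empty_families <- function() {
  tibble(rank = integer(), seed_contig_id = character(),
         seed_monomer = character(), canonical_monomer = character(),
         monomer_length = integer(), members = list(),
         n_members = integer(), seed_reads = integer(),
         recruited_reads = numeric(), genomic_fraction = numeric())
}

#' Write the pipeline's tabular and FASTA artifacts
#'
#' Emits `contigs.fasta`, `annotations.tsv`, `recruitment.tsv`,
#' `families.tsv`, `monomers.fasta` and `composition.tsv` into `out_dir`.
#' Machine-readable fractions keep full precision; percentages in
#' `composition.tsv` are rounded to 2 decimals. Output is byte-stable for
#' identical pipeline results.
#'
#' @param result [run_pipeline()] output.
#' @param out_dir output directory (created if needed).
#' @export
write_pipeline_tables <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) {
    write.table(x, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
  }
  if (nrow(result$contigs) > 0) {
    write_contigs(result$contigs, file.path(out_dir, "contigs.fasta"))
  }
  tsv(result$annotations, "annotations.tsv")
  if (!is.null(result$recruitment)) {
    rec <- tibble(contig_id = names(result$recruitment$counts),
                  reads = unname(result$recruitment$counts),
                  fraction = unname(result$recruitment$counts) /
                    result$recruitment$total_reads)
    tsv(rec, "recruitment.tsv")
  }
  fam <- result$families
  if (nrow(fam) > 0) {
    flat <- mutate(fam, members = vapply(fam$members, paste, character(1),
                                         collapse = ","))
    tsv(flat, "families.tsv")
    write_sequences(tibble(id = sprintf("family_%d", fam$rank),
                           seq = fam$seed_monomer, qual = NA_character_),
                    file.path(out_dir, "monomers.fasta"), "fasta")
  }
  comp <- tibble(
    item = c("total_tandem", if (nrow(fam)) sprintf("family_%d", fam$rank)),
    fraction = c(result$total_tandem_fraction,
                 if (nrow(fam)) fam$genomic_fraction),
    pct = sprintf("%.2f", 100 * c(result$total_tandem_fraction,
                                  if (nrow(fam)) fam$genomic_fraction)))
  tsv(comp, "composition.tsv")
  invisible(out_dir)
}
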