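#' Specify a planted tandem-repeat family
#'
#' A family is a monomer planted as `n_arrays` head-to-tail arrays of
#' `copies_per_array` copies each. Each copy is independently mutated from
#' the family monomer at `per_copy_mutation_rate` substitutions per base,
#' emulating intra-family satellite divergence.
#'
#' @param name family name.
#' @param monomer monomer sequence; omit to auto-generate.
#' @param monomer_length,gc used to generate a monomer when `monomer` is NULL
#'   (generation uses the genome seed).
#' @param n_arrays number of separate arrays.
#' @param copies_per_array monomer copies per array.
#' @param per_copy_mutation_rate substitutions/base per copy, in \[0, 0.2\].
#' @return a `repeat_family_spec` list.
#' @export
repeat_family_spec <- function(name, monomer = NULL, monomer_length = NULL,
                               gc = 0.5, n_arrays = 1L,
                               copies_per_array = 10L,
                               per_copy_mutation_rate = 0) {
  stopifnot(nzchar(name), n_arrays >= 1, copies_per_array >= 1,
            per_copy_mutation_rate >= 0, per_copy_mutation_rate <= 0.2)
  if (is.null(monomer) && is.null(monomer_length)) {
    stop("give either `monomer` or `monomer_length`", call. = FALSE)
  }
  len <- if (!is.null(monomer)) nchar(monomer) else as.integer(monomer_length)
  if (len < 2 || len > 2000) {
    stop("monomer length must be in [2, 2000]", call. = FALSE)
  }
  if (!is.null(monomer)) assert_dna(monomer, "monomer", allow_n = FALSE)
  structure(list(name = name, monomer = monomer, monomer_length = len,
                 gc = gc, n_arrays = as.integer(n_arrays),
                 copies_per_array = as.integer(copies_per_array),
                 per_copy_mutation_rate = per_copy_mutation_rate),
            class = "repeat_family_spec")
}

#' Specify a synthetic genome
#'
#' @param length genome length in bases.
#' @param gc background GC fraction in (0, 1).
#' @param families list of [repeat_family_spec()] objects.
#' @param te_spec optional dispersed-repeat (TE-like) component:
#'   `list(te_length =, n_copies =, per_copy_mutation_rate =)`.
#' @param seed integer seed; the whole genome build is deterministic in it.
#' @return a `genome_spec` list.
#' @export
genome_spec <- function(length, gc = 0.5, families = list(), te_spec = NULL,
                        seed = 1L) {
  stopifnot(length >= 1, gc > 0, gc < 1)
  planted <- sum(vapply(families, function(f) {
    f$n_arrays * f$copies_per_array * f$monomer_length
  }, numeric(1)))
  te_bases <- if (is.null(te_spec)) 0 else te_spec$te_length * te_spec$n_copies
  if (planted + te_bases > length) {
    stop("planted repeat bases exceed genome length", call. = FALSE)
  }
  structure(list(length = as.integer(length), gc = gc, families = families,
                 te_spec = te_spec, seed = as.integer(seed)),
            class = "genome_spec")
}

#' Generate a random monomer with no internal sub-period
#'
#' Rejection-resamples until the sequence is not a perfect tandem of any
#' shorter period, so the planted period is the primitive period.
#'
#' @param length monomer length in \[2, 2000\].
#' @param gc GC fraction.
#' @param seed integer seed.
#' @return a DNA string of exactly `length` bases.
#' @export
generate_monomer <- function(length, gc = 0.5, seed = 1L) {
  if (length < 2 || length > 2000) {
    stop("monomer length must be in [2, 2000]", call. = FALSE)
  }
  with_seed(seed, {
    repeat {
      m <- random_dna(length, gc)
      if (primitive_period(m) == length) return(m)
    }
  })
}

# smallest p dividing nchar(x) such that x is a perfect tandem of period p
#' @noRd
primitive_period <- function(x) {
  n <- nchar(x)
  for (p in seq_len(n - 1)) {
    if (n %% p != 0) next
    unit <- substr(x, 1, p)
    if (strrep(unit, n / p) == x) return(p)
  }
  n
}

#' Build a genome with planted repeat families
#'
#' Arrays are placed at non-overlapping loci, each on a random strand; every
#' monomer copy is independently mutated at the family's per-copy rate.
#' True fractions use planted (pre-mutation-length) bases over genome
#' length; substitutions do not change lengths, so planted intervals are
#' exact. All coordinates are 0-based half-open.
#'
#' @param spec a [genome_spec()].
#' @return `list(genome = <string>, truth = <simulation_truth>)`; truth has
#'   `families` (name, monomer, canonical_monomer, planted_bases,
#'   true_fraction), `intervals` (family, start, end, strand) and
#'   `total_tandem_fraction`.
#' @export
build_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    L <- spec$length
    genome <- random_dna(L, spec$gc)

    # resolve monomers (auto-generate those given only by length)
    fams <- lapply(spec$families, function(f) {
      if (is.null(f$monomer)) {
        repeat {
          m <- random_dna(f$monomer_length, f$gc)
          if (primitive_period(m) == f$monomer_length) break
        }
        f$monomer <- m
      }
      f
    })

    # build array sequences
    pieces <- list()
    for (f in fams) {
      for (a in seq_len(f$n_arrays)) {
        copies <- vapply(seq_len(f$copies_per_array), function(i) {
          mutate_seq(f$monomer, f$per_copy_mutation_rate)
        }, character(1))
        arr <- paste(copies, collapse = "")
        strand <- sample(c("+", "-"), 1)
        if (strand == "-") arr <- revcomp(arr)
        pieces[[length(pieces) + 1]] <- list(family = f$name, seq = arr,
                                             strand = strand)
      }
    }
    if (!is.null(spec$te_spec)) {
      te <- spec$te_spec
      master <- random_dna(te$te_length, spec$gc)
      for (i in seq_len(te$n_copies)) {
        cp <- mutate_seq(master, te$per_copy_mutation_rate)
        strand <- sample(c("+", "-"), 1)
        if (strand == "-") cp <- revcomp(cp)
        pieces[[length(pieces) + 1]] <- list(family = ".te", seq = cp,
                                             strand = strand)
      }
    }

    # place longest-first, rejection-sampling non-overlapping starts
    ord <- order(-vapply(pieces, function(p) nchar(p$seq), numeric(1)))
    placed_start <- integer(0)
    placed_end <- integer(0)
    ints <- list()
    for (idx in ord) {
      p <- pieces[[idx]]
      len <- nchar(p$seq)
      ok <- FALSE
      for (try in 1:1000) {
        s <- sample.int(L - len + 1, 1) - 1L # 0-based
        e <- s + len
        if (!any(s < placed_end & e > placed_start)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("infeasible packing: could not place all arrays",
                    call. = FALSE)
      placed_start <- c(placed_start, s)
      placed_end <- c(placed_end, e)
      substr(genome, s + 1, e) <- p$seq
      ints[[length(ints) + 1]] <- tibble(family = p$family, start = s, end = e,
                                         strand = p$strand)
    }
    intervals <- if (length(ints) == 0) {
      tibble(family = character(), start = integer(), end = integer(),
             strand = character())
    } else {
      arrange(bind_rows(ints), .data$start)
    }

    fam_tbl <- bind_rows(lapply(fams, function(f) {
      tibble(name = f$name, monomer = f$monomer,
             canonical_monomer = canonical_monomer(f$monomer),
             planted_bases = f$n_arrays * f$copies_per_array *
               f$monomer_length,
             true_fraction = f$n_arrays * f$copies_per_array *
               f$monomer_length / L)
    }))
    if (nrow(fam_tbl) == 0) {
      fam_tbl <- tibble(name = character(), monomer = character(),
                        canonical_monomer = character(),
                        planted_bases = numeric(), true_fraction = numeric())
    }
    truth <- structure(
      list(families = fam_tbl,
           intervals = filter(intervals, .data$family != ".te"),
           te_intervals = filter(intervals, .data$family == ".te"),
           genome_length = L,
           total_tandem_fraction = sum(fam_tbl$true_fraction)),
      class = "simulation_truth")
    list(genome = genome, truth = truth)
  })
}

#' Simulate single-end shotgun reads
#'
#' Emits `ceiling(coverage * genome_length / read_length)` reads with uniform
#' start positions and strands and i.i.d. substitution errors. Reads are
#' emitted single-end directly (survey designs sequence paired-end and split
#' the pairs; the pipeline uses nothing pair-aware).
#'
#' @param genome genome string.
#' @param coverage fold coverage (> 0); survey designs use < 0.1X on real
#'   libraries, but coverage is free here.
#' @param read_length read length in bases (default 150).
#' @param error_rate substitution rate per base, in \[0, 0.5).
#' @param seed integer seed.
#' @return tibble of reads (`id`, `seq`, `qual = NA`).
#' @export
shotgun_reads <- function(genome, coverage, read_length = 150L,
                          error_rate = 0, seed = 1L) {
  L <- nchar(genome)
  if (coverage <= 0) stop("coverage must be > 0", call. = FALSE)
  if (read_length > L) stop("read_length exceeds genome length", call. = FALSE)
  if (error_rate < 0 || error_rate >= 0.5) {
    stop("error_rate must be in [0, 0.5)", call. = FALSE)
  }
  n <- as.integer(ceiling(coverage * L / read_length))
  with_seed(seed, {
    starts <- sample.int(L - read_length + 1L, n, replace = TRUE)
    seqs <- substring(genome, starts, starts + read_length - 1L)
    rev <- runif(n) < 0.5
    if (any(rev)) seqs[rev] <- revcomp(seqs[rev])
    if (error_rate > 0) {
      seqs <- vapply(seqs, mutate_seq, character(1), rate = error_rate,
                     USE.NAMES = FALSE)
    }
    out <- tibble(id = sprintf("read_%06d", seq_len(n)), seq = seqs,
                  qual = NA_character_)
    # sampling layout (0-based starts), for diagnostics and truth checks
    attr(out, "layout") <- tibble(id = out$id, start = starts - 1L,
                                  strand = ifelse(rev, "-", "+"))
    out
  })
}

#' The packaged planted benchmark
#'
#' A 1 Mb genome carrying three tandem families at planted fractions of
#' about 10%, 5% and 1%, with monomer lengths 180, 350 and 184 bp (the
#' characteristic knob-repeat monomer lengths of the Andropogoneae), plus a
#' dispersed 3 kb TE-like repeat at 5% divergence as non-tandem repeat
#' background. Arrays are internally homogeneous (per-copy mutation 0); the
#' benchmark measures abundance recovery, not divergence tolerance.
#'
#' @param seed integer seed controlling the whole build.
#' @return a [genome_spec()].
#' @export
planted_benchmark_spec <- function(seed = 1L) {
  genome_spec(
    length = 1e6, gc = 0.46, seed = seed,
    families = list(
      repeat_family_spec("sat180", monomer_length = 180, gc = 0.46,
                         n_arrays = 3, copies_per_array = 185),
      repeat_family_spec("sat350", monomer_length = 350, gc = 0.46,
                         n_arrays = 2, copies_per_array = 72),
      repeat_family_spec("sat184", monomer_length = 184, gc = 0.46,
                         n_arrays = 1, copies_per_array = 54)
    ),
    te_spec = list(te_length = 3000, n_copies = 20,
                   per_copy_mutation_rate = 0.05)
  )
}

#' A repeat-free control genome
#'
#' @param seed integer seed.
#' @return a [genome_spec()] with no planted repeats.
#' @export
negative_control_spec <- function(seed = 1L) {
  genome_spec(length = 1e6, gc = 0.46, families = list(), seed = seed)
}

#' Simulate a dataset (genome, reads, truth) and optionally write it out
#'
#' @param spec a [genome_spec()].
#' @param coverage fold read coverage.
#' @param read_length read length (bases).
#' @param error_rate substitution error rate per base.
#' @param out_dir if given, writes `genome.fasta`, `reads.fastq` and
#'   `truth.tsv` there.
#' @return list with `genome`, `reads` (tibble), `truth`.
#' @export
simulate_dataset <- function(spec, coverage = 0.05, read_length = 150L,
                             error_rate = 0, out_dir = NULL) {
  built <- build_genome(spec)
  reads <- shotgun_reads(built$genome, coverage = coverage,
                         read_length = read_length, error_rate = error_rate,
                         seed = derive_seeds(spec$seed, 1))
  ss_log(sprintf("simulated %d reads (%.3fX) from a %d bp genome, %d famil%s",
                 nrow(reads), coverage, nchar(built$genome),
                 nrow(built$truth$families),
                 if (nrow(built$truth$families) == 1) "y" else "ies"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_sequences(tibble(id = "genome", seq = built$genome,
                           qual = NA_character_),
                    file.path(out_dir, "genome.fasta"), "fasta")
    write_sequences(reads, file.path(out_dir, "reads.fastq"), "fastq")
    truth_tbl <- built$truth$families
    write.table(truth_tbl, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(genome = built$genome, reads = reads, truth = built$truth)
}
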