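#' Read sequences from FASTA or FASTQ
#'
#' Returns records in file order as a tibble with columns `id`, `seq` and
#' `qual` (`NA` for FASTA). Sequences are upper-cased; bases outside
#' `{A,C,G,T,N}` are rejected. An empty file yields an empty tibble.
#'
#' @param path path to an (optionally gzipped) FASTA or FASTQ file.
#' @param format `"fasta"` or `"fastq"`; default guesses from the extension.
#' @return tibble with columns `id`, `seq`, `qual`.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  if (format == "fastq") validate_fastq(path)
  set <- withCallingHandlers(
    tryCatch(
      Biostrings::readDNAStringSet(path, format = format),
      error = function(e) {
        stop(sprintf("malformed %s in '%s': %s", format, path,
                     conditionMessage(e)), call. = FALSE)
      }
    ),
    warning = function(w) {
      # the C parser drops non-IUPAC letters with a warning; that is a
      # parse error here (bases outside {A,C,G,T,N} are rejected)
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        stop(sprintf("record in '%s' contains characters outside {A,C,G,T,N}",
                     path), call. = FALSE)
      }
      invokeRestart("muffleWarning")
    }
  )
  if (length(set) == 0) {
    return(tibble(id = character(), seq = character(), qual = character()))
  }
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  names(seqs) <- NULL
  assert_dna(seqs, "record")
  qual <- rep(NA_character_, length(seqs))
  if (format == "fastq") {
    qual <- fastq_qualities(path)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate record id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  tibble(id = ids, seq = seqs, qual = qual)
}

# Structural validation of 4-line FASTQ records, with line numbers.
# (The Biostrings FASTQ parser silently pads or truncates quality strings
# that disagree with the sequence length, so lengths are checked here.)
#' @noRd
validate_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0) return(invisible(TRUE))
  if (n %% 4 != 0) {
    stop(sprintf("malformed fastq '%s': truncated record at line %d",
                 path, (n %/% 4) * 4 + 1), call. = FALSE)
  }
  heads <- seq(1, n, by = 4)
  bad <- !startsWith(lines[heads], "@")
  if (any(bad)) {
    stop(sprintf("malformed fastq '%s': expected '@' at line %d",
                 path, heads[bad][1]), call. = FALSE)
  }
  bad <- !startsWith(lines[heads + 2], "+")
  if (any(bad)) {
    stop(sprintf("malformed fastq '%s': expected '+' at line %d",
                 path, heads[bad][1] + 2), call. = FALSE)
  }
  mismatch <- nchar(lines[heads + 1]) != nchar(lines[heads + 3])
  if (any(mismatch)) {
    stop(sprintf(
      "malformed fastq '%s': quality length differs from sequence length at line %d",
      path, heads[mismatch][1] + 3), call. = FALSE)
  }
  invisible(TRUE)
}

#' @noRd
fastq_qualities <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) return(character())
  lines[seq(4, length(lines), by = 4)]
}

#' Write sequences to FASTA or FASTQ
#'
#' Writing FASTQ records without qualities fills a uniform Sanger quality
#' of `"I"`; writing FASTA silently drops qualities (FASTA carries none).
#'
#' @param records tibble with columns `id`, `seq` and optionally `qual`.
#' @param path output path.
#' @param format `"fasta"` or `"fastq"`.
#' @export
write_sequences <- function(records, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  if (nrow(records) > 0) {
    if (any(!nzchar(records$id))) stop("empty record id", call. = FALSE)
    if (any(nchar(records$seq) < 1)) stop("empty sequence", call. = FALSE)
    assert_dna(records$seq, "record")
  }
  set <- Biostrings::DNAStringSet(records$seq)
  names(set) <- records$id
  if (format == "fasta") {
    Biostrings::writeXStringSet(set, path, format = "fasta", width = 70L)
  } else {
    qual <- records$qual
    if (is.null(qual)) qual <- rep(NA_character_, nrow(records))
    qual <- ifelse(is.na(qual), strrep("I", nchar(records$seq)), qual)
    if (any(nchar(qual) != nchar(records$seq))) {
      stop("quality length differs from sequence length", call. = FALSE)
    }
    Biostrings::writeXStringSet(
      set, path, format = "fastq",
      qualities = Biostrings::BStringSet(qual))
  }
  invisible(path)
}

#' Load a genome-size table
#'
#' Reads a tab-separated table of per-taxon genome sizes (pg/1C, i.e.
#' picograms of DNA per unreplicated haploid nucleus). The first two columns
#' are taken as taxon and size; extra columns are ignored.
#'
#' @param path tab-separated text with a header row.
#' @return tibble with columns `taxon`, `genome_size`.
#' @export
load_genome_sizes <- function(path) {
  raw <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2) stop("genome-size table needs >= 2 columns", call. = FALSE)
  taxon <- raw[[1]]
  size <- suppressWarnings(as.numeric(raw[[2]]))
  bad <- is.na(size)
  if (any(bad)) {
    stop(sprintf("non-numeric genome size in row %d ('%s')",
                 which(bad)[1], raw[[2]][which(bad)[1]]), call. = FALSE)
  }
  if (any(size <= 0)) {
    stop(sprintf("genome size must be positive (row %d)", which(size <= 0)[1]),
         call. = FALSE)
  }
  if (anyDuplicated(taxon)) {
    stop("duplicate taxon: ", taxon[duplicated(taxon)][1], call. = FALSE)
  }
  tibble(taxon = taxon, genome_size = size)
}
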