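#' @keywords internal
#' @noRd
ss_log <- function(..., quiet = getOption("satseeker.quiet", FALSE)) {
  if (!isTRUE(quiet)) message("[satseeker] ", ...)
}

# Run code under a fixed seed without disturbing the caller's RNG state.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Derive a stream of sub-seeds below 2^31 from one master seed.
#' @noRd
derive_seeds <- function(seed, n) {
  (as.integer(seed) + 1013L * seq_len(n)) %% .Machine$integer.max
}

BASES <- c("A", "C", "G", "T")

#' Random DNA sequence with a given GC fraction
#'
#' @param n length in bases.
#' @param gc GC fraction in (0, 1).
#' @return a single uppercase DNA string.
#' @noRd
random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Reverse complement of DNA strings
#'
#' Vectorised over `x`; `N` is preserved.
#' @param x character vector of DNA strings.
#' @return character vector.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @noRd
assert_dna <- function(x, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  bad <- grepl(pat, x)
  if (any(bad)) {
    stop(sprintf("%s %d contains characters outside {A,C,G,T%s}",
                 what, which(bad)[1], if (allow_n) ",N" else ""), call. = FALSE)
  }
  invisible(x)
}

# Apply substitutions at `rate` per base; substituted bases switch to one of
# the three other bases uniformly. Uses the current RNG stream.
#' @noRd
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  k <- rbinom(1, n, rate)
  if (k == 0) return(seq)
  idx <- sample.int(n, k)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  chars[idx] <- vapply(chars[idx], function(b) {
    sample(setdiff(BASES, b), 1)
  }, character(1), USE.NAMES = FALSE)
  paste(chars, collapse = "")
}
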