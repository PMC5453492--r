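# Independent oracle implementations used to validate the package's
# optimised kernels. These deliberately use a different formulation than
# the code under test.

# Alignment of `seq` (global) against a long linear concatenation of the
# monomer (local in the reference): equivalent by construction to the
# wraparound formulation when enough copies are laid out.
wdp_oracle <- function(seq, monomer, match = 2, mismatch = -7, indel = -7) {
  a <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(a)
  p <- nchar(monomer)
  copies <- n + 3 # enough that the optimum is never clipped at these sizes
  b <- strsplit(strrep(monomer, copies), "", fixed = TRUE)[[1]]
  m <- length(b)
  prev <- rep(0, m + 1) # free start phase anywhere in the reference
  for (i in seq_len(n)) {
    cur <- numeric(m + 1)
    cur[1] <- prev[1] + indel
    sub <- ifelse(b == a[i], match, mismatch)
    cand <- pmax(prev[1:m] + sub, prev[2:(m + 1)] + indel)
    run <- cur[1]
    for (j in seq_len(m)) { # reference-gap sweep
      run <- max(run + indel, cand[j])
      cand[j] <- run
    }
    cur[2:(m + 1)] <- cand
    prev <- cur
  }
  max(prev) # free end phase
}

# Brute-force period support: direct substring comparison over all offsets.
period_support_oracle <- function(seq, k, max_period) {
  L <- nchar(seq)
  vapply(seq_len(max_period), function(d) {
    n_i <- L - d - k + 1
    if (n_i < 1) return(0L)
    i <- seq_len(n_i)
    sum(substring(seq, i, i + k - 1) == substring(seq, i + d, i + d + k - 1))
  }, integer(1))
}

# Majority-vote consensus oracle via tapply (ties: alphabetical).
consensus_oracle <- function(seq, period) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  col <- ((seq_along(chars) - 1) %% period) + 1
  paste(tapply(chars, col, function(x) {
    tab <- sort(table(x), decreasing = TRUE)
    names(tab)[tab == max(tab)][order(names(tab)[tab == max(tab)])][1]
  }), collapse = "")
}

# Pearson r by the direct covariance formula.
pearson_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

random_seq <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# Reads tiling a source so that every k-mer is covered at least twice.
tiling_reads <- function(src, read_length = 150, step = 10) {
  L <- nchar(src)
  starts <- unique(pmin(seq(1, L, by = step), L - read_length + 1))
  reads <- substring(src, starts, starts + read_length - 1)
  c(reads, reads) # duplicate so no k-mer is a singleton
}

# Edit distance between canonical monomers, allowing for rotation already
# being normalised by canonical_monomer().
monomer_edit_distance <- function(a, b) {
  as.integer(utils::adist(canonical_monomer(a), canonical_monomer(b)))
}
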