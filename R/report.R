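#' Genomic composition report
#'
#' Summarises a pipeline run: the total tandem fraction and each extracted
#' family's genomic fraction, both also expressed as percentages. When a
#' simulation truth is supplied, each family is matched to the planted
#' family with the closest canonical monomer (edit distance) and the truth
#' columns are joined in.
#'
#' @param families family tibble with `genomic_fraction` filled in
#'   ([run_pipeline()] output).
#' @param total_fraction total tandem fraction ([total_tandem_fraction()]).
#' @param truth optional `simulation_truth` from [build_genome()].
#' @return a `composition_report`: list with `families` (tibble) and
#'   `total_tandem_fraction`, `total_tandem_pct`.
#' @export
composition_report <- function(families, total_fraction, truth = NULL) {
  stopifnot(is.numeric(total_fraction), total_fraction >= 0,
            total_fraction <= 1)
  fam <- families
  if (nrow(fam) > 0) {
    stopifnot(all(diff(fam$rank) == 1), fam$rank[1] == 1)
    fam$genomic_pct <- 100 * fam$genomic_fraction
  } else {
    fam$genomic_pct <- numeric(0)
  }
  if (!is.null(truth) && nrow(fam) > 0 && nrow(truth$families) > 0) {
    d <- adist(fam$canonical_monomer, truth$families$canonical_monomer)
    best <- apply(d, 1, which.min)
    fam$true_family <- truth$families$name[best]
    fam$monomer_edit_distance <- d[cbind(seq_len(nrow(fam)), best)]
    fam$true_fraction <- truth$families$true_fraction[best]
    fam$true_pct <- 100 * fam$true_fraction
  }
  structure(list(families = fam,
                 total_tandem_fraction = total_fraction,
                 total_tandem_pct = 100 * total_fraction),
            class = "composition_report")
}

#' @export
print.composition_report <- function(x, ...) {
  cat(sprintf("total tandem repeat content: %.2f%% of reads\n",
              x$total_tandem_pct))
  fam <- x$families
  if (nrow(fam) == 0) {
    cat("no tandem repeat families extracted\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(fam))) {
    cat(sprintf("  rank %d: %d bp monomer, %.2f%% of reads (%d contig%s)%s\n",
                fam$rank[i], fam$monomer_length[i], fam$genomic_pct[i],
                fam$n_members[i], if (fam$n_members[i] == 1) "" else "s",
                if ("true_family" %in% names(fam))
                  sprintf(" [planted %s: %.2f%%]", fam$true_family[i],
                          fam$true_pct[i]) else ""))
  }
  invisible(x)
}

#' Pearson correlation of tandem content with genome size
#'
#' Pairs per-taxon tandem fractions with genome sizes by taxon name and
#' computes the Pearson product-moment correlation with a two-sided t-based
#' p-value. Unmatched taxa are dropped with a warning.
#'
#' @param fractions tibble (`taxon`, `fraction`).
#' @param sizes genome-size tibble ([load_genome_sizes()]).
#' @return list `r`, `p_value`, `n`.
#' @export
genome_size_correlation <- function(fractions, sizes) {
  stopifnot(all(c("taxon", "fraction") %in% names(fractions)),
            all(c("taxon", "genome_size") %in% names(sizes)))
  merged <- inner_join(fractions, sizes, by = "taxon")
  dropped <- setdiff(union(fractions$taxon, sizes$taxon), merged$taxon)
  if (length(dropped)) {
    warning("dropping unmatched taxa: ", paste(dropped, collapse = ", "),
            call. = FALSE)
  }
  if (nrow(merged) < 3) stop("need >= 3 paired observations", call. = FALSE)
  ct <- cor.test(merged$fraction, merged$genome_size, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(merged))
}

#' Self-comparison dot plot of a sequence
#'
#' Point `(i, j)` is set iff the `window`-length windows starting at i and j
#' match at `>= min_identity` on either strand. The matrix is symmetric and
#' the main diagonal is always present; a tandem array of period p shows
#' off-diagonal bands at spacing p.
#'
#' @param seq DNA string, `nchar(seq) >= window`.
#' @param window window size in bases (>= 4).
#' @param min_identity per-window identity threshold.
#' @return a logical matrix of class `satseeker_dotplot` (rows/cols are
#'   0-based window starts).
#' @export
self_dotplot <- function(seq, window = 12L, min_identity = 0.9) {
  if (window < 4) stop("window must be >= 4", call. = FALSE)
  if (window > nchar(seq)) stop("window exceeds sequence length",
                                call. = FALSE)
  m <- dotplot_cpp(seq, as.integer(window), min_identity)
  structure(m, class = c("satseeker_dotplot", class(m)))
}

#' @export
#' @method plot satseeker_dotplot
plot.satseeker_dotplot <- function(x, ...) {
  n <- nrow(x)
  idx <- which(unclass(x), arr.ind = TRUE)
  graphics::plot(idx[, 2] - 1, idx[, 1] - 1, pch = ".", cex = 2,
                 xlab = "position (bp)", ylab = "position (bp)",
                 xlim = c(0, n - 1), ylim = c(n - 1, 0), ...)
  invisible(x)
}
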