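# Per-locus diversity statistics and Hardy-Weinberg testing for biallelic
# loci.  `counts` is always the genotype count triple (n0, n1, n2) =
# (hom-ref, het, hom-alt); missing calls are excluded locus-wise upstream.

#' Allele frequencies from genotype counts
#'
#' @param counts Integer vector `(n0, n1, n2)` of genotype counts.
#' @return Numeric `c(p_ref, p_alt)`; `p_ref = (2 n0 + n1) / (2 total)`.
#' @examples
#' alleleFrequencies(c(49, 4, 1))  # 102/108, 6/108
#' @export
alleleFrequencies <- function(counts) {
  counts <- .checkCounts(counts)
  n <- sum(counts)
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  c(p_ref = p, p_alt = 1 - p)
}

.checkCounts <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 3L || any(counts < 0)) {
    stop("counts must be three non-negative genotype counts (n0, n1, n2)")
  }
  if (sum(counts) == 0) stop("undefined locus: no observed genotypes")
  counts
}

#' Observed heterozygosity
#'
#' @inheritParams alleleFrequencies
#' @return `Ho = n1 / total`.
#' @export
observedHeterozygosity <- function(counts) {
  counts <- .checkCounts(counts)
  counts[2] / sum(counts)
}

#' Expected heterozygosity under Hardy-Weinberg equilibrium
#'
#' Uses the plain (biased) estimator `He = 1 - sum(p_i^2)` with no
#' sample-size correction.
#'
#' @param p Numeric vector of allele frequencies summing to 1 (or a single
#'   frequency, interpreted as biallelic `c(p, 1 - p)`).
#' @return `He` in `[0, 1]`.
#' @export
expectedHeterozygosity <- function(p) {
  if (length(p) == 1L) p <- c(p, 1 - p)
  if (abs(sum(p) - 1) > 1e-9) stop("allele frequencies must sum to 1")
  1 - sum(p^2)
}

#' Wright's fixation index FIS
#'
#' `Fis = (He - Ho) / He`; positive values indicate a heterozygote deficit.
#' When `He = 0` (monomorphic locus) the index is undefined and `NA` is
#' returned rather than an error.
#'
#' @param ho Observed heterozygosity.
#' @param he Expected heterozygosity.
#' @return `Fis`, or `NA` when `He = 0`.
#' @export
fixationIndex <- function(ho, he) {
  if (he == 0) return(NA_real_)
  (he - ho) / he
}

#' Polymorphic information content
#'
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`.  In
#' `"printed_compat"` mode the allele frequencies are first rounded to
#' three decimals, matching the convention under which published marker
#' tables are typically computed; `"exact"` mode uses the frequencies as
#' given.
#'
#' @inheritParams expectedHeterozygosity
#' @param mode `"exact"` (default) or `"printed_compat"`.
#' @return `PIC`, always `<=` the expected heterozygosity for the same
#'   frequencies.
#' @export
pic <- function(p, mode = c("exact", "printed_compat")) {
  mode <- match.arg(mode)
  if (length(p) == 1L) p <- c(p, 1 - p)
  if (abs(sum(p) - 1) > 1e-9) stop("allele frequencies must sum to 1")
  if (mode == "printed_compat") p <- round(p, 3)
  cross <- outer(p^2, p^2)
  1 - sum(p^2) - sum(cross[upper.tri(cross)]) * 2
}

#' Hardy-Weinberg chi-square test from genotype counts
#'
#' Expected genotype counts are `n p^2`, `2 n p q`, `n q^2` from the sample
#' allele frequencies; the statistic sums `(O - E)^2 / E` over all three
#' genotype classes with no continuity correction, on 1 degree of freedom.
#' All three classes enter the sum even when an expected count is below 1;
#' a warning flags expected counts below 5 since the chi-square
#' approximation is then rough.  Monomorphic loci return `chi2 = 0`,
#' `p = 1` with a flag.
#'
#' @inheritParams alleleFrequencies
#' @param warn_small_expected Warn when any expected count is below 5.
#' @return List with `chi2`, `df` (= 1), `p_value`, `expected`,
#'   `monomorphic`.
#' @examples
#' hweChisq(c(49, 4, 1))$chi2  # 4.671
#' @export
hweChisq <- function(counts, warn_small_expected = TRUE) {
  counts <- .checkCounts(counts)
  n <- sum(counts)
  p <- alleleFrequencies(counts)[1]
  q <- 1 - p
  if (p == 0 || q == 0) {
    return(list(chi2 = 0, df = 1L, p_value = 1, expected = counts,
      monomorphic = TRUE))
  }
  expected <- n * c(p^2, 2 * p * q, q^2)
  if (warn_small_expected && any(expected < 5)) {
    warning("expected genotype count(s) below 5; chi-square approximation is rough")
  }
  chi2 <- sum((counts - expected)^2 / expected)
  list(chi2 = chi2, df = 1L,
    p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
    expected = expected, monomorphic = FALSE)
}

#' Per-locus diversity summary table
#'
#' One row per locus with genotype counts and frequencies, allele
#' frequencies, observed/expected heterozygosity, FIS, PIC and the
#' Hardy-Weinberg chi-square test.  Missing calls are excluded locus-wise.
#'
#' @param g A [GenotypeMatrix-class].
#' @param pic_mode PIC rounding mode, see [pic()].
#' @param warn_small_expected See [hweChisq()].
#' @return data.frame with columns `rsid`, `cdna_label`, `n0`, `n1`, `n2`,
#'   `n`, `p_ref`, `p_alt`, `Ho`, `He`, `Fis`, `PIC`, `chi2`, `df`,
#'   `p_value`, `monomorphic`.
#' @export
summarizeLoci <- function(g, pic_mode = c("exact", "printed_compat"),
    warn_small_expected = TRUE) {
  stopifnot(methods::is(g, "GenotypeMatrix"))
  pic_mode <- match.arg(pic_mode)
  if (nSamples(g) == 0L || nLoci(g) == 0L) stop("empty genotype matrix")
  v <- g@variants
  rows <- lapply(seq_len(nLoci(g)), function(j) {
    col <- g@calls[, j]
    col <- col[col >= 0L]
    counts <- c(sum(col == 0L), sum(col == 1L), sum(col == 2L))
    af <- alleleFrequencies(counts)
    ho <- observedHeterozygosity(counts)
    he <- expectedHeterozygosity(af)
    hw <- hweChisq(counts, warn_small_expected = warn_small_expected)
    data.frame(rsid = v$rsid[j], cdna_label = v$cdna_label[j],
      n0 = counts[1], n1 = counts[2], n2 = counts[3], n = sum(counts),
      p_ref = af[1], p_alt = af[2], Ho = ho, He = he,
      Fis = fixationIndex(ho, he), PIC = pic(af, mode = pic_mode),
      chi2 = hw$chi2, df = hw$df, p_value = hw$p_value,
      monomorphic = hw$monomorphic, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
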