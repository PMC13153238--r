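# Pairwise linkage disequilibrium from inferred gamete counts.
#
# LD here is computed on the phased gamete pool (2n gametes), i.e. the
# marginalized haplotype table, not on genotype composite LD.  A and B
# denote the alternative (minor) alleles at the two loci; r^2 and |D'| are
# invariant under allele relabelling, so the orientation only fixes the
# sign of D.

.locusIndex <- function(variants, locus) {
  if (is.numeric(locus)) {
    idx <- as.integer(locus)
    if (idx < 1L || idx > nrow(variants)) stop("locus index out of range: ", locus)
    return(idx)
  }
  idx <- match(locus, variants$rsid)
  if (is.na(idx)) idx <- match(locus, variants$cdna_label)
  if (is.na(idx)) stop("locus not found: ", locus)
  idx
}

#' Two-locus gamete counts from a haplotype table
#'
#' Marginalizes the haplotype gamete counts onto two loci.  Cell order is
#' `AB, Ab, aB, ab` with `A`/`B` the alternative alleles.
#'
#' @param table A [HaplotypeTable-class].
#' @param locus_a,locus_b Locus selectors: rsID, variant label or index.
#' @return 2x2 integer matrix (rows: locus A alt/ref; columns: locus B
#'   alt/ref), with margins equal to the per-locus allele counts.
#' @examples
#' fit <- emPhase(reconstructUcmFixture())
#' gameteCounts(fit$table, "rs119102826", "rs408710650")  # (1,0,0,107)
#' @export
gameteCounts <- function(table, locus_a, locus_b) {
  stopifnot(methods::is(table, "HaplotypeTable"))
  v <- table@variants
  ia <- .locusIndex(v, locus_a)
  ib <- .locusIndex(v, locus_b)
  a_alt <- substring(table@haplotypes, ia, ia) == v$alt_allele[ia]
  b_alt <- substring(table@haplotypes, ib, ib) == v$alt_allele[ib]
  m <- matrix(c(
    sum(table@gametes[a_alt & b_alt]), sum(table@gametes[a_alt & !b_alt]),
    sum(table@gametes[!a_alt & b_alt]), sum(table@gametes[!a_alt & !b_alt])),
    nrow = 2L, byrow = TRUE,
    dimnames = list(c("A_alt", "A_ref"), c("B_alt", "B_ref")))
  storage.mode(m) <- "integer"
  m
}

#' Linkage disequilibrium coefficients from 2x2 gamete counts
#'
#' `D = p_AB - p_A p_B`; `Dmax` follows the piecewise rule
#' `min(p_A (1-p_B), (1-p_A) p_B)` for `D > 0` and
#' `min(p_A p_B, (1-p_A)(1-p_B))` for `D < 0`; `D' = D / Dmax` (defined as
#' 0 when `D = 0`); `r^2 = D^2 / (p_A (1-p_A) p_B (1-p_B))`.
#'
#' @param counts 2x2 gamete count matrix in `AB, Ab, aB, ab` layout (as
#'   from [gameteCounts()]).
#' @return List with `p_A`, `p_B`, `p_AB`, `D`, `D_max`, `D_prime`, `r2`;
#'   all `NA` (with `monomorphic = TRUE`) if either locus is fixed.
#' @export
ldCoefficients <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == 2L), all(counts >= 0))
  n <- sum(counts)
  p_ab <- counts[1, 1] / n
  p_a <- sum(counts[1, ]) / n
  p_b <- sum(counts[, 1]) / n
  if (p_a %in% c(0, 1) || p_b %in% c(0, 1)) {
    return(list(p_A = p_a, p_B = p_b, p_AB = p_ab, D = NA_real_,
      D_max = NA_real_, D_prime = NA_real_, r2 = NA_real_,
      monomorphic = TRUE))
  }
  d <- p_ab - p_a * p_b
  d_max <- if (d > 0) {
    min(p_a * (1 - p_b), (1 - p_a) * p_b)
  } else if (d < 0) {
    min(p_a * p_b, (1 - p_a) * (1 - p_b))
  } else NA_real_
  d_prime <- if (d == 0) 0 else d / d_max
  r2 <- d^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
  list(p_A = p_a, p_B = p_b, p_AB = p_ab, D = d, D_max = d_max,
    D_prime = d_prime, r2 = r2, monomorphic = FALSE)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Two-sided p-value summing the hypergeometric probabilities, over all
#' tables with the observed margins, that do not exceed the probability of
#' the observed table (with a small relative tie tolerance).
#'
#' @param counts 2x2 matrix of non-negative counts.
#' @return The exact p-value in `(0, 1]`.
#' @export
fisherExact2x2 <- function(counts) {
  counts <- round(as.matrix(counts))
  stopifnot(all(dim(counts) == 2L), all(counts >= 0))
  stats::fisher.test(counts)$p.value
}

#' All-pairs linkage disequilibrium matrix
#'
#' Computes LD coefficients and Fisher exact p-values for every unordered
#' locus pair from phased gamete counts.
#'
#' @param g A [GenotypeMatrix-class] (used for locus metadata and, when
#'   `haps` is missing, to run [emPhase()]).
#' @param haps Optional [HaplotypeTable-class] derived from `g`.
#' @return List with `pairs` (long data.frame: `locus_a`, `locus_b`,
#'   `D`, `D_prime`, `r2`, `fisher_p`, gamete cells `n_AB` .. `n_ab`) and
#'   symmetric matrices `r2`, `D_prime`, `fisher_p` with `NA` diagonals.
#' @export
ldMatrix <- function(g, haps = NULL) {
  stopifnot(methods::is(g, "GenotypeMatrix"))
  if (is.null(haps)) haps <- emPhase(g)$table
  stopifnot(methods::is(haps, "HaplotypeTable"))
  v <- g@variants
  m <- nrow(v)
  r2 <- dp <- fp <- matrix(NA_real_, m, m, dimnames = list(v$rsid, v$rsid))
  rows <- list()
  for (i in seq_len(m - 1L)) {
    for (j in seq(i + 1L, m)) {
      cnt <- gameteCounts(haps, i, j)
      co <- ldCoefficients(cnt)
      p <- if (co$monomorphic) NA_real_ else fisherExact2x2(cnt)
      r2[i, j] <- r2[j, i] <- co$r2
      dp[i, j] <- dp[j, i] <- co$D_prime
      fp[i, j] <- fp[j, i] <- p
      rows[[length(rows) + 1L]] <- data.frame(
        locus_a = v$rsid[i], locus_b = v$rsid[j],
        D = co$D, D_prime = co$D_prime, r2 = co$r2, fisher_p = p,
        n_AB = cnt[1, 1], n_Ab = cnt[1, 2], n_aB = cnt[2, 1], n_ab = cnt[2, 2],
        stringsAsFactors = FALSE)
    }
  }
  list(pairs = do.call(rbind, rows), r2 = r2, D_prime = dp, fisher_p = fp)
}
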