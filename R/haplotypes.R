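# EM haplotype frequency estimation and most-probable phase assignment
# from unphased diploid genotypes.
#
# Internally a haplotype is a string over {"0","1"} (ref/alt per locus,
# loci ordered by intron offset); user-facing output uses allele letters.

.MAX_HET_LOCI <- 20L

.hapToLetters <- function(hap01, variants) {
  vapply(strsplit(hap01, ""), function(bits) {
    paste(ifelse(bits == "0", variants$ref_allele, variants$alt_allele),
      collapse = "")
  }, character(1))
}

.pairsForConcreteRow <- function(row) {
  base <- ifelse(row == 2L, "1", "0")
  hets <- which(row == 1L)
  h <- length(hets)
  if (h == 0L) {
    s <- paste(base, collapse = "")
    return(matrix(c(s, s), ncol = 2L))
  }
  if (h > .MAX_HET_LOCI) stop("more than ", .MAX_HET_LOCI, " heterozygous loci in one individual")
  k <- h - 1L
  out <- matrix("", 2L^k, 2L)
  for (idx in seq_len(2L^k) - 1L) {
    bits <- if (k > 0L) as.integer(intToBits(idx))[seq_len(k)] else integer(0)
    assign1 <- c(0L, bits)        # first het locus fixed to ref on hap 1
    a1 <- base; a2 <- base
    a1[hets] <- as.character(assign1)
    a2[hets] <- as.character(1L - assign1)
    out[idx + 1L, ] <- c(paste(a1, collapse = ""), paste(a2, collapse = ""))
  }
  out
}

#' Enumerate haplotype pairs compatible with one unphased genotype
#'
#' A row with `h` heterozygous loci has `max(1, 2^(h-1))` distinct
#' unordered compatible pairs.  Missing calls are expanded over all three
#' genotypes at the missing locus and the union of pairs is returned, with
#' attribute `expanded_missing = TRUE`.
#'
#' @param genotype_row Integer vector of genotype codes for one individual.
#' @return Two-column character matrix of haplotype strings over
#'   `{"0","1"}` (ref/alt); each row is one unordered pair.
#' @export
enumerateCompatiblePairs <- function(genotype_row) {
  row <- as.integer(genotype_row)
  miss <- which(row == -1L)
  if (!length(miss)) return(.pairsForConcreteRow(row))
  if (length(miss) > 8L) stop("too many missing calls to enumerate")
  combos <- expand.grid(rep(list(0:2), length(miss)))
  pairs <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    r <- row
    r[miss] <- as.integer(combos[i, ])
    .pairsForConcreteRow(r)
  }))
  pairs <- pairs[!duplicated(paste(pairs[, 1], pairs[, 2])), , drop = FALSE]
  attr(pairs, "expanded_missing") <- TRUE
  pairs
}

# EM core over a fixed pair list.  pairs: list(p1, p2, pg) index vectors;
# w: per-group weights; K: number of haplotypes; two_n: total gametes.
.emCore <- function(pairs, w, K, two_n, init_f, tol, max_iter) {
  f <- init_f
  het_factor <- ifelse(pairs$p1 == pairs$p2, 1, 2)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  post <- NULL
  loglik <- -Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    lik <- het_factor * f[pairs$p1] * f[pairs$p2]
    gs <- rowsum(lik, pairs$pg)[, 1]
    if (any(gs <= 0)) {           # zero-probability individual: likelihood dead end
      return(list(f = f, logLik = -Inf, iterations = iter, converged = FALSE,
        trace = trace, posteriors = NULL))
    }
    loglik <- sum(w * log(gs))
    trace <- c(trace, loglik)
    post <- lik / gs[pairs$pg]
    tmp <- w[pairs$pg] * post
    cc <- rowsum(c(tmp, tmp), c(pairs$p1, pairs$p2))
    cnt <- numeric(K)
    cnt[as.integer(rownames(cc))] <- cc[, 1]
    f_new <- cnt / two_n
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(f = f, logLik = loglik, iterations = iter, converged = converged,
    trace = trace, posteriors = post)
}

# Restrict a pair list to allowed haplotypes; NULL if some group loses
# all of its pairs.
.restrictPairs <- function(pairs, allowed, n_groups) {
  keep <- allowed[pairs$p1] & allowed[pairs$p2]
  if (!all(seq_len(n_groups) %in% unique(pairs$pg[keep]))) return(NULL)
  list(p1 = pairs$p1[keep], p2 = pairs$p2[keep], pg = pairs$pg[keep])
}

#' EM haplotype phasing of an unphased genotype matrix
#'
#' Estimates haplotype frequencies by expectation-maximization under the
#' multinomial Hardy-Weinberg likelihood (E-step: pair posteriors
#' proportional to the product of pair frequencies with a factor 2 for
#' heterozygous pairs; M-step: expected gamete counts over 2n) and assigns
#' each individual its maximum-posterior pair.
#'
#' By default (`refine = "bic"`) the converged support is then subjected to
#' a parsimony refinement: rare haplotypes (expected gamete count below 4)
#' are removed one at a time, the restricted model re-converged, and the
#' removal kept whenever it lowers the Bayesian information criterion
#' `-2 logL + (K - 1) log(2n)`.  This emulates the parsimony preference of
#' Bayesian phasing algorithms, which favour resolving an ambiguous
#' individual into haplotypes already supported elsewhere in the sample
#' over positing an additional rare haplotype.  `refine = "none"` returns
#' the plain maximum-likelihood fixed point.
#'
#' After refinement, haplotypes with frequency below `1/(4n)` are pruned
#' and frequencies renormalized.  Gamete counts are `round(freq * 2n)`
#' with largest-remainder rounding (ties toward the more frequent
#' haplotype) so that they sum to `2n` exactly.
#'
#' @param g A [GenotypeMatrix-class]; individuals may have at most 20
#'   heterozygous loci (enumeration bound).
#' @param tol Convergence threshold on the maximum absolute frequency
#'   change per iteration.
#' @param max_iter Iteration cap; non-convergence returns a warning flag,
#'   not an error.
#' @param refine `"bic"` (default) or `"none"`.
#' @param ambiguity_threshold Individuals whose best pair has posterior
#'   below this are flagged `ambiguous` in the assignments.
#' @return List with elements
#'   \describe{
#'     \item{table}{[HaplotypeTable-class] of surviving haplotypes, in
#'       descending frequency order.}
#'     \item{assignments}{data.frame: `sample`, `hap1`, `hap2` (allele
#'       letters), `posterior`, `ambiguous`.}
#'     \item{logLik, iterations, converged}{fit diagnostics.}
#'     \item{trace}{per-iteration log-likelihood of the main EM run
#'       (non-decreasing).}
#'   }
#' @examples
#' fit <- emPhase(reconstructUcmFixture())
#' fit$table
#' @export
emPhase <- function(g, tol = 1e-8, max_iter = 10000L,
    refine = c("bic", "none"), ambiguity_threshold = 0.9) {
  stopifnot(methods::is(g, "GenotypeMatrix"))
  refine <- match.arg(refine)
  if (nLoci(g) < 1L) stop("need at least one locus")
  n <- nSamples(g)
  two_n <- 2L * n

  keys <- apply(g@calls, 1L, paste, collapse = ",")
  groups <- match(keys, unique(keys))
  n_groups <- max(groups)
  w <- as.numeric(tabulate(groups, n_groups))
  rep_rows <- match(seq_len(n_groups), groups)

  pair_mats <- lapply(rep_rows, function(i) enumerateCompatiblePairs(g@calls[i, ]))
  universe <- unique(unlist(pair_mats))
  K <- length(universe)
  pairs <- list(
    p1 = match(unlist(lapply(pair_mats, function(m) m[, 1])), universe),
    p2 = match(unlist(lapply(pair_mats, function(m) m[, 2])), universe),
    pg = rep(seq_len(n_groups), vapply(pair_mats, nrow, integer(1))))

  fit <- .emCore(pairs, w, K, two_n, init_f = rep(1 / K, K),
    tol = tol, max_iter = max_iter)
  if (!fit$converged) warning("EM did not converge in ", max_iter, " iterations")
  main_trace <- fit$trace

  allowed <- rep(TRUE, K)
  cur_pairs <- pairs
  if (refine == "bic") {
    repeat {
      k_eff <- sum(fit$f > 1e-7)
      bic <- -2 * fit$logLik + (k_eff - 1) * log(two_n)
      cand <- which(allowed & fit$f > 1e-9 & fit$f * two_n < 4)
      best <- NULL
      for (h in cand) {
        allowed2 <- allowed; allowed2[h] <- FALSE
        sub <- .restrictPairs(pairs, allowed2, n_groups)
        if (is.null(sub)) next
        init <- fit$f + 1e-6       # floor lets zero-frequency alternatives re-enter
        init[!allowed2] <- 0
        init <- init / sum(init)
        trial <- .emCore(sub, w, K, two_n, init_f = init,
          tol = tol, max_iter = max_iter)
        if (!is.finite(trial$logLik)) next
        k2 <- sum(trial$f > 1e-7)
        bic2 <- -2 * trial$logLik + (k2 - 1) * log(two_n)
        if (bic2 < bic - 1e-9 && (is.null(best) || bic2 < best$bic)) {
          best <- list(h = h, fit = trial, allowed = allowed2, bic = bic2)
        }
      }
      if (is.null(best)) break
      allowed <- best$allowed
      fit <- best$fit
      cur_pairs <- .restrictPairs(pairs, allowed, n_groups)
    }
  }

  # prune haplotypes below 1/(4n), keeping every individual coverable
  prune_thr <- 1 / (4 * n)
  for (h in order(fit$f)) {
    if (!allowed[h] || fit$f[h] >= prune_thr) next
    allowed2 <- allowed; allowed2[h] <- FALSE
    sub <- .restrictPairs(pairs, allowed2, n_groups)
    if (is.null(sub)) next
    allowed <- allowed2
    cur_pairs <- sub
  }
  f <- fit$f
  f[!allowed] <- 0
  f <- f / sum(f)

  # final E-step on the surviving support for assignments and logLik
  final <- .emCore(cur_pairs, w, K, two_n, init_f = f, tol = Inf, max_iter = 1L)
  post <- final$posteriors

  keep <- which(f > 0)
  ord <- keep[order(-f[keep], universe[keep])]
  freqs <- f[ord]
  gam <- .roundGametes(freqs, two_n)
  tab <- methods::new("HaplotypeTable",
    haplotypes = .hapToLetters(universe[ord], g@variants),
    frequencies = freqs, gametes = gam, totalGametes = two_n,
    variants = g@variants, logLik = final$logLik)

  best_pair <- vapply(seq_len(n_groups), function(gi) {
    idx <- which(cur_pairs$pg == gi)
    idx[which.max(post[idx])]
  }, integer(1))
  asg <- data.frame(
    sample = g@samples,
    hap1 = .hapToLetters(universe[cur_pairs$p1[best_pair[groups]]], g@variants),
    hap2 = .hapToLetters(universe[cur_pairs$p2[best_pair[groups]]], g@variants),
    posterior = post[best_pair[groups]],
    stringsAsFactors = FALSE)
  asg$ambiguous <- asg$posterior < ambiguity_threshold

  list(table = tab, assignments = asg, logLik = final$logLik,
    iterations = fit$iterations, converged = fit$converged,
    trace = main_trace)
}

# Largest-remainder rounding of freq * two_n; ties toward larger frequency.
.roundGametes <- function(freqs, two_n) {
  raw <- freqs * two_n
  base <- floor(raw + 1e-9)
  rem <- two_n - sum(base)
  frac <- raw - base
  if (rem > 0) {
    ord <- order(-frac, -freqs)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Annotated haplotype report
#'
#' Names haplotypes `Hap1..HapK` in descending frequency order and lists,
#' for each, the loci whose allele differs from a reference haplotype.
#'
#' @param table A [HaplotypeTable-class].
#' @param reference Reference haplotype letter string; defaults to the
#'   all-reference-allele haplotype.
#' @return data.frame with `name`, `haplotype`, `frequency`, `gametes`,
#'   `n_diff`, `diff_loci` (semicolon-separated `label(allele)` entries).
#' @export
haplotypeReport <- function(table, reference = NULL) {
  stopifnot(methods::is(table, "HaplotypeTable"))
  if (!length(table@haplotypes)) stop("empty haplotype table")
  v <- table@variants
  if (is.null(reference)) reference <- paste(v$ref_allele, collapse = "")
  ord <- order(-table@frequencies, table@haplotypes)
  haps <- table@haplotypes[ord]
  ref_chars <- strsplit(reference, "")[[1]]
  diffs <- lapply(strsplit(haps, ""), function(ch) which(ch != ref_chars))
  data.frame(
    name = sprintf("Hap%d", seq_along(haps)),
    haplotype = haps,
    frequency = table@frequencies[ord],
    gametes = table@gametes[ord],
    n_diff = lengths(diffs),
    diff_loci = vapply(seq_along(haps), function(i) {
      d <- diffs[[i]]
      if (!length(d)) return("")
      paste(sprintf("%s(%s)", v$cdna_label[d],
        substring(haps[i], d, d)), collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE)
}
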