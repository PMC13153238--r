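# Independent oracles used across the test files.  These deliberately use
# brute-force enumeration / grid search rather than the package's own code
# paths.

# Two-sided Fisher exact p by full enumeration of all 2x2 tables with the
# observed margins (hypergeometric probabilities, tie tolerance 1e-7).
bruteFisher2x2 <- function(tab) {
  tab <- as.matrix(tab)
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(xs, function(x) {
    exp(lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1))
  }, numeric(1))
  p_obs <- probs[xs == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Log-likelihood of haplotype frequencies f (named by 0/1 strings) for a
# set of genotype rows, by direct enumeration of compatible pairs.
hapLogLik <- function(rows, f) {
  sum(apply(rows, 1, function(row) {
    pairs <- ovisMstn::enumerateCompatiblePairs(row)
    lik <- sum(apply(pairs, 1, function(pr) {
      fac <- if (pr[1] == pr[2]) 1 else 2
      fac * f[[pr[1]]] * f[[pr[2]]]
    }))
    log(lik)
  }))
}

# Direct maximization of the haplotype likelihood over a simplex grid
# (step `by`); hap_names must cover all haplotypes compatible with rows.
gridMaxLogLik <- function(rows, hap_names, by = 0.02) {
  pair_idx <- lapply(seq_len(nrow(rows)), function(i) {
    m <- ovisMstn::enumerateCompatiblePairs(rows[i, ])
    cbind(match(m[, 1], hap_names), match(m[, 2], hap_names),
      ifelse(m[, 1] == m[, 2], 1, 2))
  })
  stopifnot(!anyNA(unlist(pair_idx)))
  k <- length(hap_names)
  steps <- round(1 / by)
  combos <- t(utils::combn(steps + k - 1, k - 1))
  best <- -Inf; best_f <- NULL
  for (i in seq_len(nrow(combos))) {
    cuts <- c(0, combos[i, ], steps + k)
    f <- (diff(cuts) - 1) * by
    ll <- sum(vapply(pair_idx, function(mm) {
      log(sum(mm[, 3] * f[mm[, 1]] * f[mm[, 2]]))
    }, numeric(1)))
    if (is.finite(ll) && ll > best) {
      best <- ll
      best_f <- stats::setNames(f, hap_names)
    }
  }
  list(logLik = best, f = best_f)
}

# Minimum RMSD over rotations by coarse-to-fine Euler-angle grid search
# (translation handled by centering).  Independent of the Kabsch path.
gridMinRmsd <- function(mobile, reference) {
  rotZ <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
  rotY <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3)
  p <- sweep(mobile, 2, colMeans(mobile))
  q <- sweep(reference, 2, colMeans(reference))
  rmsd_for <- function(ang) {
    r <- rotZ(ang[1]) %*% rotY(ang[2]) %*% rotZ(ang[3])
    sqrt(mean(rowSums((p %*% t(r) - q)^2)))
  }
  centre <- c(pi, pi / 2, pi)
  span <- c(pi, pi / 2, pi)
  best <- c(0, 0, 0); best_val <- rmsd_for(best)
  for (level in 1:6) {
    g1 <- seq(centre[1] - span[1], centre[1] + span[1], length.out = 13)
    g2 <- seq(centre[2] - span[2], centre[2] + span[2], length.out = 13)
    g3 <- seq(centre[3] - span[3], centre[3] + span[3], length.out = 13)
    for (a in g1) for (b in g2) for (cc in g3) {
      v <- rmsd_for(c(a, b, cc))
      if (v < best_val) { best_val <- v; best <- c(a, b, cc) }
    }
    centre <- best
    span <- span / 6
  }
  best_val
}

# Exhaustive PWM p-values: enumerate all 4^w words, score with the given
# integer score matrix, tabulate the exact background-weighted tail.
brutePwmTails <- function(ints, background) {
  w <- nrow(ints)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- integer(nrow(words))
  probs <- numeric(nrow(words)) + 1
  for (i in seq_len(w)) {
    scores <- scores + ints[i, words[, i]]
    probs <- probs * background[words[, i]]
  }
  agg <- rowsum(probs, scores)
  s <- as.integer(rownames(agg))
  ord <- order(s)
  s <- s[ord]; pr <- agg[ord, 1]
  list(scores = s, tail = rev(cumsum(rev(pr))))
}

# Small two-variant metadata table for toy cohorts.
toyVariants <- function(m = 2) {
  data.frame(
    rsid = sprintf("rsT%d", seq_len(m)),
    cdna_label = sprintf("c.373+%dA>G", seq_len(m) * 10),
    intron_offset = seq_len(m) * 10L,
    ref_allele = "A", alt_allele = "G",
    genomic_pos = NA_integer_, stringsAsFactors = FALSE)
}
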