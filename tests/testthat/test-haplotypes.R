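# EM haplotype frequency estimation and phase assignment.

test_that("compatible-pair enumeration has size max(1, 2^(h-1))", {
  expect_identical(nrow(enumerateCompatiblePairs(c(0L, 2L, 0L))), 1L)
  expect_identical(nrow(enumerateCompatiblePairs(c(1L, 0L))), 1L)
  expect_identical(nrow(enumerateCompatiblePairs(c(1L, 1L))), 2L)
  expect_identical(nrow(enumerateCompatiblePairs(c(1L, 1L, 1L, 1L))), 8L)
  p <- enumerateCompatiblePairs(c(1L, 2L, 1L, 0L))
  # every pair must reconstruct the genotype
  for (i in seq_len(nrow(p))) {
    a <- as.integer(strsplit(p[i, 1], "")[[1]])
    b <- as.integer(strsplit(p[i, 2], "")[[1]])
    expect_identical(a + b, c(1L, 2L, 1L, 0L))
  }
  pm <- enumerateCompatiblePairs(c(-1L, 1L))
  expect_true(isTRUE(attr(pm, "expanded_missing")))
  expect_identical(nrow(pm), 4L)   # (0,.): 1; (1,.): 2; (2,.): 1
})

test_that("single-locus phasing returns allele frequencies as haplotype frequencies", {
  v <- toyVariants(1)
  calls <- matrix(c(rep(0L, 49), rep(1L, 4), rep(2L, 1)), ncol = 1)
  fit <- emPhase(GenotypeMatrix(calls, v))
  f <- haplotypeFrequencies(fit$table)
  expect_equal(unname(f[c("A", "G")]), c(102, 6) / 108, tolerance = 1e-9)
})

test_that("a double heterozygote resolves to the common phase with high posterior", {
  v <- toyVariants(2)
  calls <- rbind(c(0L, 0L), c(0L, 0L), c(1L, 1L))   # AB/AB x2, double het
  fit <- emPhase(GenotypeMatrix(calls, v))
  asg <- fit$assignments
  expect_gt(asg$posterior[3], 0.5)
  expect_setequal(c(asg$hap1[3], asg$hap2[3]), c("AA", "GG"))
  # oracle: exact likelihood at the two candidate fixed points
  f_coupling <- list(`00` = 5 / 6, `11` = 1 / 6, `01` = 0, `10` = 0)
  f_repulsion <- list(`00` = 4 / 6, `11` = 0, `01` = 1 / 6, `10` = 1 / 6)
  expect_gt(hapLogLik(calls, f_coupling), hapLogLik(calls, f_repulsion))
})

test_that("EM log-likelihood is non-decreasing and frequencies stay normalized", {
  set.seed(3)
  v <- toyVariants(3)
  calls <- matrix(sample(0:2, 60, replace = TRUE, prob = c(0.5, 0.35, 0.15)),
    20, 3)
  fit <- emPhase(GenotypeMatrix(calls, v), refine = "none")
  expect_true(all(diff(fit$trace) >= -1e-10))
  expect_lt(abs(sum(haplotypeFrequencies(fit$table)) - 1), 1e-9)
})

test_that("haplotype frequencies marginalize to sample allele frequencies", {
  set.seed(8)
  v <- toyVariants(4)
  calls <- matrix(sample(0:2, 120, replace = TRUE, prob = c(0.6, 0.3, 0.1)),
    30, 4)
  g <- GenotypeMatrix(calls, v)
  fit <- emPhase(g, refine = "none", tol = 1e-12)
  haps <- haplotypes(fit$table)
  f <- haplotypeFrequencies(fit$table)
  for (j in 1:4) {
    alt_freq_em <- sum(f[substring(haps, j, j) == v$alt_allele[j]])
    alt_freq_sample <- mean(calls[, j]) / 2
    expect_equal(unname(alt_freq_em), alt_freq_sample, tolerance = 1e-9)
  }
})

test_that("EM matches direct grid maximization of the likelihood (small oracle)", {
  v <- toyVariants(2)
  cases <- list(
    rbind(c(0L, 0L), c(1L, 0L), c(1L, 1L), c(2L, 1L)),
    rbind(c(1L, 1L), c(1L, 1L), c(0L, 2L), c(0L, 0L), c(2L, 2L), c(1L, 0L)))
  for (calls in cases) {
    fit <- emPhase(GenotypeMatrix(calls, v), refine = "none")
    universe <- unique(as.vector(
      do.call(rbind, lapply(seq_len(nrow(calls)), function(i)
        enumerateCompatiblePairs(calls[i, ])))))
    oracle <- gridMaxLogLik(calls, universe, by = 0.02)
    expect_gte(fit$logLik, oracle$logLik - 1e-6)
    f <- haplotypeFrequencies(fit$table)
    letters_of <- vapply(universe, function(h) {
      paste(ifelse(strsplit(h, "")[[1]] == "0", "A", "G"), collapse = "")
    }, character(1))
    for (h in universe) {
      em_f <- if (letters_of[h] %in% names(f)) unname(f[letters_of[h]]) else 0
      expect_lt(abs(em_f - oracle$f[h]), 0.03)   # grid resolution bound
    }
  }
})

test_that("simulated cohorts recover generating haplotype frequencies within 3 SE", {
  ucm_haps <- c("TGTTGTCGG", "TGTTGCCGG", "TGTTTTCGG",
    "CATTTTCAG", "TATCTTTGG", "TACTTTCGA")
  freqs <- c(95, 6, 4, 1, 1, 1) / 108
  n <- 500
  g <- simulateCohort(ucm_haps, freqs, n = n, seed = 2024)
  fit <- emPhase(g)
  est <- haplotypeFrequencies(fit$table)
  for (i in seq_along(ucm_haps)) {
    se <- sqrt(freqs[i] * (1 - freqs[i]) / (2 * n))
    got <- if (ucm_haps[i] %in% names(est)) unname(est[ucm_haps[i]]) else 0
    expect_lt(abs(got - freqs[i]), 3 * se + 1e-12)
  }
})

test_that("the reconstructed cohort phases to the six published haplotypes", {
  fit <- emPhase(reconstructUcmFixture())
  tab <- fit$table
  expect_identical(length(haplotypes(tab)), 6L)
  expect_equal(unname(haplotypeFrequencies(tab)["TGTTGTCGG"]), 95 / 108,
    tolerance = 1e-6)
  expect_identical(sum(gameteTotals(tab)), 108L)
  rep <- haplotypeReport(tab)
  expect_identical(rep$name, sprintf("Hap%d", 1:6))
  expect_identical(rep$diff_loci[2], "c.373+283T>C(C)")     # Hap2: novel site only
  expect_identical(rep$diff_loci[3], "c.373+259G>T(T)")     # Hap3
  expect_identical(rep$n_diff[1], 0L)
  ref_only <- methods::new("HaplotypeTable", haplotypes = "TGTTGTCGG",
    frequencies = 1, gametes = 10L, totalGametes = 10L,
    variants = variantInfo(tab), logLik = 0)
  expect_identical(haplotypeReport(ref_only)$diff_loci, "")
})

test_that("low-posterior individuals are flagged ambiguous", {
  v <- toyVariants(2)
  # two double-hets and balanced homozygotes: phase genuinely uncertain
  calls <- rbind(c(1L, 1L), c(1L, 1L), c(0L, 2L), c(2L, 0L), c(0L, 0L), c(2L, 2L))
  fit <- emPhase(GenotypeMatrix(calls, v))
  expect_true(any(fit$assignments$ambiguous[1:2]))
})
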