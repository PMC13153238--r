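# PWM motif scanning with exact score-distribution p-values.

make_meme <- function(lines) {
  path <- withr::local_tempfile(fileext = ".meme", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

consensus_motif <- function(word, name = "consensus") {
  idx <- match(strsplit(word, "")[[1]], c("A", "C", "G", "T"))
  probs <- matrix(1e-9 / 3, length(idx), 4)
  probs[cbind(seq_along(idx), idx)] <- 1 - 1e-9
  MotifMatrix(name, probs, pseudocount = 0)
}

test_that("MEME minimal format parsing handles backgrounds, multiple motifs and errors", {
  path <- make_meme(c(
    "MEME version 4", "", "ALPHABET= ACGT", "",
    "Background letter frequencies",
    "A 0.3 C 0.2 G 0.2 T 0.3", "",
    "MOTIF FOXO1_like",
    "letter-probability matrix: alength= 4 w= 7 nsites= 20 E= 0",
    "0.05 0.05 0.85 0.05", "0.05 0.05 0.05 0.85", "0.85 0.05 0.05 0.05",
    "0.85 0.05 0.05 0.05", "0.85 0.05 0.05 0.05", "0.05 0.85 0.05 0.05",
    "0.85 0.05 0.05 0.05", "",
    "MOTIF second",
    "letter-probability matrix: alength= 4 w= 2",
    "0.25 0.25 0.25 0.25", "0.5 0.5 0.0 0.0"))
  motifs <- readMemeMotifs(path)
  expect_length(motifs, 2L)
  expect_identical(motifs[[1]]@name, "FOXO1_like")
  expect_identical(nrow(motifs[[1]]@probs), 7L)
  expect_equal(motifs[[1]]@background, c(0.3, 0.2, 0.2, 0.3))

  bad <- make_meme(c("MEME version 4", "MOTIF bad",
    "letter-probability matrix: alength= 4 w= 2",
    "0.25 0.25 0.25 0.25", "0.4 0.3 0.1 0.1"))
  expect_error(readMemeMotifs(bad), "line 5")
})

test_that("a forced-consensus motif hits with closed-form p-value on both strands", {
  m <- consensus_motif("GTAAACA")
  hits <- scanSequence("GTAAACA", m, p_threshold = 0.001)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$strand, "+")
  expect_identical(c(hits$start, hits$end), c(1L, 7L))
  expect_equal(hits$p_value, 0.25^7, tolerance = 1e-9)
  # reverse complement sequence: one minus-strand hit, same p
  hits_rc <- scanSequence("TGTTTAC", m, p_threshold = 0.001)
  expect_identical(hits_rc$strand, "-")
  expect_equal(hits_rc$p_value, hits$p_value, tolerance = 1e-12)
  expect_identical(hits_rc$matched_sequence, "TGTTTAC")
  # sequence shorter than motif: empty result
  expect_identical(nrow(scanSequence("GTA", m)), 0L)
})

test_that("strand symmetry: scanning the reverse complement mirrors hits exactly", {
  set.seed(21)
  probs <- matrix(stats::runif(4 * 5), 5, 4)
  probs <- probs / rowSums(probs)
  m <- MotifMatrix("rand5", probs)
  seq <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
  h1 <- scanSequence(seq, m, p_threshold = 0.05)
  h2 <- scanSequence(rc, m, p_threshold = 0.05)
  expect_identical(nrow(h1), nrow(h2))
  n <- nchar(seq)
  key1 <- sort(paste(h1$start, h1$strand, round(h1$score, 9)))
  key2 <- sort(paste(n - h2$end + 1L, chartr("+-", "-+", h2$strand),
    round(h2$score, 9)))
  expect_identical(key1, key2)
  expect_equal(sort(h1$p_value), sort(h2$p_value), tolerance = 1e-12)
})

test_that("DP p-values equal exhaustive enumeration for small widths", {
  set.seed(31)
  for (w in c(4L, 6L)) {
    for (bg in list(rep(0.25, 4), c(0.4, 0.1, 0.1, 0.4))) {
      probs <- matrix(stats::rgamma(4 * w, 1), w, 4)
      probs <- probs / rowSums(probs)
      m <- MotifMatrix(sprintf("w%d", w), probs)
      pw <- ovisMstn:::.pwmInts(m, bg)
      dist <- ovisMstn:::.scoreDistribution(pw$ints, bg)
      brute <- brutePwmTails(pw$ints, bg)
      dp_p <- ovisMstn:::.pvalueLookup(dist, brute$scores)
      expect_equal(dp_p, unname(brute$tail), tolerance = 1e-9)
      # monotonicity: p-values non-increasing in score
      expect_true(all(diff(dp_p) <= 1e-15))
    }
  }
})

test_that("allele comparison classifies gained/lost/unchanged/absent", {
  m <- consensus_motif("GTAAACA")
  flank <- "CCCCCCCC"
  # T allele completes the consensus (position 2 of the motif), C breaks it
  seq <- paste0(flank, "GTAAACA", flank)
  variant <- list(ref_allele = "T", alt_allele = "C")
  res <- scanAlleles(seq, variant, offset_in_seq = 10L, motifs = list(m))
  expect_identical(res$status$status, "lost")
  expect_identical(nrow(res$hits$ref), 1L)
  expect_identical(res$hits$ref$start, 9L)    # coordinates in the full sequence
  expect_identical(nrow(res$hits$alt), 0L)
  # gained is the mirror case
  res_g <- scanAlleles(seq, list(ref_allele = "C", alt_allele = "T"),
    offset_in_seq = 10L, motifs = list(m))
  expect_identical(res_g$status$status, "gained")
  # variant far from any hit footprint: absent in both
  res_a <- scanAlleles(paste0(flank, flank), variant, offset_in_seq = 4L,
    motifs = list(m))
  expect_identical(res_a$status$status, "absent-in-both")
  # variant under the tolerant middle of a C-N-C motif: unchanged
  probs3 <- matrix(1e-9 / 3, 3, 4)
  probs3[1, 2] <- probs3[3, 2] <- 1 - 1e-9
  probs3[2, ] <- 0.25
  m2 <- MotifMatrix("CnC", probs3, pseudocount = 0)
  res_u <- scanAlleles("AACCTCCAA", list(ref_allele = "T", alt_allele = "G"),
    offset_in_seq = 5L, motifs = list(m2), p_threshold = 0.1)
  expect_identical(res_u$status$status, "unchanged")
})

test_that("BH q-values follow the step-up rule and preserve order", {
  expect_equal(bhQvalues(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bhQvalues(0.2), 0.2)
  expect_equal(bhQvalues(rep(0.05, 4)), rep(0.05, 4))
  p <- c(0.04, 0.001, 0.03)
  expect_equal(bhQvalues(p), stats::p.adjust(p, "BH"))
  expect_error(bhQvalues(c(0.5, 0)), NULL)
})
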