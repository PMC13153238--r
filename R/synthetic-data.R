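# Synthetic data: deterministic reconstruction of the 54-animal Ukrainian
# Carpathian Mountain (UCM) sheep cohort from its published per-locus and
# haplotype frequencies, plus seeded cohort and trajectory simulators.

.UCM_VARIANTS <- data.frame(
  rsid = c("rs119102826", "rs427811339", "rs406172342", "rs417602601",
    "rs119102828", "rs7600797830", "rs407388367", "rs408710650",
    "rs419902890"),
  cdna_label = c("c.373+241T>C", "c.373+243G>A", "c.373+246T>C",
    "c.373+249T>C", "c.373+259G>T", "c.373+283T>C", "c.373+323C>T",
    "c.373+563G>A", "c.373+607G>A"),
  intron_offset = c(241L, 243L, 246L, 249L, 259L, 283L, 323L, 563L, 607L),
  ref_allele = c("T", "G", "T", "T", "G", "T", "C", "G", "G"),
  alt_allele = c("C", "A", "C", "C", "T", "C", "T", "A", "A"),
  genomic_pos = NA_integer_,
  stringsAsFactors = FALSE)

#' Reconstruct the 54-animal UCM sheep genotype fixture
#'
#' Rebuilds, deterministically and without any external data, the
#' 54-individual x 9-locus genotype matrix of the Ukrainian Carpathian
#' Mountain sheep cohort from its published summary frequencies: per-locus
#' genotype counts, the six-haplotype spectrum, and the eight distinct
#' ambiguity-coded genotype motifs.
#'
#' @details
#' The published aggregates determine the individual-level data uniquely.
#' Per-locus genotype counts are: `c.373+283T>C` (49, 4, 1);
#' `c.373+259G>T` (47, 7, 0); `c.373+243G>A` (51, 3, 0); each of the six
#' remaining loci (53, 1, 0).  The haplotype table lists six haplotypes:
#' the all-reference Hap1 (95/108 gametes), Hap2 = reference + C at
#' `c.373+283` (6/108), Hap3 = reference + T at `c.373+259` (4/108), and
#' three singleton haplotypes each combining the `c.373+243` A allele with
#' `c.373+259` T and one private pair of alleles: Hap4 (C at 241, A at
#' 563), Hap5 (C at 249, T at 323), Hap6 (C at 246, A at 607).
#'
#' The only individual-level arrangement consistent with those counts,
#' with exactly eight distinct unphased motifs, and with no haplotypes
#' beyond the six listed, is: 43 all-reference individuals; 3 heterozygous
#' at `c.373+283` only (Hap1/Hap2); 1 homozygous alternative at
#' `c.373+283` (Hap2/Hap2); 1 heterozygous at both `c.373+283` and
#' `c.373+259` (Hap2/Hap3); 3 heterozygous at `c.373+259` only
#' (Hap1/Hap3); and one Hap1/Hap4, one Hap1/Hap5, one Hap1/Hap6 carrier
#' (each heterozygous at four loci).  Any other arrangement either needs a
#' 55th animal, a seventh haplotype, or a ninth+1 motif class.  Sample
#' identifiers `UCM001..UCM054` are arbitrary but fixed.
#'
#' @return A [GenotypeMatrix-class], byte-identical across runs.
#' @examples
#' g <- reconstructUcmFixture()
#' tallyMotifs(encodeMotifs(g))  # 8 motifs, reference motif at 43/54
#' @export
reconstructUcmFixture <- function() {
  v <- .UCM_VARIANTS
  # locus order: 241 243 246 249 259 283 323 563 607
  row_of <- function(het = integer(0), hom = integer(0)) {
    r <- integer(9)
    r[het] <- 1L
    r[hom] <- 2L
    r
  }
  templates <- list(
    all_ref = list(n = 43L, row = row_of()),
    het283 = list(n = 3L, row = row_of(het = 6L)),
    hom283 = list(n = 1L, row = row_of(hom = 6L)),
    het283_259 = list(n = 1L, row = row_of(het = c(5L, 6L))),
    het259 = list(n = 3L, row = row_of(het = 5L)),
    hap4 = list(n = 1L, row = row_of(het = c(1L, 2L, 5L, 8L))),
    hap5 = list(n = 1L, row = row_of(het = c(2L, 4L, 5L, 7L))),
    hap6 = list(n = 1L, row = row_of(het = c(2L, 3L, 5L, 9L))))
  calls <- do.call(rbind, unlist(lapply(templates, function(t) {
    rep(list(t$row), t$n)
  }), recursive = FALSE))
  GenotypeMatrix(calls, v, samples = sprintf("UCM%03d", seq_len(nrow(calls))))
}

#' Simulate a diploid cohort from haplotype frequencies
#'
#' Each individual draws two haplotypes i.i.d. from the given frequency
#' vector; with probability `f` (an inbreeding coefficient producing
#' excess homozygosity) the second draw copies the first.  Genotype codes
#' are derived per locus.  Fully reproducible given `seed`.
#'
#' @param haplotypes Character vector of haplotype allele strings (one
#'   letter per locus, matching `variants`).
#' @param frequencies Haplotype frequencies summing to 1.
#' @param n Number of individuals.
#' @param variants Locus metadata data.frame (as in
#'   [GenotypeMatrix-class]); defaults to the UCM panel when the haplotype
#'   strings are 9 letters long.
#' @param f Inbreeding coefficient in `[0, 1)` (or 1 for full
#'   autozygosity).
#' @param seed Integer random seed.
#' @return A [GenotypeMatrix-class].
#' @examples
#' g <- simulateCohort(c("TGTTGTCGG", "TGTTGCCGG"), c(0.9, 0.1), n = 20, seed = 1)
#' @export
simulateCohort <- function(haplotypes, frequencies, n, variants = NULL,
    f = 0, seed = 1L) {
  if (!length(haplotypes)) stop("empty haplotype set")
  stopifnot(length(haplotypes) == length(frequencies),
    abs(sum(frequencies) - 1) < 1e-9, n >= 1, f >= 0, f <= 1)
  if (is.null(variants)) {
    if (all(nchar(haplotypes) == 9L)) variants <- .UCM_VARIANTS
    else stop("variants metadata required")
  }
  variants <- .normalizeVariants(variants)
  m <- nrow(variants)
  stopifnot(all(nchar(haplotypes) == m))
  hap_alt <- t(vapply(strsplit(haplotypes, ""), function(ch) {
    as.integer(ch == variants$alt_allele)
  }, integer(m)))
  if (m == 1L) hap_alt <- matrix(hap_alt, ncol = 1L)
  withr_seed <- function(expr) {           # local RNG state
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  draws <- withr_seed({
    i1 <- sample.int(length(haplotypes), n, replace = TRUE, prob = frequencies)
    i2 <- sample.int(length(haplotypes), n, replace = TRUE, prob = frequencies)
    copy <- stats::runif(n) < f
    i2[copy] <- i1[copy]
    cbind(i1, i2)
  })
  calls <- hap_alt[draws[, 1], , drop = FALSE] + hap_alt[draws[, 2], , drop = FALSE]
  GenotypeMatrix(calls, variants, samples = sprintf("SIM%04d", seq_len(n)))
}

#' Simulate a coordinate trajectory with harmonic modes and noise
#'
#' Frames are `base + sum(amplitude * sin(phase) * direction) + noise`.
#' Mode phases sweep an integer number of full cycles across the frames,
#' so a noiseless single-mode trajectory has exactly zero time-mean
#' displacement and per-atom RMSF `amplitude * |direction| / sqrt(2)`.
#'
#' @param n_atoms Number of atoms (default base structure: a helix, so
#'   superposition is never degenerate).
#' @param n_frames Number of frames (>= 2).
#' @param modes List of modes, each a list with `direction` (either an
#'   `n_atoms x 3` matrix or a single atom's 3-vector plus `atom` index),
#'   `amplitude` (nm) and optional `cycles` (default 1).
#' @param noise_sd Isotropic Gaussian noise SD (nm), default 0.
#' @param seed Integer random seed (used for the noise).
#' @param base Optional `n_atoms x 3` base structure.
#' @param atoms Optional atom metadata (see [Trajectory()]).
#' @return A [Trajectory-class].
#' @export
simulateTrajectory <- function(n_atoms = 10L, n_frames = 50L, modes = list(),
    noise_sd = 0, seed = 1L, base = NULL, atoms = NULL) {
  stopifnot(n_frames >= 2L, noise_sd >= 0)
  if (is.null(base)) {
    t <- seq_len(n_atoms)
    base <- cbind(cos(t / 2), sin(t / 2), 0.15 * t)
  }
  stopifnot(nrow(base) == n_atoms)
  mode_mats <- lapply(modes, function(mo) {
    dir <- mo$direction
    if (is.null(dim(dir))) {
      m <- matrix(0, n_atoms, 3L)
      m[mo$atom, ] <- dir
      dir <- m
    }
    stopifnot(mo$amplitude >= 0)
    list(dir = dir, amplitude = mo$amplitude,
      cycles = if (is.null(mo$cycles)) 1L else mo$cycles)
  })
  coords <- array(0, dim = c(n_frames, n_atoms, 3L))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (fidx in seq_len(n_frames)) {
    frame <- base
    for (mo in mode_mats) {
      ph <- 2 * pi * mo$cycles * (fidx - 1) / n_frames
      frame <- frame + mo$amplitude * sin(ph) * mo$dir
    }
    if (noise_sd > 0) {
      frame <- frame + matrix(stats::rnorm(n_atoms * 3L, sd = noise_sd),
        n_atoms, 3L)
    }
    coords[fidx, , ] <- frame
  }
  if (is.null(atoms)) {
    atoms <- data.frame(name = sprintf("C1'%d", seq_len(n_atoms)),
      residue = seq_len(n_atoms), mass = 1, radius = 0.15,
      backbone = TRUE, c1p = TRUE, donor = FALSE, hydrogen = FALSE,
      acceptor = FALSE, base_pairing = FALSE, bonded_to = NA_integer_)
  }
  Trajectory(coords, atoms)
}
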