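# S4 containers for genotype panels, inferred haplotype tables, motif
# matrices and coordinate trajectories.

#' Genotype matrix for a panel of biallelic loci
#'
#' Holds diploid genotype calls for `n` individuals at `m` biallelic loci,
#' coded 0 (homozygous reference), 1 (heterozygous), 2 (homozygous
#' alternative) and -1 (missing).  Loci are kept ordered by ascending
#' intronic offset so that ambiguity-motif encoding and haplotype strings
#' are well defined.
#'
#' @slot calls Integer matrix, individuals x loci, values in {-1, 0, 1, 2}.
#' @slot variants data.frame with one row per locus: `rsid`, `cdna_label`,
#'   `intron_offset`, `ref_allele`, `alt_allele`, `genomic_pos`.
#' @slot samples Character vector of unique sample identifiers.
#' @export
setClass("GenotypeMatrix",
  representation(calls = "matrix", variants = "data.frame", samples = "character"))

setValidity("GenotypeMatrix", function(object) {
  msg <- character(0)
  if (!is.integer(object@calls)) msg <- c(msg, "calls must be an integer matrix")
  if (nrow(object@calls) != length(object@samples)) {
    msg <- c(msg, "nrow(calls) must equal length(samples)")
  }
  if (ncol(object@calls) != nrow(object@variants)) {
    msg <- c(msg, "ncol(calls) must equal nrow(variants)")
  }
  if (anyDuplicated(object@samples)) msg <- c(msg, "duplicated sample identifiers")
  vals <- unique(as.vector(object@calls))
  if (!all(vals %in% c(-1L, 0L, 1L, 2L))) {
    msg <- c(msg, "calls must be in {-1, 0, 1, 2}")
  }
  off <- object@variants$intron_offset
  if (is.unsorted(off, strictly = TRUE)) {
    msg <- c(msg, "variants must be strictly ordered by intron_offset")
  }
  if (any(object@variants$ref_allele == object@variants$alt_allele)) {
    msg <- c(msg, "ref_allele must differ from alt_allele")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param calls Numeric or integer matrix of genotype codes (individuals x
#'   loci); `NA` entries are recoded to -1 (missing).
#' @param variants data.frame of locus metadata (see
#'   [GenotypeMatrix-class]); rows are reordered by ascending
#'   `intron_offset`, and the columns of `calls` with them.
#' @param samples Character vector of sample identifiers; defaults to
#'   rownames of `calls` or `S1..Sn`.
#' @return A [GenotypeMatrix-class] object.
#' @examples
#' v <- cbind(rsid = "rs1", parseVariantLabel("c.373+283T>C"))
#' GenotypeMatrix(matrix(c(0, 1), ncol = 1), v, samples = c("a", "b"))
#' @export
GenotypeMatrix <- function(calls, variants, samples = NULL) {
  variants <- .normalizeVariants(variants)
  calls <- as.matrix(calls)
  calls[is.na(calls)] <- -1
  storage.mode(calls) <- "integer"
  if (is.null(samples)) {
    samples <- if (!is.null(rownames(calls))) rownames(calls) else
      sprintf("S%d", seq_len(nrow(calls)))
  }
  # keep calls aligned with the (re)ordered variants
  ord <- order(variants$intron_offset)  # already sorted; defensive
  dimnames(calls) <- list(samples, variants$cdna_label)
  methods::new("GenotypeMatrix", calls = calls[, ord, drop = FALSE],
    variants = variants, samples = as.character(samples))
}

#' Table of inferred haplotypes with frequencies and gamete counts
#'
#' @slot haplotypes Character vector of allele strings (one letter per locus,
#'   loci ordered by intron offset).
#' @slot frequencies Numeric vector of estimated population frequencies.
#' @slot gametes Integer vector of rounded gamete counts (summing to 2n).
#' @slot totalGametes Integer, 2n.
#' @slot variants Locus metadata (as in [GenotypeMatrix-class]).
#' @slot logLik Numeric, final log-likelihood of the frequency estimates.
#' @export
setClass("HaplotypeTable",
  representation(haplotypes = "character", frequencies = "numeric",
    gametes = "integer", totalGametes = "integer", variants = "data.frame",
    logLik = "numeric"))

setValidity("HaplotypeTable", function(object) {
  msg <- character(0)
  k <- length(object@haplotypes)
  if (length(object@frequencies) != k || length(object@gametes) != k) {
    msg <- c(msg, "haplotypes, frequencies and gametes must have equal length")
  }
  if (k && abs(sum(object@frequencies) - 1) > 1e-9) {
    msg <- c(msg, "frequencies must sum to 1")
  }
  if (k && sum(object@gametes) != object@totalGametes) {
    msg <- c(msg, "gamete counts must sum to totalGametes")
  }
  m <- nrow(object@variants)
  if (k && any(nchar(object@haplotypes) != m)) {
    msg <- c(msg, "haplotype strings must have one letter per locus")
  }
  if (length(msg)) msg else TRUE
})

#' Position weight matrix in letter-probability form
#'
#' @slot name Motif identifier.
#' @slot probs Numeric matrix, width x 4, columns A/C/G/T; rows sum to 1.
#' @slot background Numeric vector of 4 background letter frequencies.
#' @slot pseudocount Smoothing constant added to probabilities before
#'   log-odds scoring.
#' @export
setClass("MotifMatrix",
  representation(name = "character", probs = "matrix",
    background = "numeric", pseudocount = "numeric"))

setValidity("MotifMatrix", function(object) {
  msg <- character(0)
  if (ncol(object@probs) != 4L) msg <- c(msg, "probs must have 4 columns (A,C,G,T)")
  if (nrow(object@probs) < 2L) msg <- c(msg, "motif width must be >= 2")
  if (any(abs(rowSums(object@probs) - 1) > 1e-6)) {
    msg <- c(msg, "each probs row must sum to 1 (within 1e-6)")
  }
  if (length(object@background) != 4L || abs(sum(object@background) - 1) > 1e-6) {
    msg <- c(msg, "background must be 4 frequencies summing to 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MotifMatrix
#' @param name Motif identifier.
#' @param probs width x 4 letter-probability matrix (columns A, C, G, T).
#' @param background Background letter frequencies (default uniform).
#' @param pseudocount Smoothing constant (default 0.001; JASPAR matrices
#'   contain exact zeros).
#' @return A [MotifMatrix-class] object.
#' @export
MotifMatrix <- function(name, probs, background = rep(0.25, 4), pseudocount = 0.001) {
  probs <- as.matrix(probs)
  colnames(probs) <- c("A", "C", "G", "T")
  methods::new("MotifMatrix", name = name, probs = probs,
    background = as.numeric(background), pseudocount = pseudocount)
}

#' Coordinate trajectory with atom metadata
#'
#' @slot coords Numeric array frames x atoms x 3, nanometres.
#' @slot atoms data.frame with per-atom columns `name`, `residue`, `mass`,
#'   `radius` and logical role flags `backbone`, `c1p`, `donor`, `hydrogen`,
#'   `acceptor`, `base_pairing`, plus optional `bonded_to` (index of the
#'   donor a hydrogen is covalently attached to).
#' @slot provenance Character vector labelling the origin of each frame.
#' @export
setClass("Trajectory",
  representation(coords = "array", atoms = "data.frame", provenance = "character"))

setValidity("Trajectory", function(object) {
  msg <- character(0)
  d <- dim(object@coords)
  if (length(d) != 3L || d[3] != 3L) msg <- c(msg, "coords must be frames x atoms x 3")
  if (!is.null(d) && d[2] != nrow(object@atoms)) {
    msg <- c(msg, "atom count must match atoms metadata")
  }
  if (any(!is.finite(object@coords))) msg <- c(msg, "coordinates must be finite")
  if (any(object@atoms$mass <= 0)) msg <- c(msg, "masses must be > 0")
  if (length(object@provenance) && length(object@provenance) != d[1]) {
    msg <- c(msg, "provenance must label every frame")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Trajectory
#' @param coords Numeric array frames x atoms x 3 (nm).
#' @param atoms Per-atom metadata data.frame; missing role columns are
#'   filled with defaults (mass 1, radius 0.15 nm, all flags FALSE).
#' @param provenance Optional per-frame origin labels.
#' @return A [Trajectory-class] object.
#' @export
Trajectory <- function(coords, atoms = NULL, provenance = character(0)) {
  coords <- unname(coords)
  n_atoms <- dim(coords)[2]
  if (is.null(atoms)) atoms <- data.frame(name = sprintf("A%d", seq_len(n_atoms)))
  defaults <- list(residue = seq_len(n_atoms), mass = 1, radius = 0.15,
    backbone = FALSE, c1p = FALSE, donor = FALSE, hydrogen = FALSE,
    acceptor = FALSE, base_pairing = FALSE, bonded_to = NA_integer_)
  for (col in names(defaults)) {
    if (!col %in% names(atoms)) atoms[[col]] <- defaults[[col]]
  }
  methods::new("Trajectory", coords = coords, atoms = atoms,
    provenance = as.character(provenance))
}
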