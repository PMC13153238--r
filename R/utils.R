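# Shared small helpers: IUPAC codes and HGVS-like intronic variant labels.

.IUPAC_PAIR <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

#' IUPAC ambiguity code for a pair of nucleotides
#'
#' Returns the single-letter IUPAC code representing an unordered pair of
#' bases; identical bases return the base itself (Y = C/T, R = A/G, W = A/T,
#' S = C/G, K = G/T, M = A/C).
#'
#' @param a,b Single characters in `A`, `C`, `G`, `T`.
#' @return A single character.
#' @examples
#' iupacCode("C", "T")  # "Y"
#' @export
iupacCode <- function(a, b) {
  stopifnot(a %in% c("A", "C", "G", "T"), b %in% c("A", "C", "G", "T"))
  if (a == b) return(a)
  unname(.IUPAC_PAIR[paste(sort(c(a, b)), collapse = "")])
}

#' Parse an HGVS-like intronic variant label
#'
#' Labels of the form `c.373+283T>C` encode the offset into the intron (the
#' `N` of `c.<exon end>+N`), the reference allele and the alternative allele.
#'
#' @param label Character vector of labels.
#' @return A data.frame with columns `cdna_label`, `intron_offset`,
#'   `ref_allele`, `alt_allele`.
#' @examples
#' parseVariantLabel("c.373+283T>C")
#' @export
parseVariantLabel <- function(label) {
  m <- regmatches(label, regexec("^c\\.(\\d+)\\+(\\d+)([ACGT])>([ACGT])$", label))
  bad <- vapply(m, length, integer(1)) != 5L
  if (any(bad)) {
    stop("cannot parse variant label(s): ", paste(label[bad], collapse = ", "))
  }
  data.frame(
    cdna_label = label,
    intron_offset = vapply(m, function(x) as.integer(x[3]), integer(1)),
    ref_allele = vapply(m, function(x) x[4], character(1)),
    alt_allele = vapply(m, function(x) x[5], character(1)),
    stringsAsFactors = FALSE
  )
}

# Reverse complement for plain character DNA strings (ACGTN).
.revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

# Validate/normalize a variants data.frame; sorts by intron_offset.
.normalizeVariants <- function(variants) {
  need <- c("rsid", "cdna_label", "intron_offset", "ref_allele", "alt_allele")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("variants table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"genomic_pos" %in% names(variants)) variants$genomic_pos <- NA_integer_
  variants$intron_offset <- as.integer(variants$intron_offset)
  if (any(variants$intron_offset < 1L)) stop("intron_offset must be >= 1")
  if (any(variants$ref_allele == variants$alt_allele)) {
    stop("ref_allele must differ from alt_allele")
  }
  ok <- variants$ref_allele %in% c("A", "C", "G", "T") &
    variants$alt_allele %in% c("A", "C", "G", "T")
  if (!all(ok)) stop("alleles must be single bases A/C/G/T")
  variants <- variants[order(variants$intron_offset), , drop = FALSE]
  if (anyDuplicated(variants$intron_offset)) stop("duplicated intron offsets")
  rownames(variants) <- NULL
  variants
}
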