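# Ambiguity-coded genotype motifs: one string per individual, one letter
# per locus, heterozygotes coded by the two-allele IUPAC letter.

#' Encode unphased multilocus genotypes as IUPAC ambiguity motifs
#'
#' Every individual becomes a string with one letter per locus (loci ordered
#' by ascending intron offset): the reference letter for homozygous
#' reference calls, the alternative letter for homozygous alternative
#' calls, the IUPAC two-allele ambiguity code for heterozygotes, and `N`
#' for missing calls.
#'
#' @param g A [GenotypeMatrix-class].
#' @return Character vector of motifs, named by sample.
#' @examples
#' g <- reconstructUcmFixture()
#' encodeMotifs(g)[1]  # "TGTTGTCGG"
#' @export
encodeMotifs <- function(g) {
  stopifnot(methods::is(g, "GenotypeMatrix"))
  v <- g@variants
  het <- mapply(iupacCode, v$ref_allele, v$alt_allele)
  lut <- rbind(v$ref_allele, het, v$alt_allele)   # rows: code 0, 1, 2
  calls <- g@calls
  out <- vapply(seq_len(nrow(calls)), function(i) {
    letters <- ifelse(calls[i, ] < 0L, "N",
      lut[cbind(calls[i, ] + 1L, seq_len(ncol(calls)))])
    paste(letters, collapse = "")
  }, character(1))
  stats::setNames(out, g@samples)
}

#' Tally distinct genotype motifs
#'
#' @param motifs Character vector of motifs (e.g. from [encodeMotifs()]).
#' @return data.frame with columns `motif`, `count`, `frequency`, ordered by
#'   descending count then lexicographically; counts sum to the number of
#'   individuals and frequencies to 1.
#' @export
tallyMotifs <- function(motifs) {
  if (!length(motifs)) stop("empty motif list")
  tab <- table(motifs)
  df <- data.frame(motif = names(tab), count = as.integer(tab),
    stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$motif), , drop = FALSE]
  df$frequency <- df$count / sum(df$count)
  rownames(df) <- NULL
  df
}
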