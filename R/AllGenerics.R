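# Generics, accessors and show methods.

#' Accessors for GenotypeMatrix objects
#'
#' `nSamples` and `nLoci` return the matrix dimensions, `sampleIds` the
#' sample identifiers, `variantInfo` the locus metadata data.frame (also
#' available for [HaplotypeTable-class]) and `genotypeCalls` the integer
#' matrix of genotype codes.
#'
#' @param object A [GenotypeMatrix-class] (or, for `variantInfo`, a
#'   [HaplotypeTable-class]).
#' @return See the individual accessor descriptions.
#' @name genotype-accessors
#' @examples
#' g <- reconstructUcmFixture()
#' nSamples(g); nLoci(g)
NULL

#' @rdname genotype-accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @rdname genotype-accessors
#' @export
setGeneric("nLoci", function(object) standardGeneric("nLoci"))

#' @rdname genotype-accessors
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname genotype-accessors
#' @export
setGeneric("variantInfo", function(object) standardGeneric("variantInfo"))

#' @rdname genotype-accessors
#' @export
setGeneric("genotypeCalls", function(object) standardGeneric("genotypeCalls"))

#' @rdname genotype-accessors
#' @export
setMethod("nSamples", "GenotypeMatrix", function(object) length(object@samples))

#' @rdname genotype-accessors
#' @export
setMethod("nLoci", "GenotypeMatrix", function(object) nrow(object@variants))

#' @rdname genotype-accessors
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(object) object@samples)

#' @rdname genotype-accessors
#' @export
setMethod("variantInfo", "GenotypeMatrix", function(object) object@variants)

#' @rdname genotype-accessors
#' @export
setMethod("genotypeCalls", "GenotypeMatrix", function(object) object@calls)

#' @rdname genotype-accessors
#' @export
setMethod("variantInfo", "HaplotypeTable", function(object) object@variants)

#' Accessors for HaplotypeTable objects
#'
#' `haplotypes` returns the allele strings, `haplotypeFrequencies` the
#' estimated frequencies (named by haplotype) and `gameteTotals` the
#' rounded gamete counts (summing to 2n).
#'
#' @param object A [HaplotypeTable-class].
#' @return See the individual accessor descriptions.
#' @name haplotype-accessors
NULL

#' @rdname haplotype-accessors
#' @export
setGeneric("haplotypes", function(object) standardGeneric("haplotypes"))

#' @rdname haplotype-accessors
#' @export
setGeneric("haplotypeFrequencies", function(object) standardGeneric("haplotypeFrequencies"))

#' @rdname haplotype-accessors
#' @export
setGeneric("gameteTotals", function(object) standardGeneric("gameteTotals"))

#' @rdname haplotype-accessors
#' @export
setMethod("haplotypes", "HaplotypeTable", function(object) object@haplotypes)

#' @rdname haplotype-accessors
#' @export
setMethod("haplotypeFrequencies", "HaplotypeTable", function(object) {
  stats::setNames(object@frequencies, object@haplotypes)
})

#' @rdname haplotype-accessors
#' @export
setMethod("gameteTotals", "HaplotypeTable", function(object) {
  stats::setNames(object@gametes, object@haplotypes)
})

#' Accessors for Trajectory objects
#'
#' `nFrames` returns the frame count and `atomInfo` the per-atom metadata.
#'
#' @param object A [Trajectory-class].
#' @return See the individual accessor descriptions.
#' @name trajectory-accessors
NULL

#' @rdname trajectory-accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname trajectory-accessors
#' @export
setGeneric("atomInfo", function(object) standardGeneric("atomInfo"))

#' @rdname trajectory-accessors
#' @export
setMethod("nFrames", "Trajectory", function(object) unname(dim(object@coords)[1]))

#' @rdname trajectory-accessors
#' @export
setMethod("atomInfo", "Trajectory", function(object) object@atoms)

#' @export
setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d individuals x %d loci\n",
    nSamples(object), nLoci(object)))
  cat("loci:", paste(object@variants$cdna_label, collapse = ", "), "\n")
  n_miss <- sum(object@calls == -1L)
  if (n_miss) cat(sprintf("missing calls: %d\n", n_miss))
})

#' @export
setMethod("show", "HaplotypeTable", function(object) {
  cat(sprintf("HaplotypeTable: %d haplotypes over %d loci (2n = %d)\n",
    length(object@haplotypes), nrow(object@variants), object@totalGametes))
  print(as.data.frame(object))
})

#' Coerce a HaplotypeTable to a data.frame
#' @param x A [HaplotypeTable-class].
#' @param ... Unused.
#' @return data.frame with `haplotype`, `frequency`, `gametes`.
#' @export
as.data.frame.HaplotypeTable <- function(x, ...) {
  data.frame(haplotype = x@haplotypes, frequency = x@frequencies,
    gametes = x@gametes, stringsAsFactors = FALSE)
}

#' @export
setMethod("show", "MotifMatrix", function(object) {
  cat(sprintf("MotifMatrix '%s': width %d, pseudocount %g\n",
    object@name, nrow(object@probs), object@pseudocount))
})

#' @export
setMethod("show", "Trajectory", function(object) {
  d <- dim(object@coords)
  cat(sprintf("Trajectory: %d frames x %d atoms\n", d[1], d[2]))
  roles <- c("backbone", "c1p", "donor", "hydrogen", "acceptor")
  n <- vapply(roles, function(r) sum(object@atoms[[r]]), numeric(1))
  cat("atom roles:", paste(sprintf("%s=%d", roles, n), collapse = " "), "\n")
})
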