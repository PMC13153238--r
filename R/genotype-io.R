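# Genotype input/output: CSV panels, minimal VCF 4.2, summary tables, FASTA.

#' Read a genotype matrix from CSV or minimal VCF
#'
#' The CSV dialect has a header `sample,<label_1>,...,<label_m>` where each
#' label is an HGVS-like intronic variant label (`c.373+283T>C`), optionally
#' prefixed `rsid:` to carry an rsID.  Cells contain genotype codes
#' (`0`/`1`/`2`/`NA`) or allele pairs (`T/C`).  The VCF dialect is VCF 4.2
#' with biallelic SNP records and a `GT` field; unphased `/` and phased `|`
#' separators are both accepted (phase is ignored at this layer).
#'
#' Unparseable genotype cells become missing calls (-1) with a warning;
#' duplicated sample identifiers and multi-allelic records are errors.
#'
#' @param path File to read.
#' @param format `"csv"` or `"vcf"`.
#' @param variants Optional locus metadata data.frame used to override or
#'   complete what the file itself carries (matched by `rsid`, then by
#'   `cdna_label`).
#' @return A [GenotypeMatrix-class].
#' @seealso [writeGenotypes()]
#' @export
readGenotypes <- function(path, format = c("csv", "vcf"), variants = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  g <- switch(format, csv = .readGenotypesCsv(path), vcf = .readGenotypesVcf(path))
  if (!is.null(variants)) {
    v <- g@variants
    key <- if ("rsid" %in% names(variants) &&
      all(v$rsid %in% variants$rsid)) "rsid" else "cdna_label"
    idx <- match(v[[key]], variants[[key]])
    if (anyNA(idx)) stop("variants metadata does not cover all loci in file")
    g <- GenotypeMatrix(g@calls, .normalizeVariants(variants[idx, , drop = FALSE]),
      samples = g@samples)
  }
  g
}

.parseHeaderToken <- function(tok) {
  has_rsid <- grepl(":", tok, fixed = TRUE)
  rsid <- ifelse(has_rsid, sub(":.*$", "", tok), tok)
  label <- ifelse(has_rsid, sub("^[^:]*:", "", tok), tok)
  cbind(rsid = rsid, parseVariantLabel(label))
}

.readGenotypesCsv <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (names(raw)[1] != "sample") stop("CSV header must start with 'sample'")
  samples <- raw[[1]]
  if (anyDuplicated(samples)) {
    stop("duplicated sample IDs: ",
      paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  variants <- .parseHeaderToken(names(raw)[-1])
  cells <- as.matrix(raw[, -1, drop = FALSE])
  calls <- matrix(-1L, nrow(cells), ncol(cells))
  n_bad <- 0L
  for (j in seq_len(ncol(cells))) {
    x <- trimws(cells[, j])
    code <- suppressWarnings(as.integer(x))
    is_pair <- grepl("^[ACGT]/[ACGT]$", x)
    if (any(is_pair)) {
      a1 <- substr(x[is_pair], 1, 1); a2 <- substr(x[is_pair], 3, 3)
      ref <- variants$ref_allele[j]; alt <- variants$alt_allele[j]
      pc <- (a1 == alt) + (a2 == alt)
      pc[!(a1 %in% c(ref, alt)) | !(a2 %in% c(ref, alt))] <- NA_integer_
      code[is_pair] <- pc
    }
    bad <- !is.na(x) & x != "" & x != "NA" & is.na(code)
    bad <- bad | (!is.na(code) & !code %in% 0:2)
    n_bad <- n_bad + sum(bad)
    code[bad] <- NA_integer_
    calls[, j] <- ifelse(is.na(code), -1L, code)
  }
  if (n_bad) warning(n_bad, " unparseable genotype cell(s) set to missing")
  GenotypeMatrix(calls, variants, samples = samples)
}

.readGenotypesVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix[, , drop = FALSE], stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE) | nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L
  if (any(multi)) {
    stop("non-biallelic-SNP record(s): ",
      paste(fix$ID[multi], collapse = ", "))
  }
  info <- v@fix[, "INFO"]
  info[is.na(info)] <- ""
  pull_info <- function(key) {
    pat <- paste0("(^|;)", key, "=([^;]+)")
    has <- grepl(pat, info)
    out <- rep(NA_character_, length(info))
    out[has] <- sub(paste0(".*", pat, ".*"), "\\2", info[has])
    out
  }
  info_cdna <- pull_info("CDNA")
  info_off <- suppressWarnings(as.integer(pull_info("OFFSET")))
  label <- ifelse(is.na(info_cdna),
    paste0(fix$CHROM, ":", fix$POS, fix$REF, ">", fix$ALT), info_cdna)
  offset <- ifelse(is.na(info_off), as.integer(fix$POS), info_off)
  variants <- data.frame(
    rsid = ifelse(fix$ID == "." | is.na(fix$ID), label, fix$ID),
    cdna_label = label, intron_offset = offset,
    ref_allele = fix$REF, alt_allele = fix$ALT,
    genomic_pos = suppressWarnings(as.integer(fix$POS)),
    stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")   # loci x samples
  if (anyDuplicated(colnames(gt))) stop("duplicated sample IDs in VCF")
  gt[is.na(gt)] <- "./."
  missing_gt <- gt %in% c("./.", ".|.", ".")
  parts <- strsplit(as.vector(gt), "[/|]")
  ok <- vapply(parts, function(p) length(p) == 2L && all(p %in% c("0", "1")),
    logical(1))
  codes <- rep(NA_integer_, length(parts))
  codes[ok] <- vapply(parts[ok], function(p) sum(p == "1"), integer(1))
  n_bad <- sum(is.na(codes) & !as.vector(missing_gt))
  if (n_bad) warning(n_bad, " unparseable GT field(s) set to missing")
  codes[is.na(codes)] <- -1L
  codes <- matrix(codes, nrow = nrow(gt), ncol = ncol(gt))
  GenotypeMatrix(t(codes), variants, samples = colnames(gt))
}

#' Write a genotype matrix to CSV or minimal VCF
#'
#' CSV output uses the header convention of [readGenotypes()] (rsIDs kept as
#' a `rsid:label` prefix when they differ from the label).  VCF output is a
#' minimal VCF 4.2 with `GT`-only genotypes and `CDNA`/`OFFSET` INFO keys so
#' that reading the file back reproduces the object.
#'
#' @param g A [GenotypeMatrix-class].
#' @param path Output file.
#' @param format `"csv"` or `"vcf"`.
#' @return Invisibly, `path`.
#' @export
writeGenotypes <- function(g, path, format = c("csv", "vcf")) {
  format <- match.arg(format)
  v <- g@variants
  if (format == "csv") {
    tok <- ifelse(v$rsid == v$cdna_label, v$cdna_label,
      paste0(v$rsid, ":", v$cdna_label))
    calls <- g@calls
    out <- data.frame(sample = g@samples, stringsAsFactors = FALSE)
    for (j in seq_len(ncol(calls))) {
      col <- as.character(calls[, j])
      col[calls[, j] == -1L] <- "NA"
      out[[tok[j]]] <- col
    }
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    gt_codes <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1", `-1` = "./.")
    hdr <- c("##fileformat=VCFv4.2",
      "##INFO=<ID=CDNA,Number=1,Type=String,Description=\"Intronic variant label\">",
      "##INFO=<ID=OFFSET,Number=1,Type=Integer,Description=\"Intron offset\">",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
        "FORMAT", g@samples), collapse = "\t"))
    pos <- ifelse(is.na(v$genomic_pos), v$intron_offset, v$genomic_pos)
    rows <- vapply(seq_len(nrow(v)), function(i) {
      paste(c("intron1", pos[i], v$rsid[i], v$ref_allele[i], v$alt_allele[i],
        ".", "PASS",
        sprintf("CDNA=%s;OFFSET=%d", v$cdna_label[i], v$intron_offset[i]),
        "GT", gt_codes[as.character(g@calls[, i])]), collapse = "\t")
    }, character(1))
    writeLines(c(hdr, rows), path)
  }
  invisible(path)
}

#' Write a tabular result to CSV or TSV
#'
#' Numeric columns survive a write/read round trip to at least 12
#' significant digits.
#'
#' @param table A data.frame (or matrix).
#' @param path Output file.
#' @param format `"csv"` or `"tsv"`.
#' @return Invisibly, `path`.
#' @export
writeSummary <- function(table, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  df <- as.data.frame(table)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) {
      df[[j]] <- formatC(df[[j]], digits = 15, format = "g")
    }
  }
  utils::write.table(df, path, sep = if (format == "csv") "," else "\t",
    row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read DNA sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning plain
#' upper-case character strings suitable for [scanSequence()].
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
readFasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(seqs)), names(seqs))
}
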