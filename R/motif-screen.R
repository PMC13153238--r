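# PWM motif scanning with exact score-distribution p-values.
#
# Scores are log2 odds of pseudocounted letter probabilities over a 0-order
# background.  P-values come from the exact distribution of scores of
# background-weighted random words, computed by dynamic programming over
# integer-discretized scores; the discretization bin width is chosen so the
# accumulated rounding error is below 1e-3 in score units, and observed hit
# scores are discretized identically so DP and enumeration agree exactly.

#' Read motifs in MEME minimal letter-probability format
#'
#' Parses `MOTIF` blocks with their `letter-probability matrix` sections;
#' uses the file's `Background letter frequencies` if present, else
#' uniform.
#'
#' @param path MEME-format text file.
#' @param pseudocount Smoothing constant attached to each motif.
#' @return List of [MotifMatrix-class] objects.
#' @export
readMemeMotifs <- function(path, pseudocount = 0.001) {
  lines <- readLines(path)
  background <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(trimws(lines[bg_at[1] + 1L]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    background <- vals[!is.na(vals)]
    if (length(background) != 4L) {
      stop("malformed background frequencies at line ", bg_at[1] + 1L)
    }
  }
  motif_at <- grep("^MOTIF", lines)
  if (!length(motif_at)) stop("no MOTIF entries found in ", path)
  lapply(motif_at, function(start) {
    name <- trimws(sub("^MOTIF\\s+", "", lines[start]))
    hdr_rel <- grep("^letter-probability matrix", lines[seq(start, length(lines))])
    if (!length(hdr_rel)) stop("no letter-probability matrix for motif ", name)
    hdr <- start + hdr_rel[1] - 1L
    w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", lines[hdr]))
    if (is.na(w)) stop("cannot parse motif width at line ", hdr)
    rows <- lapply(seq_len(w), function(i) {
      ln <- hdr + i
      vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[ln]), "\\s+")[[1]]))
      if (length(vals) != 4L || anyNA(vals)) {
        stop("malformed matrix row at line ", ln)
      }
      if (abs(sum(vals) - 1) > 1e-6) {
        stop("matrix row does not sum to 1 at line ", ln)
      }
      vals
    })
    MotifMatrix(name, do.call(rbind, rows), background = background,
      pseudocount = pseudocount)
  })
}

# Integer-discretized log2-odds score matrix (width x 4) and bin width.
.pwmInts <- function(motif, background) {
  w <- nrow(motif@probs)
  probs <- motif@probs + motif@pseudocount
  probs <- probs / rowSums(probs)
  s <- log2(sweep(probs, 2L, background, "/"))
  binwidth <- 1e-3 / w          # accumulated rounding error <= w * bin/2 = 5e-4
  list(ints = round(s / binwidth), binwidth = binwidth)
}

# Exact distribution of integer scores of random background words:
# position-wise convolution.  Returns upper-tail p-values indexed by
# integer score offset.
.scoreDistribution <- function(ints, background) {
  dist <- 1
  cur_min <- 0L; cur_max <- 0L
  for (i in seq_len(nrow(ints))) {
    lo <- cur_min + min(ints[i, ]); hi <- cur_max + max(ints[i, ])
    new <- numeric(hi - lo + 1L)
    for (l in 1:4) {
      sh <- ints[i, l]
      idx <- (cur_min + sh - lo + 1L):(cur_max + sh - lo + 1L)
      new[idx] <- new[idx] + background[l] * dist
    }
    dist <- new; cur_min <- lo; cur_max <- hi
  }
  list(min = cur_min, max = cur_max, prob = dist,
    tail = rev(cumsum(rev(dist))))
}

.pvalueLookup <- function(dist, int_scores) {
  idx <- pmin(pmax(int_scores, dist$min), dist$max) - dist$min + 1L
  p <- dist$tail[idx]
  p[int_scores > dist$max] <- 0            # unreachable above support
  p[int_scores < dist$min] <- 1
  pmin(pmax(p, .Machine$double.xmin), 1)
}

.reverseComplementMotif <- function(motif) {
  MotifMatrix(motif@name, motif@probs[rev(seq_len(nrow(motif@probs))), 4:1],
    background = motif@background, pseudocount = motif@pseudocount)
}

# Integer window scores for one strand; NA where the window has non-ACGT.
.windowScores <- function(seq_idx, ints) {
  w <- nrow(ints)
  n_win <- length(seq_idx) - w + 1L
  if (n_win < 1L) return(integer(0))
  total <- integer(n_win)
  bad <- logical(n_win)
  for (i in seq_len(w)) {
    li <- seq_idx[i:(i + n_win - 1L)]
    ok <- !is.na(li)
    bad <- bad | !ok
    total[ok] <- total[ok] + ints[i, li[ok]]
  }
  total[bad] <- NA_integer_
  total
}

#' Scan a DNA sequence with a position weight matrix
#'
#' Both strands are scanned; minus-strand hits are reported on
#' forward-strand 1-based inclusive coordinates with the forward-strand
#' letters as `matched_sequence`.  P-values are exact upper-tail
#' probabilities of the (discretized) score under the background model;
#' q-values are Benjamini-Hochberg adjusted across all windows of this
#' scan (both strands).  Windows containing non-ACGT letters are skipped.
#'
#' @param seq DNA sequence (character string, ACGTN).
#' @param motif A [MotifMatrix-class].
#' @param p_threshold Report hits with `p < p_threshold` (default 0.001).
#' @param background `"uniform"` (default), `"sequence"` (0-order
#'   frequencies of the scanned sequence), or a numeric vector of 4
#'   frequencies.
#' @return data.frame with `motif`, `strand`, `start`, `end`, `score`,
#'   `p_value`, `q_value`, `matched_sequence`, sorted by position.
#' @export
scanSequence <- function(seq, motif, p_threshold = 0.001,
    background = "uniform") {
  stopifnot(methods::is(motif, "MotifMatrix"))
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!(is.numeric(p_threshold) && p_threshold > 0 && p_threshold < 1)) {
    stop("p_threshold must be in (0, 1)")
  }
  seq <- toupper(seq)
  chars <- strsplit(seq, "")[[1]]
  seq_idx <- match(chars, c("A", "C", "G", "T"))
  w <- nrow(motif@probs)
  empty <- data.frame(motif = character(0), strand = character(0),
    start = integer(0), end = integer(0), score = numeric(0),
    p_value = numeric(0), q_value = numeric(0),
    matched_sequence = character(0), stringsAsFactors = FALSE)
  if (length(chars) < w) return(empty)

  bg <- if (is.numeric(background)) {
    background / sum(background)
  } else if (identical(background, "sequence")) {
    cnt <- tabulate(seq_idx, 4L)
    if (sum(cnt) == 0) rep(0.25, 4) else cnt / sum(cnt)
  } else rep(0.25, 4)

  strands <- list(`+` = motif, `-` = .reverseComplementMotif(motif))
  hits <- list()
  all_p <- numeric(0)
  for (s in names(strands)) {
    pw <- .pwmInts(strands[[s]], bg)
    dist <- .scoreDistribution(pw$ints, bg)
    int_sc <- .windowScores(seq_idx, pw$ints)
    ok <- which(!is.na(int_sc))
    if (!length(ok)) next
    p <- .pvalueLookup(dist, int_sc[ok])
    keep <- p < p_threshold
    if (any(keep)) {
      hits[[s]] <- data.frame(
        motif = motif@name, strand = s,
        start = ok[keep], end = ok[keep] + w - 1L,
        score = int_sc[ok][keep] * pw$binwidth,
        p_value = p[keep],
        q_index = length(all_p) + which(keep),
        matched_sequence = substring(seq, ok[keep], ok[keep] + w - 1L),
        stringsAsFactors = FALSE)
    }
    all_p <- c(all_p, p)
  }
  out <- if (length(hits)) do.call(rbind, hits) else empty
  if (nrow(out)) {
    q_all <- bhQvalues(all_p)
    out$q_value <- q_all[out$q_index]
    out$q_index <- NULL
    out <- out[, c("motif", "strand", "start", "end", "score", "p_value",
      "q_value", "matched_sequence")]
    out <- out[order(out$start, out$strand), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Compare motif hits between the two alleles of a variant
#'
#' Substitutes each allele into the sequence, scans a window of
#' `max motif width - 1` (plus `window` slack) around the variant with
#' every motif, and classifies each motif by the presence of hits whose
#' footprint covers the variant position: `gained` (alt only), `lost`
#' (ref only), `unchanged` (both) or `absent-in-both`.
#'
#' @param seq DNA sequence containing the variant.
#' @param variant One-row data.frame (or list) with `ref_allele` and
#'   `alt_allele` (e.g. a row of [variantInfo()]).
#' @param offset_in_seq 1-based position of the variant within `seq`.
#' @param motifs List of [MotifMatrix-class] objects.
#' @param p_threshold Hit threshold, see [scanSequence()].
#' @param window Extra slack (bases) added on each side of the scan window.
#' @param background Background model, see [scanSequence()].
#' @return List with `status` (data.frame `motif`, `status`) and `hits`
#'   (per-allele hit tables in sequence coordinates).
#' @export
scanAlleles <- function(seq, variant, offset_in_seq, motifs,
    p_threshold = 0.001, window = 0L, background = "uniform") {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (offset_in_seq < 1L || offset_in_seq > n) stop("offset out of range")
  if (methods::is(motifs, "MotifMatrix")) motifs <- list(motifs)
  max_w <- max(vapply(motifs, function(m) nrow(m@probs), integer(1)))
  lo <- max(1L, offset_in_seq - (max_w - 1L) - window)
  hi <- min(n, offset_in_seq + (max_w - 1L) + window)
  pos_in_win <- offset_in_seq - lo + 1L

  sub_with <- function(allele) {
    s <- substring(seq, lo, hi)
    substr(s, pos_in_win, pos_in_win) <- allele
    s
  }
  seq_ref <- sub_with(variant$ref_allele)
  seq_alt <- sub_with(variant$alt_allele)

  scan_one <- function(s) {
    res <- lapply(motifs, function(m) {
      h <- scanSequence(s, m, p_threshold = p_threshold, background = background)
      h[h$start <= pos_in_win & h$end >= pos_in_win, , drop = FALSE]
    })
    out <- do.call(rbind, res)
    if (nrow(out)) {
      out$start <- out$start + lo - 1L
      out$end <- out$end + lo - 1L
    }
    out
  }
  hits_ref <- scan_one(seq_ref)
  hits_alt <- scan_one(seq_alt)

  status <- vapply(motifs, function(m) {
    in_ref <- m@name %in% hits_ref$motif
    in_alt <- m@name %in% hits_alt$motif
    if (in_ref && in_alt) "unchanged"
    else if (in_ref) "lost"
    else if (in_alt) "gained"
    else "absent-in-both"
  }, character(1))
  list(
    status = data.frame(
      motif = vapply(motifs, function(m) m@name, character(1)),
      status = status, stringsAsFactors = FALSE),
    hits = list(ref = hits_ref, alt = hits_alt))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Standard step-up false discovery rate adjustment with monotonicity
#' enforcement; input order is preserved.
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @export
bhQvalues <- function(p_values) {
  stopifnot(all(p_values > 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}
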