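#' Signed binomial log10-odds statistic
#'
#' The pLogo-style statistic for a residue observed k times among n
#' foreground sequences given background frequency \code{pBg}: when k is at
#' or above its expectation, \code{p = P[Binomial(n, pBg) >= k]} and
#' \code{s = log10((1-p)/p)}; otherwise \code{p = P[Binomial(n, pBg) <= k]}
#' and \code{s = -log10((1-p)/p)}. Tails are exact (no normal
#' approximation). Infinite values (arising when \code{pBg} is 0 or 1, or
#' from tail underflow) are capped at the sentinel +/-99.
#'
#' @param k foreground counts (vector ok).
#' @param n foreground size.
#' @param pBg background frequency in [0, 1].
#' @return data.frame with \code{k}, \code{n}, \code{p_bg}, \code{p},
#'   \code{s} and a logical \code{capped} flag.
#' @examples
#' binomialLogOdds(4, 4, 0.5)$s  # log10(15) = 1.176
#' @export
binomialLogOdds <- function(k, n, pBg) {
  if (any(pBg < 0 | pBg > 1)) stop("pBg must lie in [0, 1]")
  stopifnot(all(k >= 0), all(k <= n), n >= 1)
  m <- max(length(k), length(pBg))
  k <- rep_len(k, m)
  pBg <- rep_len(pBg, m)
  upper <- k >= n * pBg
  p <- ifelse(upper,
              stats::pbinom(k - 1, n, pBg, lower.tail = FALSE),
              stats::pbinom(k, n, pBg))
  s <- ifelse(upper, 1, -1) * log10((1 - p) / p)
  # a count that exactly matches a certain background (k = 0 with p_bg = 0,
  # k = n with p_bg = 1) carries no evidence either way
  match0 <- (pBg == 0 & k == 0) | (pBg == 1 & k == n)
  s[match0] <- 0
  capped <- !is.finite(s)
  s[capped] <- sign(s[capped]) * 99
  data.frame(k = k, n = n, p_bg = pBg, p = p, s = s, capped = capped)
}

#' Bonferroni-corrected log10-odds significance threshold
#'
#' The log-odds value corresponding to a family-wise error rate
#' \code{alpha} over \code{nTests} residue-by-position tests:
#' \code{log10((1 - alpha/nTests) / (alpha/nTests))}. For alpha = 0.05 and a
#' 7-codon window over 20 amino acids (140 tests) this is 3.45.
#'
#' @param alpha family-wise error rate in (0, 1).
#' @param nTests number of tests in the family (>= 1).
#' @return the threshold on the log10-odds scale.
#' @examples
#' round(bonferroniThreshold(0.05, 140), 2)  # 3.45
#' @export
bonferroniThreshold <- function(alpha, nTests) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (nTests < 1) stop("nTests must be >= 1")
  a <- alpha / nTests
  log10((1 - a) / a)
}

#' Extract C-terminal amino-acid windows
#'
#' Returns, for each requested ORF, the amino acids at stop-anchored codon
#' positions -windowCodons .. -1 (position -1 is the last sense codon, the
#' P-site codon of the terminating ribosome). ORFs with fewer sense codons
#' than the window are padded with \code{NA} on the left.
#'
#' @param annotation ORF annotation data.frame.
#' @param sequences \code{DNAStringSet} of transcript sequences.
#' @param ids ORF ids to extract; default all.
#' @param windowCodons window width in codons (default 7).
#' @return character matrix (rows = ORFs, columns named "-7" .. "-1").
#' @export
ctermWindow <- function(annotation, sequences, ids = NULL, windowCodons = 7L) {
  .checkAnnotation(annotation)
  if (is.null(ids)) ids <- annotation$transcript_id
  idx <- match(ids, annotation$transcript_id)
  if (anyNA(idx)) stop("unknown ORF id(s): ",
                       paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
  w <- as.integer(windowCodons)
  out <- matrix(NA_character_, nrow = length(ids), ncol = w,
                dimnames = list(ids, as.character(seq.int(-w, -1L))))
  seqChar <- as.character(sequences[ids])
  for (i in seq_along(ids)) {
    a <- annotation[idx[i], ]
    nSense <- (a$cds_end - a$cds_start) / 3L - 1L
    take <- min(w, nSense)
    # last `take` sense codons, excluding the stop codon
    stop0 <- a$cds_end - 3L
    codStart <- stop0 - 3L * take
    codons <- substring(seqChar[i],
                        codStart + 3L * (seq_len(take) - 1L) + 1L,
                        codStart + 3L * seq_len(take))
    out[i, (w - take + 1L):w] <- translateCodons(codons)
  }
  out
}

#' Position-specific background amino-acid frequencies
#'
#' Empirical per-position frequencies across a comparison set of C-terminal
#' windows (by default the coverage-filtered ORF universe from which the
#' foreground was selected).
#'
#' @param aaWindows character matrix from \code{\link{ctermWindow}}.
#' @param source free-text description of the background set.
#' @return list with \code{freqs} (per position, named frequency vectors over
#'   the 20 amino acids, each summing to 1), \code{n}, and \code{source}.
#' @export
backgroundFrequencies <- function(aaWindows, source = "comparison set") {
  if (!nrow(aaWindows)) stop("empty background set")
  aa <- aminoAcids()
  freqs <- lapply(seq_len(ncol(aaWindows)), function(j) {
    col <- aaWindows[, j]
    col <- col[!is.na(col)]
    if (!length(col)) return(stats::setNames(rep(NA_real_, length(aa)), aa))
    tab <- table(factor(col, levels = aa))
    stats::setNames(as.numeric(tab) / length(col), aa)
  })
  names(freqs) <- colnames(aaWindows)
  list(freqs = freqs, n = nrow(aaWindows), source = source)
}

#' Positional amino-acid over/under-representation (pLogo-style)
#'
#' For every (position, residue) pair, compares the foreground count against
#' the background frequency with exact binomial tails and reports the signed
#' log10-odds statistic (\code{\link{binomialLogOdds}}). Significance is
#' called at the Bonferroni log-odds line for the full
#' positions-by-residues family (\code{\link{bonferroniThreshold}}).
#'
#' @param foreground character matrix of foreground windows
#'   (\code{\link{ctermWindow}}).
#' @param background result of \code{\link{backgroundFrequencies}} on the
#'   comparison set.
#' @param alpha family-wise error rate (default 0.05).
#' @return data.frame with \code{position}, \code{residue}, \code{k},
#'   \code{n}, \code{p_bg}, \code{p}, \code{s}, \code{capped},
#'   \code{significant}; the threshold is attached as attribute
#'   \code{"threshold"} and \code{"nTests"}.
#' @export
positionalLogodds <- function(foreground, background, alpha = 0.05) {
  if (!nrow(foreground)) stop("empty foreground set")
  if (!identical(colnames(foreground), names(background$freqs)))
    stop("foreground and background cover different positions")
  aa <- aminoAcids()
  nTests <- ncol(foreground) * length(aa)
  thr <- bonferroniThreshold(alpha, nTests)
  res <- vector("list", ncol(foreground))
  for (j in seq_len(ncol(foreground))) {
    col <- foreground[, j]
    col <- col[!is.na(col)]
    n <- length(col)
    k <- as.integer(table(factor(col, levels = aa)))
    d <- binomialLogOdds(k, n, background$freqs[[j]][aa])
    res[[j]] <- cbind(data.frame(position = as.integer(colnames(foreground)[j]),
                                 residue = aa, stringsAsFactors = FALSE), d)
  }
  out <- do.call(rbind, res)
  out$significant <- abs(out$s) >= thr
  attr(out, "threshold") <- thr
  attr(out, "nTests") <- nTests
  out
}

.lastSenseCodon <- function(annotation, sequences, ids) {
  idx <- match(ids, annotation$transcript_id)
  if (anyNA(idx)) stop("unknown ORF id(s)")
  seqChar <- as.character(sequences[ids])
  stop0 <- annotation$cds_end[idx] - 3L
  substring(seqChar, stop0 - 2L, stop0)
}

#' Stop-codon context: C-terminal codon over-representation
#'
#' Applies the binomial log10-odds machinery at the codon level to the 61
#' sense codons at position -1 (the last sense codon before the stop), with
#' the background taken from the C-terminal codon frequencies of the
#' comparison set. Detects, e.g., over-representation of the lysine codon
#' AAA and arginine codons AGA/CGN among high-queuing ORFs.
#'
#' @param foregroundIds ORF ids of the foreground (selected) set.
#' @param annotation,sequences annotation and transcript sequences.
#' @param backgroundIds comparison set ids (default: all annotated ORFs).
#' @param alpha family-wise error rate (default 0.05) over the 61 codon
#'   tests.
#' @return data.frame with \code{codon}, \code{aa}, \code{k}, \code{n},
#'   \code{p_bg}, \code{p}, \code{s}, \code{capped}, \code{significant};
#'   threshold in attribute \code{"threshold"}.
#' @export
stopCodonContext <- function(foregroundIds, annotation, sequences,
                             backgroundIds = NULL, alpha = 0.05) {
  .checkAnnotation(annotation)
  if (!length(foregroundIds)) stop("empty foreground set")
  if (is.null(backgroundIds)) backgroundIds <- annotation$transcript_id
  fg <- .lastSenseCodon(annotation, sequences, foregroundIds)
  bg <- .lastSenseCodon(annotation, sequences, backgroundIds)
  codons <- senseCodons()
  n <- length(fg)
  k <- as.integer(table(factor(fg, levels = codons)))
  pBg <- as.numeric(table(factor(bg, levels = codons))) / length(bg)
  thr <- bonferroniThreshold(alpha, length(codons))
  d <- binomialLogOdds(k, n, pBg)
  out <- cbind(data.frame(codon = codons, aa = translateCodons(codons),
                          stringsAsFactors = FALSE), d)
  out$significant <- abs(out$s) >= thr
  attr(out, "threshold") <- thr
  out
}

#' Association between stop-codon identity and queuing
#'
#' Rank-based K-group (Kruskal-Wallis) test of the queuing metric across the
#' TAA/TAG/TGA stop-codon classes; a non-significant result indicates that
#' queuing is not driven by the identity of the stop codon itself.
#'
#' @param scores score table for one condition (\code{\link{scoreAll}}),
#'   needing columns \code{Q} and \code{stop_codon}.
#' @return list with \code{statistic} (H), \code{df}, \code{p.value} and
#'   \code{groups} (per-codon sizes).
#' @export
stopIdentityAssociation <- function(scores) {
  def <- scores[!is.na(scores$Q), , drop = FALSE]
  sizes <- table(def$stop_codon)
  if (sum(sizes >= 2) < 2)
    stop("need at least two stop-codon groups with >= 2 ORFs")
  kt <- stats::kruskal.test(def$Q, factor(def$stop_codon))
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p.value = kt$p.value, groups = sizes)
}
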