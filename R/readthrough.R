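#' Post-stop (3'UTR) over ORF-body density ratio
#'
#' Ratio of the mean density in a window just after the stop codon to the
#' mean density over the 3'-terminal ORF window. Being a ratio it is
#' invariant to library rescaling. The UTR window starts at +3, the first
#' nucleotide after the stop codon.
#'
#' @param rpmTrack per-position density vector for one transcript.
#' @param orf one annotation row.
#' @param utrWindow half-open stop-anchored UTR window, default
#'   \code{c(3, 63)}.
#' @param orfWindow half-open stop-anchored ORF window, default
#'   \code{c(-120, 0)}.
#' @return list with \code{ratio} (NA when the ORF-window mean is zero or
#'   the UTR has zero length), \code{utr_mean}, \code{orf_mean},
#'   \code{truncated} (TRUE when the UTR was shorter than the window) and
#'   \code{flag}.
#' @export
utr3Ratio <- function(rpmTrack, orf, utrWindow = c(3L, 63L),
                      orfWindow = c(-120L, 0L)) {
  s0 <- stopAnchor(orf)
  if (s0 + orfWindow[1] < 0L)
    stop("ORF shorter than the ORF window")
  orfMean <- mean(rpmTrack[.anchorIdx(s0, orfWindow)])
  if (orf$utr3_len <= 0L)
    return(list(ratio = NA_real_, utr_mean = NA_real_, orf_mean = orfMean,
                truncated = FALSE, flag = "no_utr"))
  hi <- min(utrWindow[2], 3L + orf$utr3_len)
  truncated <- hi < utrWindow[2]
  utrMean <- mean(rpmTrack[.anchorIdx(s0, c(utrWindow[1], hi))])
  if (orfMean == 0)
    return(list(ratio = NA_real_, utr_mean = utrMean, orf_mean = orfMean,
                truncated = truncated, flag = "zero_orf_coverage"))
  list(ratio = utrMean / orfMean, utr_mean = utrMean, orf_mean = orfMean,
       truncated = truncated, flag = if (truncated) "truncated_utr" else "")
}

#' Reading-frame periodicity of a coverage region
#'
#' Bins P-site counts of a region by sub-codon position (\code{(position -
#' region start) mod 3}; align the region start to the continuation of the
#' stop-codon frame so that frame 0 extends the ORF's reading frame) and
#' tests the three frame totals against the uniform (1/3, 1/3, 1/3)
#' expectation with a chi-square goodness-of-fit test (2 df). Genuine
#' readthrough translation shows codon periodicity; background 3'UTR density
#' does not.
#'
#' @param counts integer per-position counts over the region, first element
#'   at frame 0.
#' @return list with \code{fractions} (f0, f1, f2), \code{statistic},
#'   \code{p.value} and \code{n} (total reads); all NA when the region has
#'   no reads.
#' @examples
#' framePeriodicity(rep(c(10L, 0L, 0L), 10))$statistic  # 60
#' @export
framePeriodicity <- function(counts) {
  frames <- (seq_along(counts) - 1L) %% 3L
  tot <- vapply(0:2, function(f) sum(counts[frames == f]), numeric(1))
  n <- sum(tot)
  if (n == 0)
    return(list(fractions = rep(NA_real_, 3), statistic = NA_real_,
                p.value = NA_real_, n = 0))
  ct <- suppressWarnings(stats::chisq.test(tot, p = rep(1 / 3, 3)))
  list(fractions = tot / n, statistic = unname(ct$statistic),
       p.value = ct$p.value, n = n)
}

#' Per-ORF readthrough diagnostics
#'
#' Combines the 3'UTR/ORF density ratio (from RPM tracks) with the frame
#' periodicity test on raw counts in the UTR window, reported per ORF as
#' fractions plus a test rather than a binary readthrough call.
#'
#' @param tracks RPM-normalised \code{\linkS4class{RiboTrackSet}}.
#' @param annotation ORF annotation data.frame.
#' @param utrWindow,orfWindow stop-anchored half-open windows (defaults
#'   \code{c(3, 63)} and \code{c(-120, 0)}).
#' @return data.frame with \code{orf_id}, \code{utr_mean_rpm},
#'   \code{orf_mean_rpm}, \code{ratio}, \code{f0}, \code{f1}, \code{f2},
#'   \code{chisq}, \code{p_frame}, \code{utr_reads}, \code{flag}. ORFs too
#'   short for the ORF window are omitted.
#' @export
readthroughScores <- function(tracks, annotation, utrWindow = c(3L, 63L),
                              orfWindow = c(-120L, 0L)) {
  .checkAnnotation(annotation)
  r <- rpm(tracks)
  cnt <- counts(tracks)
  rows <- vector("list", nrow(annotation))
  for (i in seq_len(nrow(annotation))) {
    orf <- annotation[i, ]
    s0 <- stopAnchor(orf)
    if (s0 + orfWindow[1] < 0L || orf$utr3_len <= 0L) next
    vec <- r[[orf$transcript_id]]
    if (is.null(vec)) next
    rt <- utr3Ratio(vec, orf, utrWindow, orfWindow)
    hi <- min(utrWindow[2], 3L + orf$utr3_len)
    fp <- framePeriodicity(cnt[[orf$transcript_id]][.anchorIdx(s0, c(utrWindow[1], hi))])
    rows[[i]] <- data.frame(orf_id = orf$transcript_id,
                            utr_mean_rpm = rt$utr_mean,
                            orf_mean_rpm = rt$orf_mean,
                            ratio = rt$ratio,
                            f0 = fp$fractions[1], f1 = fp$fractions[2],
                            f2 = fp$fractions[3],
                            chisq = fp$statistic, p_frame = fp$p.value,
                            utr_reads = fp$n, flag = rt$flag,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no ORF qualifies for readthrough scoring")
  rownames(out) <- NULL
  out
}
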