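#' Construct the peak/inter-peak layout for the queuing metric
#'
#' The default layout places three peak windows of half-width
#' \code{halfWidth} at the expected P-site codon starts of stacked ribosomes,
#' \code{-3 - k*spacing} for k = 1, 2, 3, i.e. at [-38,-28), [-68,-58),
#' [-98,-88) with the 30 nt default spacing. The inter-peak windows are the
#' gaps between them plus the gap up to -6; the stop-proximal zone [-6, 0) is
#' excluded because terminating footprints are depleted in
#' cycloheximide-free protocols.
#'
#' @param spacing nt between successive queued P-sites (default 30).
#' @param halfWidth half-width of each peak window in nt (default 5).
#' @param nPeaks number of peak windows (default 3).
#' @param stopExclusion upper bound of the stop-proximal zone excluded from
#'   the inter-peak windows (default 6 nt).
#' @return a \code{\linkS4class{PeakLayout}}.
#' @examples
#' peakLayout()
#' @export
peakLayout <- function(spacing = 30L, halfWidth = 5L, nPeaks = 3L,
                       stopExclusion = 6L) {
  centers <- -3L - seq_len(nPeaks) * as.integer(spacing)
  peaks <- cbind(centers - as.integer(halfWidth),
                 centers + as.integer(halfWidth))
  gaps <- cbind(c(peaks[-1, 2], NA), c(peaks[-nPeaks, 1], NA))
  gaps[nPeaks, ] <- c(peaks[1, 2], -as.integer(stopExclusion))
  new("PeakLayout", peaks = peaks, gaps = gaps)
}

#' Per-ORF C-terminal ribosome queuing metric
#'
#' Q is the ratio between the sum of the maximal densities within the three
#' peak windows preceding the stop codon and the mean density over the union
#' of the inter-peak windows. On a strictly positive flat track Q is exactly
#' the number of peak windows (3 by default); Q is invariant under any
#' rescaling of the track, so counts and RPM give the same value. When the
#' inter-peak mean is zero Q is undefined and \code{NA} is returned.
#'
#' @param rpmTrack numeric per-position density vector for one transcript
#'   (RPM or counts).
#' @param stopStart transcript coordinate (0-based) of the first stop-codon
#'   nucleotide.
#' @param layout a \code{\linkS4class{PeakLayout}}.
#' @return Q as a single numeric, \code{NA} when undefined.
#' @examples
#' track <- rep(2, 200)
#' queuingMetric(track, 150L)  # flat track: exactly 3
#' @export
queuingMetric <- function(rpmTrack, stopStart, layout = peakLayout()) {
  lowest <- min(layout@peaks[, 1], layout@gaps[, 1])
  if (stopStart + lowest < 0L)
    stop("ORF too short for the peak layout (needs ", -lowest,
         " nt upstream of the stop codon)")
  peakSum <- sum(apply(layout@peaks, 1, function(w)
    max(rpmTrack[.anchorIdx(stopStart, w)])))
  gapIdx <- unlist(apply(layout@gaps, 1, function(w)
    .anchorIdx(stopStart, w), simplify = FALSE))
  gapMean <- mean(rpmTrack[gapIdx])
  if (gapMean == 0) return(NA_real_)
  peakSum / gapMean
}

#' Queuing analysis configuration
#'
#' @param layout a \code{\linkS4class{PeakLayout}}.
#' @param coverageWindow half-open stop-anchored coverage-filter window,
#'   default \code{c(-120, 0)}.
#' @param minCoverage minimum mean RPM over the coverage window, default 10.
#' @param zCutoff Z-score cutoff for selecting high-queuing ORFs, default 1.
#' @param conditions conditions that must all pass the coverage filter;
#'   \code{NULL} means every condition supplied to \code{\link{scoreAll}}.
#' @return a list of class \code{"QueuingConfig"}.
#' @export
queuingConfig <- function(layout = peakLayout(), coverageWindow = c(-120L, 0L),
                          minCoverage = 10, zCutoff = 1, conditions = NULL) {
  if (minCoverage < 0) stop("minCoverage must be >= 0")
  structure(list(layout = layout,
                 coverageWindow = as.integer(coverageWindow),
                 minCoverage = minCoverage, zCutoff = zCutoff,
                 conditions = conditions),
            class = "QueuingConfig")
}

#' Coverage filter over the 3'-terminal window
#'
#' An ORF passes when its coding region is long enough to host the coverage
#' window (plus the stop codon) and its mean RPM over the window reaches
#' \code{minCoverage} in every required condition.
#'
#' @param tracksByCondition named list of RPM-normalised
#'   \code{\linkS4class{RiboTrackSet}} objects, one per condition.
#' @param annotation ORF annotation data.frame.
#' @param config a \code{\link{queuingConfig}}.
#' @return data.frame with \code{transcript_id}, \code{pass}, \code{reason}
#'   (empty string when passing; otherwise \code{"too_short"} or
#'   \code{"low_coverage:<condition>"}).
#' @export
coverageFilter <- function(tracksByCondition, annotation,
                           config = queuingConfig()) {
  .checkAnnotation(annotation)
  conds <- config$conditions %||% names(tracksByCondition)
  missing <- setdiff(conds, names(tracksByCondition))
  if (length(missing))
    stop("missing condition track(s): ", paste(missing, collapse = ", "))
  wnd <- config$coverageWindow
  minLen <- -wnd[1] + 3L  # window plus the stop codon itself
  out <- data.frame(transcript_id = annotation$transcript_id,
                    pass = TRUE, reason = "", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(annotation))) {
    orf <- annotation[i, ]
    if (orf$cds_end - orf$cds_start < minLen) {
      out$pass[i] <- FALSE
      out$reason[i] <- "too_short"
      next
    }
    s0 <- stopAnchor(orf)
    for (cn in conds) {
      vec <- rpm(tracksByCondition[[cn]])[[orf$transcript_id]]
      if (is.null(vec) || mean(vec[.anchorIdx(s0, wnd)]) < config$minCoverage) {
        out$pass[i] <- FALSE
        out$reason[i] <- paste0("low_coverage:", cn)
        break
      }
    }
  }
  out
}

#' Score every coverage-filtered ORF in every condition
#'
#' Computes the queuing metric Q per ORF and condition on the shared
#' coverage-filtered ORF set, plus a within-condition Z-score over the
#' defined Q values (sample standard deviation, ddof = 1). ORFs with an
#' undefined Q (zero inter-peak density) are excluded from the mean and the
#' Z computation and flagged instead.
#'
#' @inheritParams coverageFilter
#' @return data.frame with one row per (ORF, condition): \code{orf_id},
#'   \code{condition}, \code{Q}, \code{z}, \code{cterm_aa},
#'   \code{stop_codon}, \code{mean_rpm}, \code{flag}. Attribute
#'   \code{"meanQ"} holds the per-condition mean of defined Q values;
#'   attribute \code{"filter"} the coverage-filter table.
#' @examples
#' # see vignette("ribosome-queuing") for an end-to-end example
#' @export
scoreAll <- function(tracksByCondition, annotation, config = queuingConfig()) {
  filt <- coverageFilter(tracksByCondition, annotation, config)
  keep <- annotation[filt$pass, , drop = FALSE]
  conds <- config$conditions %||% names(tracksByCondition)
  res <- vector("list", length(conds))
  for (ci in seq_along(conds)) {
    cn <- conds[ci]
    r <- rpm(tracksByCondition[[cn]])
    Q <- numeric(nrow(keep))
    meanRpm <- numeric(nrow(keep))
    for (i in seq_len(nrow(keep))) {
      orf <- keep[i, ]
      s0 <- stopAnchor(orf)
      vec <- r[[orf$transcript_id]]
      Q[i] <- queuingMetric(vec, s0, config$layout)
      meanRpm[i] <- mean(vec[.anchorIdx(s0, config$coverageWindow)])
    }
    def <- !is.na(Q)
    z <- rep(NA_real_, length(Q))
    if (sum(def) >= 2) {
      s <- stats::sd(Q[def])
      if (s > 0) z[def] <- (Q[def] - mean(Q[def])) / s
      else warning("all Q values equal in condition ", cn, "; z not computed")
    } else {
      warning("fewer than 2 defined Q values in condition ", cn,
              "; z not computed")
    }
    res[[ci]] <- data.frame(orf_id = keep$transcript_id, condition = cn,
                            Q = Q, z = z, cterm_aa = keep$cterm_aa,
                            stop_codon = keep$stop_codon, mean_rpm = meanRpm,
                            flag = ifelse(def, "", "undefined_Q"),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  attr(out, "meanQ") <- vapply(res, function(d) mean(d$Q, na.rm = TRUE),
                               numeric(1)) |> stats::setNames(conds)
  attr(out, "filter") <- filt
  out
}

#' Select high-queuing ORFs by Z-score
#'
#' @param scores score table from \code{\link{scoreAll}} (filter to one
#'   condition first if several are present).
#' @param cutoff select rows with \code{z > cutoff} (default 1).
#' @return the selected rows of \code{scores}.
#' @export
zscoreSelect <- function(scores, cutoff = 1) {
  scores[!is.na(scores$z) & scores$z > cutoff, , drop = FALSE]
}

#' Summarise queuing by C-terminal amino acid
#'
#' @param scores score table rows for one condition.
#' @return list with \code{summary} (data.frame: \code{cterm_aa}, \code{n},
#'   \code{mean_q}) over all 20 amino acids, and \code{values} (named list of
#'   the per-amino-acid Q distributions, for plotting).
#' @export
groupByCterm <- function(scores) {
  aa <- aminoAcids()
  def <- scores[!is.na(scores$Q), , drop = FALSE]
  values <- split(def$Q, factor(def$cterm_aa, levels = aa))
  summary <- data.frame(
    cterm_aa = aa,
    n = lengths(values),
    mean_q = vapply(values, function(v) if (length(v)) mean(v) else NA_real_,
                    numeric(1)),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  list(summary = summary, values = values)
}
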