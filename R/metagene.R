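#' Construct a MetageneProfile directly
#'
#' Mostly useful for feeding constructed shapes to \code{\link{wavePeriod}};
#' analysis code should build profiles from tracks with
#' \code{\link{metageneProfile}}.
#'
#' @param position integer vector of contiguous stop-anchored positions.
#' @param density mean normalised density per position.
#' @param nGenes number of contributing genes.
#' @param window half-open window bounds; defaults to the position range.
#' @return a \code{\linkS4class{MetageneProfile}}.
#' @rdname MetageneProfile-class
#' @export
MetageneProfile <- function(position, density, nGenes = 0L, window = NULL) {
  position <- as.integer(position)
  if (is.null(window)) window <- c(position[1], position[length(position)] + 1L)
  new("MetageneProfile", position = position, density = as.numeric(density),
      nGenes = as.integer(nGenes), window = as.integer(window))
}

#' Stop-codon-anchored metagene profile
#'
#' For every ORF whose stop-anchored window fits inside its transcript and
#' whose window mean RPM passes the threshold (strictly positive in any
#' case), the window is extracted from the RPM track, divided by its own
#' mean, and the normalised windows are averaged with equal weight per gene.
#' Per-gene normalisation makes the profile scale-invariant and prevents
#' highly expressed genes from dominating; by construction the profile mean
#' over the window is 1.
#'
#' @param tracks an RPM-normalised \code{\linkS4class{RiboTrackSet}}.
#' @param annotation ORF annotation data.frame.
#' @param window half-open stop-anchored window, default \code{c(-120, 60)}
#'   (position 0 = first stop-codon nucleotide).
#' @param minWindowMeanRpm minimum window mean RPM for a gene to contribute
#'   (default 0, i.e. only all-zero windows are excluded).
#' @return a \code{\linkS4class{MetageneProfile}}.
#' @examples
#' cfg <- simConfig(nOrfs = 20, seed = 2, orfLengthRange = c(300L, 600L))
#' ds <- generateAnnotation(cfg)
#' lib <- simulateFootprints(cfg, ds$annotation, ds$truth)
#' tr <- normalizeRpm(assignPsites(lib$alignments,
#'                    transcriptLengths = setNames(ds$annotation$length,
#'                                        ds$annotation$transcript_id))$tracks)
#' mg <- metageneProfile(tr, ds$annotation)
#' wavePeriod(mg)
#' @export
metageneProfile <- function(tracks, annotation, window = c(-120L, 60L),
                            minWindowMeanRpm = 0) {
  .checkAnnotation(annotation)
  window <- as.integer(window)
  r <- rpm(tracks)
  width <- window[2] - window[1]
  rows <- vector("list", nrow(annotation))
  nGenes <- 0L
  for (i in seq_len(nrow(annotation))) {
    orf <- annotation[i, ]
    vec <- r[[orf$transcript_id]]
    if (is.null(vec)) next
    s0 <- stopAnchor(orf)
    lo <- s0 + window[1]
    hi <- s0 + window[2]
    if (lo < 0L || hi > length(vec)) next
    w <- vec[(lo + 1L):hi]
    m <- mean(w)
    if (m <= 0 || m < minWindowMeanRpm) next
    nGenes <- nGenes + 1L
    rows[[nGenes]] <- w / m
  }
  if (nGenes == 0L) stop("empty metagene: no qualifying genes")
  mat <- do.call(rbind, rows[seq_len(nGenes)])
  MetageneProfile(position = seq.int(window[1], window[2] - 1L),
                  density = colMeans(mat), nGenes = nGenes, window = window)
}

# prominence of a strict local maximum at index i of y: height above the
# higher of the two bases, where each base is the minimum between the peak
# and the nearest higher point (or the edge) on that side
.prominence <- function(y, i) {
  n <- length(y)
  leftBase <- y[i]
  j <- i
  while (j > 1L) {
    j <- j - 1L
    if (y[j] > y[i]) break
    leftBase <- min(leftBase, y[j])
  }
  rightBase <- y[i]
  j <- i
  while (j < n) {
    j <- j + 1L
    if (y[j] > y[i]) break
    rightBase <- min(rightBase, y[j])
  }
  y[i] - max(leftBase, rightBase)
}

#' Estimate the period of queuing waves in a metagene profile
#'
#' Detects local maxima of the profile within a stop-anchored search region
#' and returns the median spacing between successive peaks, the signature of
#' stacked ribosomes (one protected-fragment length apart, approximately 30
#' nt). The profile is first smoothed with a centred 3 nt (one codon) moving
#' average, which removes sub-codon frame structure without displacing peaks
#' spaced a footprint apart; peaks must then be strict local maxima with
#' topographic prominence of at least \code{minProminence} times the smoothed
#' profile maximum in the region. With fewer than two peaks the period is
#' not detected and \code{NA} is returned.
#'
#' @param profile a \code{\linkS4class{MetageneProfile}}.
#' @param searchRegion closed stop-anchored interval to search, default
#'   \code{c(-120, -6)} (the stop-proximal zone is excluded).
#' @param minProminence prominence floor as a fraction of the regional
#'   profile maximum (default 0.1).
#' @return median peak spacing in nt, or \code{NA_real_} when fewer than two
#'   peaks are found. The detected peak positions are attached as attribute
#'   \code{"peaks"}.
#' @export
wavePeriod <- function(profile, searchRegion = c(-120L, -6L),
                       minProminence = 0.1) {
  pos <- profile@position
  if (searchRegion[1] < pos[1] || searchRegion[2] > pos[length(pos)])
    stop("profile does not cover the search region")
  y <- profile@density
  sm <- as.numeric(stats::filter(y, rep(1 / 3, 3), sides = 2))
  sm[is.na(sm)] <- y[is.na(sm)]
  inReg <- pos >= searchRegion[1] & pos <= searchRegion[2]
  yr <- sm[inReg]
  pr <- pos[inReg]
  n <- length(yr)
  if (n < 3L || max(yr) <= 0) return(NA_real_)
  floorProm <- minProminence * max(yr)
  # plateau-aware local maxima: a maximal run of equal values higher than
  # both neighbouring runs peaks at its centre; values are compared at 12
  # significant digits so summation order cannot split a plateau
  r <- rle(signif(yr, 12))
  nr <- length(r$values)
  runEnd <- cumsum(r$lengths)
  runStart <- runEnd - r$lengths + 1L
  isMax <- integer(0)
  if (nr >= 3L) {
    for (j in 2:(nr - 1L)) {
      if (r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L])
        isMax <- c(isMax, as.integer(floor((runStart[j] + runEnd[j]) / 2)))
    }
  }
  isMax <- isMax[vapply(isMax, function(i) .prominence(yr, i) >= floorProm,
                        logical(1))]
  if (length(isMax) < 2L) return(structure(NA_real_, peaks = pr[isMax]))
  peaks <- sort(pr[isMax])
  structure(stats::median(diff(peaks)), peaks = peaks)
}
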