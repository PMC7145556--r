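#' @import methods
NULL

.checkProb <- function(p, what, tol = 1e-9) {
  if (any(p < 0)) return(sprintf("%s contains negative probabilities", what))
  if (abs(sum(p) - 1) > tol)
    return(sprintf("%s must sum to 1 (got %.12g)", what, sum(p)))
  NULL
}

#' Generative parameters for the synthetic footprint simulator
#'
#' A \code{SimConfig} holds everything needed to generate a reproducible
#' synthetic Ribo-Seq dataset: an ORF set (lengths, C-terminal amino acid and
#' stop codon distributions), per-position coverage intensities, the geometry
#' of stacked-ribosome queue peaks upstream of the stop codon, the
#' footprint-length mixture, and an RNG seed. Construct with
#' \code{\link{simConfig}}.
#'
#' Intensities are expected P-site read counts per transcript position. The
#' flat ORF-body intensity is \code{bodyIntensity} at every coding position
#' under the default uniform \code{frameWeights}; a queued ORF additionally
#' carries point-mass peaks of \code{queueAmplitude * queueDecay^(k-1)} at the
#' first nucleotide of the P-site codon of the k-th stacked ribosome,
#' \code{footprintSpacing} nucleotides apart, counting upstream from the last
#' sense codon.
#'
#' @slot nOrfs number of ORFs to generate.
#' @slot orfLengthRange min/max coding length in nt (multiples of 3, stop
#'   codon included).
#' @slot ctermAaDistribution named probabilities over the 20 amino acids for
#'   the C-terminal residue.
#' @slot stopCodonDistribution named probabilities over TAA/TAG/TGA.
#' @slot queuedFraction probability that an eligible ORF carries queue peaks.
#' @slot queueCterm amino acids whose ORFs are eligible for queuing
#'   (\code{character(0)} means every ORF is eligible).
#' @slot queueAmplitude expected extra P-site reads at the first queue peak.
#' @slot queueDecay multiplicative decay per successive peak, in (0, 1].
#' @slot nQueuePeaks number of stacked-ribosome peaks.
#' @slot stopPeakWeight relative intensity of the terminating-ribosome peak at
#'   the last sense codon (0 emulates protocols in which terminating
#'   footprints are lost).
#' @slot footprintSpacing nt between successive queued P-sites.
#' @slot bodyIntensity expected reads per in-frame codon-start position.
#' @slot frameWeights relative read density of the three sub-codon positions
#'   (sums to 1; uniform gives a flat body).
#' @slot queueJitterSd optional Gaussian jitter (nt) smearing queue peaks;
#'   0 keeps exact point masses.
#' @slot utrIntensity expected reads per 3'UTR position (frame-uniform).
#' @slot utr3Length,utr5Length flanking UTR lengths in nt.
#' @slot pLong probability a read belongs to the long (28-30 nt) class;
#'   otherwise short (20-22 nt).
#' @slot shortLengthProbs,longLengthProbs within-class length probabilities.
#' @slot depthScale global multiplier on all intensities.
#' @slot seed integer RNG seed.
#' @seealso \code{\link{simConfig}}, \code{\link{generateAnnotation}},
#'   \code{\link{simulateFootprints}}
#' @export
setClass("SimConfig", representation(
  nOrfs = "integer",
  orfLengthRange = "integer",
  ctermAaDistribution = "numeric",
  stopCodonDistribution = "numeric",
  queuedFraction = "numeric",
  queueCterm = "character",
  queueAmplitude = "numeric",
  queueDecay = "numeric",
  nQueuePeaks = "integer",
  stopPeakWeight = "numeric",
  footprintSpacing = "integer",
  bodyIntensity = "numeric",
  frameWeights = "numeric",
  queueJitterSd = "numeric",
  utrIntensity = "numeric",
  utr3Length = "integer",
  utr5Length = "integer",
  pLong = "numeric",
  shortLengthProbs = "numeric",
  longLengthProbs = "numeric",
  depthScale = "numeric",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  add <- function(x) if (!is.null(x)) msg <<- c(msg, x)
  if (object@nOrfs < 0) add("nOrfs must be >= 0")
  lr <- object@orfLengthRange
  if (length(lr) != 2 || lr[1] > lr[2]) add("orfLengthRange must be c(min, max)")
  if (any(lr %% 3 != 0)) add("orfLengthRange must be multiples of 3")
  if (lr[1] < 9) add("orfLengthRange minimum must be >= 9 nt")
  add(.checkProb(object@ctermAaDistribution, "ctermAaDistribution"))
  add(.checkProb(object@stopCodonDistribution, "stopCodonDistribution"))
  if (!all(names(object@stopCodonDistribution) %in% c("TAA", "TAG", "TGA")))
    add("stopCodonDistribution names must be among TAA/TAG/TGA")
  if (object@queuedFraction < 0 || object@queuedFraction > 1)
    add("queuedFraction must be in [0,1]")
  if (object@queueAmplitude < 0) add("queueAmplitude must be >= 0")
  if (object@queueDecay <= 0 || object@queueDecay > 1)
    add("queueDecay must be in (0,1]")
  if (object@nQueuePeaks < 1) add("nQueuePeaks must be >= 1")
  if (object@footprintSpacing < 1) add("footprintSpacing must be >= 1")
  if (object@bodyIntensity < 0) add("bodyIntensity must be >= 0")
  if (length(object@frameWeights) != 3) add("frameWeights must have length 3")
  add(.checkProb(object@frameWeights, "frameWeights"))
  if (object@queueJitterSd < 0) add("queueJitterSd must be >= 0")
  if (object@utrIntensity < 0) add("utrIntensity must be >= 0")
  if (object@utr3Length < 0 || object@utr5Length < 0) add("UTR lengths must be >= 0")
  if (object@pLong < 0 || object@pLong > 1) add("pLong must be in [0,1]")
  if (!identical(names(object@shortLengthProbs), c("20", "21", "22")))
    add("shortLengthProbs must be named 20/21/22")
  if (!identical(names(object@longLengthProbs), c("28", "29", "30")))
    add("longLengthProbs must be named 28/29/30")
  add(.checkProb(object@shortLengthProbs, "shortLengthProbs"))
  add(.checkProb(object@longLengthProbs, "longLengthProbs"))
  if (object@depthScale < 0) add("depthScale must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Per-transcript P-site coverage for one footprint library
#'
#' Container for nucleotide-resolution P-site counts (and, after
#' \code{\link{normalizeRpm}}, reads-per-million) over a set of transcripts,
#' together with the library size used as the RPM denominator and a condition
#' label. Created by \code{\link{assignPsites}} and \code{\link{poolLibraries}}.
#'
#' @slot counts named list of per-transcript integer count vectors.
#' @slot rpm named list of per-transcript RPM vectors (empty until
#'   \code{normalizeRpm} is called).
#' @slot librarySize total P-site-assigned reads in the library.
#' @slot condition condition label (e.g. \code{"wt_20C"}).
#' @slot offsetsProvenance free-text description of the offset table used.
#' @seealso \code{\link{assignPsites}}, \code{\link{normalizeRpm}},
#'   \code{\link{poolLibraries}}
#' @export
setClass("RiboTrackSet", representation(
  counts = "list",
  rpm = "list",
  librarySize = "numeric",
  condition = "character",
  offsetsProvenance = "character"
))

setValidity("RiboTrackSet", function(object) {
  msg <- character(0)
  if (is.null(names(object@counts)) && length(object@counts))
    msg <- c(msg, "counts must be a named list")
  if (any(vapply(object@counts, function(x) any(x < 0), logical(1))))
    msg <- c(msg, "counts must be non-negative")
  if (object@librarySize < 0) msg <- c(msg, "librarySize must be >= 0")
  if (length(object@rpm)) {
    if (!identical(names(object@rpm), names(object@counts)))
      msg <- c(msg, "rpm and counts must cover the same transcripts")
    else if (!all(lengths(object@rpm) == lengths(object@counts)))
      msg <- c(msg, "rpm and counts vectors must have matching lengths")
  }
  if (length(msg)) msg else TRUE
})

#' Stop-codon-anchored average density profile
#'
#' Positions are relative to the first nucleotide of the stop codon
#' (position 0). Each contributing gene's window is normalised by its own
#' window mean before equal-weight averaging, so the profile is in units of
#' "fold of the gene's local mean". Built by \code{\link{metageneProfile}};
#' construct directly with \code{\link{MetageneProfile}} (e.g. for testing
#' \code{\link{wavePeriod}} on known shapes).
#'
#' @slot position integer stop-anchored positions (contiguous).
#' @slot density mean normalised density per position.
#' @slot nGenes number of genes contributing.
#' @slot window half-open window bounds \code{c(lower, upper)}.
#' @export
setClass("MetageneProfile", representation(
  position = "integer",
  density = "numeric",
  nGenes = "integer",
  window = "integer"
))

setValidity("MetageneProfile", function(object) {
  msg <- character(0)
  if (length(object@position) != length(object@density))
    msg <- c(msg, "position and density must have equal length")
  if (length(object@position) > 1 && any(diff(object@position) != 1L))
    msg <- c(msg, "positions must be contiguous")
  if (any(object@density < 0)) msg <- c(msg, "density must be >= 0")
  if (object@nGenes < 0) msg <- c(msg, "nGenes must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Peak and inter-peak windows for the queuing metric
#'
#' Stop-anchored, half-open nucleotide intervals locating the three coverage
#' peaks expected from stacked ribosomes upstream of the stop codon, and the
#' inter-peak gaps used for the background density. Construct with
#' \code{\link{peakLayout}}.
#'
#' @slot peaks 3 x 2 integer matrix of half-open peak windows, ordered from
#'   the stop codon outward.
#' @slot gaps n x 2 integer matrix of half-open inter-peak windows.
#' @seealso \code{\link{peakLayout}}, \code{\link{queuingMetric}}
#' @export
setClass("PeakLayout", representation(
  peaks = "matrix",
  gaps = "matrix"
))

setValidity("PeakLayout", function(object) {
  msg <- character(0)
  all <- rbind(object@peaks, object@gaps)
  if (ncol(all) != 2) msg <- c(msg, "windows must be two-column (lower, upper)")
  else {
    if (any(all[, 1] >= all[, 2])) msg <- c(msg, "windows must be non-empty half-open intervals")
    if (any(all[, 1] < -120L) || any(all[, 2] > 0L))
      msg <- c(msg, "windows must lie within [-120, 0)")
    pos <- unlist(apply(all, 1, function(w) seq(w[1], w[2] - 1L), simplify = FALSE))
    if (anyDuplicated(pos)) msg <- c(msg, "windows must be disjoint")
    if (nrow(object@peaks) > 1 && any(diff(object@peaks[, 1]) >= 0))
      msg <- c(msg, "peaks must be ordered from the stop codon outward")
  }
  if (length(msg)) msg else TRUE
})
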