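#' Accessors for coverage track sets and metagene profiles
#'
#' \code{counts} and \code{rpm} return the named lists of per-transcript
#' vectors; \code{librarySize} the RPM denominator; \code{conditionLabel} the
#' condition tag; \code{transcriptLengths} the per-transcript track lengths.
#'
#' @param object a \code{\linkS4class{RiboTrackSet}} (or, where documented, a
#'   \code{\linkS4class{MetageneProfile}}).
#' @param ... ignored.
#' @return see the individual accessor descriptions.
#' @name accessors
#' @aliases counts rpm librarySize conditionLabel transcriptLengths
#' @examples
#' aln <- data.frame(transcript_id = "tx1", start = c(100, 100, 103),
#'                   end = c(128, 128, 131), read_length = 28L)
#' ts <- assignPsites(aln, transcriptLengths = c(tx1 = 200L))$tracks
#' librarySize(ts)
#' counts(ts)$tx1[113]
NULL

#' @rdname accessors
#' @export
setGeneric("rpm", function(object, ...) standardGeneric("rpm"))

#' @rdname accessors
#' @export
setGeneric("librarySize", function(object, ...) standardGeneric("librarySize"))

#' @rdname accessors
#' @export
setGeneric("conditionLabel", function(object, ...) standardGeneric("conditionLabel"))

#' @rdname accessors
#' @export
setGeneric("transcriptLengths", function(object, ...) standardGeneric("transcriptLengths"))

#' @rdname accessors
#' @importFrom BiocGenerics counts
#' @export counts
#' @exportMethod counts
setMethod("counts", "RiboTrackSet",
          function(object, ...) object@counts)

#' @rdname accessors
#' @export
setMethod("rpm", "RiboTrackSet", function(object, ...) {
  if (!length(object@rpm))
    stop("tracks are not RPM-normalised yet; call normalizeRpm()")
  object@rpm
})

#' @rdname accessors
#' @export
setMethod("librarySize", "RiboTrackSet", function(object, ...) object@librarySize)

#' @rdname accessors
#' @export
setMethod("conditionLabel", "RiboTrackSet", function(object, ...) object@condition)

#' @rdname accessors
#' @export
setMethod("transcriptLengths", "RiboTrackSet", function(object, ...)
  vapply(object@counts, length, integer(1)))

setMethod("show", "RiboTrackSet", function(object) {
  cat(sprintf("RiboTrackSet: %d transcripts, %s assigned reads%s%s\n",
              length(object@counts),
              format(object@librarySize, big.mark = ","),
              if (!is.na(object@condition)) paste0(", condition '", object@condition, "'") else "",
              if (length(object@rpm)) ", RPM-normalised" else ""))
})

setMethod("show", "MetageneProfile", function(object) {
  cat(sprintf("MetageneProfile: window [%d, %d), %d genes\n",
              object@window[1], object@window[2], object@nGenes))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0(
    "SimConfig: %d ORFs (%d-%d nt), body intensity %.3g, queue A=%.3g ",
    "rho=%.2f K=%d spacing=%d nt, queued fraction %.2f on {%s}, seed %d\n"),
    object@nOrfs, object@orfLengthRange[1], object@orfLengthRange[2],
    object@bodyIntensity, object@queueAmplitude, object@queueDecay,
    object@nQueuePeaks, object@footprintSpacing, object@queuedFraction,
    if (length(object@queueCterm)) paste(object@queueCterm, collapse = ",") else "all",
    object@seed))
})

setMethod("show", "PeakLayout", function(object) {
  fmt <- function(m) paste(sprintf("[%d,%d)", m[, 1], m[, 2]), collapse = " ")
  cat("PeakLayout (stop-anchored nt):\n  peaks:", fmt(object@peaks),
      "\n  gaps: ", fmt(object@gaps), "\n")
})

#' @rdname MetageneProfile-class
#' @param object a \code{MetageneProfile}.
#' @export
setGeneric("profilePositions", function(object) standardGeneric("profilePositions"))

#' @rdname MetageneProfile-class
#' @export
setGeneric("profileDensity", function(object) standardGeneric("profileDensity"))

#' @rdname MetageneProfile-class
#' @export
setMethod("profilePositions", "MetageneProfile", function(object) object@position)

#' @rdname MetageneProfile-class
#' @export
setMethod("profileDensity", "MetageneProfile", function(object)
  stats::setNames(object@density, object@position))
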