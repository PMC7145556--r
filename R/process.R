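#' Read-length to P-site offset tables
#'
#' \code{defaultOffsets} returns the package default: a 12 nt 5'-end to
#' P-site offset for every read length 20-32 nt, reflecting the approximately
#' fixed distance between the yeast ribosome's 5' boundary and its P-site.
#' \code{loadOffsets} reads a two-column TSV (\code{length}, \code{offset},
#' header optional) and validates it: integer values, offsets >= 0, each
#' length at most once, non-empty. Every analysis records which table was
#' used via the table's \code{"provenance"} attribute.
#'
#' @param path path to a tab-separated offset table.
#' @return data.frame with integer columns \code{length} and \code{offset}
#'   and a \code{"provenance"} attribute.
#' @examples
#' defaultOffsets()
#' p <- tempfile()
#' write.table(data.frame(length = 28:30, offset = c(12L, 12L, 13L)), p,
#'             sep = "\t", row.names = FALSE)
#' loadOffsets(p)
#' @export
defaultOffsets <- function() {
  off <- data.frame(length = 20:32, offset = 12L)
  attr(off, "provenance") <- "riboQueue defaults: 12 nt for read lengths 20-32"
  off
}

#' @rdname defaultOffsets
#' @export
loadOffsets <- function(path) {
  raw <- tryCatch(utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE),
                  error = function(e) stop("no offsets in ", path, call. = FALSE))
  if (!nrow(raw)) stop("no offsets in ", path)
  # tolerate an optional header line (read lengths are always numeric)
  if (is.na(suppressWarnings(as.numeric(raw[1, 1])))) raw <- raw[-1, , drop = FALSE]
  if (!nrow(raw)) stop("no offsets in ", path)
  if (ncol(raw) < 2) stop("offset table must have two columns (length, offset)")
  lenN <- suppressWarnings(as.numeric(raw[[1]]))
  offN <- suppressWarnings(as.numeric(raw[[2]]))
  if (any(is.na(lenN)) || any(is.na(offN)))
    stop("offset table contains non-numeric values")
  if (any(lenN != round(lenN)) || any(offN != round(offN)))
    stop("offset table contains non-integer values")
  if (any(offN < 0)) stop("offsets must be >= 0")
  if (any(lenN <= 0)) stop("read lengths must be positive")
  if (anyDuplicated(lenN))
    stop("duplicate read length(s) in offset table: ",
         paste(unique(lenN[duplicated(lenN)]), collapse = ", "))
  off <- data.frame(length = as.integer(lenN), offset = as.integer(offN))
  attr(off, "provenance") <- paste0("loaded from ", path)
  off
}

#' Read a BED-like transcript-coordinate alignment table
#'
#' Expects tab-separated columns \code{transcript_id}, \code{start},
#' \code{end}, \code{read_length} (0-based, half-open); a fourth column is
#' derived from \code{end - start} when absent.
#'
#' @param path path to the TSV.
#' @return alignment data.frame.
#' @export
readAlignments <- function(path) {
  aln <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "start", "end")
  miss <- setdiff(need, names(aln))
  if (length(miss))
    stop("alignment file ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  if (is.null(aln$read_length)) aln$read_length <- aln$end - aln$start
  if (nrow(aln) && (any(aln$start < 0) || any(aln$read_length <= 0)))
    stop("alignments must have start >= 0 and length > 0")
  aln
}

#' Assign P-sites and build per-transcript coverage tracks
#'
#' Each read of length l is assigned a P-site at \code{start + offset(l)}
#' using a read-length-specific offset table. Reads whose length has no
#' offset, or whose P-site falls outside the transcript, are dropped and
#' counted. The library size used for RPM normalisation is the number of
#' assigned reads.
#'
#' @param alignments data.frame with \code{transcript_id}, \code{start},
#'   \code{read_length} (transcript coordinates, 0-based).
#' @param offsets offset table (see \code{\link{defaultOffsets}}).
#' @param transcriptLengths named integer vector of transcript lengths; every
#'   alignment's transcript must appear here.
#' @param condition optional condition label stored on the tracks.
#' @return list with \code{tracks} (a \code{\linkS4class{RiboTrackSet}},
#'   counts filled, RPM not yet) and \code{stats} (see
#'   \code{\link{lengthHistogram}}; additionally \code{dropped},
#'   \code{assigned}).
#' @examples
#' aln <- data.frame(transcript_id = "tx1", start = 100L, end = 128L,
#'                   read_length = 28L)
#' res <- assignPsites(aln, transcriptLengths = c(tx1 = 200L))
#' which(counts(res$tracks)$tx1 > 0)  # P-site at 0-based position 112
#' @export
assignPsites <- function(alignments, offsets = defaultOffsets(),
                         transcriptLengths, condition = NA_character_) {
  if (is.null(names(transcriptLengths)))
    stop("transcriptLengths must be a named vector")
  unknown <- setdiff(unique(alignments$transcript_id), names(transcriptLengths))
  if (length(unknown))
    stop("alignments reference unknown transcript(s): ",
         paste(utils::head(unknown, 10), collapse = ", "))
  nTx <- length(transcriptLengths)
  txLen <- as.integer(transcriptLengths)

  nIn <- nrow(alignments)
  if (nIn) {
    offVec <- rep(NA_integer_, max(offsets$length, alignments$read_length))
    offVec[offsets$length] <- offsets$offset
    o <- offVec[alignments$read_length]
    psite <- alignments$start + o
    ti <- match(alignments$transcript_id, names(transcriptLengths))
    keep <- !is.na(o) & psite >= 0L & psite < txLen[ti]
    base <- cumsum(c(0L, txLen))[seq_len(nTx)]
    glob <- base[ti[keep]] + psite[keep] + 1L
    flat <- tabulate(glob, nbins = sum(txLen))
  } else {
    keep <- logical(0)
    flat <- integer(sum(txLen))
  }
  cnt <- split(flat, rep.int(seq_len(nTx), txLen))
  names(cnt) <- names(transcriptLengths)
  cnt <- lapply(cnt, as.integer)

  stats <- lengthHistogram(alignments)
  stats$assigned <- sum(keep)
  stats$dropped <- nIn - sum(keep)
  tracks <- new("RiboTrackSet", counts = cnt, rpm = list(),
                librarySize = as.numeric(sum(keep)), condition = condition,
                offsetsProvenance = attr(offsets, "provenance") %||% "unspecified")
  list(tracks = tracks, stats = stats)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reads-per-million normalisation
#'
#' Fills the RPM tracks as \code{counts * 1e6 / librarySize}. Summed over the
#' whole library the RPM values total one million by construction.
#'
#' @param tracks a \code{\linkS4class{RiboTrackSet}} with counts filled.
#' @param librarySize RPM denominator; defaults to the track set's stored
#'   library size (assigned reads).
#' @return the track set with \code{rpm} filled.
#' @export
normalizeRpm <- function(tracks, librarySize = NULL) {
  if (is.null(librarySize)) librarySize <- tracks@librarySize
  if (librarySize <= 0)
    stop("cannot RPM-normalise a library of size 0")
  tracks@rpm <- lapply(tracks@counts, function(x) x * 1e6 / librarySize)
  tracks@librarySize <- librarySize
  validObject(tracks)
  tracks
}

#' Footprint-length accounting
#'
#' Tabulates read lengths and the fractions of the "short" (20-22 nt, vacant
#' A-site) and "long" (28-30 nt, occupied A-site) footprint classes. Class
#' fractions are computed over classified reads only; with no classified
#' reads they are reported as \code{NA}.
#'
#' @param alignments alignment data.frame with a \code{read_length} column.
#' @return list with \code{total}, \code{perLength} (named count vector),
#'   \code{shortFraction}, \code{longFraction}.
#' @examples
#' lengthHistogram(data.frame(read_length = c(20, 21, 28, 29, 29)))
#' @export
lengthHistogram <- function(alignments) {
  lens <- alignments$read_length
  total <- length(lens)
  perLength <- if (total) table(lens) else table(integer(0))
  nShort <- sum(lens >= 20 & lens <= 22)
  nLong <- sum(lens >= 28 & lens <= 30)
  nClass <- nShort + nLong
  list(total = total,
       perLength = stats::setNames(as.integer(perLength), names(perLength)),
       shortFraction = if (nClass) nShort / nClass else if (total) 0 else NA_real_,
       longFraction = if (nClass) nLong / nClass else if (total) 0 else NA_real_)
}

#' Pool replicate libraries
#'
#' Sums per-position counts and library sizes across replicate track sets and
#' recomputes RPM from the pooled totals (which differs from averaging
#' per-replicate RPM values).
#'
#' @param trackList list of \code{\linkS4class{RiboTrackSet}} objects over
#'   the same transcript set.
#' @param condition condition label for the pooled tracks; defaults to the
#'   first input's label.
#' @return pooled, RPM-normalised \code{RiboTrackSet}.
#' @export
poolLibraries <- function(trackList, condition = NULL) {
  if (!length(trackList)) stop("no libraries to pool")
  ref <- trackList[[1]]
  for (ts in trackList[-1]) {
    if (!identical(names(ts@counts), names(ref@counts)) ||
        !identical(lengths(ts@counts), lengths(ref@counts)))
      stop("cannot pool libraries over mismatched transcript sets")
  }
  cnt <- ref@counts
  for (ts in trackList[-1])
    cnt <- mapply(`+`, cnt, ts@counts, SIMPLIFY = FALSE)
  pooled <- new("RiboTrackSet", counts = cnt, rpm = list(),
                librarySize = sum(vapply(trackList, slot, numeric(1), "librarySize")),
                condition = condition %||% ref@condition,
                offsetsProvenance = ref@offsetsProvenance)
  normalizeRpm(pooled)
}

#' Project genome-space alignments into transcript coordinates
#'
#' Maps single-interval genomic reads onto spliced-transcript coordinates
#' using the exon chains of a GFF3 annotation. A read is projected only when
#' it is fully contained in a single exon of exactly one transcript;
#' junction-spanning, intergenic and ambiguous reads are dropped and counted.
#' Minus-strand transcripts are reversed, so the read's 3'-most genomic base
#' maps closest to the transcript 5' end.
#'
#' @param genomicAlignments data.frame with \code{chrom}, \code{start},
#'   \code{end} (0-based half-open genomic intervals).
#' @param gff3 path to a GFF3 file, or a \code{GRangesList} of exons grouped
#'   by transcript (each element ordered 5' to 3').
#' @return list with \code{alignments} (transcript-space data.frame:
#'   \code{transcript_id}, \code{start}, \code{end}, \code{read_length}) and
#'   \code{dropped} (reads not projected).
#' @export
projectToTranscript <- function(genomicAlignments, gff3) {
  exonsByTx <- if (is.character(gff3)) .exonsFromGff3(gff3) else gff3
  flat <- unlist(exonsByTx, use.names = FALSE)
  txOf <- rep(names(exonsByTx), lengths(exonsByTx))
  # cumulative transcript offset of each exon, honouring strand order
  cumOff <- unlist(lapply(exonsByTx, function(ex) {
    w <- GenomicRanges::width(ex)
    cumsum(c(0L, w[-length(w)]))
  }), use.names = FALSE)

  reads <- GenomicRanges::GRanges(
    genomicAlignments$chrom,
    IRanges::IRanges(start = genomicAlignments$start + 1L,
                     end = genomicAlignments$end))
  hits <- GenomicRanges::findOverlaps(reads, flat, type = "within",
                                      ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  # drop reads hitting exons of more than one transcript (ambiguous)
  txHit <- txOf[S4Vectors::subjectHits(hits)]
  nTxPerRead <- vapply(split(txHit, qh), function(x) length(unique(x)), integer(1))
  okReads <- as.integer(names(nTxPerRead)[nTxPerRead == 1L])
  sel <- qh %in% okReads & !duplicated(qh)
  qh <- qh[sel]
  sh <- S4Vectors::subjectHits(hits)[sel]

  ex <- flat[sh]
  minus <- as.character(GenomicRanges::strand(ex)) == "-"
  rs <- GenomicRanges::start(reads)[qh]
  re <- GenomicRanges::end(reads)[qh]
  txStart <- integer(length(sh))
  txStart[!minus] <- cumOff[sh[!minus]] + (rs[!minus] - GenomicRanges::start(ex)[!minus])
  txStart[minus] <- cumOff[sh[minus]] + (GenomicRanges::end(ex)[minus] - re[minus])
  len <- re - rs + 1L
  list(alignments = data.frame(transcript_id = txOf[sh],
                               start = txStart,
                               end = txStart + len,
                               read_length = len,
                               stringsAsFactors = FALSE),
       dropped = nrow(genomicAlignments) - length(qh))
}

.exonsFromGff3 <- function(path) {
  g <- tryCatch(rtracklayer::import(path, format = "gff3"),
                error = function(e) stop("malformed GFF3: ", conditionMessage(e),
                                         call. = FALSE))
  ex <- g[g$type == "exon"]
  if (!length(ex)) stop("GFF3 contains no exon records")
  parent <- as.character(S4Vectors::unstrsplit(ex$Parent, ","))
  byTx <- GenomicRanges::split(ex, parent)
  # order exons 5'->3' within each transcript
  S4Vectors::endoapply(byTx, function(e) {
    o <- order(GenomicRanges::start(e),
               decreasing = all(as.character(GenomicRanges::strand(e)) == "-"))
    e[o]
  })
}
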