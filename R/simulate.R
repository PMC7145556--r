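#' Construct a simulator configuration
#'
#' Builds a validated \code{\linkS4class{SimConfig}}. Defaults emulate the
#' experimental regime the package targets: a termination/recycling-defective
#' library in which ORFs ending in lysine or arginine accumulate stacked
#' ribosomes upstream of the stop codon, with queue peaks spaced one
#' protected-fragment length (30 nt) apart, a decaying amplitude per
#' successive ribosome, no terminating-ribosome peak at the last sense codon
#' (\code{stopPeakWeight = 0}), and footprint lengths drawn from the short
#' (20-22 nt) and long (28-30 nt) classes. Set \code{queueAmplitude = 0} for a
#' wild-type-like control library.
#'
#' @param nOrfs number of ORFs (default 200).
#' @param orfLengthRange coding-length range in nt, multiples of 3, stop
#'   included (default \code{c(300, 1500)}).
#' @param ctermAaDistribution named amino-acid probabilities for the
#'   C-terminal residue (default uniform over the 20 amino acids).
#' @param stopCodonDistribution named probabilities for TAA/TAG/TGA (default
#'   0.47/0.23/0.30, a typical yeast stop-codon usage).
#' @param queuedFraction probability that an eligible ORF is queued (default 1).
#' @param queueCterm amino acids eligible for queuing (default
#'   \code{c("K", "R")}; \code{character(0)} makes every ORF eligible).
#' @param queueAmplitude expected extra reads at the first queue peak
#'   (default 50, i.e. 10x the default body intensity).
#' @param queueDecay per-peak multiplicative decay in (0,1] (default 0.7).
#' @param nQueuePeaks number of queue peaks (default 3).
#' @param stopPeakWeight relative weight of the terminating-ribosome peak
#'   (default 0).
#' @param footprintSpacing nt between successive queued P-sites (default 30).
#' @param bodyIntensity expected reads per in-frame codon-start position
#'   (default 5).
#' @param frameWeights sub-codon weights summing to 1; the uniform default
#'   gives a flat body of \code{bodyIntensity} at every coding position.
#' @param queueJitterSd Gaussian smear (nt) of queue peaks, default 0 (exact
#'   point masses).
#' @param utrIntensity expected reads per 3'UTR position (default 0.25).
#' @param utr3Length,utr5Length UTR lengths in nt (defaults 100 and 18).
#' @param pLong probability of the long read class (default 0.7).
#' @param shortLengthProbs,longLengthProbs within-class length probabilities.
#' @param depthScale global intensity multiplier (default 1).
#' @param seed integer RNG seed (default 1).
#' @return a \code{SimConfig}.
#' @examples
#' cfg <- simConfig(nOrfs = 5, seed = 42)
#' cfg
#' @export
simConfig <- function(nOrfs = 200L,
                      orfLengthRange = c(300L, 1500L),
                      ctermAaDistribution = NULL,
                      stopCodonDistribution = c(TAA = 0.47, TAG = 0.23, TGA = 0.30),
                      queuedFraction = 1,
                      queueCterm = c("K", "R"),
                      queueAmplitude = 50,
                      queueDecay = 0.7,
                      nQueuePeaks = 3L,
                      stopPeakWeight = 0,
                      footprintSpacing = 30L,
                      bodyIntensity = 5,
                      frameWeights = rep(1 / 3, 3),
                      queueJitterSd = 0,
                      utrIntensity = 0.25,
                      utr3Length = 100L,
                      utr5Length = 18L,
                      pLong = 0.7,
                      shortLengthProbs = c("20" = 0.25, "21" = 0.5, "22" = 0.25),
                      longLengthProbs = c("28" = 0.25, "29" = 0.5, "30" = 0.25),
                      depthScale = 1,
                      seed = 1L) {
  if (is.null(ctermAaDistribution)) {
    aa <- aminoAcids()
    ctermAaDistribution <- stats::setNames(rep(1 / length(aa), length(aa)), aa)
  }
  new("SimConfig",
      nOrfs = as.integer(nOrfs),
      orfLengthRange = as.integer(orfLengthRange),
      ctermAaDistribution = ctermAaDistribution,
      stopCodonDistribution = stopCodonDistribution,
      queuedFraction = queuedFraction,
      queueCterm = queueCterm,
      queueAmplitude = queueAmplitude,
      queueDecay = queueDecay,
      nQueuePeaks = as.integer(nQueuePeaks),
      stopPeakWeight = stopPeakWeight,
      footprintSpacing = as.integer(footprintSpacing),
      bodyIntensity = bodyIntensity,
      frameWeights = frameWeights,
      queueJitterSd = queueJitterSd,
      utrIntensity = utrIntensity,
      utr3Length = as.integer(utr3Length),
      utr5Length = as.integer(utr5Length),
      pLong = pLong,
      shortLengthProbs = shortLengthProbs,
      longLengthProbs = longLengthProbs,
      depthScale = depthScale,
      seed = as.integer(seed))
}

.emptyAnnotation <- function() {
  data.frame(transcript_id = character(0), length = integer(0),
             cds_start = integer(0), cds_end = integer(0),
             strand = character(0), utr3_len = integer(0),
             stop_codon = character(0), cterm_aa = character(0),
             stringsAsFactors = FALSE)
}

.emptyTruth <- function() {
  data.frame(transcript_id = character(0), is_queued = logical(0),
             cterm_aa = character(0), stop_codon = character(0),
             expected_q = numeric(0), stringsAsFactors = FALSE)
}

#' Generate a synthetic ORF annotation, sequences and ground truth
#'
#' Draws \code{nOrfs} single-transcript ORFs: coding lengths uniform over the
#' configured multiples of 3, internal codons uniform over the 61 sense
#' codons (no internal stops by construction), the last sense codon encoding
#' an amino acid drawn from \code{ctermAaDistribution}, and the stop codon
#' from \code{stopCodonDistribution}. Each transcript carries a short 5'
#' leader and a 3'UTR of random nucleotides. Queue assignment (ground truth)
#' is drawn here: an ORF is queued with probability \code{queuedFraction} if
#' its C-terminal amino acid is in \code{queueCterm} (or if that set is
#' empty). The expected queuing metric under the default
#' \code{\link{peakLayout}} is recorded per ORF as
#' \code{(3b + A * sum(rho^(k-1)))/b} for queued ORFs and 3 otherwise.
#'
#' Deterministic given \code{seed}: identical configurations give
#' byte-identical output.
#'
#' @param config a \code{\linkS4class{SimConfig}}.
#' @return a list with elements \code{annotation} (data.frame:
#'   \code{transcript_id}, \code{length}, \code{cds_start}, \code{cds_end},
#'   \code{strand}, \code{utr3_len}, \code{stop_codon}, \code{cterm_aa}),
#'   \code{sequences} (\code{DNAStringSet}) and \code{truth} (data.frame:
#'   \code{transcript_id}, \code{is_queued}, \code{cterm_aa},
#'   \code{stop_codon}, \code{expected_q}).
#' @examples
#' ds <- generateAnnotation(simConfig(nOrfs = 3, seed = 7))
#' ds$annotation
#' @export
generateAnnotation <- function(config) {
  validObject(config)
  if (config@nOrfs == 0L)
    return(list(annotation = .emptyAnnotation(),
                sequences = Biostrings::DNAStringSet(),
                truth = .emptyTruth()))
  set.seed(config@seed)
  n <- config@nOrfs
  lens <- sampleVec(seq.int(config@orfLengthRange[1], config@orfLengthRange[2],
                            by = 3L), n, replace = TRUE)
  aaDist <- config@ctermAaDistribution
  cterm <- sampleVec(names(aaDist), n, replace = TRUE, prob = aaDist)
  stopD <- config@stopCodonDistribution
  stops <- sampleVec(names(stopD), n, replace = TRUE, prob = stopD)

  codonTab <- codonsForAa()
  penult <- vapply(cterm, function(a) sampleVec(codonTab[[a]], 1L), character(1))

  nInternal <- lens / 3L - 2L
  internal <- sampleVec(senseCodons(), sum(nInternal), replace = TRUE)
  splits <- rep.int(seq_len(n), nInternal)
  internalByOrf <- split(internal, factor(splits, levels = seq_len(n)))

  nt <- c("A", "C", "G", "T")
  leader <- vapply(seq_len(n), function(i)
    paste(sampleVec(nt, config@utr5Length, replace = TRUE), collapse = ""),
    character(1))
  utr3 <- vapply(seq_len(n), function(i)
    paste(sampleVec(nt, config@utr3Length, replace = TRUE), collapse = ""),
    character(1))
  cds <- vapply(seq_len(n), function(i)
    paste(c(internalByOrf[[i]], penult[i], stops[i]), collapse = ""),
    character(1))

  eligible <- if (length(config@queueCterm)) cterm %in% config@queueCterm else rep(TRUE, n)
  queued <- eligible & (stats::runif(n) < config@queuedFraction)

  ids <- sprintf("tx%04d", seq_len(n))
  annotation <- data.frame(
    transcript_id = ids,
    length = config@utr5Length + lens + config@utr3Length,
    cds_start = config@utr5Length,
    cds_end = config@utr5Length + lens,
    strand = "+",
    utr3_len = config@utr3Length,
    stop_codon = stops,
    cterm_aa = cterm,
    stringsAsFactors = FALSE)

  b <- config@bodyIntensity
  rho <- config@queueDecay
  kMax <- min(config@nQueuePeaks, 3L)
  expQ <- ifelse(queued & b > 0,
                 (3 * b + config@queueAmplitude * sum(rho^(seq_len(kMax) - 1))) / b,
                 3)
  truth <- data.frame(transcript_id = ids, is_queued = queued,
                      cterm_aa = cterm, stop_codon = stops,
                      expected_q = expQ, stringsAsFactors = FALSE)

  sequences <- Biostrings::DNAStringSet(paste0(leader, cds, utr3))
  names(sequences) <- ids
  list(annotation = annotation, sequences = sequences, truth = truth)
}

#' Expected per-position P-site intensity for one ORF
#'
#' Evaluates the generative intensity vector lambda over a transcript: a flat
#' body of \code{3 * bodyIntensity * frameWeights[frame]} on coding positions
#' (so exactly \code{bodyIntensity} everywhere under the uniform default),
#' \code{utrIntensity} on 3'UTR positions, and, for queued ORFs, point-mass
#' additions \code{queueAmplitude * queueDecay^(k-1)} at stop-anchored
#' positions \code{-3 - k*footprintSpacing} (k = 1..nQueuePeaks) plus
#' \code{stopPeakWeight * queueAmplitude} at \code{-3}. Peaks that would fall
#' upstream of the CDS start are dropped. Everything is scaled by
#' \code{depthScale}. With \code{queueJitterSd > 0} each peak mass is smeared
#' over a discretised Gaussian kernel instead of a point mass.
#'
#' @param config a \code{\linkS4class{SimConfig}}.
#' @param orf one annotation row (list or single-row data.frame).
#' @param isQueued logical flag from the ground truth.
#' @return numeric vector of expected counts, one per transcript position.
#' @examples
#' ds <- generateAnnotation(simConfig(nOrfs = 1, seed = 1))
#' lam <- expectedIntensity(simConfig(nOrfs = 1), ds$annotation[1, ], TRUE)
#' @export
expectedIntensity <- function(config, orf, isQueued) {
  validObject(config)
  len <- as.integer(orf$length)
  lam <- numeric(len)
  cs <- as.integer(orf$cds_start)
  ce <- as.integer(orf$cds_end)
  body <- seq.int(cs, ce - 1L)
  frame <- (body - cs) %% 3L
  lam[body + 1L] <- 3 * config@bodyIntensity * config@frameWeights[frame + 1L]
  if (orf$utr3_len > 0)
    lam[seq.int(ce, len - 1L) + 1L] <- lam[seq.int(ce, len - 1L) + 1L] + config@utrIntensity
  if (isQueued && config@queueAmplitude > 0) {
    s0 <- ce - 3L
    addPeak <- function(center, mass) {
      if (config@queueJitterSd > 0) {
        halo <- ceiling(3 * config@queueJitterSd)
        off <- seq.int(-halo, halo)
        w <- stats::dnorm(off, sd = config@queueJitterSd)
        w <- w / sum(w)
        pos <- center + off
        keep <- pos >= cs & pos < len
        lam[pos[keep] + 1L] <<- lam[pos[keep] + 1L] + mass * w[keep]
      } else if (center >= cs && center < len) {
        lam[center + 1L] <<- lam[center + 1L] + mass
      }
    }
    for (k in seq_len(config@nQueuePeaks)) {
      ck <- s0 - 3L - k * config@footprintSpacing
      addPeak(ck, config@queueAmplitude * config@queueDecay^(k - 1))
    }
    if (config@stopPeakWeight > 0)
      addPeak(s0 - 3L, config@stopPeakWeight * config@queueAmplitude)
  }
  lam * config@depthScale
}

#' Simulate a footprint alignment library
#'
#' Samples per-position P-site counts as independent Poisson draws from the
#' expected intensities (\code{\link{expectedIntensity}}), then converts each
#' P-site event into a footprint alignment: a read length is drawn from the
#' short/long class mixture and the 5' start is placed at
#' \code{psite - offset(length)} using the same offset table that
#' \code{\link{assignPsites}} uses by default, so that P-site assignment
#' round-trips the simulated library exactly. Reads whose 5' start would fall
#' before the transcript start are dropped and logged.
#'
#' @param config a \code{\linkS4class{SimConfig}}.
#' @param annotation,truth from \code{\link{generateAnnotation}}.
#' @param seed RNG seed for this library; defaults to \code{config@seed + 1}.
#'   Give each replicate its own seed.
#' @param offsets offset table shared with P-site assignment
#'   (default \code{\link{defaultOffsets}()}).
#' @return list with \code{alignments} (data.frame \code{transcript_id},
#'   \code{start}, \code{end}, \code{read_length}), \code{sampledCounts}
#'   (named list of the per-position Poisson draws, the ground-truth P-site
#'   count vectors), \code{dropped} (number of dropped reads) and
#'   \code{librarySize} (emitted reads).
#' @examples
#' ds <- generateAnnotation(simConfig(nOrfs = 2, seed = 3))
#' lib <- simulateFootprints(simConfig(nOrfs = 2, seed = 3), ds$annotation, ds$truth)
#' head(lib$alignments)
#' @export
simulateFootprints <- function(config, annotation, truth, seed = NULL,
                               offsets = defaultOffsets()) {
  validObject(config)
  .checkAnnotation(annotation)
  if (!identical(annotation$transcript_id, truth$transcript_id))
    stop("annotation and truth describe different transcripts")
  set.seed(if (is.null(seed)) config@seed + 1L else as.integer(seed))
  n <- nrow(annotation)
  txLen <- .txLengths(annotation)
  emptyAln <- data.frame(transcript_id = character(0), start = integer(0),
                         end = integer(0), read_length = integer(0),
                         stringsAsFactors = FALSE)
  if (n == 0L)
    return(list(alignments = emptyAln, sampledCounts = list(),
                dropped = 0L, librarySize = 0L))

  lam <- lapply(seq_len(n), function(i)
    expectedIntensity(config, annotation[i, ], truth$is_queued[i]))
  lens <- lengths(lam)
  countsAll <- stats::rpois(sum(lens), unlist(lam, use.names = FALSE))
  idxTx <- rep.int(seq_len(n), lens)
  posAll <- unlist(lapply(lens, function(l) seq.int(0L, l - 1L)), use.names = FALSE)

  sampledCounts <- split(countsAll, factor(idxTx, levels = seq_len(n)))
  names(sampledCounts) <- annotation$transcript_id
  sampledCounts <- lapply(sampledCounts, as.integer)

  nz <- countsAll > 0L
  psite <- rep.int(posAll[nz], countsAll[nz])
  tx <- rep.int(idxTx[nz], countsAll[nz])
  nReads <- length(psite)
  if (nReads == 0L)
    return(list(alignments = emptyAln, sampledCounts = sampledCounts,
                dropped = 0L, librarySize = 0L))

  long <- stats::runif(nReads) < config@pLong
  readLen <- integer(nReads)
  nLong <- sum(long)
  if (nLong)
    readLen[long] <- sampleVec(c(28L, 29L, 30L), nLong, replace = TRUE,
                               prob = config@longLengthProbs)
  if (nReads - nLong)
    readLen[!long] <- sampleVec(c(20L, 21L, 22L), nReads - nLong, replace = TRUE,
                                prob = config@shortLengthProbs)

  offVec <- rep(NA_integer_, max(offsets$length))
  offVec[offsets$length] <- offsets$offset
  start <- psite - offVec[readLen]
  keep <- !is.na(start) & start >= 0L
  alignments <- data.frame(
    transcript_id = annotation$transcript_id[tx[keep]],
    start = start[keep],
    end = start[keep] + readLen[keep],
    read_length = readLen[keep],
    stringsAsFactors = FALSE)
  list(alignments = alignments,
       sampledCounts = sampledCounts,
       dropped = sum(!keep),
       librarySize = nrow(alignments))
}

#' Write / read a synthetic dataset as plain-text files
#'
#' \code{writeDataset} writes the FASTA sequences, TSV annotation, TSV ground
#' truth and one BED-like TSV per footprint library into a directory;
#' \code{readDataset} reads them back. The BED-like format has columns
#' \code{transcript_id}, \code{start}, \code{end}, \code{read_length}
#' (0-based, half-open) and is the same format \code{\link{readAlignments}}
#' accepts.
#'
#' @param dataset list from \code{\link{generateAnnotation}}.
#' @param libraries named list of alignment data.frames (each either the
#'   \code{alignments} element of \code{\link{simulateFootprints}} output or
#'   such an output list itself).
#' @param dir output (input) directory; created if needed.
#' @return \code{writeDataset}: invisibly, the written file paths.
#'   \code{readDataset}: a list with \code{annotation}, \code{sequences},
#'   \code{truth} and \code{libraries}.
#' @examples
#' cfg <- simConfig(nOrfs = 2, seed = 5)
#' ds <- generateAnnotation(cfg)
#' lib <- simulateFootprints(cfg, ds$annotation, ds$truth)
#' d <- tempfile(); writeDataset(ds, list(rep1 = lib), d)
#' back <- readDataset(d)
#' @export
writeDataset <- function(dataset, libraries, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(annotation = file.path(dir, "annotation.tsv"),
             truth = file.path(dir, "truth.tsv"),
             sequences = file.path(dir, "sequences.fasta"))
  utils::write.table(dataset$annotation, paths["annotation"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  Biostrings::writeXStringSet(dataset$sequences, paths["sequences"])
  for (nm in names(libraries)) {
    lib <- libraries[[nm]]
    aln <- if (is.data.frame(lib)) lib else lib$alignments
    p <- file.path(dir, paste0("library_", nm, ".tsv"))
    utils::write.table(aln, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[paste0("library_", nm)] <- p
  }
  invisible(paths)
}

#' @rdname writeDataset
#' @export
readDataset <- function(dir) {
  if (!dir.exists(dir)) stop("no such dataset directory: ", dir)
  annotation <- utils::read.delim(file.path(dir, "annotation.tsv"),
                                  stringsAsFactors = FALSE)
  truth <- utils::read.delim(file.path(dir, "truth.tsv"),
                             stringsAsFactors = FALSE)
  sequences <- Biostrings::readDNAStringSet(file.path(dir, "sequences.fasta"))
  libFiles <- list.files(dir, pattern = "^library_.*\\.tsv$", full.names = TRUE)
  libraries <- lapply(libFiles, readAlignments)
  names(libraries) <- sub("^library_(.*)\\.tsv$", "\\1", basename(libFiles))
  list(annotation = annotation, sequences = sequences, truth = truth,
       libraries = libraries)
}
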