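# In-code fixtures shared across test files.

# one-ORF annotation row with controllable geometry
mkOrf <- function(id = "tx1", cdsLen = 153L, utr5 = 0L, utr3 = 60L,
                  ctermAa = "K", stopCodon = "TAA") {
  data.frame(transcript_id = id, length = utr5 + cdsLen + utr3,
             cds_start = utr5, cds_end = utr5 + cdsLen, strand = "+",
             utr3_len = utr3, stop_codon = stopCodon, cterm_aa = ctermAa,
             stringsAsFactors = FALSE)
}

# RiboTrackSet straight from given per-transcript RPM vectors
mkTracks <- function(rpmList, countsList = NULL, librarySize = 1e6,
                     condition = "cond1") {
  if (is.null(countsList))
    countsList <- lapply(rpmList, function(x) as.integer(round(x)))
  new("RiboTrackSet", counts = countsList, rpm = rpmList,
      librarySize = librarySize, condition = condition,
      offsetsProvenance = "test fixture")
}

# rpm vector for a 153-nt ORF (stop at 150) with inter-peak level 1 and a
# single spike of height `q` in the stop-proximal peak window, zero in the
# other peak windows: queuingMetric returns exactly q
spikeTrack <- function(q, cdsLen = 153L, utr3 = 0L) {
  stop0 <- cdsLen - 3L
  v <- numeric(cdsLen + utr3)
  v[(stop0 - 120L):(stop0 - 1L) + 1L] <- 1
  for (w in list(c(-38L, -28L), c(-68L, -58L), c(-98L, -88L)))
    v[(stop0 + w[1]):(stop0 + w[2] - 1L) + 1L] <- 0
  v[stop0 - 33L + 1L] <- q
  v
}

# annotation + sequences with prescribed codon strings (no 5' leader)
mkSeqOrfs <- function(cdsList, utr3 = 0L) {
  ids <- sprintf("sx%03d", seq_along(cdsList))
  ann <- do.call(rbind, lapply(seq_along(cdsList), function(i) {
    cds <- cdsList[[i]]
    mkOrf(ids[i], cdsLen = nchar(cds), utr3 = utr3)
  }))
  ann$stop_codon <- substring(unlist(cdsList), nchar(unlist(cdsList)) - 2L)
  seqs <- Biostrings::DNAStringSet(paste0(unlist(cdsList),
                                          strrep("A", utr3)))
  names(seqs) <- ids
  list(annotation = ann, sequences = seqs)
}

# run simulate -> assign -> normalise for a config; returns tracks + dataset
simTracks <- function(cfg, seed = NULL) {
  ds <- generateAnnotation(cfg)
  lib <- simulateFootprints(cfg, ds$annotation, ds$truth, seed = seed)
  txLen <- stats::setNames(ds$annotation$length, ds$annotation$transcript_id)
  res <- assignPsites(lib$alignments, transcriptLengths = txLen)
  list(tracks = normalizeRpm(res$tracks), dataset = ds, lib = lib,
       stats = res$stats)
}
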