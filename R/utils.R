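# Shared helpers: genetic code tables, sampling, coordinate conventions.
#
# Coordinates are transcript-space, 0-based, half-open throughout. The
# stop-anchored frame places position 0 on the first nucleotide of the stop
# codon, so the last sense codon starts at -3 and the k-th stacked ribosome's
# P-site codon at -3 - k*spacing.

senseCodons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

aminoAcids <- function() sort(unique(unname(
  Biostrings::GENETIC_CODE[Biostrings::GENETIC_CODE != "*"])))

codonsForAa <- function() {
  sc <- senseCodons()
  split(sc, unname(Biostrings::GENETIC_CODE[sc]))
}

translateCodons <- function(codons) unname(Biostrings::GENETIC_CODE[codons])

# sample() treats a length-1 numeric x as 1:x; avoid that trap
sampleVec <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

# transcript coordinate of the first stop-codon nucleotide
stopAnchor <- function(orf) orf$cds_end - 3L

.checkAnnotation <- function(annotation) {
  need <- c("transcript_id", "length", "cds_start", "cds_end", "utr3_len")
  miss <- setdiff(need, names(annotation))
  if (length(miss))
    stop("annotation is missing columns: ", paste(miss, collapse = ", "))
  invisible(annotation)
}

.txLengths <- function(annotation) {
  stats::setNames(as.integer(annotation$length), annotation$transcript_id)
}

# window of stop-anchored positions [w1, w2) as 1-based indices into a track
.anchorIdx <- function(stop0, window) {
  seq.int(stop0 + window[1], stop0 + window[2] - 1L) + 1L
}
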