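test_that("generated annotations honour the genetic code and the config", {
  cfg <- simConfig(nOrfs = 40, seed = 11, orfLengthRange = c(150L, 300L))
  ds <- generateAnnotation(cfg)
  ann <- ds$annotation
  expect_equal(nrow(ann), 40)
  cdsLen <- ann$cds_end - ann$cds_start
  expect_true(all(cdsLen %% 3 == 0))
  for (i in seq_len(nrow(ann))) {
    cds <- as.character(Biostrings::subseq(ds$sequences[[i]],
                                           ann$cds_start[i] + 1, ann$cds_end[i]))
    codons <- substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
    nC <- length(codons)
    # ends with the recorded stop, no internal stop, penultimate codon
    # translates to the recorded C-terminal amino acid
    expect_identical(codons[nC], ann$stop_codon[i])
    expect_false(any(codons[-nC] %in% c("TAA", "TAG", "TGA")))
    expect_identical(unname(Biostrings::GENETIC_CODE[codons[nC - 1]]),
                     ann$cterm_aa[i])
  }
  expect_identical(ds$truth$cterm_aa, ann$cterm_aa)
  expect_identical(ds$truth$stop_codon, ann$stop_codon)
})

test_that("empty and deterministic generation behave as specified", {
  expect_equal(nrow(generateAnnotation(simConfig(nOrfs = 0))$annotation), 0)
  cfg <- simConfig(nOrfs = 5, seed = 1)
  a <- generateAnnotation(cfg)
  b <- generateAnnotation(cfg)
  expect_identical(a$annotation, b$annotation)
  expect_identical(as.character(a$sequences), as.character(b$sequences))
  expect_identical(a$truth, b$truth)
  la <- simulateFootprints(cfg, a$annotation, a$truth)
  lb <- simulateFootprints(cfg, b$annotation, b$truth)
  expect_identical(la$alignments, lb$alignments)
})

test_that("C-terminal amino-acid frequencies match the configured law", {
  # binomial 99% CI oracle for the fraction of K-ending ORFs at p = 0.5
  aa <- riboQueue:::aminoAcids()
  p <- stats::setNames(rep(0.5 / 19, length(aa)), aa)
  p["K"] <- 0.5
  cfg <- simConfig(nOrfs = 1000, seed = 3, ctermAaDistribution = p,
                   orfLengthRange = c(150L, 300L))
  ds <- generateAnnotation(cfg)
  nK <- sum(ds$annotation$cterm_aa == "K")
  ci <- stats::qbinom(c(0.005, 0.995), 1000, 0.5)
  expect_gte(nK, ci[1])
  expect_lte(nK, ci[2])
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(ctermAaDistribution = c(K = 0.5, R = 0.4)),
               "sum to 1")
  expect_error(simConfig(queueDecay = 0), "queueDecay")
  expect_error(simConfig(queueAmplitude = -1), "queueAmplitude")
  expect_error(simConfig(frameWeights = c(0.5, 0.5, 0.5)), "frameWeights")
})

test_that("expected intensity encodes the queue geometry", {
  cfg0 <- simConfig(bodyIntensity = 2, queueAmplitude = 0, utrIntensity = 0.5)
  orf <- mkOrf(cdsLen = 300L, utr3 = 60L)
  lam <- expectedIntensity(cfg0, orf, FALSE)
  # flat body at b everywhere under uniform frame weights; UTR at its own level
  expect_true(all(lam[1:300] == 2))
  expect_true(all(lam[301:360] == 0.5))

  # frozen evaluation of the peak formula: all body mass in frame 0,
  # lambda(in-frame) = 3*b*w0 = 3, plus A*rho^(k-1) at -3 - 30k
  cfgQ <- simConfig(bodyIntensity = 1, frameWeights = c(1, 0, 0),
                    queueAmplitude = 10, queueDecay = 0.7, nQueuePeaks = 3,
                    footprintSpacing = 30, stopPeakWeight = 0)
  lamQ <- expectedIntensity(cfgQ, orf, TRUE)
  stop0 <- 297L
  expect_equal(lamQ[stop0 - 33 + 1], 13)
  expect_equal(lamQ[stop0 - 63 + 1], 10)
  expect_equal(lamQ[stop0 - 93 + 1], 7.9)
  expect_equal(lamQ[stop0 - 34 + 1], 0)  # off-frame, no body mass

  # closed form under defaults: Q on lambda = (3b + A(1+rho+rho^2))/b
  cfgD <- simConfig(bodyIntensity = 1, queueAmplitude = 10, queueDecay = 0.7)
  lamD <- expectedIntensity(cfgD, orf, TRUE)
  expect_equal(queuingMetric(lamD, stop0), 24.9)

  # peaks that would fall upstream of the CDS are dropped
  short <- mkOrf(cdsLen = 60L, utr3 = 0L)
  lamS <- expectedIntensity(cfgD, short, TRUE)
  expect_equal(sum(lamS > 1), 1)  # only the k=1 peak at -33 fits
})

test_that("simulated libraries are Poisson-consistent and conserve reads", {
  cfg <- simConfig(nOrfs = 1, orfLengthRange = c(1200L, 1200L),
                   bodyIntensity = 5, queueAmplitude = 0, seed = 9)
  ds <- generateAnnotation(cfg)
  lib <- simulateFootprints(cfg, ds$annotation, ds$truth)
  lamSum <- sum(expectedIntensity(cfg, ds$annotation[1, ], FALSE))
  ci <- stats::qpois(c(0.005, 0.995), lamSum)
  total <- sum(unlist(lib$sampledCounts))
  expect_gte(total, ci[1])
  expect_lte(total, ci[2])
  # conservation: emitted + dropped = sampled
  expect_equal(nrow(lib$alignments) + lib$dropped, total)

  # null library at zero depth
  cfg0 <- simConfig(nOrfs = 2, depthScale = 0, utrIntensity = 0)
  ds0 <- generateAnnotation(cfg0)
  lib0 <- simulateFootprints(cfg0, ds0$annotation, ds0$truth)
  expect_equal(nrow(lib0$alignments), 0)
})

test_that("P-site assignment round-trips the simulator exactly", {
  cfg <- simConfig(nOrfs = 15, seed = 21, orfLengthRange = c(153L, 450L))
  st <- simTracks(cfg)
  expect_identical(lapply(counts(st$tracks), as.integer),
                   st$lib$sampledCounts)
  expect_equal(st$stats$dropped, st$lib$dropped)
})

test_that("datasets round-trip through plain-text files", {
  cfg <- simConfig(nOrfs = 4, seed = 13, orfLengthRange = c(150L, 300L))
  ds <- generateAnnotation(cfg)
  lib <- simulateFootprints(cfg, ds$annotation, ds$truth)
  d <- withr::local_tempdir()
  writeDataset(ds, list(rep1 = lib), d)
  back <- readDataset(d)
  expect_equal(back$annotation, ds$annotation)
  expect_equal(back$truth, ds$truth)
  expect_identical(as.character(back$sequences), as.character(ds$sequences))
  expect_equal(back$libraries$rep1, lib$alignments)

  # an empty library still writes a valid, re-readable file with a header
  empty <- lib$alignments[0, ]
  writeDataset(ds, list(none = empty), d)
  expect_equal(nrow(readDataset(d)$libraries$none), 0)
})

test_that("a four-condition two-replicate design emits eight libraries", {
  cfg <- defaultPipelineConfig(seed = 5, nOrfs = 6)
  cfg$stages <- "simulate"
  cfg$sim$orfLengthRange <- c(150L, 300L)
  b <- suppressMessages(runPipeline(cfg))
  expect_length(b$libraries, 8)
  d <- withr::local_tempdir()
  writeDataset(b$dataset, b$libraries, d)
  expect_length(list.files(d, pattern = "^library_"), 8)
})
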