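test_that("the default peak layout places peaks one footprint apart", {
  lay <- peakLayout()
  expect_equal(lay@peaks, cbind(c(-38L, -68L, -98L), c(-28L, -58L, -88L)))
  expect_equal(lay@gaps[3, ], c(-28L, -6L))
  expect_error(peakLayout(spacing = 45), "within")  # peak outside [-120, 0)
})

test_that("Q is 3 on flat tracks, scale-invariant, and matches hand values", {
  for (c0 in c(0.1, 2, 57)) {
    expect_equal(queuingMetric(rep(c0, 200), 150L), 3.0)
  }
  # hand evaluation: background 2 with spikes 10/8/6 at the peak centres
  v <- rep(2, 200)
  v[150 - c(33, 63, 93) + 1] <- c(10, 8, 6)
  expect_equal(queuingMetric(v, 150L), (10 + 8 + 6) / 2)
  expect_equal(queuingMetric(v * 1000, 150L), queuingMetric(v, 150L))

  # zero inter-peak density -> undefined
  z <- numeric(200)
  z[150 - 33 + 1] <- 5
  expect_true(is.na(queuingMetric(z, 150L)))

  # ORF too short to host the layout
  expect_error(queuingMetric(rep(1, 60), 50L), "too short")
})

test_that("Q grows monotonically with queue amplitude as the closed form", {
  orf <- mkOrf(cdsLen = 300L, utr3 = 0L)
  b <- 2
  qs <- vapply(c(0, 5, 10, 20, 40), function(A) {
    cfg <- simConfig(bodyIntensity = b, queueAmplitude = A, queueDecay = 0.7)
    lam <- expectedIntensity(cfg, orf, TRUE)
    queuingMetric(lam, 297L)
  }, numeric(1))
  expect_true(all(diff(qs) > 0))
  expect_equal(qs, (3 * b + c(0, 5, 10, 20, 40) * (1 + 0.7 + 0.49)) / b)
})

test_that("the coverage filter applies the >= 10 RPM rule per condition", {
  ann <- mkOrf("g1", cdsLen = 153L, utr3 = 0L)
  flat <- function(level) mkTracks(list(g1 = rep(level, 153)))
  cfgQ <- queuingConfig()

  both10 <- list(c1 = flat(10), c2 = flat(10), c3 = flat(10), c4 = flat(10))
  expect_true(coverageFilter(both10, ann, cfgQ)$pass)

  oneLow <- list(c1 = flat(10), c2 = flat(9.9), c3 = flat(10), c4 = flat(10))
  f <- coverageFilter(oneLow, ann, cfgQ)
  expect_false(f$pass)
  expect_equal(f$reason, "low_coverage:c2")

  shortOrf <- mkOrf("g1", cdsLen = 90L, utr3 = 0L)
  fs <- coverageFilter(list(c1 = flat(100)), shortOrf, cfgQ)
  expect_false(fs$pass)
  expect_equal(fs$reason, "too_short")

  expect_error(coverageFilter(both10, ann,
                              queuingConfig(conditions = c("c1", "missing"))),
               "missing")
})

test_that("Z-scores use the sample standard deviation over defined Q", {
  qs <- c(1, 2, 3, 4, 10)
  ann <- do.call(rbind, lapply(seq_along(qs), function(i)
    mkOrf(sprintf("g%d", i), cdsLen = 153L, utr3 = 0L)))
  tracks <- list(cond1 = mkTracks(stats::setNames(
    lapply(qs, spikeTrack), ann$transcript_id)))
  sc <- scoreAll(tracks, ann, queuingConfig(minCoverage = 0))
  expect_equal(sc$Q, qs)
  expect_equal(attr(sc, "meanQ")[["cond1"]], 4.0)
  # hand calculation with ddof = 1: sd = 3.5355, z(Q=10) = 1.6971
  expect_equal(sc$z[5], (10 - 4) / sd(qs), tolerance = 1e-12)
  expect_equal(sc$z[5], 1.697056, tolerance = 1e-6)

  sel <- zscoreSelect(sc, 1)
  expect_equal(sel$orf_id, "g5")
  expect_equal(nrow(zscoreSelect(sc, Inf)), 0)
  expect_equal(nrow(zscoreSelect(sc, -Inf)), 5)

  # selection is invariant to track rescaling
  tracks1000 <- list(cond1 = mkTracks(stats::setNames(
    lapply(qs, function(q) spikeTrack(q) * 1000), ann$transcript_id)))
  sc1000 <- scoreAll(tracks1000, ann, queuingConfig(minCoverage = 0))
  expect_equal(zscoreSelect(sc1000, 1)$orf_id, sel$orf_id)
  expect_equal(sc1000$z, sc$z, tolerance = 1e-12)
})

test_that("degenerate Q sets are flagged rather than patched", {
  ann <- rbind(mkOrf("g1", cdsLen = 153L, utr3 = 0L),
               mkOrf("g2", cdsLen = 153L, utr3 = 0L))
  flatBoth <- list(c1 = mkTracks(list(g1 = rep(5, 153), g2 = rep(5, 153))))
  expect_warning(sc <- scoreAll(flatBoth, ann, queuingConfig(minCoverage = 0)),
                 "z not computed")
  expect_true(all(is.na(sc$z)))
  expect_equal(nrow(zscoreSelect(sc)), 0)

  # an undefined-Q ORF leaves every other ORF's z untouched
  qs <- c(1, 2, 3, 4, 10)
  ann5 <- do.call(rbind, lapply(seq_along(qs), function(i)
    mkOrf(sprintf("g%d", i), cdsLen = 153L, utr3 = 0L)))
  tr5 <- stats::setNames(lapply(qs, spikeTrack), ann5$transcript_id)
  sc5 <- scoreAll(list(c1 = mkTracks(tr5)), ann5, queuingConfig(minCoverage = 0))

  annU <- rbind(ann5, mkOrf("gU", cdsLen = 153L, utr3 = 0L))
  undef <- numeric(153)
  undef[150 - 33 + 1] <- 7  # peak only, zero inter-peak mean
  trU <- c(tr5, list(gU = undef))
  scU <- scoreAll(list(c1 = mkTracks(trU)), annU, queuingConfig(minCoverage = 0))
  expect_equal(scU$flag[scU$orf_id == "gU"], "undefined_Q")
  expect_equal(scU$z[match(ann5$transcript_id, scU$orf_id)], sc5$z)
})

test_that("grouping by C-terminal amino acid reports n, mean and spread", {
  sc <- data.frame(orf_id = c("a", "b", "c"), condition = "c1",
                   Q = c(4, 6, 10), z = 0,
                   cterm_aa = c("K", "K", "R"),
                   stop_codon = "TAA", mean_rpm = 1, flag = "")
  g <- groupByCterm(sc)
  expect_equal(g$summary$mean_q[g$summary$cterm_aa == "K"], 5.0)
  expect_equal(g$summary$mean_q[g$summary$cterm_aa == "R"], 10.0)
  expect_equal(g$summary$n[g$summary$cterm_aa == "A"], 0L)
  expect_true(is.na(g$summary$mean_q[g$summary$cterm_aa == "A"]))
  expect_equal(g$values$K, c(4, 6))
})

test_that("queuing imposed on K/R-ending ORFs raises their mean Q", {
  cfg <- simConfig(nOrfs = 200, seed = 6, orfLengthRange = c(153L, 450L),
                   queueAmplitude = 50)
  st <- simTracks(cfg)
  sc <- scoreAll(list(lib = st$tracks), st$dataset$annotation,
                 queuingConfig(minCoverage = 0))
  kr <- sc$Q[sc$cterm_aa %in% c("K", "R") & !is.na(sc$Q)]
  rest <- sc$Q[!sc$cterm_aa %in% c("K", "R") & !is.na(sc$Q)]
  expect_gt(mean(kr), mean(rest))
  wt <- stats::wilcox.test(kr, rest, alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})
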