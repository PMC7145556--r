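# independent oracle: exact binomial tail by direct summation in log space
.tailGE <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(exp(lchoose(n, k:n) + (k:n) * log(p) + (n - (k:n)) * log1p(-p)))
}
.tailLE <- function(k, n, p) {
  sum(exp(lchoose(n, 0:k) + (0:k) * log(p) + (n - 0:k) * log1p(-p)))
}

test_that("the signed log-odds statistic matches its defining cases", {
  expect_equal(binomialLogOdds(1, 1, 0.5)$s, 0)
  expect_equal(binomialLogOdds(4, 4, 0.5)$s, log10(15), tolerance = 1e-9)
  expect_equal(binomialLogOdds(0, 4, 0.5)$s, -log10(15), tolerance = 1e-9)
  expect_equal(binomialLogOdds(4, 4, 0.5)$p, 0.0625)
  expect_error(binomialLogOdds(1, 2, 1.5), "pBg")
  # degenerate backgrounds are capped at the +/-99 sentinel and flagged
  d <- binomialLogOdds(3, 4, 0)
  expect_true(d$capped)
  expect_equal(d$s, 99)
})

test_that("log-odds agree with brute-force binomial tails for n <= 50", {
  for (n in c(1, 2, 5, 17, 50)) {
    for (p in c(0.05, 0.2, 0.5, 0.8)) {
      k <- 0:n
      got <- binomialLogOdds(k, n, p)
      oracle <- vapply(k, function(ki) {
        if (ki >= n * p) {
          pt <- .tailGE(ki, n, p)
          log10((1 - pt) / pt)
        } else {
          pt <- .tailLE(ki, n, p)
          -log10((1 - pt) / pt)
        }
      }, numeric(1))
      fin <- is.finite(oracle) & !got$capped
      expect_equal(got$s[fin], oracle[fin], tolerance = 1e-9)
    }
  }
})

test_that("antisymmetry: swapping k <-> n-k with p <-> 1-p flips the sign", {
  n <- 23
  for (p in c(0.1, 0.37, 0.5)) {
    # at k exactly n*p both orientations sit on the same (upper) branch, so
    # the mirror identity only applies away from that tie
    k <- (0:n)[0:n != n * p]
    s1 <- binomialLogOdds(k, n, p)$s
    s2 <- binomialLogOdds(n - k, n, 1 - p)$s
    expect_equal(s1, -s2, tolerance = 1e-9)
  }
})

test_that("the Bonferroni log-odds line follows the closed form", {
  expect_equal(bonferroniThreshold(0.5, 1), 0)
  expect_equal(bonferroniThreshold(0.05, 100), log10(1999))
  expect_equal(bonferroniThreshold(0.05, 100), 3.3008, tolerance = 1e-4)
  # monotone increasing in the family size
  ths <- vapply(c(1, 10, 100, 140, 1000), bonferroniThreshold,
                numeric(1), alpha = 0.05)
  expect_true(all(diff(ths) > 0))
  expect_error(bonferroniThreshold(0, 10), "alpha")
})

test_that("background frequencies count positions correctly", {
  m <- rbind(c("A", "K"), c("A", "R"))
  colnames(m) <- c("-2", "-1")
  bg <- backgroundFrequencies(m)
  expect_equal(bg$freqs[["-2"]][["A"]], 1.0)
  expect_equal(bg$freqs[["-1"]][["K"]], 0.5)
  expect_equal(bg$freqs[["-1"]][["R"]], 0.5)
  expect_equal(sum(bg$freqs[["-1"]]), 1)
  one <- backgroundFrequencies(m[1, , drop = FALSE])
  expect_true(all(unlist(one$freqs) %in% c(0, 1)))
  expect_error(backgroundFrequencies(m[0, , drop = FALSE]), "empty")
})

test_that("C-terminal windows translate the right codons", {
  # Met-Lys-Gly-Arg-stop: positions -3 -2 -1 are K G R
  fx <- mkSeqOrfs(list("ATGAAAGGTAGATAA"))
  w <- ctermWindow(fx$annotation, fx$sequences, windowCodons = 3L)
  expect_equal(unname(w[1, ]), c("K", "G", "R"))
  # short ORFs are left-padded with NA
  w7 <- ctermWindow(fx$annotation, fx$sequences, windowCodons = 7L)
  expect_equal(sum(is.na(w7[1, ])), 3)
  expect_equal(unname(w7[1, c("-3", "-1")]), c("K", "R"))
})

test_that("a foreground equal to its background shows no signal", {
  set.seed(1)
  cfg <- simConfig(nOrfs = 120, seed = 17, orfLengthRange = c(150L, 300L))
  ds <- generateAnnotation(cfg)
  win <- ctermWindow(ds$annotation, ds$sequences, windowCodons = 5L)
  bg <- backgroundFrequencies(win)
  res <- positionalLogodds(win, bg)
  expect_false(any(res$significant))
  expect_equal(attr(res, "nTests"), 100)
})

test_that("stop-codon context flags an over-represented C-terminal codon", {
  # background of 50 ORFs with 5 ending AAA (p_bg = 0.1), plus one extra
  # AAA ORF so the 10-ORF foreground can carry k = 6
  endings <- c(rep("AAA", 5), rep(c("GGT", "TGT", "CAA", "GAT", "TCT"), 9))
  cds <- c(paste0("ATG", strrep("GCT", 20), endings, "TAA"),
           paste0("ATG", strrep("GCT", 20), "AAA", "TAA"))
  fx2 <- mkSeqOrfs(as.list(cds))
  ids2 <- fx2$annotation$transcript_id
  aaaIds <- ids2[substring(cds, nchar(cds) - 5, nchar(cds) - 3) == "AAA"]
  fgIds <- c(aaaIds, setdiff(ids2, aaaIds)[1:4])  # n = 10, k(AAA) = 6
  bgIds <- ids2[1:50]                             # p_bg(AAA) = 5/50 = 0.1
  res <- stopCodonContext(fgIds, fx2$annotation, fx2$sequences,
                          backgroundIds = bgIds)
  row <- res[res$codon == "AAA", ]
  expect_equal(row$k, 6)
  expect_equal(row$p_bg, 0.1)
  # exact-tail oracle by direct summation
  pOracle <- .tailGE(6, 10, 0.1)
  expect_equal(row$p, pOracle, tolerance = 1e-12)
  expect_equal(row$s, log10((1 - pOracle) / pOracle), tolerance = 1e-9)
  expect_equal(row$s, 3.833, tolerance = 1e-3)
})

test_that("simulated K/R queuing puts AAA over the context threshold", {
  cfg <- simConfig(nOrfs = 200, seed = 23, orfLengthRange = c(153L, 450L),
                   ctermAaDistribution = local({
                     aa <- riboQueue:::aminoAcids()
                     p <- stats::setNames(rep(0.5 / 19, length(aa)), aa)
                     p[["K"]] <- 0.5
                     p
                   }))
  st <- simTracks(cfg)
  sc <- scoreAll(list(lib = st$tracks), st$dataset$annotation,
                 queuingConfig(minCoverage = 0))
  sel <- zscoreSelect(sc)$orf_id
  expect_gt(length(sel), 5)
  res <- stopCodonContext(sel, st$dataset$annotation, st$dataset$sequences)
  sigUp <- res$codon[res$significant & res$s > 0]
  expect_true(any(c("AAA", "AAG") %in% sigUp))
})

test_that("stop-codon identity association behaves at both extremes", {
  same <- data.frame(Q = rep(c(1, 2, 3), 3),
                     stop_codon = rep(c("TAA", "TAG", "TGA"), each = 3))
  r <- stopIdentityAssociation(same)
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)

  set.seed(42)
  shifted <- data.frame(
    Q = c(rnorm(50, 5), rnorm(50, 5), rnorm(50, 105)),
    stop_codon = rep(c("TAA", "TAG", "TGA"), each = 50))
  expect_lt(stopIdentityAssociation(shifted)$p.value, 0.001)

  expect_error(stopIdentityAssociation(
    data.frame(Q = c(1, 2), stop_codon = c("TAA", "TAG"))), "two stop-codon")
})
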