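---
title: "Quantifying ribosome queuing at stop codons with riboQueue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ribosome queuing at stop codons with riboQueue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboQueue)
```

## The phenomenon and the model

Ribosome profiling reads out the positions of translating ribosomes at
nucleotide resolution: each ribosome protects a short mRNA fragment, and the
5' end of that fragment sits at a fixed, read-length-dependent distance from
the ribosome's P-site codon. When termination or ribosome recycling at a
stop codon is slow, the terminating ribosome occupies the last sense codon
longer than usual and elongating ribosomes queue behind it. Stacked
ribosomes sit one protected-fragment length apart — approximately 30 nt in
yeast — so a queue appears in P-site coverage as up to a few discrete peaks
at stop-anchored positions $-3 - kL$ (the first nucleotide of the P-site
codon of the $k$-th stacked ribosome, $k = 1, 2, 3, \dots$, $L \approx 30$).
Two further observations shape the analysis:

* footprints come in two length classes — short (20–22 nt, A-site vacant)
  and long (28–30 nt, A-site occupied) — and libraries prepared without
  cycloheximide retain both;
* in such libraries the terminating ribosome's own peak at the last sense
  codon is largely lost during preparation, so the queue is detected from
  the *trailing* ribosomes, not from a stop-codon peak.

riboQueue turns this picture into three measurements: a stop-anchored
metagene with a wave-period estimate, a per-ORF queuing metric with
Z-score selection, and positional sequence enrichment over the selected
ORFs, plus readthrough diagnostics as a negative control.

Throughout the package, transcript coordinates are 0-based and half-open,
and stop-anchored position 0 is the first nucleotide of the stop codon.

## The synthetic-data generator

Real queuing datasets are large external downloads, so the package carries
a generative model (`simConfig()`, `generateAnnotation()`,
`simulateFootprints()`) that reproduces exactly the statistical structure
the analysis relies on. Per ORF, the expected P-site intensity is

$$\lambda(x) = 3\,b\,w_{x \bmod 3}
  \;+\; \mathbf{1}[\text{queued}] \sum_{k=1}^{K} A\rho^{k-1}\,
        \delta(x = c_k)
  \;+\; u\,\mathbf{1}[x \in \text{3'UTR}],$$

with $c_k = -3 - kL$ in stop-anchored coordinates, and observed counts are
independent Poisson draws from $\lambda$. The defaults are the conditions
the rest of the package is tested under:

| parameter | default | meaning |
|---|---|---|
| `bodyIntensity` (b) | 5 | expected reads per in-frame codon-start position |
| `frameWeights` (w) | (1/3, 1/3, 1/3) | sub-codon distribution of body reads |
| `queueAmplitude` (A) | 50 (= 10b) | extra reads at the first queue peak |
| `queueDecay` (rho) | 0.7 | amplitude decay per successive ribosome |
| `nQueuePeaks` (K) | 3 | stacked ribosomes modelled |
| `footprintSpacing` (L) | 30 nt | distance between queued P-sites |
| `stopPeakWeight` | 0 | terminating-ribosome peak (lost in CHX-free preps) |
| `queueCterm` | K, R | amino acids whose ORFs are queue-eligible |
| `queuedFraction` | 1 | queue probability for eligible ORFs |
| `utrIntensity` (u) | 0.25 | 3'UTR background per position |
| `pLong` | 0.7 | probability of the long (28–30 nt) read class |
| `orfLengthRange` | 300–1500 nt | coding lengths (multiples of 3) |

Uniform frame weights make the ORF body exactly flat at $b$ per position,
which keeps the expected queuing metric in closed form,
$Q = (3b + A(1+\rho+\rho^2))/b$ under the default peak layout (recorded per
ORF in the ground-truth table). Real libraries show strong sub-codon frame
bias; that is available through `frameWeights` and exercised in the tests,
but it is deliberately not the default because the flat body makes every
downstream expectation analytic. Queue peaks are point masses by default
(`queueJitterSd` adds a discretised Gaussian smear when wanted). Each read
takes a length from the short/long mixture and a 5' start at
`P-site - offset(length)` using the same offset table the processing module
uses, so P-site assignment round-trips a simulated library *exactly* — a
property the test suite asserts.

What the generator does **not** emulate: sequencing errors and adapters,
codon-usage-dependent elongation pauses, expression-level variation between
ORFs (all ORFs share one depth scale), variable UTR lengths, genuine
readthrough translation (3'UTR density is frame-uniform background by
construction), and RNA-Seq companion libraries. Tests passing on synthetic
data therefore establish the correctness of the *computations* under the
stated model, not the biological validity of any threshold on a particular
real dataset.

```{r simulate}
cfg <- simConfig(nOrfs = 60, seed = 7, orfLengthRange = c(300L, 600L))
ds  <- generateAnnotation(cfg)
lib <- simulateFootprints(cfg, ds$annotation, ds$truth)
c(reads = lib$librarySize, dropped = lib$dropped)
```

## Footprint processing

`assignPsites()` places each read's P-site at `start + offset(length)`.
The default offset table (`defaultOffsets()`) uses 12 nt for all lengths
20–32, reflecting the approximately fixed distance between the yeast
ribosome's 5' boundary and its P-site; any two-column TSV can be supplied
instead (`loadOffsets()`), and every track records which table produced it.
Reads with unknown lengths or out-of-transcript P-sites are dropped and
counted, so `assigned + dropped = input` is auditable per library. RPM
normalisation divides by the number of assigned reads; summed over a
library the RPM tracks total one million. Replicates are pooled by summing
counts and library sizes and recomputing RPM from the pooled totals (not by
averaging per-replicate RPM, which would weight replicates equally
regardless of depth). Genome-space alignments can be brought into
transcript space with `projectToTranscript()`, which maps reads fully
contained in a single exon of a single transcript and drops
junction-spanning, intergenic and ambiguous reads with a count.

## Metagene and wave period

`metageneProfile()` averages stop-anchored windows (default $[-120, +60)$,
covering the three expected peaks and the proximal 3'UTR) after dividing
each gene's window by its own mean. Equal-weight per-gene averaging is a
deliberate choice: pooled raw summation would let a handful of
highly expressed genes dominate the profile. A consequence used by the
tests is that the profile's own mean is exactly 1 and the profile is
invariant to any rescaling of the tracks.

`wavePeriod()` reports the median spacing between prominent local maxima in
a search region (default $[-120, -6]$; the stop-proximal zone is excluded
because the terminating peak is absent in the targeted protocols). Three
numerical choices matter:

* the profile is first smoothed with a centred 3 nt (one codon) moving
  average. Sub-codon frame structure and per-position Poisson noise create
  strict local maxima every 3 nt that have nothing to do with queuing;
  averaging over exactly one codon removes them without displacing maxima
  spaced a footprint apart;
* peaks must be strict local maxima with topographic prominence at least
  10% of the smoothed regional maximum (`minProminence`). Plateaus of
  equal smoothed values (compared at 12 significant digits, so summation
  order cannot split them) peak at their centre;
* with fewer than two qualifying peaks the period is *not detected*
  (`NA`), which is a result, not an error — it is the expected outcome for
  wild-type libraries.

```{r metagene}
txLen  <- setNames(ds$annotation$length, ds$annotation$transcript_id)
tracks <- normalizeRpm(assignPsites(lib$alignments,
                                    transcriptLengths = txLen)$tracks)
prof <- metageneProfile(tracks, ds$annotation)
wavePeriod(prof)
```

## The queuing metric

`queuingMetric()` implements
$Q = \sum_{k=1}^{3} \max_{x \in P_k} d(x) \,/\, \mathrm{mean}_{x \in G} d(x)$
with peak windows $P_k$ of half-width 5 nt centred at $c_k = -3 - 30k$
(i.e. $[-38,-28)$, $[-68,-58)$, $[-98,-88)$) and $G$ the union of the gaps
between them plus $[-28, -6)$. The layout is fully configurable
(`peakLayout()` takes the spacing, half-width, and number of peaks) because
peak positions scale with the protected-fragment length of the organism and
protocol. Three properties anchor the scale: $Q = 3$ exactly on any
positive constant track; $Q$ is scale-invariant, so RPM and raw counts
agree; and on the generator's expected intensities $Q$ equals
$(3b + A(1+\rho+\rho^2))/b$, strictly increasing in the queue amplitude.

ORFs enter scoring only if their coding region hosts the 120 nt coverage
window (>= 123 nt with the stop codon) and their window mean reaches
`minCoverage` (default 10 RPM) in **every** condition — the filter is
inclusive (exactly 10.0 passes) and failures carry a reason code naming the
offending condition. When the inter-peak mean is zero, Q is undefined; such
ORFs are flagged and excluded from means and Z-scores rather than patched
with pseudocounts, so a pathological track cannot silently inflate a
condition mean. Z-scores use the sample standard deviation (ddof = 1) on
the raw Q scale per condition, and `zscoreSelect()` keeps ORFs with
$z > 1$: with a heavy-tailed Q distribution this selects the
strongly queued minority while a well-behaved library yields a selection
indistinguishable from noise. The default 10 RPM threshold is calibrated to
real libraries, where a million RPM is spread over thousands of transcripts
with wide expression variation; synthetic libraries spread the same million
over a few hundred uniformly expressed ORFs, so pipeline examples on
simulated data set `minCoverage = 1`.

## Positional enrichment

For the selected ORFs, `ctermWindow()` extracts the amino acids at codon
positions $-w..-1$ before the stop (default $w = 7$), and
`positionalLogodds()` compares each (position, residue) count $k$ of $n$
sequences against its background frequency $p$ with exact binomial tails
(n is at most a few hundred, so no normal approximation is warranted):

$$s = \begin{cases}
  \log_{10}\frac{1-P[\mathrm{Bin}(n,p) \ge k]}{P[\mathrm{Bin}(n,p) \ge k]}
    & k \ge np\\[4pt]
 -\log_{10}\frac{1-P[\mathrm{Bin}(n,p) \le k]}{P[\mathrm{Bin}(n,p) \le k]}
    & k < np
\end{cases}$$

Significance is called at the Bonferroni log-odds line for the whole
family: $\log_{10}((1-\alpha')/\alpha')$ with $\alpha' = \alpha/m$. With
$\alpha = 0.05$ and the default 7-codon window ($m = 20 \times 7 = 140$)
the line sits at 3.45; a 5-codon window ($m = 100$) gives 3.30, and both
widths are supported. The background defaults to the position-specific
frequencies over the coverage-filtered ORF universe — the comparison set
the foreground was selected from — rather than a proteome-wide table,
which the data at hand may not represent. Conventions for degenerate
cases: infinite statistics (a residue absent from the background but
present in the foreground, or tail underflow) are capped at the sentinel
±99 and flagged; a count that exactly matches a *certain* background
(k = 0 with p = 0) carries no evidence and scores 0.

`stopCodonContext()` runs the same machinery at codon level over the 61
sense codons at position −1, where queuing driven by a C-terminal amino
acid surfaces as over-representation of its codons (e.g. AAA for lysine,
AGA/CGN for arginine). `stopIdentityAssociation()` asks the complementary
question — is Q associated with the identity of the stop codon itself? —
with a Kruskal–Wallis test across TAA/TAG/TGA; the rank-based test is used
because Q is heavy-tailed by construction in queued libraries.

```{r bonferroni}
bonferroniThreshold(0.05, 140)
```

## Readthrough diagnostics

A termination defect could in principle reflect increased stop-codon
readthrough. Two per-ORF diagnostics address this without a binary call:
the ratio of mean density in a post-stop window (default $[+3, +63)$,
starting at the first nucleotide after the stop codon; windows are
truncated and flagged on short UTRs) to the 3'-terminal ORF window, and a
chi-square test (2 df) of the three reading-frame totals in the UTR window
against uniformity. Genuine readthrough translation is codon-periodic;
background UTR density is not. The test runs on raw counts (the chi-square
needs counts, not RPM), with frame 0 aligned to the continuation of the
ORF's reading frame.

## Pipeline, provenance and problem sizes

`runPipeline()` chains the stages from one configuration (R list or YAML)
and is deterministic for a fixed configuration: the master seed derives one
seed per simulated library, and every report written by `writeReports()`
carries the package version, a hash of the analysis configuration (the
output directory is excluded from the hash), the seed and the offset-table
provenance, plus a JSON manifest with per-file MD5 checksums. Per-stage
read/drop counts are always logged so that count conservation is auditable
end to end.

The shipped test-suite simulations are sized to make their statistical
checks decisive while staying quick: 200 ORFs for wave-period recovery,
1000 ORFs (coding lengths 153–600 nt) across 10 seeds for the K/R
pattern-recovery contrast, 100 replicate runs of 80 ORFs for the
stop-identity null calibration, and 100 single-ORF runs with ~420 expected
UTR reads for the frame-periodicity null. Fixed seeds make every one of
these runs reproducible.

## Known limitations

* The default P-site offset (12 nt for all lengths) is a serviceable yeast
  approximation, not a calibration; serious use on real data should supply
  offsets derived from start-codon meta-profiles for that dataset.
* The projector handles reads contained in single exons only;
  junction-spanning footprints are dropped (rare for 20–30 nt reads in
  yeast, common in intron-rich genomes).
* The queuing metric presumes the three-peak geometry; layouts with more
  peaks, or spacings pushing windows past −120 nt, require re-deriving the
  window bounds.
* Z-score selection is within-condition; cross-condition differential
  queuing (e.g. mutant-versus-wild-type per ORF) is left to downstream
  modelling of the score tables.
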