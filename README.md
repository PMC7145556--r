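# riboQueue

Detect and quantify **ribosome queuing upstream of stop codons** in ribosome
profiling (Ribo-Seq) data.

When translation termination or ribosome recycling slows down, the
terminating ribosome lingers on the last sense codon and elongating
ribosomes stack up behind it. Because each ribosome protects roughly one
footprint length of mRNA (~30 nt in yeast), this stacking leaves a
characteristic fingerprint in P-site coverage: periodic "waves" of density
preceding the stop codon, spaced one protected-fragment length apart, and
strongest on ORFs whose last sense codon encodes a positively charged
residue (lysine or arginine). riboQueue is for anyone who wants to score
that fingerprint per ORF, compare it across strains or conditions, and ask
which C-terminal sequences drive it.

## The core statistic

For each ORF the **C-terminal ribosome queuing metric** is

```
         max RPM in P1 + max RPM in P2 + max RPM in P3
    Q = ------------------------------------------------
              mean RPM over the inter-peak gaps
```

where `P1, P2, P3` are stop-anchored windows centred on the expected P-site
codon starts of the first three stacked ribosomes (`-3 - k*30` nt for
k = 1, 2, 3; windows `[-38,-28)`, `[-68,-58)`, `[-98,-88)` by default) and
the gaps are the intervals between them (the stop-proximal zone `[-6, 0)` is
excluded). On a flat positive track Q is exactly 3; Q is invariant to
library rescaling. ORFs are kept when their 3'-terminal 120 nt window holds
at least 10 RPM mean coverage in every condition; high-queuing ORFs are
selected at Z > 1 (sample standard deviation), and their C-terminal windows
are tested for positional amino-acid over-representation with exact binomial
tails on the signed log10-odds scale, against a Bonferroni line of
`log10((1 - a/m)/(a/m))` (3.45 for a = 0.05 over m = 140 position-residue
tests).

Around the metric the package provides: P-site assignment with
read-length-specific offsets, RPM normalisation and replicate pooling, a
genome-to-transcript projector for GFF3-annotated genomes, stop-anchored
metagene profiles with wave-period estimation, stop-codon context and
identity tests, 3'UTR readthrough diagnostics (density ratio + reading-frame
periodicity), and a fully seeded synthetic footprint generator so the whole
chain is testable offline.

## Worked example

A complete wild-type versus termination-defective comparison on synthetic
data (300 shared ORFs, two replicates per condition; the mutant carries
queue peaks on K/R-ending ORFs at 10x body intensity):

```r
library(riboQueue)

cfg <- defaultPipelineConfig(seed = 42, nOrfs = 300)
cfg$conditions <- list(wt    = list(replicates = 2L, queueAmplitude = 0),
                       new1d = list(replicates = 2L))
cfg$queue$minCoverage <- 1   # synthetic libraries spread 1e6 RPM over 300 ORFs
bundle <- runPipeline(cfg)
```

which logs, among other lines:

```
[riboQueue] metagene: wt: 300 genes, wave period not detected
[riboQueue] metagene: new1d: 300 genes, wave period 30 nt
[riboQueue] queue: 300 ORFs pass the coverage filter; mean Q: wt=4.59, new1d=6.27
[riboQueue] enrich: new1d: 25 selected ORFs, 2 significant position/residue pairs
[riboQueue] enrich: wt: 54 selected ORFs, 0 significant position/residue pairs
```

The mutant metagene shows the 30 nt wave period (the control does not), its
mean queuing metric is raised with a heavy tail (6.27 vs 4.59; a flat
library would give ~3 plus Poisson max-bias), and the enrichment table
pinpoints what drives the tail:

```r
e <- bundle$enrichment$new1d
head(e[order(-e$s), c("position", "residue", "k", "n", "p_bg", "s", "significant")], 2)
#     position residue  k  n       p_bg         s significant
# 135       -1       R 15 25 0.05000000 13.209380        TRUE
# 129       -1       K 10 25 0.03333333  8.456911        TRUE
```

Only lysine and arginine at position -1 (the last sense codon) clear the
3.45 log-odds line; nothing is significant in the wild-type arm. The
stop-codon identity test is null (`bundle$stopIdentity$new1d$p.value` =
0.52), and mean 3'UTR/ORF density ratios stay at the background level
(~0.05) in both arms -- queuing without readthrough.

## Documentation

The methods vignette (`vignettes/ribosome-queuing.Rmd`) describes the
generative model behind the simulator, every tunable threshold with its
default and rationale, the numerical conventions (peak plateaus, degenerate
backgrounds, undefined Q), and what passing the synthetic-data suite does
and does not establish about real libraries.
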