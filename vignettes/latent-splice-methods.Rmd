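---
title: "Methods: latent 5' splice-site annotation and activation calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: latent 5' splice-site annotation and activation calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records the models, conventions and design decisions behind
`latsplice` — the reasoning a maintainer would need, in one place.

## The problem

Intronic sequences resembling the 5' splice-donor consensus are abundant but
silent under normal growth. Using one would extend the upstream exon into the
intron; for the large class of *latent* donors (LSSs) that extension contains
an in-frame STOP codon, so the resulting mRNA carries a premature termination
codon (PTC). A nuclear quality-control activity — suppression of splicing —
is thought to silence precisely this class. The computational question has
two halves: annotate all candidate donors genome-wide and classify them by
PTC consequence, and then decide from case/control RNA-seq which of them were
*activated* when a suppressing factor was depleted, with statistics that
separate the PTC-linked signal from experimental stress.

## Donor sequence model

A donor site is represented by its 9-mer: the last 3 exonic and first 6
intronic nucleotides, with the invariant GT at intronic positions +1/+2. The
scoring model is the maximum-entropy family: the distribution `p*` over all
4^9 9-mers that minimises KL divergence to a background `q` (uniform by
default) subject to matching the training data's marginal distributions on a
list of position subsets. The default constraint sets are all singletons and
all adjacent pairs — low-order marginals carry most of the donor signal,
including nearest-neighbour dependencies a PWM misses, while remaining
estimable from modest training sets. A site scores
`log2(p*(s) / q(s))`: 0 means "no more donor-like than background", and
scores are unbounded below (a zero-probability 9-mer scores `-Inf`, which
fails every finite threshold). With singleton constraints only, the maxent
model factorises and reproduces the PWM exactly (`fit_pwm()` is the explicit
baseline implementation).

**Fitting.** `fit_maxent()` uses iterative proportional scaling: each step
rescales the current distribution so one constrained marginal matches its
target exactly, cycling over constraints until the largest discrepancy falls
below `tol` (default 1e-6, capped at `max_iter` sweeps with a warning on
non-convergence — never silent). For the default chain of adjacent-pair
constraints this converges in a couple of sweeps because the constraint
hypergraph is decomposable.

**Smoothing.** Zero marginal cells would make constraints unsatisfiable by
any positive distribution, so a pseudocount (default 0.5) is applied — as a
uniform smoothing of the *joint* distribution scaled so each cell of the
finest constrained marginal table receives exactly the pseudocount, with
coarser marginals inheriting the equivalent smoothing. The per-table
alternative (adding 0.5 independently to every marginal table) looks natural
but makes overlapping targets mutually inconsistent — the singleton marginals
implied by the smoothed pair tables differ from the separately smoothed
singleton targets — so *no* distribution satisfies all constraints and no
fitter can reach tolerance. Consistent joint smoothing keeps the problem
exactly solvable and reduces to the obvious behaviour when all constraint
sets have one resolution. Tests verify the fit against an independent
dual-space numerical optimiser (BFGS on the feature weights) at KL < 1e-6.

**Thresholds.** The catalog threshold is 0 in log2-odds units, *inclusive*
(score ≥ 0 passes). The inclusive reading was chosen because the threshold's
purpose is permissive annotation — it excludes the bulk of intronic GTs while
retaining nearly all annotated donors — and strictness at the boundary is a
coin-flip either way, so it is exposed as `score_threshold(value,
inclusive)`. A stringent alternative around 6.77 (retaining roughly the
strongest 80% of annotated donors) is expressible the same way.

## Candidate catalog

Coordinates are 0-based half-open internally; GTF input/output is 1-based
inclusive; BED-like output is 0-based half-open. Candidate enumeration walks
every *within-CDS* intron — the gap between adjacent CDS-bearing exons whose
CDS reaches the splice junction on both sides — on the transcript sense
strand (minus-strand introns are scanned on the reverse complement). Every GT
with extension length 1–1000 nt and residual intron ≥ 20 nt is a candidate
unless its donor position is an annotated donor in *any* supplied annotation
(the annotated-donor set is the union over all input GTFs, including
non-coding multi-exon transcripts).

**Classification.** The extension is translated in the frame continued from
the upstream exon: the frame offset is the cumulative CDS length modulo 3 at
the exon end, so the first codon may span the old exon/intron junction. A
STOP counts if its codon has at least one base in the extension and ends
before the GT; a codon that would run past the GT never counts. This is the
most literal reading of "an in-frame STOP upstream of the latent donor" for
junction-spanning codons, and it is centralised in `has_inframe_stop()` so an
alternative rule would be one function swap. Classes partition the
candidates: `LSS` ⇔ in-frame STOP; otherwise `adSS_3n` (extension ≡ 0 mod 3)
or `adSS_fs` (frameshifting).

**Deduplication.** Sites are keyed by (chromosome, strand, GT position,
parent 5'SS); a site reachable from several transcripts is one record listing
all transcript ids. When transcripts disagree on the reading frame at a
shared site, the longest-CDS transcript wins (deterministic tie-break; the
disagreement is reported via `message()`).

The whole catalog path is validated site-for-site against an independent
brute-force oracle (regex GT scan plus naive translation, no shared code) on
20 random toy genomes, and is invariant under reverse-complementing the
genome with flipped annotation strands.

## Junctions, usage and profiles

A split read's `N` CIGAR operation defines a junction as the 0-based
half-open gap `[donor, acceptor)`: `donor` is the first intronic base and
`acceptor` the first base after the gap. Junctions are keyed by exact gap
coordinates — no fuzzy merging, since latent-site detection depends on exact
donor positions. Secondary, supplementary and unmapped alignments are
skipped; `total_mapped` counts primary mapped reads and is used only for
cross-sample tallies (reads per million), never for usage ratios. Junction
strand is inferred from the annotation at the gap ends (either end may be an
annotated donor or acceptor; latent junctions share the annotated acceptor).

Normalised latent usage is `#split-reads_LSS / #split-reads_5'SS`. A zero
canonical count makes usage *undefined*, not zero — such records are excluded
rather than pseudocounted, because every downstream criterion requires
canonical support anyway.

Coverage profiles over the exon-extension region come from bedGraph
intervals; the per-sample normalisation factor is the annotated-donor
split-read count (floored at one read-equivalent to keep folds defined).

## Activation calling

For 2 case + 2 control replicates, paired by replicate index:

* **Initial criteria** — some replicate (either may play the primary role)
  has ≥ 4 latent reads and usage fold ≥ 1.5 over its paired control, and the
  other has ≥ 1 latent read and any increase (fold > 1, strictly). A control
  usage of 0 with positive case usage yields fold `+Inf`, satisfying any fold
  condition — "any increase" must be satisfiable from zero.
* **Stringent criteria** — ≥ 4 reads and ≥ 1.5-fold in *both* replicates;
  stringent ⇒ initial by construction, and the suite asserts it.
* **Profile check** — evaluated only for sites passing the read criteria:
  raw coverage ≥ 1 at 100% of extension positions in each case replicate
  ("present throughout"), and normalised case coverage strictly higher than
  the paired control's at ≥ 95% of positions ("consistently higher").
  The 100% / 95% quantifications are deliberate strictness choices for vague
  words; both are `activation_config()` parameters.
* **Ranking** — per-replicate one-sided Fisher's exact tests on
  `[[lss_case, canonical_case], [lss_control, canonical_control]]`, combined
  by Fisher's method (−2Σln p against χ² with 2k = 4 df); fold reported as
  the geometric mean over replicates. Ranking is reporting, not thresholding:
  no multiple-testing correction is applied across sites.
* **Label switching** — the identical pipeline with case/control labels
  exchanged; switching twice is the identity. Calls under switched labels
  estimate the stress/technical background.

The composite profile aggregates per-site coverage folds (case over control,
replicate-averaged, control depth floored at 1 read-equivalent): the
point-wise median across sites with an order-statistic 95% confidence band
(binomial bounds on the order statistics; for very small n the band widens to
the sample range and a single site is flagged as degenerate — an exact 95%
band does not exist below n = 6), plus a standardised representation
averaging each site's fold within 100 equal-width bins along its extension.

## Class-bias and enrichment statistics

`fisher_one_sided()` computes the exact hypergeometric upper tail (inclusive)
that the first row of a 2×2 table is enriched in the first column; callers
order rows so that the alternative of interest is "first row under true
labels". It is checked against exhaustive enumeration for every table with
N ≤ 40. `class_bias()` applies it to call counts of two site classes under
true and switched labels: preferential true-label activation of the
PTC-introducing classes (LSS, adSS_fs) relative to the PTC-free adSS_3n
baseline is the signature of a PTC-directed mechanism rather than stress.
Gene-set over-representation uses the inclusive hypergeometric upper tail
within an explicit, caller-supplied universe (the universe is a genuine
analysis decision, not a default), with Bonferroni at the collection level
and across all supplied collections. Spearman correlation uses midranks and
the large-sample t approximation.

## Synthetic data: what it emulates, and what it does not

`generate_reference()` builds a toy genome of single-transcript multi-exon
coding genes (one chromosome per gene, alternating strands), with annotated
donors sampled from a consensus-like donor distribution and planted candidate
sites of all three classes. Planted 9-mers are rejection-sampled (capped at
10,000 attempts) into a target score window, decoupling score control from
model internals; LSS extensions receive an in-frame TAA, adSS extensions are
built STOP-free with the class-appropriate length modulo 3. With
`background_gt = FALSE` the intronic background is GT-free, so the catalog
contains *exactly* the planted sites — the configuration used when a test
needs a closed-world truth; the default allows chance GTs, as real introns
do.

`simulate_experiment()` draws, per intron, an expression level from a gamma
distribution shared across samples and per-sample canonical counts as
Poisson around it — marginally negative binomial with the requested mean
(200) and dispersion (0.15), while biological replicates stay correlated as
in real RNA-seq (independent NB draws per sample would make paired
normalisation factors differ by tens of percent, an artifact real designs do
not show). Latent counts are Poisson with mean `expression × usage`, usage
being 1% of canonical at baseline, times the effect fold (5) in case samples
at activated sites, times a log-normal replicate jitter (sd 0.1). Extension
coverage is a read pileup: a Poisson number of 50-nt reads tiled uniformly so
the expected per-base depth equals the latent junction count — piecewise
constant and autocorrelated like real coverage. Position-independent noise
per segment was rejected: it produces unphysical per-position spikes that
make the "consistently higher at ≥ 95% of positions" criterion reject
genuinely activated sites.

The generator does **not** emulate: sequencing error or quality scores,
paired-end fragment geometry, multi-isoform genes (one transcript per gene),
alternative acceptors for one latent donor, GC or positional coverage bias,
or expression changes of the depleted factor itself. Passing tests therefore
demonstrate the pipeline's logic and statistics under a faithful count model,
not robustness to alignment artifacts or annotation errors in real data.

## Problem sizes and verification regime

The test suite and `scripts/acceptance.R` use: 20 toy genomes (3 genes each)
for catalog/brute-force parity; constraint configurations at k ≤ 4 for the
maxent/dual-optimiser comparison; all 2×2 tables with N ≤ 40 for the Fisher
enumeration; 20 seeds × (10 genes, 10 planted LSSs of which 8 activated) for
planted-truth recovery; and 50 seeds at effect fold 1 for null label-parity.
The recovery property is evaluated in the regime it claims — activated sites
whose realized data show ≥ 10 latent reads in both case replicates, canonical
support ≥ 100 in all samples, and usage fold ≥ 3 in both replicates. With a
baseline usage of 1% and canonical mean 200, expected case support sits at
the 10-read boundary, so roughly half the planted sites fall outside that
regime by Poisson realization; sites below it are genuinely borderline
(realized folds near 1 are common when control counts of ~2 fluctuate) and
their recovery is not claimed.

## Known limitations

* The donor model is trained on the package's own consensus sampler by
  default; scores are interface-compatible with published maximum-entropy
  donor scores but not numerically identical to any published score table.
* Frame disagreements between transcripts are resolved by CDS length, which
  is deterministic but arbitrary when lengths tie.
* One latent donor joining multiple acceptors is reported per junction, not
  deconvolved per isoform.
* The profile criteria quantify "throughout" and "consistently" as 100% and
  95% of positions; other readings are configuration, not code, but no
  empirical calibration against deep real data is attempted here.
* `call_activated()` is defined for the 2+2 design; `replicates_override`
  exists for other designs but the criteria then only use the first two
  replicates per condition.
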