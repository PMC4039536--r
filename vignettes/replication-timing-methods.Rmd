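---
title: "Models and methods behind repliscape"
author: "repliscape maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind repliscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repliscape)
set_log_level(0)
```

# The measurement and the question

Budding yeast fires a few hundred replication origins with reproducible
timing. BrdU-IP-Seq marks nascent DNA: cells synchronized in G1 are released
into S-phase in the presence of the thymidine analogue BrdU, newly
synthesized DNA is immunoprecipitated and sequenced, and coverage marks the
regions that replicated before harvest. Two experimental designs are
supported:

* **Hydroxyurea (HU) arrest.** HU depletes dNTPs, stalling S-phase shortly
  after the earliest origins fire while the intra-S checkpoint blocks the
  rest. BrdU signal at an origin therefore reads out whether the origin
  fires *early*; signal is inversely related to the origin's characteristic
  replication time T~Rep~.
* **Timepoint harvests.** Cells progressing through an unperturbed S-phase
  are harvested at fixed times (25 and 35 min after release), giving a
  direct temporal profile.

The scientific question the pipeline addresses is how a regulator (here
Rif1) reshapes this program: which origins gain signal when the regulator is
deleted (normally repressed by it), which lose signal, and which are
untouched — and how those classes distribute along chromosomes relative to
centromeres, telomeres and protein binding sites.

# Signal model of the synthetic generator

Simulated data come from a population-level model of origin firing. Each
origin *o* fires at a Normal(μ~o~, σ) time; forks move at speed *v* in both
directions. A position *x* is replicated by harvest time t~h~ in the
fraction of cells

$$ f_o(x) = \Phi\!\left(\frac{t_h - |x - \mathrm{mid}(o)|/v - \mu_o}{\sigma}\right) $$

and origins combine independently (a position is replicated if *any* origin
got there — passive replication of dormant origins falls out of this
naturally):

$$ f(x) = 1 - \prod_o \bigl(1 - f_o(x)\bigr). $$

A uniform non-specific background β (0.05 fragments per kb-equivalent,
about 5% of a typical library) is added, and a library of fixed depth is
drawn multinomially from the resulting density, start positions uniform
within the drawn 50 bp bin and fragments extending 250 bp.

The truncation of firing times at zero is immaterial at the defaults
(μ ≥ 10 min, σ = 4 min: Φ(−2.5) ≈ 0.006) and the plain Gaussian form above
is used exactly; with σ = 0 the profile degenerates to an exact step of
radius v·(t~h~ − μ), boundary included.

`rif1Δ` is modeled by a single parameter: a designated subset of late
origins fires Δ = 20 min earlier. Nothing else changes, so any
difference the pipeline reports at other origins is by construction an
artifact of measurement or analysis — which is what makes the generator a
useful null instrument.

## Default study conditions

| parameter | default | meaning |
|---|---|---|
| genome | 4 × 500 kb | equal chromosomes, one 120 bp centromere each |
| origins | 40, ≥ 20 kb apart | allocated to chromosomes by length |
| μ~early~ / μ~late~ | 10 / 35 min | two timing classes, half early |
| regulated fraction | 0.7 of late origins | the Rif1-repressed truth set |
| Δ | 20 min | advance of regulated origins in the mutant |
| σ | 4 min | firing-time dispersion |
| v | 1500 bp/min (S-phase), 150 bp/min (HU) | fork speed |
| t~h~ | 25 or 35 min (timepoints); 25 program-min (HU) | harvest |
| depth | 2 × 10^5^ fragments × 2 replicates | per strain |

Two modeling choices deserve explanation.

**HU time runs on the replication-program clock.** A 45 min wall-clock HU
arrest does not correspond to 45 min of replication progression: dNTP
depletion slows forks roughly tenfold and the checkpoint (active within
~30 min of release) keeps late origins from firing at all. Rather than
simulate checkpoint signaling, the HU regime represents the arrest as a
harvest at 25 *program*-minutes with slow forks (150 bp/min). With
μ~late~ = 35 this leaves late origins essentially unfired in wild type
(Φ((25−35)/4) ≈ 0.006) while advanced origins in the mutant (μ = 15) fire
almost fully (Φ(2.5) ≈ 0.994) — the qualitative HU phenotype that makes the
assay informative. Fork speeds in HU of 100–300 bp/min and unperturbed
speeds of 1–2 kb/min are conventional values for budding yeast; neither is
asserted by any test beyond the qualitative behavior.

**What the generator does not emulate.** Real BrdU-IP data have
locus-specific IP efficiency, mappability and copy-number artifacts
(rDNA, telomeric repeats), checkpoint-dependent fork slowing gradients, and
competition for limiting initiation factors, which couples origins: firing
extra origins in the mutant genuinely lowers early-origin efficiency. The
generator's origins are independent, so its truth contains *no*
"Rif1-activated" origins; in real data that class is expected and partly
reflects exactly this competition. Passing the parameter-recovery tests
therefore shows the analysis is calibrated for the direct effect, not that
real activated calls are artifacts.

# The analysis chain

## Coverage tracks

Fragments are midpoint-assigned to 50 bp non-overlapping bins (midpoint
assignment conserves the fragment count exactly and never double-counts;
binning by start, midpoint or full overlap is a convention choice, and
midpoint is the one documented here). Tracks are median-smoothed over
a 1 kb window. 1 kb over 50 bp bins is an even 20 bins; the symmetric
21-bin window is used so the smoother is centered and unbiased. At
chromosome ends the window is truncated (shrinks) rather than padded — no
signal is invented at telomeres, where much of the biology lives. Replicate
tracks are quantile-normalized (within a strain only), averaged, and
smoothed again. Ties in quantile normalization — guaranteed by count data —
receive the mean of the reference values across the tied rank span.

## Peak calling

Enrichment is tested on *raw pooled counts* (the Poisson model needs
counts; smoothing and normalization would distort it). Every bin's centered
1 kb window is scored with a stably computed Poisson upper tail against
λ~local~, the maximum of the genome-wide mean rate and the rates in 5 kb
and 10 kb windows centered on the bin — the conservative local-background
idea of the standard enrichment callers. Significant bins (p < 0.01, no
multiple-testing correction at this stage) are merged across gaps up to
500 bp. Peaks are then cross-referenced against the origin annotation: an
origin is *called* when any peak shares at least 1 bp with the 1 kb window
centered on its midpoint (half-open intervals; abutting windows do not
overlap). Replicates are pooled by summation for calling — pooling is more sensitive
than intersecting per-replicate calls and is the documented choice.

A consequence of the max-local-λ background worth knowing: enrichment
domains wider than the background windows are self-masking. Under HU,
fork-bounded BrdU tracks are a few kb wide and the caller is sensitive; in
mid-S-phase data, replicated domains span tens of kb and this caller is not
the right tool (the timepoint analyses here use metaprofiles, not peaks).

## Differential classification

Called origins from both strains are merged and counted: fragment midpoints
in the 1 kb origin windows, per strain and replicate.

*Normalization.* BrdU-IP libraries are compositional. When the mutant
fires many extra origins at fixed sequencing depth, every unchanged locus's
share of the library shrinks (here by ~40%), so normalizing by total
fragment counts would report every unchanged origin as "lower in the
mutant" — a large, significant, and entirely artifactual fold change at
well-covered origins. The pipeline instead estimates an *effective* library
size from the genome-wide background rate: the masked mean of total counts
in non-overlapping 5 kb windows (median pilot, then the mean of windows
below pilot + 3√pilot, iterated), which sits on the unreplicated majority
of the genome and is invariant to how many origins fire. The estimator runs
at the precision floor set by the ~10^4^ background fragments per library
(~1% relative), and its estimated relative variance is propagated into the
test as additional dispersion (below). Robust-ratio normalizations (TMM,
median-of-ratios) were deliberately not used: they anchor on the majority
of *tested windows*, and in this assay a majority of origins can genuinely
change.

*Test.* With two replicates per strain, per-origin dispersion is
unestimable; a single common NB dispersion is estimated by method of
moments on normalized counts, φ = median over origin × strain pairs of
max((s² − m)/m², 0). (At n = 2 this estimator is biased low roughly
twofold — the median of a χ²₁-scaled variance — which is acceptable here
because the simulated counts are near-Poisson and the estimator is a guard,
not an inference target.) The anchor's relative variance is added to φ. Each
origin is then tested with a two-sided exact conditional test: counts are
scaled to the common effective library size and pooled per strain; under
the null, the wild-type pooled count given the two-strain total follows a
distribution free of the unknown mean — a binomial split when φ = 0, a
negative-hypergeometric split (per-strain sizes n/φ) when φ > 0. The
two-sided p sums all splits at most as probable as the observed one, so
p ∈ (0, 1] and an all-zero origin gives p = 1. Benjamini–Hochberg step-up
q-values at q < 0.05 with the sign of the normalized log2 fold change
(pseudocount 0.5) give the three classes: **Rif1-repressed** (higher in the
mutant), **Rif1-activated** (lower), **Rif1-unregulated** (everything
else). Positive fold change means higher in the mutant; the class names
invert the sign, which is why it is stated explicitly.

At the default conditions the residual misclassification of
truth-unregulated origins is dominated by the shared anchor noise: usually
0, occasionally 1–2 of 26 origins across seeds. This is the calibrated
price of normalizing a compositional assay from its own background.

## Landscape statistics

Origins with known T~Rep~ are ranked (ties broken by name) and split into
four contiguous quartiles, sizes differing by at most one with extras going
to the earlier quartiles (the origin count is rarely divisible by four).
Metaprofiles average track values at fixed bin offsets around origin
midpoints over a 40 kb (temporal) or 5 kb (HU) window; offsets beyond a
chromosome end simply contribute nothing, with the per-offset n
decremented.

For cross-strain metaprofile comparison, each strain's track is scaled by
its *fully-replicated plateau level* (the 98th percentile of bin values):
the cores of the earliest origins are replicated in essentially every cell
in every regime, so the plateau is a per-cell unit shared by the strains.
(Equalizing genome-wide sums would be confounded by the number of active
origins; the background rate used for differential normalization is the
better anchor under HU but is unreliable in mid-S-phase tracks, where most
of the genome is partially replicated and clean background windows are
scarce.) After scaling, profile units read approximately as the fraction
of cells that have replicated each position.

Distances use the edge-gap convention of the standard interval tools:
0 for overlapping intervals, otherwise the gap between nearest edges,
never across chromosomes. Centromere/telomere proximity takes the origin
*midpoint* (as a 1 bp interval) against the centromere interval or the
terminal base pair of the chromosome; "within 20 kb" means ≤ 20000 bp
inclusive. Telomeres are chromosome-end coordinates, not subtelomeric
element boundaries, since no element annotation is assumed. Per-class mean
centromere distances exclude pericentric and subtelomeric origins first
(they would skew the means) and class pairs are compared with Welch
two-sided t-tests (identical constant samples give p = 1 by convention;
classes with fewer than two members are flagged and skipped). Binding-site
overlap expands ORF sites to their full coordinates and intergenic sites
to the 1 kb nearest the naming gene (the reader requires a `gene_side`
column saying which end that is), then counts origins whose 1 kb midpoint
window shares ≥ 1 bp with any site window.

# Numerical choices and degenerate inputs

* Poisson upper tails are computed in log space (lower-tail complement when
  k ≤ λ + 1, direct term accumulation otherwise) and agree with direct
  summation to 10^−12^ relative; tails below ~10^−300^ underflow to 0, as
  they must in double precision.
* The sliding median uses the C implementation for interior windows and
  recomputes the truncated windows at the ends explicitly.
* Quantile normalization resolves within-track ties by averaging the
  reference values over the tied rank span.
* All-zero origins in the differential test return p = 1; an all-zero track
  yields no peaks rather than an error; empty fragment files parse to empty
  sets.
* All randomness flows from explicit integer seeds through a local RNG
  scope that restores the caller's RNG state; replicate seeds are derived
  deterministically from the master seed.

# Problem sizes

The packaged study conditions — a 2 Mb genome, 40 origins, 2 × 10^5^
fragments per library, two replicates per strain — were chosen so that a
full simulate–track–call–classify–profile cycle completes in seconds while
every statistical regime of the method (saturated early origins, silent
late origins, partially fired advanced origins, background-dominated
windows) is populated with comfortable margins. The same code runs
unchanged on the real 12 Mb genome with hundreds of origins; the R64
chromosome and centromere coordinates ship with the package
(`system.file("extdata", ...)`).

# Known limitations

* The common-dispersion exact test is the package's own differential-binding
  engine; its correctness standard is parameter recovery on simulated truth,
  not numerical identity with any particular external package.
* Background-anchored normalization requires a genuine unreplicated
  background; it degrades if background coverage is very sparse (the code
  falls back to total counts with a log message) or if most of the genome
  is replicated.
* The peak caller is built for HU-style narrow enrichment, not broad
  mid-S domains (see above).
* The generator's independent-origin assumption omits factor competition,
  checkpoint gradients and locus-specific IP artifacts; see the synthetic
  data section for what recovery results do and do not show about real
  data.
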