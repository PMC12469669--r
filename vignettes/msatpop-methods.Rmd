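---
title: "Microsatellite population genetics with msatpop: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microsatellite population genetics with msatpop: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msatpop)
```

msatpop analyses codominant diploid microsatellite genotypes scored from
gel band sizes, the data produced by PAGE genotyping of tandem-repeat
markers in livestock diversity surveys. This vignette is the package's own
account of the statistical machinery: the estimators, their assumptions,
the tunable parameters, and the choices made where the methodology was
genuinely open. The motivating application is a survey of seven rabbit
breeds — four Egyptian natives (BB, WB, RB, JAB) and three exotics (NZW,
AR, CH) with 127/40/40/112/87/60/60 individuals — genotyped at 14
microsatellite loci; the raw genotypes of that survey are not public, so
the package pairs every estimator with a seeded simulator that reproduces
the survey's design.

## Data model

A genotype table is a plain tibble with one row per individual × locus
call: `individual`, `population`, `locus`, `allele_a`, `allele_b`. Alleles
are integer fragment sizes in base pairs. Genotypes are unphased, so calls
are stored canonically with `allele_a <= allele_b`; a missing call has both
alleles `NA`, never one. Two interchange formats are supported: a wide CSV
(`individual,population,<locus>,...` with `A/B` cells, empty = missing) and
GenePop with 2- or 3-digit allele coding (`0` = missing; 3-digit coding is
written on export). Allele identity is the integer bp size after binning;
no repeat-unit normalisation is attempted because motif lengths are
generally not known per locus. Population labels are taken verbatim from
the input — no inference.

Frequencies (`allele_freqs()`) count each typed individual as two genes;
cells with no typed individuals have no spectrum and downstream tables
show them as undefined (`NA`, rendered `-` in the pipeline's TSV output)
rather than zero — sparse breed × locus cells are a fact of gel data after
failed amplifications.

## Gel sizing and allele binning

Fragment sizes are calibrated against a DNA ladder with the conventional
log-linear model, `log10(size) = a·migration + b`, fitted by ordinary least
squares (`fit_sizing_curve()`). The fit's R² is the quality-control
statistic; a warning (never an error) is raised below 0.99, the usual bar
for accepting a gel's sizing. Migration units are arbitrary but must be
consistent; pixel-level image processing is out of scope — the package
starts from band migration measurements.

Raw sizes are binned into allele classes (`bin_alleles()`) by
single-linkage chaining: neighbouring sizes whose gap is *strictly* below
the tolerance (default 2 bp, typical PAGE resolution) join one chain, and
any chain spanning the tolerance or more is split recursively at its
largest internal gap, so class boundaries fall at the sparsest points of
the size distribution and no class ever spans the tolerance. The strict
inequality matters: dinucleotide-style markers place true alleles exactly
2 bp apart, and a `<=` rule would fuse clean neighbouring alleles. Classes
are labelled with their rounded mean size. Scoring follows the standard
codominant rule: one band is a homozygote, two distinct bands a
heterozygote; two bands that bin to the same class collapse to a
homozygote with a warning (mirroring manual resolution of faint double
bands) and more than two bands is an error under the diploid model.

## Diversity statistics

Per population × locus, with `p_i` the sample allele frequencies over
`n` genes:

* observed allele count `No`, effective allele count `Ne = 1/Σp_i²`
  (`1 ≤ Ne ≤ No`, equality iff equifrequent);
* observed heterozygosity `Ho`, the typed-individual heterozygote
  fraction;
* expected heterozygosity `He = 1 − Σp_i²`, by default with Nei's
  small-sample correction `n/(n−1)` because breed samples as small as
  n = 40 individuals are typical (the uncorrected form is a flag away,
  since reference surveys rarely state their estimator);
* Botstein's polymorphic information content
  `PIC = 1 − Σp_i² − Σ_{i<j} 2 p_i² p_j²`, with the conventional reading
  of >0.50 as highly and 0.25–0.50 as moderately informative;
* the per-locus inbreeding coefficient `F = 1 − Ho/He`, undefined at
  monomorphic loci. Negative `F` indicates heterozygote excess.

Breed summaries average each statistic over loci and report the standard
error as the n−1 sample standard deviation over loci divided by √loci.
Breed-level `F` is the mean of per-locus `1 − Ho/He` over polymorphic loci;
because published tables are sometimes internally inconsistent here (a
reported breed `F` can be irreconcilable with its own printed `Ho` and
`He`, whose ratio convention is then unrecoverable), the ratio-of-means
alternative `1 − mean(Ho)/mean(He)` is reported alongside rather than
guessed at.

## Hierarchical F-statistics and gene flow

`locus_fstats()` uses Nei's gene-diversity decomposition: `HI` is the
weighted mean observed heterozygosity across populations, `HS` the
weighted mean within-population gene diversity (uncorrected `1 − Σp²`,
as the decomposition requires), and `HT` the gene diversity of the
weighted pooled frequencies. Then `FIS = 1 − HI/HS`, `FST = 1 − HS/HT`,
`FIT = 1 − HI/HT`, so Wright's identity `(1−FIS)(1−FST) = (1−FIT)` holds
exactly by construction and `FST` cannot go negative. This estimator was
chosen over Weir–Cockerham variance components because reported F-statistic
tables in this literature typically obey the Wright identity within print
rounding — the signature of a gene-diversity decomposition; a
Weir–Cockerham `theta` is available via `estimator = "wc"` for sensitivity
(it can go negative and does not satisfy the identity exactly).
Populations are weighted by typed sample size by default — breed samples
of 40 to 127 are too unequal to ignore — with equal weighting as the
sensitivity option.

Degenerate cases are reported, not hidden: `HT = 0` (locus monomorphic
overall) leaves FST undefined; `HS = 0` with `HT > 0` (populations fixed
for different alleles) gives `FST = 1` with FIS undefined.

Gene flow uses Wright's island-model transform `Nm = (1 − FST)/(4·FST)`.
The transform diverges as FST → 0, so `gene_flow()` suppresses estimates
at `FST ≤ 0.005` (reporting the raw value in a message), the same
convention that makes reference tables print a dash at near-zero-FST
loci. Summaries attach the conventional differentiation label (high above
FST = 0.15).

## Ewens–Watterson neutrality

For each population × locus cell the observed sample homozygosity
`F = Σp̂_i²` is compared with its null distribution under the Ewens
sampling formula conditioned on the number of genes `n` and observed
alleles `k` — the classical homozygosity test of neutrality, the natural
choice for multi-allelic markers where site-frequency tests do not apply.
The reported deviate is `D = (E[F_null] − F_obs)/sd[F_null]`, oriented so
allele-rich, even spectra score positive (large breeds without a selection
history typically sit there); `sign = -1` flips the convention. Cells with
`k = 1`, or whose conditional null has a single configuration (`sd = 0`),
are undefined. Breed means average the defined deviates; note that some
published tables report breed means that are *not* the arithmetic mean of
their printed per-locus deviates — only internally consistent columns can
be used for validation.

Three evaluation routes are provided:

* **Closed-form exact moments** (default). Conditioned on `(n, k)` the
  ESF is exactly the cycle-type law of a uniform random permutation of
  `n` elements with `k` cycles, so `E[F]` and `sd[F]` follow from cycle
  count moments, e.g. `E[a_j] = C(n,j)(j−1)!·|s(n−j,k−1)|/|s(n,k)|` with
  `|s(·,·)|` unsigned Stirling numbers of the first kind evaluated in log
  space. This is O(n²), exact for any sample size, and is what
  `neutrality_test()` uses.
* **Full enumeration** (`method = "exact"`): all partitions of `n` into
  `k` parts with probabilities `n!/(Π_j j^{a_j} a_j!)/|s(n,k)|`,
  materialising the null's support. Used when the partition count is
  within budget (default 10⁶); beyond it the method falls back to Monte
  Carlo with a warning.
* **Monte Carlo** (`method = "monte_carlo"`): partitions are drawn by the
  Feller coupling — independent Bernoulli(θ/(θ+i−1)) indicators whose
  spacings are exactly an ESF configuration — at the θ solving
  `E[K|θ,n] = k`, rejecting draws with `K ≠ k`. A seed is mandatory;
  the default 10⁴ accepted draws put the Monte-Carlo standard error of
  `E[F]` well below the deviate's working precision.

The three routes agree (enumeration vs closed form to ~10⁻¹⁰; Monte Carlo
within sampling error), which the test suite checks explicitly.

## Distances and dendrograms

Breed-level trees use Nei's standard genetic distance between
allele-frequency spectra at one locus,
`D = −ln(Σp_i q_i / sqrt(Σp_i²·Σq_i²))`, capped (default 10) when no
alleles are shared rather than returned as infinite. Individual-level
trees use the Dice band-sharing distance `1 − 2|A∩B|/(|A|+|B|)` on allele
class sets, the standard choice for band-pattern data. Trees are built
with UPGMA — reported dendrograms in this literature are drawn
ultrametric, which UPGMA produces and neighbour-joining does not — with
labels sorted before clustering so ties break lexicographically and
deterministically. Merge heights are half the average linkage distance;
output is an `ape` `phylo`, serialisable to Newick with a stable
write–read–write round trip. Published per-locus tree topologies cannot be
reproduced exactly without the underlying gels, and branch-length
annotations of unstated metrics are not targeted; the two reconstructions
here are offered as defensible, documented alternatives.

## The synthetic-data generator

`simulate_genotypes()` draws data under the Balding–Nichols model: per
locus, ancestral frequencies from a flat Dirichlet over the allele count
(drawn uniformly from 2–10), then population frequencies from
`Dirichlet(p_anc·(1−FST)/FST)`, which makes the target FST the expected
differentiation; `fst = 0` degenerates to all populations sharing `p_anc`
exactly. Genotypes are drawn with inbreeding `fis`:
`P(hom i) = p_i² + fis·p_i(1−p_i)`, `P(het ij) = 2p_i p_j(1−fis)` (negative
`fis` is handled by exact rejection, clamped where the target law is
infeasible for rare alleles). Defaults are the seven-breed survey
conditions: sizes 127/40/40/112/87/60/60, 14 loci, FST 0.22, FIS 0, and 2%
missing calls to exercise the undefined-cell pathways. Allele classes map
to sizes `100 + 2·index` bp (dinucleotide-style spacing; cosmetic for the
statistics, but it fixes the difficulty of the gel round trip — see
below). The seed is mandatory and the output is a pure function of the
configuration.

What the generator does *not* emulate: mutation processes (no stepwise
model — the analyses never use one), linkage between loci, null alleles,
allelic dropout, or population history beyond a single differentiation
parameter. Passing tests on synthetic data therefore validate the
estimators' arithmetic and sampling behaviour, not robustness to those
artefacts of real gels.

A note on what parameter recovery shows: with seven populations weighted
by these sample sizes, the Nei `GST`-style estimator recovers
approximately `(1 − Σw_k²) ≈ 0.83` of the Balding–Nichols FST (the
weighted among-population variance omits the share of drift variance
absorbed by the weighted mean), so simulations at target 0.22 estimate
FST near 0.19. That sits comfortably inside the ±0.05 recovery band the
tests use, and the deflation factor is a property of every
frequency-decomposition estimator at a finite number of populations, not
an implementation artefact.

`simulate_band_table()` inverts the log-linear sizing model (defaults:
slope −0.02, intercept 2.899, i.e. a 50–500 bp window) to produce
migration distances per band, with optional seeded Gaussian size noise and
a matching 50-bp ladder, so the sizing → binning → calling stage can be
exercised end to end. Noiseless tables round-trip every genotype exactly.
With 2 bp allele spacing there is a hard accuracy ceiling under noise:
at size noise σ the probability a band crosses the midpoint to a
neighbouring class is about `2Φ(−1/σ)` even with perfect class centres —
roughly 4.6% per interior band at σ = 0.5, bounding genotype-level
recovery near 93% (heterozygotes need both bands right) and lower for
data-driven boundaries. Recovery above 99% is only achievable for
σ ≲ 0.25 at this spacing; the package reports measured recovery rather
than assuming it.

## Numerical choices and problem sizes

Frequency sums are validated to 1e−9; Wright's identity holds to 1e−12 by
construction and is asserted at that tolerance. Stirling tables, ESF
weights and partition probabilities are computed in log space and
validated against the triangular recurrence and against brute-force
enumeration. Estimated band sizes are rounded to 1e−6 bp before binning so
that mathematically equal fragments are never separated by float jitter.
UPGMA inherits `hclust`'s exact average-linkage arithmetic; ultrametricity
is checked to 1e−9. The test suite runs the full seven-breed design where
the statistic is cheap (F-statistics, neutrality via closed-form moments)
and scales down to two or three populations of 15–60 individuals where a
stage is exercised end to end (gel round trips, pipeline reruns); Monte
Carlo checks use 5 000–20 000 accepted draws. These sizes were chosen to
keep the default suite fast while leaving every code path covered.

## Known limitations

* Allele binning assumes a common size grid per locus across the whole
  gel set; plate-to-plate offsets are not modelled.
* The inbreeding sampler clamps infeasible negative-`fis` cells, so
  strongly negative targets with rare alleles are reproduced only
  approximately.
* `FST` confidence intervals, pairwise-population FST matrices, AMOVA,
  bootstrap tree support and rarefied allelic richness are out of scope.
* Reported-survey validation is internal-consistency only: without the
  raw genotypes, column means, the Nm transform and the Wright identity
  are checkable; per-locus values are not.
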