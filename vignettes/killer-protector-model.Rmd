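---
title: "The gamete killer–protector model behind segdrive"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The gamete killer–protector model behind segdrive}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segdrive)
```

## The biological problem

Hybrids between African rice (*Oryza glaberrima*) and Asian rice
(*O. sativa*) are semi-sterile: roughly half of their pollen grains and
spikelets abort. The cause is a single-locus gamete killer–protector system.
The African allele of the locus, here written `g`, is a cluster of three
tightly linked genes (`A4`, `TPR`, `A6`); the Asian allele `s` carries only a
truncated, non-functional copy of the protector gene (`TP`). When a plant
carries all three killer components anywhere in its genome, its sporophytic
tissue produces a sterility signal. The signal kills developing gametes —
male and female alike — *unless the gamete itself* carries a functional
protector gene (`TPR`). In a `g/s` heterozygote every `g` gamete is
protected and every `s` gamete dies, so the African allele is transmitted to
nearly all progeny: a classic selfish-element drive that shows up as
transmission ratio distortion and as ~50% sterility of the hybrid.

segdrive implements this logic as a small algebra:

* an **allele** is a named set of functional components;
* a **locus** is one linkage unit (the three-gene cluster is a single locus;
  unlinked transgene insertions are separate loci with a null allele `-`);
* the **killer arms** on the diploid sporophyte if the union of components
  over all alleles at all loci contains the killer set (default
  `{A4, TPR, A6}`) — components complement in trans, which is how two
  unlinked transgene insertions reconstitute the killer;
* **protection is gametophytic**: once the killer is armed, a gamete
  survives only if its own components contain the protector set (default
  `{TPR}`); every other gamete aborts with probability $k$ (the abortion
  probability, sex-specific in principle: $k_m$, $k_f$);
* the truncated `TP` component is carried around but inert: it neither arms
  the killer nor protects.

## From gametes to progeny

For a genotype with $L$ loci, meiosis yields up to $2^L$ equally weighted
gamete classes (independent assortment; identical classes are merged).
Viability selection multiplies each unprotected class's weight by $1 - k$
when the parent's killer is armed, renormalises, and records the surviving
mass fraction — the *viable fraction*. Fertility predictions are simply the
viable fractions: pollen fertility from the male pool, spikelet fertility
from the female pool (pollen is assumed in excess, so seed set tracks the
ovule side). With complete killing ($k = 1$) this reproduces the familiar
series: `g/s` alone is 50% fertile; adding one hemizygous protector
transgene copy rescues half the dying class (75%); a homozygous transgene
rescues all of it (100%); and a plant carrying the three killer components
on hemizygous transgenes has every non-`TPR` gamete die, again 50%.

Progeny distributions come from the random union of the mother's
post-selection female gametes with the father's post-selection male gametes.
The well-known worked example: selfing a plant heterozygous at the native
locus (`g/s`) and hemizygous for an unlinked protector transgene (`T/-`)
gives surviving gametes `gT : g- : sT` at 1/3 each, hence genotype ratios
4:4:1 at *both* loci — `g/g : g/s : s/s` and `T/T : T/- : -/-`.

Class labels are canonical: within a locus the two alleles are sorted
lexicographically with the null allele last (`T/-`, not `-/T`), and
multi-locus classes join per-locus labels with `|`. Merging of identical
gamete classes uses exact allele-name equality.

## Segregation statistics

`chi_square_gof()` computes the Pearson statistic against model-expected
proportions with `df = (#classes with expected probability > 0) − 1` and an
upper-tail chi-square p-value; no continuity or multiple-testing correction
is applied (these are single planned tests). Two policies deal with the
$k = 1$ model assigning zero mass to some classes: a zero-expected class
with zero observed count is dropped from the statistic and the degrees of
freedom, while an observed count in such a class raises an explicit
model-contradiction error — the data then demand $k < 1$, and silently
returning an infinite statistic would hide that.

`transmission_ratio()` reports the dosage-weighted allele frequency with a
Wilson score interval (chosen over the Wald interval for stability at small
counts and extreme frequencies).

`estimate_killing_efficiency()` inverts the forward model: the expected
class probabilities of a declared cross design are a function $p(k)$, and
the multinomial log-likelihood of the observed counts is maximised over
$k \in [0, 1]$ with Brent's method at tolerance $10^{-8}$ (endpoints checked
explicitly, since the maximum often sits at $k = 1$). The 95% interval is
the profile-likelihood set $\{k : 2[\ell(\hat k) - \ell(k)] \le
\chi^2_{1,0.95}\}$, found by bisection on each side. Designs whose class
probabilities are constant in $k$ (no killer present, or no segregating
protector) are rejected as non-identifiable rather than returning an
arbitrary estimate. Note that the maximum-likelihood estimate uses *all*
classes jointly: for the two-transgene design, observing 75.8% `T/T` with
the remainder hemizygous yields $\hat k = 0.862$ (the allele-frequency
inversion $k = 2 - 1/\hat t$ with $\hat t = 0.879$), slightly above the
value obtained by inverting the `T/T` fraction alone — the zero count in
the `-/-` class is information too.

## Drive dynamics

The deterministic recursion propagates genotype-class frequencies. Under
selfing (the default — the benchmark F2 populations are selfed F1s) each
genotype self-fertilises, and its contribution to the next generation is
weighted by its female viable fraction: a semi-sterile plant sets fewer
seeds. Under random mating, male and female gamete clouds are pooled across
the population, each individual contributing its post-selection gametes
scaled by frequency × surviving mass. The single-generation closed form for
a `g/s` heterozygote is the textbook $p' = 1/(2 - k)$ per gamete pool; at
$k = 0.95$ that is 0.952 — the ~0.95 F2 driver frequency quoted for these
hybrids. There is a real tension worth knowing about: ~50% F1 semi-sterility
suggests $k$ near 1, while an F2 driver frequency of 0.95 back-computes to
$k = 0.95$. The package does not resolve this — $k$ is an explicit
parameter (default 1 for clean expected-ratio predictions) to be estimated
from data when it matters.

`wright_fisher_sim()` is the finite-population counterpart: each generation
draws $N$ offspring multinomially from the deterministic expectation.
Replicate $r$ seeds its own generator at `seed + r − 1`, making runs
reproducible and replicates independent. Fixation gets no special
treatment; trajectories simply continue at frequency 1. With $k = 0$ the
driver frequency is a martingale, which the test suite checks against
replicate means.

## Haplotype typing

The evolutionary-survey side of the pipeline classifies accessions by their
locus structure from two inputs a standard alignment pipeline produces:

* **Presence/absence of the flanking killer genes** (`A4`, `A6`) from
  per-base depth: breadth of coverage = fraction of interval positions with
  depth ≥ 2, gene called present when breadth ≥ 0.8. The published analyses
  state that per-position depth was used but not the decision rule, so the
  rule here is a deliberate choice — breadth is robust to uneven coverage,
  and both thresholds are exposed as arguments. The call is monotone in
  depth by construction. Depth files are samtools-depth dialect (1-based
  positions); positions absent from the file count as depth 0, so both the
  default and `-a` output styles work. Gene intervals arrive as BED
  (0-based half-open) and are converted internally to 1-based inclusive —
  the conversion has its own test.
* **The protector-gene state** from a 7-site SNP panel inside the gene:
  site 7 is the C→A stop-gain, so `C` types the accession as full-length
  `TPR` and `A` as truncated `TP`. Anything else (missing genotype,
  unexpected base) makes the accession *untypable* — reported, never
  guessed. Only panel-site records are read from the VCF; heterozygous
  calls are treated as missing (the panel is meant for inbred accessions).
  Panel states are defined on the forward strand of the driver-allele
  reference; no reverse-complement handling is attempted.

The structure label concatenates the calls — `{A4-}? {TPR|TP} {-A6}?` —
giving the eight possible one-, two- and three-gene structures. A separate
pattern→allele-name catalogue maps exact 7-character SNP patterns to
published allele names, with `"novel"` for no match; the file shipped under
`inst/extdata/` is a synthetic placeholder illustrating the format (the
authoritative pattern table lives in supplementary material of the primary
literature and should be substituted by the user). Duplicate catalogue
patterns are a configuration error.

## The synthetic-data generator

Because the raw resequencing panel is an external deposit, every pipeline
input can be generated synthetically, and the generators are first-class
tested code:

* `sample_progeny_counts()` draws multinomial genotype-class counts from the
  model's cross predictions — exactly the sampling assumption behind the
  chi-square tests.
* `simulate_depth_profile()` draws independent Poisson(λ) depths per
  position: λ = mean depth for present genes, λ = mean depth × 0.01 for
  absent ones (cross-mapping contamination). No GC or mappability bias is
  modelled — the simplest model that exercises the breadth rule.
* `simulate_accession_panel()` writes per-accession single-sample VCFs
  (panel sites only) and depth files in exactly the dialects the classifier
  reads, plus BED, sample manifest and ground-truth tables. SNP states are
  deterministic given the lineage pattern; a site whose simulated depth is
  zero is emitted as a missing genotype, so a zero-depth panel is wholly
  untypable, mirroring real missingness.

All generators are pure functions of (configuration, seed). What passing
tests on these data show is that the *inference logic* is correct under the
model's own assumptions; they do not validate the model against real
sequencing artefacts (mapping bias, index hopping, heterozygous residual
variation), which the Poisson/deterministic generators deliberately omit.

## Default study conditions and numerical choices

* Abortion probability default **k = 1** (both sexes): the printed expected
  ratios (4:4:1, 1:2:1 with fixed transgene) are the $k = 1$ limits, and the
  sexes are kept equal by default because the reported pollen and spikelet
  fertilities match; nothing in the package assumes equality.
* Estimator validation uses 200 replicate datasets of n = 500 progeny per
  scenario at $k \in \{0.2, 0.5, 0.85, 1\}$ — n = 500 is a realistic large
  F2 family, and the bias of $\hat k$ is assessed per scenario while CI
  coverage is pooled across scenarios (at $k = 1$ the data are degenerate —
  every draw is all `T/T` — so per-scenario coverage is structurally 1).
* Probability bookkeeping is exact to floating point: gamete weights and
  progeny probabilities are required to sum to 1 within $10^{-12}$ in the
  invariant tests.
* Monte-Carlo calibration of chi-square p-values uses 10,000 multinomial
  draws at n in the hundreds, where the asymptotic approximation is expected
  to hold to about 0.01 for df ≤ 4.
* Synthetic accession panels use 20 accessions at mean depth 30 (typical
  resequencing coverage) with 600–900 bp gene intervals — small enough to
  regenerate at test time, large enough that Poisson breadth at depth ≥ 10
  is effectively deterministic.
* Optimisation tolerances: Brent and bisection at $10^{-8}$ on $k$.

## Known limitations

* No recombination within or between loci — loci assort independently and
  the three-gene cluster never recombines internally. Mapping recombinants
  of the cluster is outside the model.
* No molecular mechanism: killing is a probability, not a pathway; epistasis
  beyond component-set containment is not representable.
* The drive recursion tracks genotype frequencies only — no mutation,
  migration, overlapping generations, or fitness effects other than gamete
  viability; fecundity weighting under selfing is the one demographic
  assumption, and it matters only for mixed populations.
* Spikelet fertility equals the female viable fraction; pollen limitation is
  not modelled.
* The ~95% "fully fertile" baseline of real transgenic controls (background
  sterility) is not modelled; predictions are relative to an ideal fully
  fertile plant.
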