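---
title: "Reference-panel genotype imputation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-panel genotype imputation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(panelpute)
```

# The problem

Many long-running canine association studies hold genotypes from a legacy
medium-density array.  Rather than re-genotyping every dog on a newer,
denser platform, the missing markers can be *imputed*: a reference panel of
individuals genotyped (or sequenced) at high density supplies the haplotype
background, and each study dog's low-density genotypes are extended to the
panel's site list with a probabilistic model of haplotype sharing.  This
package implements that whole study design as testable code: building a
merged reference panel from heterogeneous sources, aligning annotation
dialects that disagree on DNA strand, phasing and imputing with a
haplotype-copying hidden Markov model, and scoring accuracy by hold-out
masking.  A breed-structured simulator generates every input, so the full
pipeline runs end-to-end with no external data.

# The copying model

Phasing and imputation both use the Li–Stephens haplotype-copying HMM.  A
target haplotype is modelled as an imperfect mosaic of the $K$ reference
haplotypes.  The hidden state at each site is the template being copied;
between adjacent sites at genetic distance $d$ Morgans the template
switches with probability

$$s = 1 - \exp(-\rho/K), \qquad \rho = 4 N_e d,$$

landing uniformly on one of the $K$ templates.  Emission is an imperfect
copy: the observed allele equals the template allele with probability
$1-\lambda$, where $\lambda = \theta / (2(\theta + K))$ and
$\theta = (\sum_{i=1}^{K-1} 1/i)^{-1}$ is the Watterson-style mutation
parameter.  This transition family is a semigroup
($A(d_1)A(d_2) = A(d_1+d_2)$), so running the forward–backward recursion on
the typed sites and propagating the state posterior analytically across
untyped intervals is exact — the package exploits this to keep the
per-haplotype cost at $O(MK)$.

*Haploid imputation* (`impute_haploid`) runs forward–backward over the
typed sites and returns, per site, the posterior probability of carrying
allele 1.  *Diploid phasing* (`phase_diploid`) finds the most probable
path through the $K \times K$ ordered-pair state space (Viterbi, in
compiled code with the factorized-transition $O(K^2)$ recursion), with
emissions that constrain the unordered template-allele sum to the observed
genotype.  The genotype probability triple of a study dog at an untyped
site combines the two per-haplotype posteriors $q_1, q_2$ as
$(p_0,p_1,p_2) = ((1-q_1)(1-q_2),\; q_1(1-q_2)+q_2(1-q_1),\; q_1 q_2)$.

Key parameters (all in `model_params()`):

* `ne = 200` — effective population size scaling recombination, for both
  phasing and imputation.  Dog breeds are strongly bottlenecked; this
  value is the study condition the pipeline is built around.
* `window_bp = 2e6`, `overlap_bp = 2.5e5` — chromosomes are processed in
  2 Mb windows with 250 kb buffers, stitched at the overlap midpoints
  (each site is reported from the window whose centre is nearest).
* `theta = NULL` — Watterson default; override for sensitivity analyses.
* `min_chrom_rate = 0.90` — per-chromosome individual call filter applied
  before phasing.
* `phase_states = 40` — number of conditioning haplotypes.  Rather than
  conditioning on all $K$ haplotypes (quadratic cost in phasing), each
  individual is phased against the haplotypes of its genotypically
  nearest neighbours (mean absolute genotype difference).  Similarity
  selection is what the established tools in this family do, and it is
  deterministic.
* `phase_rounds_min = 2`, `phase_rounds_max = 10` — reference panels are
  phased iteratively from a random genotype-consistent start until no
  heterozygous assignment changes.  Conditioning sets are fixed across
  rounds so the stopping rule can trigger.

## Windowing is not posterior-invariant

The forward–backward posterior at a site depends on data at genetic
distance $d$ with weight roughly $\exp(-4 N_e d / K)$; with $N_e = 200$
and $K = 40$ the correlation length is of order $K/(4N_e) = 0.05$ Morgans
— several megabases.  A 250 kb buffer therefore cannot make window
posteriors bit-identical to a whole-chromosome run, and the package does
not claim it does.  What holds, and what the tests assert, is that typed
sites are unchanged, dosage drift away from the cuts is bounded, and
hold-out accuracy is equal between window layouts (measured agreement
within 0.03 $R^2$ on the test scenario).

# Harmonization

The panel-construction module reproduces the paper-trail of filters a
practitioner applies when merging array and sequence-derived datasets:

* **Call-rate filters** use strict inequality (exactly at threshold is
  kept): individuals $<90\%$ for panel inputs and $<95\%$ for study sets
  and the pooled panel; sites $<97\%$ everywhere.
* **Hardy–Weinberg**: a two-sided exact test on the Levene–Haldane
  conditional distribution of the heterozygote count (`hwe_exact_test`),
  sites removed at $p < 5\times10^{-5}$.  Plain exact test, no mid-$p$:
  deterministic and checkable against full enumeration.  The filter
  applies to array-genotyped and study data, not to sequence-derived
  extractions before merging.
* **MAF** $<1\%$ for study sets and the pooled panel (computed on
  non-missing calls), $<5\%$ in the post-imputation GWAS-ready filter.
* **Filter order** within a step is call rate, then HWE, then MAF, each
  removed site tallied once under the first rule it fails.  The order
  within a step is a package decision; the sources describe the filters
  but not their sequence.
* **Strand**: two annotations for the same site are compared by allele
  codes — equal sets mean same strand, complement-equal sets mean a flip,
  and the palindromic pairs {A,T} and {C,G} are undecidable from codes
  alone.  Palindromic sites fall back to comparing 10 bases of upstream
  and downstream flanking sequence (a flip shows as swapped
  reverse-complemented flanks); when flanks are unavailable they are
  excluded rather than assumed same-strand, the conservative option.
  Applying a flip complements the allele letters and leaves genotype
  codes untouched, so flipping is an involution.
* **Duplicates** at one genomic position keep the record with the highest
  call rate, ties broken by smallest site id (the dedup rule is stated
  only as "keep unique" in the sources; the tie-break is fixed here by
  decision).  **Merging** intersects sites across datasets, enforces
  allele-set identity, and swaps the 0/2 coding where two datasets label
  the same pair with transposed allele-1.

# The synthetic scenario

`sim_config()` defaults define the desk-scale study conditions used by
the tests and the acceptance script:

| quantity | default | what it emulates |
|---|---|---|
| `n_sites = 2000`, `chrom_length_bp = 20e6` | one 20 Mb autosome at 1 cM/Mb | a mid-sized chromosome, 2 Mb windows exercised ~10 times |
| `n_breeds = 20` × `founders_per_breed = 4` | 80-dog multi-breed backbone | consortium panels: many breeds, few dogs each |
| `focal_size = 70` (40 panel + 30 study), `n_overlap = 8` | breed-specific component and re-genotyped dogs | the breed-specific panel and hold-out design |
| `generations = 20` | random mating in closed breeds | breed bottlenecks, long shared haplotypes, within-breed LD |
| `ancestral_maf_shape = c(1, 1)` | uniform ancestral frequencies | array-ascertained common variants rather than a sequencing SFS |
| `mutation_rate = 1e-5` | per-site per-meiosis flips | a small amount of recurrent error/mutation |
| `genotyping_error_rate = 0.002` | array call errors | discrepancies between re-genotyped copies of the same dog |
| `ld_fraction = 0.25` | low-density site list | the legacy array's share of the new array's markers |
| `flip_fraction = 0.05`, `palindromic_fraction = 0.10` | annotation dialects | strand disagreements between platform annotation files |

The simulator is a mosaic-pedigree model, not a coalescent: founders are
drawn from a Beta-frequency ancestral pool, and each generation's gametes
are recombinant mosaics with Poisson(map length) crossovers placed on the
cM scale.  It reproduces the *structure* the study design needs —
relatedness within breeds, LD decaying with genetic distance,
cosmopolitan diversity across breeds — but not canine demographic
history, realistic site-frequency spectra, gene conversion, or genotyping
artefacts beyond symmetric call errors.  Passing tests on this generator
therefore demonstrate that the pipeline's machinery is correct and that
its qualitative behaviour (panel-size response, Info stratification)
matches expectation; they do not certify accuracy numbers on real dog
data.

# Evaluation

Held dogs are never in the panel used to impute them.  Two hold-out modes
mirror the two designs in the underlying study: `regenotyped_overlap`
(dogs genotyped on both platforms; truth is their high-density array
calls, so truth itself carries genotyping error) and
`artificial_lowdensity` (panel dogs down-filtered to the low-density site
list; truth is identical to the study genotypes at typed sites).

Scoring excludes the observed low-density sites: per-dog dosage $R^2$ is
the squared Pearson correlation between imputed dosage and truth genotype
over masked sites; hard calls use uncertainty $1-\max(p)$ with threshold
0.1 (calls above it become missing); concordance is the percentage of
matching non-missing calls, with missing calls excluded from numerator
and denominator and the missing fraction reported separately (the
denominator convention is not stated in the sources; this one is fixed
here and flagged).  The per-site Info score is the ratio-of-variances
certainty metric: $1 - \sum_i(f_i - e_i^2) / (2N\hat\theta(1-\hat\theta))$
with $e_i = p_{i1} + 2p_{i2}$, $f_i = p_{i1} + 4p_{i2}$, defined as 1
when $\hat\theta \in \{0, 1\}$.  Info bins are half-open below and closed
at 1.0.

# Experiments

`run_panel_ablation()` re-imputes a fixed hold-out with the
breed-specific panel component reduced level by level (nested random
removals with a recorded seed; the multi-breed backbone is never
removed), re-filtering the panel site list after each removal.  Panel
haplotypes are phased once on the largest panel per seed and restricted
per level: held dogs are in no panel, so scoring is unaffected, and the
level response isolates panel *content* rather than phasing noise.  The
ablation scenario uses `focal_panel_n = 88` so that 80 breed-specific
dogs remain after the 8 hold-outs.

`ibs_distance_matrix()` + `mds_coordinates()` (classical Torgerson
scaling with a deterministic sign convention; axes with numerically zero
eigenvalues are dropped with a warning) reproduce the
population-structure check that panel and study individuals of the focal
breed overlap in genotype space.

# Numerical and degenerate-input decisions

* All HMM arithmetic is per-site normalized (forward–backward) or
  log-space (Viterbi); posteriors are independent of the stabilization to
  well below $10^{-9}$, and triples sum to 1 within $10^{-9}$.
* Viterbi ties resolve deterministically (lowest candidate class, then
  lowest linear state index); at a heterozygous site whose two templates
  agree, allele 1 goes to the first haplotype.
* An individual with zero sites has call rate 1; a monomorphic site has
  HWE $p = 1$; MAF at fully-missing sites is undefined and fails the MAF
  filter only when a MAF filter is active.
* PED files carry no ref/alt semantics: the first allele letter
  encountered in file order becomes `allele_a`, and heterozygotes are
  written `a b` so a read/write cycle is idempotent after one
  normalization.  Sites observed monomorphic keep `allele_b = NA` until
  an annotation supplies the other letter (`apply_annotation`).
* Genetic-map lookups are piecewise-linear with constant extrapolation
  beyond the mapped range; the 3-column map dialect (bp, cM/Mb, cum cM)
  is adopted without claiming fidelity to any particular published file.

# Problem sizes

The shipped tests and drivers run at desk scale, chosen so the whole
suite exercises every stage in minutes: the default scenario is one
20 Mb chromosome with 2000 sites, 120 panel dogs and 38 study dogs; the
ablation experiments use 10 simulation replicates at levels
{10, 20, 40, 80} with 3 phasing rounds (accuracy at 3 rounds is
indistinguishable from the converged phaser on these panels, and the
level response is the quantity of interest); oracle comparisons
enumerate all copying paths on instances up to 5 sites and 4 reference
haplotypes, where enumeration is exact and fast.

# Known limitations

* Autosomal, diploid, biallelic SNPs only; no X-chromosome dosage model,
  no indels or multiallelic sites (excluded and tallied on read).
* The simulator's breeds are closed populations of constant size; no
  migration, selection, or overlapping generations.
* Imputation quality on real data depends on reference-panel relatedness
  structure the simulator only caricatures; the shipped accuracy numbers
  characterize the synthetic conditions, not any real cohort.
* No bit-level reproduction of external phasing/imputation tools is
  attempted or claimed; the copying-model parameterization matches the
  published standard, and agreement is behavioural (accuracy trends,
  Info stratification), not numerical.
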