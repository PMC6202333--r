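---
title: "Methods: pedigree-aware rare-variant discovery in founder populations"
author: "founderseek"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pedigree-aware rare-variant discovery in founder populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(founderseek)
```

## Problem setting

Chronic granulomatous disease (CGD) is a rare primary immunodeficiency in
which phagocytes fail to mount the NADPH-oxidase reactive-oxygen burst.
In a bottlenecked founder population, a recessive loss-of-function allele
can drift to a frequency high enough that homozygotes appear in
population-scale genotype collections, making the discovery route
unusual: first a family-based rare-genotype search in a handful of
whole-genome-sequenced relatives, then genealogy-driven imputation of the
candidate allele into a chip-genotyped population, and finally
recessive-model association with clinical phenotypes plus a biochemical
burst assay on genotype-recalled carriers. `founderseek` implements that
entire analysis chain as reusable, tested components, together with a
synthetic-population generator that reproduces the statistical structure
the chain assumes.

## Rare-genotype prioritization

Within a sequenced family the package screens coding/splicing variants
for genotypes compatible with the disease model:

* **dominant**: heterozygous in every affected member, minor allele
  frequency (MAF) below 0.05% in both the internal population reference
  and an external database column, and absent from both unaffected
  parents;
* **recessive**: homozygous (hemizygous for males on X) in every
  affected member, or a gene-level pair of heterozygous variants
  (potential compound heterozygote), each variant below 2% MAF in both
  references.

Frequencies are always minor-allele folded (`compute_maf`); at exactly
0.5 the alternate allele is treated as minor. A variant absent from the
external database **passes** the external clause: for very rare alleles,
absence from a large external catalogue is evidence of rarity, not
missing evidence. A missing genotype in an affected individual excludes
the variant — the conservative choice, since carriage cannot be
confirmed.

Compound-heterozygous pairs are phased by parental transmission
(`phase_compound_het`): the four assignments of the two alternate
alleles to parental origins are enumerated, and a pair is called in
trans (or in cis) only when every transmission configuration consistent
with the parental genotypes forces that phase. Pairs forced in cis are
discarded; unphaseable pairs are retained but flagged `ambiguous`,
because discarding them would silently drop true compound heterozygotes
whenever both parents happen to carry both variants.

Segregation checking (`check_segregation`) removes candidates carried in
full by an unaffected relative. For compound-het candidates this check
is itself phase-aware: an unaffected member who merely carries both
variants is *not* disqualifying unless its own parental genotypes force
the trans configuration (or it is homozygous at one site of the pair).
The naive "carries both hets" rule would reject every ambiguous pair,
because the two transmitting parents each carry both variants by
construction.

The impact vocabulary maps each consequence term to exactly one of five
classes — high (stop-gained, frameshift, splice acceptor/donor, ...),
moderate (missense, splice-region, in-frame indels), low, DHS
(regulatory), remaining — and unknown terms always fall through to
`remaining`, so classification is total.

## Founder-population arithmetic

Under Hardy–Weinberg equilibrium with minor-allele frequency $p$:
carrier (heterozygote) fraction $2p(1-p)$, homozygote fraction $p^2$,
expected homozygote count $p^2 n$. `genotype_based_prevalence` estimates
disease prevalence directly as genotype-positives over the genotyped set
size. Reporting conventions are the package's own (the quantities are
conventionally printed pre-rounded): carrier reciprocals round to one
significant figure; prevalence reciprocals round to the nearest 1,000
above 10,000, nearest 100 above 1,000, nearest 10 above 10, and the
nearest integer below that (so `positives = n` reports "1 in 1").
Unrounded values are always returned alongside. No inbreeding
coefficient is modelled; HWE is assumed throughout.

## Genealogical imputation

Population-scale long-range haplotype phasing requires genotype-array
data across tens of thousands of individuals; `founderseek` instead
implements single-site transmission phasing with pedigree propagation,
which keeps every assignment *forced* (derivable by Mendelian logic
alone) and therefore exactly checkable against an enumerable oracle:

1. typed homozygotes resolve both received haplotypes; a typed
   heterozygote resolves when one parental origin is known;
2. a parent whose two haplotypes are equal transmits that allele to
   every child (propagated to a fixed point);
3. an untyped individual whose typed child demonstrably received an
   allele from them (the other parent cannot have donated it) has one
   haplotype resolved to carry that allele. Two children forcing the
   same value are conservatively attributed to a single parental
   haplotype.

Mendelian inconsistencies between typed parent-child pairs flag the site
and suppress phasing-derived assignments.

Expected dosages are then assembled per haplotype, top-down through the
pedigree: a forced haplotype contributes its allele; an unresolved
haplotype received from a known parent contributes half that parent's
expected dosage (fair segregation); an unresolved founder haplotype
contributes the population frequency $p$. This makes dosages calibrated
conditional expectations — for example, the untyped mother of a typed
heterozygous child whose typed father lacks the allele receives
$\hat\theta = 1 + p$, which equals the exhaustive Hardy–Weinberg
posterior. The design intentionally stops short of full probabilistic
peeling: information that does not travel along a forced chain or a
direct parent-child expectation (e.g. a typed *sibling's* genotype) is
ignored, so dosages are exact conditional expectations given a defined
subset of the data, not the full-likelihood posterior.

The informativeness of an imputation is scored as

$$\mathrm{info} = \frac{\widehat{\mathrm{Var}}(\mathrm{E}[\theta \mid \mathrm{data}])}{p(1-p)},$$

where $\theta$ is the per-haplotype allele count: the observed variance
of the per-haplotype imputed expectations over the binomial haplotype
variance. It is 0 when the same value is always imputed, about 1 under
complete typing, and asymptotically equals the squared correlation
between imputed and true counts. The dosage container therefore carries
*per-haplotype* expectations: a typed heterozygote's haplotypes are one
0 and one 1 (which order is irrelevant to a variance), so full typing
scores ~1. When only genotype-level dosages are available the package
falls back to $\hat\theta/2$ per haplotype, which is documented to cap
the score at 0.5 under full typing — callers comparing against
array-style information scores should use the haplotype-level form.
Sampling noise can push the score marginally above 1.

## Association testing

Binary phenotypes are tested by logistic regression of case status on a
recessive (homozygote) indicator plus covariates, with the p-value from
the likelihood-ratio statistic on 1 df and a Wald 95% CI on the log-odds
scale. With a handful of homozygotes, complete separation is common; the
package then refits with Firth's penalized likelihood (Jeffreys-prior
score correction, penalized LRT) and flags the result in `model_label`.
The hard-call rule converting dosages to the indicator is
$\hat\theta > 1.5$ by default, configurable.

Quantitative traits are first adjusted for covariates and standardized
by the rank-based inverse-normal transform with the Blom offset,
$z_i = \Phi^{-1}\!\big((r_i - 3/8)/(n + 1/4)\big)$, ties sharing
averaged ranks; the genetic effect is then an ordinary-least-squares
coefficient in SD units (multiply by a reference SD for natural units).
A fixed-effect linear model is used deliberately in place of a
mixed-model association: relatedness correction is out of scope here,
and on strongly structured cohorts the fixed-effect p-values will be
anti-conservative — the synthetic generator can inject family structure
precisely so that this inflation can be demonstrated rather than hidden.

Genome-wide significance uses impact-class weighted Bonferroni
thresholds: 2.5×10⁻⁷ (high), 5.0×10⁻⁸ (moderate), 4.5×10⁻⁹ (low),
2.3×10⁻⁹ (DHS), 7.5×10⁻¹⁰ (remaining).

## Oxidative-burst assay

The dihydrorhodamine burst test compares per-cell fluorescence of
PMA-stimulated and unstimulated neutrophils. The stimulation index is
defined here as the **geometric-mean fluorescence ratio** of stimulated
to unstimulated events — the standard DHR convention; published indices
are often printed without a formula, so this definition is a documented
choice, and printed clinical SI values serve as classification fixtures
rather than computation targets. A positivity gate is placed at the 0.99
quantile (configurable) of the unstimulated distribution, and the
fraction of stimulated cells above it accompanies the index. SI is
scale-equivariant; zero intensities are handled by a +1 offset applied
to both conditions. Classification is strict: SI < 3 is `impaired`
(SI = 3.0 is `normal`), the conventional boundary for a severely
impaired burst as seen in X-linked CGD. At least 100 events per
condition are required.

## Synthetic population generator

The generator's defaults are the study regime the package targets, and
they are not tuning knobs: focal founder-allele frequency 0.76%, a
recessive binary outcome with homozygote odds ratio 67.6 on a 1%
baseline risk, a −1.24 SD homozygote shift on the standardized
quantitative trait, and a chip-typed fraction of 0.46. Where the regime
does not fix a value we chose once what is realistic for a European
founder cohort and kept it: mean sibship 2.5, eight region strata with
mild outcome effects (so covariate adjustment is genuinely exercised),
adult age range 20–90, lognormal flow events with $\sigma = 0.3$ on the
log scale.

The genealogy grows founder couples forward; each generation's offspring
mate monogamously with newly introduced immigrant founders. This keeps
the parent graph acyclic and loop-free, which means the generator
emulates *descent* structure (deep transmission chains for imputation)
but not *inbreeding*: synthetic homozygotes arise from two independent
carrier lineages, slightly rarer than in a genuinely consanguineous
founder population. Genotypes are gene-dropped: founder haplotypes are
Bernoulli draws at the configured frequency and each meiosis transmits
one parental haplotype fairly; every haplotype is recorded as ground
truth, which is what lets the imputation and phasing tests assert exact
agreement rather than statistical similarity. A single focal site with
independent decoy variants is simulated — no linkage disequilibrium and
no recombination, because every analysis under test is single-variant.
Passing tests on these cohorts therefore demonstrate correctness of the
inheritance logic and calibration of the statistics, not robustness to
LD, genotyping error, or call-rate artefacts, none of which are
simulated.

The fixed proband-family fixture (`build_proband_family_fixture`)
encodes the canonical discovery configuration — two affected brothers
homozygous for a rare stop-gained allele (MAF 0.76%), heterozygous
parents, 2 heterozygous and 1 non-carrier unaffected siblings — plus a
second qualifying homozygous missense genotype (MAF 0.33%), a known
recessive site absent from the brothers (MAF 0.58%), and four decoy
failure modes (frequency, zygosity, segregation, cis-phase). Recessive
filtering at 2% returns exactly two candidates, and requiring high
impact isolates the stop-gained one.

## Pipeline

`run_pipeline()` chains the stages — cohort simulation, fixture
prioritization, focal-variant imputation with its information score,
association, burst classification — writing per-stage plain-text
artifacts and a versioned JSON summary; identical seeds give identical
summaries. The association stage runs on a simulated population-scale
genotype-recall cohort (n = 50,000 Hardy–Weinberg draws at the realized
focal frequency) rather than the discovery pedigree: at a 0.76% allele
frequency a few-thousand-person pedigree almost surely contains no
homozygote, and the discovery design's power genuinely comes from the
population-scale recall step. When a simulated cohort still contains no
homozygote the stage reports `untestable` rather than a fit.

## Numerical choices and degenerate inputs

* MAF with zero called alleles, information with $p \in \{0, 1\}$,
  all-identical traits, fewer than 3 non-missing trait values, zero
  homozygotes in a binary fit, and sub-100-event assays are errors, not
  silent NAs.
* Logistic separation is detected as non-convergence or a genotype
  log-odds beyond ±10 (OR beyond ~2×10⁴); the Firth refit uses Newton
  iteration with step-halving, tolerance 10⁻⁸.
* The tie-break folding MAF at exactly 0.5 treats the alternate allele
  as minor.
* Problem sizes in the test suite were chosen to make stochastic checks
  sharp but quick: 10,000 haplotypes for information-score agreement
  (tolerance 0.05), 1,000 replicates for type-I calibration at the
  binomial 99% bound, 100 replicates for quantitative-effect CI
  coverage, 1,000 random trios for exhaustive phasing agreement.

## Known limitations

* Single-site logic throughout: no LD, no recombination, no multi-site
  haplotype estimation (no HMM-style statistical imputation).
* Fixed-effect association only; no kinship/mixed-model correction.
* The imputation is forced-chain + parental expectation, not full
  pedigree peeling; typed siblings of an untyped individual contribute
  nothing unless a chain forces them to.
* VCF handling is biallelic after decomposition; structural variants,
  phased input genotypes and BCF indexing are out of scope.
* Pseudo-autosomal regions are not modelled; males on the configured X
  label are strictly hemizygous.
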