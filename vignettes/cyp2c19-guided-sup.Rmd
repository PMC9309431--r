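---
title: "CYP2C19-guided stress ulcer prophylaxis: models and methods"
author: "cyp2c19sup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CYP2C19-guided stress ulcer prophylaxis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyp2c19sup)
```

## The clinical problem

Critically ill patients routinely receive stress ulcer prophylaxis (SUP),
most often with a proton pump inhibitor (PPI). Most PPIs are inactivated in
the liver by the CYP2C19 isoenzyme, whose activity is strongly shaped by two
common single nucleotide polymorphisms:

* **rs12248560** (c.-806C>T), the promoter variant defining the
  increased-function star allele **\*17** (overexpression, faster drug
  degradation);
* **rs4244285** (c.681G>A), the exonic variant defining the no-function
  star allele **\*2** (aberrant splice site, truncated protein).

A patient's ability to degrade a PPI can therefore be predicted from the
*pair of genotypes* at these two markers — a **haplogenotype**, written
`<rs12248560 star genotype>/<rs4244285 star genotype>`, e.g. `*1*17/*1*2`.
This package implements that prediction, the dosing recommendations keyed
to it, and the population-genetic machinery needed to ask which populations
benefit most from genotyping before SUP.

## Haplogenotypes, phasing, and the six predictive phenotypes

Each marker has three unphased genotypes, giving $3 \times 3 = 9$
haplogenotypes. The two variant alleles are in strong linkage
disequilibrium: \*2 and \*17 are not observed on the same haplotype. Under
that constraint each haplotype is exactly one of \*1, \*2, or \*17, and
only the $\binom{3}{2} + 3 = 6$ unordered haplotype pairs are
constructible. Those 6 **canonical** haplogenotypes are phaseable without
ambiguity and map one-to-one onto predictive metabolizer phenotypes:

| haplogenotype | phenotype | interpretation |
|---|---|---|
| `*1*1/*2*2` | PM | poor — no functional enzyme |
| `*1*1/*1*2` | IM | intermediate — one no-function allele |
| `*1*17/*1*2` | AM | ambivalent — opposing alleles, **provisional** |
| `*1*1/*1*1` | EM | extensive (normal) |
| `*1*17/*1*1` | RM | rapid — one increased-function allele |
| `*17*17/*1*1` | UM | ultrarapid — two increased-function alleles |

The remaining 3 combinations (`*1*17/*2*2`, `*17*17/*2*2`, `*17*17/*1*2`)
would require a cis \*2–\*17 haplotype. Such carriers exist but are
extremely rare (on the order of 0.045 per mille in very large genotyped
populations); `classify_phenotype()` labels them **UNKNOWN** rather than
erroring, because a dosing engine downstream must still respond to them —
the fail-safe answer is CYP2C19-independent therapy. The AM class carries a
persistent `provisional` flag: the available evidence suggests \*17 cannot
fully compensate for \*2, so AM patients are grouped with PM/IM for dosing
but flagged until the phenotype is confirmed by therapeutic drug
monitoring. No quantitative activity score is computed; the classification
system is purely categorical.

```{r}
haplogenotype_table()
```

## The dosing rule engine

Recommendations live in a *declarative, versioned YAML rule table*
(`inst/extdata/sup_rules.yaml`) interpreted by a small first-match engine,
rather than hard-coded branches. Pharmacogenomic guidance evolves and
consensus bodies differ; a data file with explicit rule ids, citations and
a version string can be amended and diffed without touching code, and every
emitted recommendation is traceable to the rule that produced it.

Priority order encodes the clinical overrides:

1. **PPI hypersensitivity** dominates everything: switch to a non-PPI
   agent (H~2~ receptor antagonist or gastric mucosa protectant).
2. **No genotype / UNKNOWN phenotype / interacting co-medication**:
   CYP2C19-independent therapy — rabeprazole preferred at standard dose.
3. **Rabeprazole** is degraded predominantly non-enzymatically: standard
   dose for every phenotype.
4. **Esomeprazole** has no genotype-specific recommendation except a
   50–100% increase for ultrarapid metabolizers in *H. pylori*
   eradication. (We deliberately do not extend the first-generation EM/RM
   indication-based increase to esomeprazole: its published dosing row
   carries only the standard dose.)
5. **PM/IM/AM on first-generation PPIs** (omeprazole, lansoprazole,
   pantoprazole): standard dose with rabeprazole preferred; for chronic
   therapy beyond 12 weeks, consider a 50% dose reduction.
6. **EM/RM on first-generation PPIs**: standard dose; 50–100% increase
   (splittable) for *H. pylori* eradication or erosive esophagitis.
7. **UM on first-generation PPIs**: +100% for SUP; drug-specific folds for
   *H. pylori* eradication (omeprazole 3x, lansoprazole 4x,
   pantoprazole 5x); if the critically ill patient is *H. pylori*-positive
   under SUP, standard-dose rabeprazole is preferred instead.
8. **Dexlansoprazole** inherits the first-generation rules (its metabolism
   parallels lansoprazole, so it also takes the 4-fold eradication rule);
   it has no established standard SUP dose, so absolute doses are
   unavailable and recommendations remain text-only.

Dose changes are expressed as *multiplier intervals* relative to the
standard SUP daily dose (omeprazole 20, lansoprazole 30, pantoprazole 20,
esomeprazole 20, rabeprazole 20 mg/day); "increase by 50–100%" is the
interval [1.5, 2.0] and consumers choose within it. The engine is total
and deterministic over the full phenotype x drug x indication x flag
space, which the test suite verifies by exhaustive enumeration (4032
cases). Uncallable samples (a missing genotype slot) are dosed under the
genotype-unavailable rule rather than dropped.

```{r}
recommend("UM", clinical_context("omeprazole", "SUP"))
```

Out of scope by design: pediatric dosing, renal/hepatic adjustment,
drug–drug interaction resolution beyond the single boolean flag, and
adverse-event risk quantification.

## Population profiles under Hardy–Weinberg equilibrium

Let $h_1, h_2, h_{17}$ be the haplotype frequencies of \*1, \*2, \*17
(summing to 1; `renormalize_alleles()` drops mass on other reported star
alleles, which are negligible in most populations, and renormalizes with a
warning). Random mating gives the haplogenotype frequencies as the terms
of $(h_1 + h_2 + h_{17})^2$:

$$ f_{EM} = h_1^2,\quad f_{IM} = 2h_1h_2,\quad f_{PM} = h_2^2,\quad
   f_{RM} = 2h_1h_{17},\quad f_{UM} = h_{17}^2,\quad f_{AM} = 2h_2h_{17}. $$

The linkage-disequilibrium constraint makes the three non-canonical
haplogenotypes have frequency zero under this model. Conversely,
`estimate_haplotype_freqs()` recovers $h_{17}$ and $h_2$ from a genotyped
cohort by allele counting ($h_{17} = \#T/2N$ at rs12248560,
$h_2 = \#A/2N$ at rs4244285, $h_1$ the remainder) with binomial standard
errors $\sqrt{p(1-p)/2N}$; samples with non-canonical haplogenotypes are
counted but flagged, since the estimator's phasing assumption fails for
them. When observed cohorts are displayed next to projected profiles,
`cohort_profile()` merges the UNKNOWN mass into AM by default, the
convention used for such figures.

## Comparing populations

`compare_populations()` tabulates two populations over the six phenotype
classes (2 x 6 counts) and computes the Pearson statistic
$\chi^2$, $\text{dof} = 5$, and Cramér's phi

$$ \phi = \sqrt{\frac{\chi^2}{N\,(\min(r,c)-1)}} = \sqrt{\chi^2 / N}
   \text{ for a } 2 \times k \text{ table}, $$

with the effect-size bins $0.3 \le \phi < 0.5$ medium and $\phi \ge 0.5$
large; values below 0.3 are labelled "below-medium" because the scale
defines only the upper two bins.

Numerical and design choices:

* **"Exact" test.** The exact test is implemented as a seeded Monte Carlo
  conditional test with fixed margins (`chisq.test(simulate.p.value =
  TRUE)`, default 100,000 replicates), with an asymptotic fallback mode.
  No specific exact-test algorithm is canonical for 2 x 6 tables, the
  Monte Carlo conditional test is the standard general answer, and seeding
  makes it reproducible; the suite checks it agrees with the asymptotic
  p-value within 0.02 at n = 2000 per population.
* **Frequencies to counts.** Profiles supplied as frequencies are realized
  as counts by largest-remainder allocation (counts sum exactly to n,
  ties broken by category order). When no sizes are stated the comparison
  uses an equal synthetic n per population (default 10,000, configurable):
  under equal sizes phi is invariant to the common n, so effect sizes are
  well-defined even when only frequency profiles are published.
* **Degenerate tables.** Categories empty in both populations are pooled
  out (with the dropped names reported) before testing; a table with fewer
  than two non-empty categories is an error, as is a zero-total table.

## The synthetic-cohort simulator

`simulate_cohort()` draws, per sample, two haplotypes i.i.d. from
$(h_1, h_2, h_{17})$ and converts them to marker genotypes — i.e., it
inverts the Hardy–Weinberg model above, so the LD constraint holds by
construction. Randomness is consumed as a fixed-width block of four
uniforms per sample from one seeded stream, making the first $k$ samples
identical across runs that differ only in cohort size. Non-canonical
carriers can be injected by replacement at a configurable rate capped at
1% (default 0; 0.000045 reproduces the reported real-world carrier rate);
replacement is used because no frequency model exists for cis \*2–\*17
haplotypes. The simulator deliberately has **no genotyping-error,
missingness, or admixture model**: passing tests demonstrate correctness
of the calling, dosing and estimation machinery under clean HWE data, not
robustness to assay artefacts or population structure in real cohorts.

`make_fixture_suite()` freezes a deterministic demo set (the 9-sample
haplogenotype enumeration, six synthetic allele-frequency populations
spanning a PM-dominant to a \*17-rich regime, and a 50-sample simulated
VCF).

## Problem sizes and tolerances in the test suite

Stochastic checks run at sizes chosen to make 4-standard-error bounds
sharp while keeping the suite fast: probability conservation of the HWE
expansion is checked on 10,000 random simplex points at $10^{-9}$;
parameter recovery at $n = 10{,}000$ samples across three seeds (and at
$n = 100{,}000$ for the simulator's law-of-large-numbers property);
Monte Carlo vs asymptotic p-value agreement at $n = 2000$ per population
with 100,000 replicates. An internal-consistency check back-solves the
haplotype frequencies of a strongly PM-dominant population from its
printed extremes (PM 51.0%, UM 0.4%) and verifies they round-trip through
the HWE expansion: $h \approx (0.2226, 0.7141, 0.0632)$.

## Known limitations

* Only \*1, \*2, \*17 are modelled. Other no-function alleles (\*3 and
  rarer) are negligible in most populations but not in all (notably some
  East Asian populations for \*3); their mass is dropped at
  renormalization, with a warning.
* Reproducing published cross-population effect sizes requires the
  external allele-frequency table they were computed from (e.g. a
  PharmGKB export massaged into the `population,allele,frequency` CSV
  dialect); the package ships only synthetic population fixtures.
* The rule table encodes a specific published proposal; it is not a
  substitute for local clinical guidance, and the AM class in particular
  is provisional pending pharmacokinetic confirmation.
* VCF handling is deliberately minimal: GT-field genotypes at two rsID-
  matched markers, no imputation, no genotype likelihoods, no support for
  other star alleles' defining variants.
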