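---
title: "Simulating unnecessarily failed stem-cell-donor searches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating unnecessarily failed stem-cell-donor searches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Unrelated hematopoietic stem-cell transplantation requires a donor whose HLA
phenotype matches the patient's at high resolution across HLA-A, -B, -C,
-DRB1 and -DQB1 (a 10/10 match). Registries, however, know many of their
donors only through partial typings: some loci untyped, others typed at low
resolution. When no fully typed match is on file, a search coordinator
requests additional typings for the most promising partially typed donors,
under a budget. A search can therefore end without a match *even though a
fully matched donor is registered* — an **unnecessarily failed search
(UFS)**, the "hidden donor" problem. `ufsim` simulates this process end to
end on virtual registries and quantifies the UFS share as a function of
registry size, typing-profile composition, search strategy, typing-request
budget and haplotype diversity.

## Model and assumptions

**Population model.** A haplotype is a five-locus allele combination; a
population is a normalized haplotype-frequency (HF) set (`hf_set`). Under
random mating, an individual is two i.i.d. haplotype draws, so phenotype
probabilities follow Hardy–Weinberg proportions by construction:
$P(\text{phenotype}) = \sum_{\{h_1,h_2\}} 2f_1 f_2$ (or $f^2$ for a
homozygous pair) over all pair decompositions.

**Typing profiles.** Every donor carries one of five typing profiles
(`typing_profiles()`): from all five loci at high resolution (#1) down to
HLA-A/B at low resolution only (#4 and #5, identical in content; #5 labels
the donors a search strategy may refuse to type). Masking a phenotype under
a profile (`mask_phenotype()`) is the only observation process: untyped loci
are dropped and low-resolution loci keep only the mapped image of each
allele. Low resolution is realized by an explicit `resolution_map()`;
the default map truncates each two-field code at the first `:`, a
first-field molecular dialect. Whether real-world low-resolution typings are
serological or first-field molecular is left to the map file — the machinery
is agnostic.

**Matching probability.** For a fully typed patient $p$ and a donor known
only through observation $o$,
$$\mathrm{MP}(p, o) \;=\; \frac{P(\text{phenotype} = p)}{P(\text{mask} = o)}$$
when $p$ could have produced $o$, and 0 otherwise
(`matching_probability()`). Sums run over the finite haplotype support;
phenotypes outside it have zero mass, which makes the computation exact.
The efficient path buckets haplotypes by masked image, so the denominator is
a sum of `f_i * F(complement image)` over the few candidate haplotypes
compatible with the observation. Tests verify exact agreement with an
independent brute-force enumeration (`mp_bruteforce_oracle()`). No MP floor
is applied — arbitrarily small positive MPs stay rankable.

**Search policy.** For each patient (`run_search()`,
`run_panel_search()`): (1) if a fully typed matching donor exists the
search is `READY` with zero requests (lowest donor id on ties); (2)
otherwise compatible, incompletely typed donors are ranked by MP descending
and typed one by one — each request unmasks the donor's true phenotype —
stopping at the first confirmed match (`FOUND_IN_SEARCH`) or when the budget
$T$ is exhausted; (3) a failed search is `UFS` if a true match exists
anywhere in the registry, else `NO_MATCH_EXISTS`. Strategy `A` allows
typing requests to profile-#5 donors, strategy `B` avoids them. Donors whose
MP agrees to 12 significant digits form a tie group ordered by a seeded
random permutation; the rounding realizes "identical MP" robustly in
floating point. A typed non-matching donor is conclusively excluded and the
candidate order is frozen at search start — re-ranking could not change the
order anyway, because the remaining donors' MPs depend only on the patient
and their own observations. When fewer than $T$ positive-MP candidates
exist the search exhausts them and stops.

## Estimation and diagnostics

**EM haplotype frequencies.** `em_estimate()` fits multilocus haplotype
frequencies from unphased, possibly masked observations: the E-step
distributes each observation's weight over the consistent ordered haplotype
pairs proportionally to $f_{h_1} f_{h_2}$, the M-step renormalizes expected
haplotype counts. The log-likelihood trace is asserted non-decreasing at
every iteration; convergence is a relative log-likelihood change below
`tol` (default `1e-8`, `max_iter = 1000`). Initialization is uniform over
the consistent support by default, with an optional seeded random start.
The support is whatever is consistent with at least one observation — with
heavily masked data the maximum-likelihood solution is genuinely
non-unique, and the estimate spreads mass over unidentifiable haplotypes;
tests therefore check recovery only on identifiable designs. Estimated
frequencies below the resolution limit $1/n$ (`resolution_limit()`) are
flagged as possible EM artifacts in `tidy()`, never pruned automatically.
The module targets desk-scale correctness; industrial-scale sparse EM over
hundreds of thousands of donors is out of scope.

**Hardy–Weinberg diagnostics.** `hwe_report()` converts phenotypes to
broad serological antigens per locus and reports observed/expected
homozygosity and the bounded effect size
$W_n = \sqrt{X^2 / (n(k-1))}$, a Cramér-style normalization of the Pearson
statistic over genotype categories ($k$ = number of alleles). The exact
effect-size formula behind published registry reports is not spelled out in
the literature we reproduce; this form satisfies every property those
reports state — range $[0,1]$, zero exactly at HWE proportions, small
values near HWE at large $n$ — and is cross-checked in tests against an
independently coded evaluation. The homozygosity difference is reported as
`delta = observed - expected` (positive = excess homozygosity); published
tables are not always consistent in this sign convention, so the package
fixes one.

## Synthetic data: what it emulates, what it does not

Real registry HF distributions are unavailable at desk scale, so
`gen_hf_distribution()` builds synthetic five-locus distributions: distinct
random haplotypes over per-locus allele pools with a power or geometric
rank-decay law. `gen_reference_hf()` calibrates the decay by exponent
tilting (`reshape_diversity()`) so that the top-20 cumulative frequency
equals 25.1%, the value published for the German donor population — the one
concentration statistic available in print. Diversity variants re-tilt the
same distribution to top-50 cumulative targets of 0.22 (more diverse) and
0.48 (less diverse); the calibrated reference falls strictly between the
two (verified in the test suite), so the variants bracket it, standing in
for the unpublished extremes of the ethnic-diversity study the original
design referenced. The tilt family
$f_i^\gamma/\sum_j f_j^\gamma$ is the simplest one-parameter slope control
that preserves rank order; $\gamma$ is found by monotone root-finding to
within $10^{-6}$ of the target.

The generator reproduces a heavy-tailed rank-frequency law and exact HWE
sampling. It does **not** reproduce real linkage structure between loci
beyond what the rank law induces, allele-frequency realism per locus, or
the long tail of tens of thousands of rare haplotypes at full scale.
Consequently, passing the scaled suite demonstrates the correctness and the
qualitative comparative statics of the search machinery (directions of the
size, mix, diversity, strategy and budget effects), not the numerical UFS
levels of any real registry.

## Scaled study design and numerical choices

The scaled suite (`scenario_grid("scaled")`) uses 5,000 haplotypes,
registries of 20,000/50,000/100,000 donors around a 50,000-donor reference,
2,000 patients, a budget of 3 requests and 3 repeats, with the strategy
comparison simulated at budget 10 and smaller budgets derived from the
request logs (each patient's request sequence under a smaller budget is a
prefix of the simulated one, so the derivation is exact; verified in
tests). These sizes keep one full suite within minutes on a single core
while leaving every comparison direction resolvable above its Monte-Carlo
noise. The full-scale design (registries of 0.6M–4.6M donors, 30,000
haplotypes, 10,000 patients) is exposed as `scenario_grid("full")` and runs
for hours.

Repeats regenerate the registry *and* the patient panel from seeds derived
deterministically from the base seed (`base`, repeat index, stage);
across-repeat standard deviations use denominator $n-1$. Each patient's
tie-break stream derives from the panel seed and the patient id, so results
are independent of processing order. Profile assignment within a registry
is stratified-exact (largest-remainder apportionment, then a seeded
shuffle) rather than i.i.d. multinomial: the study design specifies a
registry *composition*, and exact stratification removes a nuisance
variance component. Frequencies are stored as probabilities in $[0,1]$;
percent appears only at presentation. All randomness flows through
explicitly passed seeds; no function touches the global RNG state without
restoring it.

Degenerate inputs are defined, not accidental: a fully untyped observation
has probability mass 1; a patient incompatible with an observation has MP
0; a monomorphic locus has $W_n = 0$; empty patient panels are rejected
(nothing to summarize); diversity targets outside the attainable range
$(k/n, 1)$ raise an error naming the range.

## Interfaces

Tables move through plain TSV (frequency tables, resolution maps, registry
observed/hidden files, patient panels), YAML scenario configurations and a
JSON run manifest (`run_manifest()`) with input digests and seeds. The
registry's observed and hidden phenotypes are written to *separate* files so
a search can be executed against the observed file alone — the simulation
mirrors the information hygiene of a real registry, and tests verify that
ranking is invariant to scrambling the hidden table. The package is
function-first: scripts and vignettes compose the exported functions, and
`scripts/acceptance.R` in the source repository re-runs the scaled study
end to end.

## Worked example

```{r, eval = FALSE}
library(ufsim)

toy <- make_toy_fixture()
patient <- phenotype_from_haplotypes(toy$hfs$haplotype[1], toy$hfs$haplotype[1])
donor_view <- mask_phenotype(patient, 4, toy$map)
matching_probability(patient, donor_view, toy$hfs, toy$map)
#> value 0.390625 = P(patient) 0.25 / P(observation) 0.64

cfg <- scenario_config(size = 50000, n_patients = 2000, repeats = 3, seed = 1)
summary_ref <- run_scenario(cfg)
summary_ref$summary          # outcome shares, mean +- sd over repeats
summary_ref$conditional      # UFS share among coordinator-dependent searches
autoplot(summary_ref)
```

## Known limitations

Single population for donors and patients; no donor attrition or
availability; no intermediate-resolution typings; no 9/10 mismatch
acceptance; no time dimension or shared typing budgets across patients; no
ambiguity (NMDP) codes or real IMGT/HLA nomenclature parsing — allele
tokens, including `g`-group suffixes, are atomic strings.
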