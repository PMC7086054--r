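---
title: "Functional MHC diversity from presence/absence genotypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional MHC diversity from presence/absence genotypes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhcdiv)
```

## The data model and its central constraint

Amplicon sequencing of duplicated MHC genes returns, per individual, an
unphased *set* of allele sequences. Because paralogous loci share alleles
through concerted evolution, alleles cannot be assigned to loci; an
individual with three detected variants may be carrying them in any
dosage across an unknown number of loci. `mhcdiv` therefore never
represents copy number: a genotype is a set (`MultilocusGenotype` in the
long `individual, site, allele` table), the frequency notion is the
*incidence frequency* (share of individuals carrying an allele), and
every downstream statistic is chosen to be well-defined on sets.

The reading frame of an amplicon fragment is primer-dependent and not
recoverable from the sequence itself, so `frame_offset` is an explicit
input (default 0, trailing incomplete codon trimmed). All translation
uses the standard genetic code via Biostrings; catalogs reject ambiguity
codes, length heterogeneity and stop codons outright, naming the
offending records, because a single corrupt allele silently poisons
every pairwise statistic downstream.

## Supertype clustering

Functional similarity of MHC molecules is carried by the biochemistry of
their antigen-binding residues, not by overall sequence identity. Each
positively selected site (PSS — an *input*, typically from codon-model
selection tests run elsewhere) is encoded as the five z-descriptors of
its residue, giving an alleles × 5·|PSS| matrix; alleles identical at
all PSS collapse to identical rows by construction.

k-means (best of `n_starts = 50` restarts, squared-Euclidean) is scored
with `BIC(k) = n ln(WSS_k/n) + k ln(n)`. Two numerical points deserve
honesty:

- With clusters that have internal spread, this BIC keeps creeping
  downward past the true k — the `k ln(n)` penalty has no dimension
  factor — so the curve's *argmin* overfits. This mirrors the behaviour
  of the standard population-genetics implementation of the same scan,
  where the user reads the elbow off the curve. The elbow is therefore
  the decision rule, not the argmin.
- "Decreases by a negligible amount" is operationalized as: the smallest
  k after which **every** subsequent decrease is below `drop_threshold`
  (default 0.01) of the curve's total range. Requiring *all* later drops
  to be small prevents a flat shoulder ahead of a large cliff from
  terminating the scan early, which demonstrably happens on 89-allele
  catalogs. The threshold is exposed, a manual `k` override is honoured,
  and the full BIC curve is always written out so a reader can audit the
  choice. With a default threshold of 0.01 the rule is calibrated for
  near-zero within-cluster spread (the regime produced by supertype-
  specific residue pools); for noisy descriptor clouds a looser
  threshold (~0.05) reads the elbow more robustly.
- When `k` reaches the number of distinct rows, `WSS = 0`; the scan
  floors it at `1e-8` to keep the BIC finite.

Cluster labels are canonicalized by first appearance in catalog order,
making the labelling a deterministic function of the partition. Ties and
restarts are controlled by a mandatory seed. No PCA pre-reduction and no
discriminant-analysis refinement are applied: allele counts are small,
and it is the assignment — not a visualization — that downstream stages
consume.

## Index of association

For two alleles and every unordered pair of individuals, `d_a(i,j)`
indicates disagreement in carrying allele a. The index

$$I_A = \frac{\mathrm{Var}(d_a + d_b)}{\mathrm{Var}(d_a) + \mathrm{Var}(d_b)} - 1
      = \frac{2\,\mathrm{Cov}(d_a, d_b)}{\mathrm{Var}(d_a) + \mathrm{Var}(d_b)}$$

uses population (divide-by-N) moments over all pairs. `I_A = 1` iff the
two mismatch vectors coincide — note this includes the *complement*
pattern (b present exactly where a is absent, at equal incidence), so a
co-occurrence report should accompany any I_A = 1 finding. A monomorphic
column leaves the statistic undefined; such pairs are skipped and do not
count towards the Bonferroni denominator.

Because `d_a` depends on the data only through the carrier counts
(n, n_a, n_b) and the co-carrier overlap m, I_A has a closed form in
those four numbers, and the column-permutation null is *exactly* the
hypergeometric law of m. The permutation test draws `m* ~ rhyper`, which
is a faithful realization of the permutation scheme, not an
approximation; tests cross-check it against explicit column shuffles and
an exhaustive-pair brute-force oracle. The add-one estimator
`p = (1 + #{I_A* ≥ I_A}) / (n_perm + 1)` keeps p strictly positive;
the default 99,999 permutations puts the p floor (10⁻⁵) below the
Bonferroni threshold even for thousands of tested pairs.

## Null genotype simulation

The question "do individuals carry more supertypes than chance?" needs a
chance model. The default assembly includes each allele independently
with its observed incidence frequency (preserving marginals exactly,
before rejection); all-zero genotypes are rejected and redrawn, with the
rejection count and the raw pre-rejection marginals stored for audit.
The alternative `fixed_counts` assembly draws each genotype's allele
count from a supplied distribution and fills it by weighted sampling
(weights `f/(1−f)`, conditional-Bernoulli style); it exists because the
mechanism behind "random genotypes" admits both readings and they are
not identical — under Bernoulli assembly the allele-count distribution
is Poisson-binomial, not the observed one. A comparison of real data
against the Bernoulli null therefore mixes two signals (supertype
composition *and* count-shape mismatch); when that matters, rerun with
`assembly = "fixed_counts"`.

Linked mode treats each Bonferroni-significant pair as one inclusion
unit at the mean of its members' incidences — complete linkage, matching
an all-or-none reading of significant association. A `proportional` mode
(pair acts as a unit for a fraction of genotypes equal to its strength,
e.g. its observed I_A) brackets the other reading. Overlapping pairs are
rejected rather than merged into cliques.

Observed counts are compared to the ensemble with a discrete KS test: D
is the sup-distance between the observed ECDF and the ensemble CDF over
the joint support (exact for step functions), and p comes from
Monte-Carlo resampling of observed-size draws from the null CDF
(default 100,000), because the asymptotic continuous-case distribution
is wrong for small discrete samples. A mean-based upper-tail permutation
p accompanies the KS p, since "means differ" and "distributions differ"
are distinct questions and published analyses do not always say which
was asked.

## Diversity statistics

All sequence-level statistics operate on *unique alleles, unweighted*,
because dosage is unknown (incidence weighting is available behind a
flag). π is the mean pairwise proportion of differing positions
(p-distance; no multiple-hit correction, consistent with values ≈ 0.1).
The synonymous/nonsynonymous partition follows the classic pathway-
counting method: per-codon synonymous site fractions (denominator 3 per
position; changes to stop codons never count as synonymous) averaged
over the two sequences of a pair, and differences averaged with equal
weight over minimal mutational pathways, excluding pathways through stop
codons (falling back to all pathways only if none is stop-free). Per
pair, syn + nonsyn differences always equal the nucleotide difference
count — a conservation law the tests assert. Pairs with zero synonymous
sites are excluded from the synonymous mean with a warning rather than
zero-filled.

Allelic richness uses individual-record rarefaction,
`A_R = Σ_a [1 − C(N−n_a, g)/C(N, g)]` on presence records, computed on
log-binomials. This is *not* the gene-copy rarefaction of
ploidy-assuming tools — presence data cannot express gene copies — so
A_R values are comparable within an analysis but not across conventions.
The default g is the smallest per-site record total.

## Rho differentiation

Rho is reconstructed from between-individual gene identity: the
probability that one allele drawn uniformly from one individual's set
equals one drawn from another's. With Q2 the mean within-site identity
(pairwise: average of the two sites' means; global: pooled over all
within-site pairs with equal pair weight) and Q3 the mean cross-site
identity, `Rho = (Q2 − Q3)/(1 − Q3)`, reported alongside the
linearizing transform `Rho/(1 − Rho)` (infinite at fixation, flagged).
Within-individual identity never enters — this is precisely what makes
the statistic ploidy-independent and applicable to both marker types.

Two small-sample properties of this estimator are worth knowing. Sites
with literally identical genotype multisets do not give exactly 0:
cross-site pairs include identical-individual pairs, which biases Q3
upward at small n (the bias vanishes as 1/n; under label permutation Rho
is centred at 0). And a diploid panel of all-heterozygous individuals
with disjoint allele pairs per site gives Rho = 0.5, not 1 — an
ANOVA-style estimator that removes the within-individual component from
the denominator would give 1, but it would no longer be the
between-individual identity statistic defined here. Significance comes
from permuting individuals between the two sites (add-one, upper tail).

Mantel and partial Mantel tests (Pearson, 719 matrix permutations,
add-one one-tailed p, first matrix permuted) are delegated to vegan with
a pinned permutation design so the requested count is honoured even
where complete enumeration would be possible. Great-circle distances use
the haversine formula with mean Earth radius 6371 km.

## The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions: 89 alleles of 184 nt, 10 planted supertypes, 5 PSS, seven
sites with 16/7/35/27/107/36/89 individuals, allele counts on 2–6
(probabilities 0.25/0.40/0.20/0.10/0.05, mean ≈ 3.3).

- **Catalog.** Supertype anchors are residues chosen greedily to be
  maximally spread in z-space (minimum pairwise distance ≥ `separation`;
  4 is the best attainable for 10 anchors among 20 residues). Non-PSS
  codons descend from one ancestral stop-free sequence with per-allele
  codon replacement at rate 0.04, giving π ≈ 0.1 — the right order for
  MHC amplicons — instead of the ≈ 0.75 of unrelated random sequences.
  `separation = 0` is the negative control: no planted structure,
  clustering recovery at chance.
- **Populations.** Site incidence frequencies perturb dataset-level base
  frequencies (Beta(0.7, 1.4), clamped to [0.03, 0.95]) on the logit
  scale with SD `divergence`; `spatial = TRUE` replaces the independent
  perturbations with allele-specific logit-linear clines along the site
  order, which produces clean isolation by distance on a linear layout.
  Genotypes draw a count, then alleles by conditional-Bernoulli weights;
  linked pairs are sampled as all-or-none units with the stated
  strength; `min_supertypes` resamples genotypes until they span at
  least that many planted supertypes (a divergent-allele-advantage
  population).
- **Microsatellite panel.** Island-model Dirichlet draws per locus with
  concentration `(1/divergence − 1) × n_alleles`; divergence is monotone
  in realized Rho.

What passing tests on these data do **not** show: real amplicon data
carry genotyping artefacts, allele-calling thresholds, shared
polymorphic positions from recombination and recurrent mutation, and
count distributions entangled with incidence — none of which the
generator emulates. Recovery rates quoted in the tests (planted k and
partition in ≥ 95% of seeds, a planted fully linked pair flagged exactly
in ≥ 95%, divergent-advantage populations rejected in ≥ 90%, coupled
divergence detected by Mantel in ≥ 90%) are statements about the method
under its own assumptions.

## Problem sizes, determinism, reproduction

Defaults follow the published conventions (99,999 association
permutations, 50,000-genotype ensembles, 100,000 KS resamples, 719
Mantel permutations); the test suite runs reduced sizes (hundreds to a
few thousand permutations, 5,000–50,000-genotype ensembles) chosen so
the whole suite completes in well under a minute while binomial error
still separates the asserted effects. Every stochastic function takes an
explicit seed; the pipeline derives stage seeds from one master seed and
echoes its full configuration, and rerunning any configuration
reproduces every artifact bit for bit. `scripts/acceptance.R --seed N
--out f.json` recomputes the headline quantities from scratch at the
full default sizes in about a minute.

## Known limitations

- The assembly mechanism of the "random genotypes" null and the exact
  linkage construction are reconstructions; the two provided switches
  (`assembly`, `linkage_mode`) bracket the plausible readings but cannot
  settle which one any particular published analysis used.
- Rho here is the between-individual identity formulation; ANOVA-style
  estimators differ at boundaries (see above) and in small samples.
- Rarefied richness is record-based, not gene-copy-based.
- The elbow rule depends on its threshold wherever clusters have
  internal spread; the BIC curve should always be inspected.
- Supertype assignments inherit k-means' sensitivity to the PSS list:
  the positions are an input, and a different selection-test consensus
  changes the encoding.
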