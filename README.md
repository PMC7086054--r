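# mhcdiv

Functional MHC supertype diversity and population differentiation for
multilocus amplicon genotypes of unknown allele dosage.

## The problem

Amplicon genotyping of duplicated MHC loci (e.g. the class II DRB exon-2
fragment) yields, per individual, a *set* of 2–6 allele sequences that
cannot be assigned to loci: homozygosity and copy number are invisible, so
classical allele frequencies, Hardy–Weinberg machinery and F\_ST do not
apply. `mhcdiv` implements an analysis chain built entirely on
presence/absence data:

- **Supertype clustering.** Each positively selected site (PSS) of every
  allele's translated fragment is replaced by the five physicochemical
  z-descriptors of its residue (Sandberg et al. 1998); k-means over the
  resulting alleles × 5·|PSS| matrix with
  `BIC(k) = n ln(WSS_k/n) + k ln(n)` and an explicit elbow rule groups
  alleles into functional supertypes — alleles that bind similar antigen
  repertoires.
- **Allele association.** For alleles a, b let `d_a(i,j)` indicate that
  individuals i, j differ in carrying a. The index of association
  `I_A = Var(d_a + d_b) / (Var(d_a) + Var(d_b)) − 1
       = 2 Cov(d_a, d_b) / (Var(d_a) + Var(d_b))`
  is 1 exactly under perfect co-segregation; significance comes from
  column permutations (default 99,999) with Bonferroni correction over
  tested pairs.
- **Null genotype simulation.** Artificial genotypes are assembled from
  the observed incidence spectrum (share of carriers per allele), either
  with every allele independent (unlinked null) or with significantly
  associated pairs forced all-or-none (linked null); 50,000 genotypes per
  ensemble. Observed individual supertype counts are compared to the null
  with a discrete Kolmogorov–Smirnov test (Monte-Carlo p) and a
  mean-based permutation test. An observed mean *above* the unlinked null
  is the signature of divergent allele advantage.
- **Diversity statistics.** Per site: allele and private-allele counts,
  rarefied allelic richness `A_R = Σ_a [1 − C(N−n_a, g)/C(N, g)]`,
  alleles/supertypes per individual, segregating sites, nucleotide
  diversity π and its Nei–Gojobori synonymous/nonsynonymous partition
  (pathway counting, no distance correction), and the mean
  within-individual amino-acid p-distance at PSS.
- **Differentiation.** Rho compares between-individual gene identity
  within sites (Q2) and across sites (Q3): `Rho = (Q2 − Q3)/(1 − Q3)`.
  Because within-individual identity never enters, Rho is independent of
  ploidy and within-individual diversity, and applies equally to the MHC
  presence data and to a diploid microsatellite panel. Pairwise matrices
  are reported as `Rho/(1 − Rho)` with permutation p-values; isolation by
  distance uses Mantel and partial Mantel tests (719 permutations).
- **Synthetic data.** Generators with stored ground truth emulate the
  study conditions (89 alleles of 184 nt, 10 planted supertypes, 5 PSS,
  seven sites with 16–107 individuals, linked pairs, divergence and
  isolation-by-distance knobs) so every stage is testable offline.

## Worked example

```r
library(mhcdiv)

ct  <- make_allele_catalog(n_alleles = 30, planted_k = 5, seed = 2)
model <- cluster_supertypes(ct$catalog, ct$truth$pss_positions,
                            k_range = 1:10, seed = 3)
model
#> Supertype model: k = 5 supertypes over 30 alleles
#> supertype
#> 1 2 3 4 5
#> 6 6 6 6 6

pop <- make_populations(ct, n_sites = 3,
                        individuals_per_site = c(20, 25, 30),
                        divergence = 0.3, seed = 4)
ens <- simulate_unlinked(incidence_spectrum(pop$dataset), 5000,
                         seed = 5, model = model)
compare_supertype_means(pop$dataset, model, ens,
                        n_resample = 2000, seed = 6)
#> Observed mean supertypes/individual: 2.80 (n = 75)
#> Null (unlinked) mean: 2.76 over 5000 genotypes
#> Discrete KS: D = 0.091 , p = 0.193 ; mean-based upper-tail p = 0.384
```

Here the population was assembled without any supertype advantage, and
the comparison correctly finds nothing: the observed mean (2.80) sits
within Monte-Carlo error of the unlinked null (2.76), KS p = 0.19. A
population forced to span ≥3 supertypes per genotype
(`min_supertypes = 3`) is rejected with p < 0.001.

The full pipeline — clustering, association screen, null simulations per
site group, diversity table, Rho matrices, Mantel tests, run log — runs
from one seeded configuration:

```r
res <- run_all(run_config(simulate = TRUE, seed = 1), "out/")
```

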