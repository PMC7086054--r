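test_that("allele and private-allele counts follow set logic", {
  d <- toy_dataset()
  # X carries a1,a2,a3; Y carries a1,a2,a3 -> no private alleles
  expect_equal(allele_counts(d, "X"), list(A = 3L, A_priv = 0L))
  single <- suppressWarnings(mhc_dataset(
    toy_catalog(),
    data.frame(individual = c("i1", "i1"), site = "Z",
               allele = c("a1", "a2"))))
  expect_equal(allele_counts(single, "Z"), list(A = 2L, A_priv = 2L))
  expect_error(allele_counts(d, "nope"), "unknown site")
})

test_that("rarefied richness matches subset enumeration and its bounds", {
  cat3 <- toy_catalog()
  d <- suppressWarnings(mhc_dataset(
    cat3, data.frame(individual = c("i1", "i1", "i2", "i3"),
                     site = "X", allele = c("a1", "a2", "a1", "a3"))))
  # records (a1: 2, a2: 1, a3: 1); g = 2 -> 5/6 + 1/2 + 1/2
  expect_equal(rarefied_richness(d, "X", 2), 5 / 6 + 1 / 2 + 1 / 2)
  expect_equal(rarefied_richness(d, "X", 4), 3)   # g = N -> A
  expect_equal(rarefied_richness(d, "X", 1), 1)   # one draw, one allele
  ar <- vapply(1:4, function(g) rarefied_richness(d, "X", g), 0)
  expect_true(all(diff(ar) >= 0))
  expect_error(rarefied_richness(d, "X", 5), "g must lie")
})

test_that("segregating sites count polymorphic positions", {
  c1 <- allele_catalog(c(a = "AAA", b = "AAA"))
  expect_equal(segregating_sites(c1), 0L)
  c2 <- allele_catalog(c(a = "AAA", b = "AAT"))
  expect_equal(segregating_sites(c2), 1L)
  c3 <- allele_catalog(c(a = "AAA", b = "AAT", c = "ATT"))
  expect_equal(segregating_sites(c3), 2L)
  expect_error(segregating_sites(allele_catalog(c(a = "AAA")), "a"), "2 alleles")
})

test_that("nucleotide diversity equals mean pairwise mismatch", {
  c1 <- allele_catalog(c(a = "AAAACC", b = "AAAACC"))
  expect_equal(nucleotide_diversity(c1), 0)
  c2 <- allele_catalog(c(a = "AAAACCC", b = "AATTCCC"))
  # differs at 2 of 7 positions
  expect_equal(nucleotide_diversity(c2), 2 / 7)
  c3 <- allele_catalog(c(a = "AAAA", b = "AATT", c = "AAAT"))
  expect_equal(nucleotide_diversity(c3), mean(c(0.5, 0.25, 0.25)))
  # oracle equivalence on a random catalog
  ct <- make_allele_catalog(n_alleles = 6, length_nt = 30, planted_k = 2,
                            pss_positions = c(2L, 5L), seed = 3)
  expect_equal(nucleotide_diversity(ct$catalog),
               brute_pi(ct$catalog$sequences), tolerance = 1e-12)
})

test_that("Nei-Gojobori components follow the genetic code", {
  # Phe/Phe third-position change: purely synonymous
  ng1 <- nei_gojobori(allele_catalog(c(a = "TTT", b = "TTC")))
  expect_equal(ng1$pairs$nonsyn_diffs, 0)
  expect_equal(ng1$pairs$syn_diffs, 1)
  expect_gt(ng1$pairs$syn_sites, 0)
  expect_equal(ng1$pi_nonsyn, 0)

  # Met/Ile: a nonsynonymous third-position change; ATG has no synonymous
  # sites, ATA contributes 2/3, so the pair mean is 1/3 with zero syn diffs
  ng2 <- nei_gojobori(allele_catalog(c(a = "ATG", b = "ATA")))
  expect_equal(ng2$pairs$syn_diffs, 0)
  expect_equal(ng2$pairs$nonsyn_diffs, 1)
  expect_equal(ng2$pairs$syn_sites, 1 / 3)
  expect_equal(ng2$pi_syn, 0)
  expect_gt(ng2$pi_nonsyn, 0)

  # Lys/Arg
  ng3 <- nei_gojobori(allele_catalog(c(a = "AAA", b = "AGA")))
  expect_equal(ng3$pairs$nonsyn_diffs, 1)
  expect_equal(ng3$pairs$syn_diffs, 0)
})

test_that("pathway averaging matches exhaustive enumeration and conserves diffs", {
  set.seed(21)
  codons <- setdiff(
    apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                      c("A","C","G","T")), 1, paste, collapse = ""),
    c("TAA", "TAG", "TGA"))
  for (rep in 1:25) {
    pair <- sample(codons, 2)
    ng <- nei_gojobori(allele_catalog(
      stats::setNames(pair, c("x", "y"))))
    oracle <- brute_codon_diffs(pair[1], pair[2])
    expect_equal(ng$pairs$syn_diffs, unname(oracle["syn"]), tolerance = 1e-12)
    expect_equal(ng$pairs$nonsyn_diffs, unname(oracle["nonsyn"]),
                 tolerance = 1e-12)
    # conservation: components sum to the nucleotide difference count
    nd <- sum(strsplit(pair[1], "")[[1]] != strsplit(pair[2], "")[[1]])
    expect_equal(ng$pairs$syn_diffs + ng$pairs$nonsyn_diffs, nd,
                 tolerance = 1e-12)
  }
  # site counts + diffs behave on multi-codon sequences too
  ct <- make_allele_catalog(n_alleles = 4, length_nt = 18, planted_k = 2,
                            pss_positions = c(1L, 4L), seed = 9)
  ng <- nei_gojobori(ct$catalog)
  m <- do.call(rbind, strsplit(ct$catalog$sequences, ""))
  for (j in seq_len(nrow(ng$pairs))) {
    nd <- sum(m[ng$pairs$allele_1[j], ] != m[ng$pairs$allele_2[j], ])
    expect_equal(ng$pairs$syn_diffs[j] + ng$pairs$nonsyn_diffs[j], nd,
                 tolerance = 1e-12)
    expect_equal(ng$pairs$syn_sites[j] + ng$pairs$nonsyn_sites[j], 18)
  }
})

test_that("within-individual PSS distance averages pairwise residue mismatch", {
  cat5 <- allele_catalog(c(
    a = strrep("AAA", 5),                               # K K K K K
    b = paste0("AGA", "AGA", "AAA", "AAA", "AAA"),      # R R K K K
    c = paste0("AAA", "AAA", "ACA", "ACA", "ACA")))     # K K T T T
  expect_equal(individual_pss_distance(c("a", "a"), cat5, 1:5), 0)
  expect_equal(individual_pss_distance(c("b", "c"), cat5, 1:5), 1.0)
  expect_equal(individual_pss_distance(c("a", "b", "c"), cat5, 1:5),
               mean(c(2, 3, 5) / 5))
  expect_error(individual_pss_distance(c("a", "b"), cat5, integer(0)),
               "no PSS")
  expect_error(individual_pss_distance("a", cat5, 1:5), ">= 2 alleles")
})

test_that("the diversity table recovers planted quantities per site", {
  cat3 <- allele_catalog(c(a = "AAAA", b = "AATT", c = "AAAT"))
  g <- data.frame(
    individual = c("i1", "i1", "i2", "i2", "i3", "i3", "i4"),
    site = c("X", "X", "X", "X", "Y", "Y", "Y"),
    allele = c("a", "b", "a", "c", "a", "b", "c"))
  d <- suppressWarnings(mhc_dataset(cat3, g))
  model <- structure(list(k = 2L,
                          assignment = c(a = 1L, b = 2L, c = 2L)),
                     class = "supertype_model")
  tab <- suppressWarnings(diversity_table(d, model = model,
                                          pss_positions = 1L, g = 3))
  x <- tab[tab$site == "X", ]
  expect_equal(x$n, 2)
  expect_equal(x$A, 3)
  expect_equal(x$A_priv, 0)
  expect_equal(x$S, 2L)
  expect_equal(x$pi, mean(c(0.5, 0.25, 0.25)))
  expect_equal(x$IndA_mean, 2)
  expect_equal(x$N_S, 2L)
  expect_equal(x$IndS_mean, 2)

  # one-individual site still yields a row, undefined fields flagged NA
  g2 <- rbind(g, data.frame(individual = "i9", site = "Z", allele = "a"))
  d2 <- suppressWarnings(mhc_dataset(cat3, g2))
  tab2 <- suppressWarnings(diversity_table(d2, model = model, g = 1))
  z <- tab2[tab2$site == "Z", ]
  expect_equal(z$n, 1)
  expect_equal(z$A, 1)
  expect_true(is.na(z$S) && is.na(z$pi))

  # pooled group rows
  tab3 <- suppressWarnings(diversity_table(
    d, model = model, g = 3, groups = list(all = c("X", "Y"))))
  expect_true("all" %in% tab3$site)
  expect_equal(tab3$A[tab3$site == "all"], 3)
})
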