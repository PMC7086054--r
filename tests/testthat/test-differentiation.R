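fixed_two_site_dataset <- function() {
  catalog <- allele_catalog(c(a = "AAATTT", b = "CCCGGG"))
  g <- data.frame(
    individual = sprintf("i%d", 1:10),
    site = rep(c("R", "S"), each = 5),
    allele = rep(c("a", "b"), each = 5))
  suppressWarnings(mhc_dataset(catalog, g))
}

test_that("gene identity is the match probability of uniform draws", {
  expect_equal(gene_identity("a", "a"), 1)
  expect_equal(gene_identity(c("a", "b"), c("c", "d")), 0)
  expect_equal(gene_identity(c("a", "b"), c("a", "c")), 0.25)
  expect_error(gene_identity(character(0), "a"), "empty")
  # diploid: one shared copy out of 2x2 draws at one locus
  expect_equal(gene_identity_diploid(matrix(c(1, 2), 1), matrix(c(1, 3), 1)),
               0.25)
  expect_equal(gene_identity_diploid(matrix(c(1, 1), 1), matrix(c(1, 1), 1)),
               1)
  expect_true(is.na(gene_identity_diploid(matrix(c(NA, NA), 1),
                                          matrix(c(1, 2), 1))))
})

test_that("sites fixed for distinct alleles give Rho = 1", {
  d <- fixed_two_site_dataset()
  expect_equal(rho_pairwise(d, "R", "S"), 1)
  g <- rho_global(d)
  expect_equal(g$rho, 1)
  expect_true(is.infinite(g$transformed))
  # diploid analogue, all heterozygous with disjoint pairs per site:
  # Q2 = 0.5 (two shared copies out of four draws), Q3 = 0, so the
  # between-individual identity estimator gives Rho = 0.5
  arr <- array(NA_integer_, c(6, 1, 2))
  arr[1:3, 1, ] <- rep(c(1L, 2L), each = 3)
  arr[4:6, 1, ] <- rep(c(3L, 4L), each = 3)
  panel <- structure(list(alleles = arr, sites = rep(c("R", "S"), each = 3),
                          ids = sprintf("i%d", 1:6)),
                     class = "diploid_panel")
  expect_equal(rho_pairwise(panel, "R", "S"), 0.5)
  # fixed homozygous disjoint sites do reach Rho = 1
  arr2 <- array(NA_integer_, c(6, 1, 2))
  arr2[1:3, 1, ] <- 1L
  arr2[4:6, 1, ] <- 2L
  panel2 <- structure(list(alleles = arr2, sites = rep(c("R", "S"), each = 3),
                           ids = sprintf("i%d", 1:6)),
                      class = "diploid_panel")
  expect_equal(rho_pairwise(panel2, "R", "S"), 1)
})

test_that("label-permuted pools show no differentiation", {
  ct <- make_allele_catalog(n_alleles = 20, planted_k = 4, seed = 3)
  pop <- make_populations(ct, n_sites = 2, individuals_per_site = 40,
                          divergence = 0, seed = 3)
  r <- rho_pairwise(pop$dataset, "S1", "S2")
  expect_lt(abs(r), 0.05)
  t <- rho_permutation_test(pop$dataset, "S1", "S2", n_perm = 199, seed = 3)
  expect_gt(t$p, 0.05)
  expect_gte(t$p, 1 / 200)
})

test_that("permutation p-values are uniform under exchangeability", {
  ct <- make_allele_catalog(n_alleles = 15, planted_k = 3, seed = 4)
  ps <- vapply(1:30, function(s) {
    pop <- make_populations(ct, n_sites = 2, individuals_per_site = 15,
                            divergence = 0, seed = 100 + s)
    rho_permutation_test(pop$dataset, "S1", "S2", n_perm = 99,
                         seed = s)$p
  }, 0)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("Rho approaches zero as identical-composition samples grow", {
  # identical multisets of genotypes: cross-site self-pairs bias Rho
  # negative at small n; the bias vanishes as 1/n
  catalog <- allele_catalog(c(a = "AAATTT", b = "CCCGGG"))
  make_pair <- function(n_per) {
    g <- data.frame(
      individual = sprintf("i%d", seq_len(2 * n_per)),
      site = rep(c("R", "S"), each = n_per),
      allele = rep(rep(c("a", "b"), n_per / 2), 2))
    suppressWarnings(mhc_dataset(catalog, g))
  }
  r_small <- rho_pairwise(make_pair(4), "R", "S")
  r_large <- rho_pairwise(make_pair(40), "R", "S")
  expect_lt(abs(r_large), abs(r_small))
  expect_lt(abs(r_large), 0.05)
})

test_that("Mantel statistics behave on identities, affine maps and negation", {
  set.seed(6)
  m1 <- as.matrix(dist(matrix(rnorm(14), 7, 2)))
  expect_equal(mantel_test(m1, m1, n_perm = 99, seed = 1)$r, 1)
  expect_equal(mantel_test(m1, 2 * m1 + 1, n_perm = 99, seed = 1)$r, 1)
  mt <- mantel_test(m1, -m1, n_perm = 719, seed = 1)
  expect_equal(mt$r, -1)
  expect_gt(mt$p, 0.9)
  const <- matrix(1, 7, 7); diag(const) <- 0
  expect_warning(mc <- mantel_test(m1, const * 0, n_perm = 99), "constant")
  expect_true(is.na(mc$r))
})

test_that("partial Mantel handles constant and collinear covariates", {
  set.seed(8)
  m1 <- as.matrix(dist(matrix(rnorm(16), 8, 2)))
  m2 <- as.matrix(dist(matrix(rnorm(16), 8, 2)))
  const <- matrix(1, 8, 8); diag(const) <- 0
  pm <- partial_mantel_test(m1, m2, const, n_perm = 99, seed = 2)
  expect_equal(pm$r, mantel_test(m1, m2, n_perm = 99, seed = 2)$r)
  expect_warning(
    deg <- partial_mantel_test(m1, m2, m1, n_perm = 99, seed = 2),
    "collinear")
  expect_true(is.na(deg$r))
  # planted confounding: m1 = m3 + noise, m2 independent -> partial r small
  noise <- as.matrix(dist(rnorm(8, sd = 0.05)))
  m3 <- m1 + noise
  pr <- partial_mantel_test(m1, m2, m3, n_perm = 99, seed = 3)
  expect_lt(abs(pr$r), 0.5)
})

test_that("geographic distances respect conventions and the triangle bound", {
  cd <- data.frame(site = c("p", "q"), x = c(0, 0), y = c(0, 90))
  m <- geographic_distance(cd, lonlat = TRUE)
  expect_equal(m["p", "q"], 10007.5, tolerance = 1e-3)
  expect_equal(m["p", "p"], 0)
  planar <- geographic_distance(
    data.frame(site = c("p", "q"), x = c(0, 3), y = c(0, 4)), lonlat = FALSE)
  expect_equal(planar["p", "q"], 5)
  set.seed(10)
  cd3 <- data.frame(site = c("u", "v", "w"), x = runif(3, -90, 90),
                    y = runif(3, -60, 60))
  g <- geographic_distance(cd3, lonlat = TRUE)
  expect_lte(g["u", "w"], g["u", "v"] + g["v", "w"] + 1e-9)
})

test_that("differentiation matrices are symmetric with transformed cells", {
  ct <- make_allele_catalog(n_alleles = 15, planted_k = 3, seed = 5)
  pop <- make_populations(ct, n_sites = 3, individuals_per_site = 15,
                          divergence = 1.5, seed = 5)
  dm <- rho_matrix(pop$dataset, n_perm = 49, seed = 5, marker_label = "MHC")
  expect_equal(dm$rho, t(dm$rho))
  expect_equal(diag(dm$rho), stats::setNames(rep(0, 3), dm$sites))
  ut <- upper.tri(dm$rho)
  expect_equal(dm$rho_transformed[ut], dm$rho[ut] / (1 - dm$rho[ut]))
  expect_true(all(dm$p_values[ut] >= 1 / 50))
  f <- tempfile(fileext = ".tsv")
  write_differentiation_matrix(dm, f)
  expect_true(file.exists(f))
})
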