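#' Pairwise index of association between two alleles
#'
#' For every unordered pair of individuals, let `d_a` be 1 when the pair
#' differs in the presence of allele a (and likewise `d_b`). The index of
#' association is
#' `I_A = Var(d_a + d_b) / (Var(d_a) + Var(d_b)) - 1
#'      = 2 Cov(d_a, d_b) / (Var(d_a) + Var(d_b))`,
#' with population (divide-by-N) moments over the n(n-1)/2 pairs. It is 1
#' exactly when the two mismatch vectors coincide, i.e. the alleles
#' co-segregate perfectly. Because `d_a` depends on the columns only through
#' the carrier counts and their overlap, the statistic is evaluated in
#' closed form from the 2x2 carrier table; an exhaustive-pair computation
#' gives identical values.
#'
#' @param incidence binary individuals-by-alleles matrix
#'   (see [incidence_matrix]).
#' @param a,b column names or indices of the two alleles.
#' @return `I_A`, or `NA` with a warning when either column is monomorphic
#'   (the index is undefined there, not zero).
#' @export
pairwise_ia <- function(incidence, a, b) {
  x <- incidence[, a]; y <- incidence[, b]
  n <- length(x)
  na <- sum(x); nb <- sum(y)
  if (na == 0L || na == n || nb == 0L || nb == n) {
    warning("monomorphic allele column; I_A undefined")
    return(NA_real_)
  }
  .ia_from_counts(n, na, nb, sum(x * y))
}

# I_A from the joint carrier counts: n individuals, na carriers of a,
# nb of b, m carrying both. Over the N = n(n-1)/2 pairs the mismatch
# indicators have means Sa/N, Sb/N and cross-product mean Sab/N.
# Vectorized over m.
.ia_from_counts <- function(n, na, nb, m) {
  N <- n * (n - 1) / 2
  Sa <- na * (n - na)
  Sb <- nb * (n - nb)
  Sab <- m * (n - na - nb + m) + (na - m) * (nb - m)
  ma <- Sa / N; mb <- Sb / N
  va <- ma - ma^2
  vb <- mb - mb^2
  cab <- Sab / N - ma * mb
  2 * cab / (va + vb)
}

#' Permutation p-value for a pairwise index of association
#'
#' The null is built by randomly permuting allele b's column across
#' individuals; a uniform permutation changes the statistic only through
#' the co-carrier count `m = sum(a & b_perm)`, whose null law is
#' hypergeometric, so each permutation is realized exactly as one
#' hypergeometric draw. The add-one estimator
#' `p = (1 + #\{null I_A >= observed\}) / (n_perm + 1)` never returns 0.
#'
#' @inheritParams pairwise_ia
#' @param n_perm number of permutations.
#' @param seed integer RNG seed.
#' @return List with `ia` (observed), `p`, `n_perm`.
#' @export
ia_permutation_test <- function(incidence, a, b, n_perm = 99999L, seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  x <- incidence[, a]; y <- incidence[, b]
  n <- length(x); na <- sum(x); nb <- sum(y)
  obs <- pairwise_ia(incidence, a, b)
  if (is.na(obs)) stop("I_A undefined for this pair (monomorphic column)")
  set.seed(seed)
  m_null <- stats::rhyper(n_perm, na, n - na, nb)
  null_ia <- .ia_from_counts(n, na, nb, m_null)
  p <- (1 + sum(null_ia >= obs - 1e-12)) / (n_perm + 1)
  list(ia = obs, p = p, n_perm = as.integer(n_perm))
}

#' Test all polymorphic allele pairs for association
#'
#' Computes `I_A` and its permutation p-value for every unordered pair of
#' alleles polymorphic within the site group, then applies a Bonferroni
#' correction over the number of *tested* pairs (pairs with a monomorphic
#' member are undefined and excluded from the denominator).
#'
#' @param dataset an [mhc_dataset].
#' @param sites optional site group (default: all sites).
#' @param alpha family-wise error level.
#' @param n_perm permutations per pair.
#' @param seed integer RNG seed.
#' @return Data frame sorted by p: `allele_1`, `allele_2`, `ia`, `p`,
#'   `n_perm`, `bonferroni_threshold`, `significant`; attribute
#'   `n_tested_pairs`.
#' @export
significant_pairs <- function(dataset, sites = NULL, alpha = 0.05,
                              n_perm = 99999L, seed = 1L) {
  inc <- incidence_matrix(dataset, sites = sites)
  n <- nrow(inc)
  cs <- colSums(inc)
  poly <- colnames(inc)[cs > 0L & cs < n]
  if (length(poly) < 2L) {
    warning("fewer than 2 polymorphic alleles; nothing to test")
    out <- data.frame(allele_1 = character(), allele_2 = character(),
                      ia = numeric(), p = numeric(), n_perm = integer(),
                      bonferroni_threshold = numeric(),
                      significant = logical())
    attr(out, "n_tested_pairs") <- 0L
    return(out)
  }
  pairs <- utils::combn(poly, 2L)
  n_pairs <- ncol(pairs)
  res <- vector("list", n_pairs)
  for (j in seq_len(n_pairs)) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    t <- ia_permutation_test(inc, a, b, n_perm = n_perm,
                             seed = seed + j)
    res[[j]] <- data.frame(allele_1 = a, allele_2 = b, ia = t$ia,
                           p = t$p, n_perm = t$n_perm)
  }
  out <- do.call(rbind, res)
  out$bonferroni_threshold <- alpha / n_pairs
  out$significant <- out$p <= out$bonferroni_threshold
  out <- out[order(out$p, -out$ia), ]
  rownames(out) <- NULL
  attr(out, "n_tested_pairs") <- n_pairs
  out
}

#' Write an association table as TSV
#' @param assoc result of [significant_pairs].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(assoc, path) {
  utils::write.table(assoc, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
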