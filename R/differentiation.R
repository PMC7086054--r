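#' Gene identity between two presence-type genotypes
#'
#' The probability that one allele drawn uniformly from the first
#' individual's set equals one drawn from the second's:
#' `|g1 intersect g2| / (|g1| * |g2|)`. Only *between*-individual identity
#' is ever used by Rho, which is what makes the statistic independent of
#' ploidy and within-individual diversity.
#'
#' @param g1,g2 character vectors of allele ids (non-empty sets).
#' @return Numeric in `[0, 1]`.
#' @export
gene_identity <- function(g1, g2) {
  if (length(g1) == 0L || length(g2) == 0L) stop("empty allele set")
  length(intersect(g1, g2)) / (length(g1) * length(g2))
}

#' Gene identity between two diploid multilocus genotypes
#'
#' Average over loci (with both genotypes non-missing) of the probability
#' that one of the first individual's two allele copies matches one of the
#' second's.
#'
#' @param g1,g2 integer/character matrices `loci x 2` (NA = missing).
#' @return Numeric in `[0, 1]`, or `NA` if no locus is jointly typed.
#' @export
gene_identity_diploid <- function(g1, g2) {
  if (is.null(dim(g1))) g1 <- matrix(g1, ncol = 2L)
  if (is.null(dim(g2))) g2 <- matrix(g2, ncol = 2L)
  ok <- stats::complete.cases(g1) & stats::complete.cases(g2)
  if (!any(ok)) return(NA_real_)
  per_locus <- vapply(which(ok), function(l) {
    mean(outer(g1[l, ], g2[l, ], "=="))
  }, 0)
  mean(per_locus)
}

#' Pairwise between-individual identity matrix
#'
#' @param x an [mhc_dataset] or a `diploid_panel`.
#' @return List with `identity` (n x n symmetric numeric, diagonal `NA` --
#'   within-individual identity is never used) and `sites` (character,
#'   per-individual site labels).
#' @export
pair_identity_matrix <- function(x) UseMethod("pair_identity_matrix")

#' @export
pair_identity_matrix.mhc_dataset <- function(x) {
  inc <- incidence_matrix(x)
  sizes <- rowSums(inc)
  shared <- inc %*% t(inc)
  m <- shared / outer(sizes, sizes)
  diag(m) <- NA_real_
  list(identity = m, sites = unname(individual_sites(x)))
}

#' @export
pair_identity_matrix.diploid_panel <- function(x) {
  n <- dim(x$alleles)[1L]
  m <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1L)) {
    gi <- x$alleles[i, , , drop = TRUE]
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <-
        gene_identity_diploid(gi, x$alleles[j, , , drop = TRUE])
    }
  }
  list(identity = m, sites = as.character(x$sites))
}

.rho_from_identity <- function(idm, sites, site_r, site_s) {
  in_r <- sites == site_r
  in_s <- sites == site_s
  if (sum(in_r) < 2L || sum(in_s) < 2L)
    stop("each site needs >= 2 individuals")
  within_mean <- function(sel) {
    sub <- idm[sel, sel, drop = FALSE]
    mean(sub[upper.tri(sub)], na.rm = TRUE)
  }
  Q2 <- (within_mean(in_r) + within_mean(in_s)) / 2
  Q3 <- mean(idm[in_r, in_s], na.rm = TRUE)
  if (Q3 >= 1) return(NA_real_)
  (Q2 - Q3) / (1 - Q3)
}

#' Pairwise Rho differentiation between two sites
#'
#' Rho compares between-individual gene identity within sites (`Q2`, the
#' average of the two sites' within-site pair means) with identity for
#' cross-site pairs (`Q3`): `Rho = (Q2 - Q3) / (1 - Q3)`. Built only from
#' between-individual identities, it needs no ploidy, allele dosage or
#' Hardy-Weinberg assumptions.
#'
#' @param x an [mhc_dataset] or `diploid_panel`.
#' @param site_r,site_s the two site ids.
#' @return Rho (numeric), `NA` when `Q3 = 1` (all individuals identical).
#' @export
rho_pairwise <- function(x, site_r, site_s) {
  pim <- pair_identity_matrix(x)
  .rho_from_identity(pim$identity, pim$sites, site_r, site_s)
}

#' Global Rho over all sites
#'
#' `Q2` pools every within-site pair with equal weight across sites; `Q3`
#' pools every cross-site pair. Reports the linearizing transform
#' `Rho / (1 - Rho)` alongside (infinite, with a flag, at Rho = 1).
#'
#' @param x an [mhc_dataset] or `diploid_panel`.
#' @return List with `rho` and `transformed`.
#' @export
rho_global <- function(x) {
  pim <- pair_identity_matrix(x)
  idm <- pim$identity; sites <- pim$sites
  if (length(unique(sites)) < 2L) stop("need >= 2 sites")
  same <- outer(sites, sites, "==")
  ut <- upper.tri(idm)
  Q2 <- mean(idm[ut & same], na.rm = TRUE)
  Q3 <- mean(idm[ut & !same], na.rm = TRUE)
  rho <- if (Q3 >= 1) NA_real_ else (Q2 - Q3) / (1 - Q3)
  transformed <- if (is.na(rho)) NA_real_ else
    if (rho >= 1) Inf else rho / (1 - rho)
  list(rho = rho, transformed = transformed)
}

#' Permutation test for pairwise Rho
#'
#' Permutes individuals between the two sites (site labels shuffled,
#' sample sizes kept) and reports the add-one upper-tail p-value for the
#' observed Rho.
#'
#' @inheritParams rho_pairwise
#' @param n_perm number of permutations.
#' @param seed integer RNG seed.
#' @return List with `rho`, `p`, `n_perm`.
#' @export
rho_permutation_test <- function(x, site_r, site_s, n_perm = 999L,
                                 seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  pim <- pair_identity_matrix(x)
  obs <- .rho_from_identity(pim$identity, pim$sites, site_r, site_s)
  if (is.na(obs)) stop("Rho undefined for this site pair")
  sel <- which(pim$sites %in% c(site_r, site_s))
  labels <- pim$sites[sel]
  idm <- pim$identity[sel, sel, drop = FALSE]
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    .rho_from_identity(idm, sample(labels), site_r, site_s)
  }, 0)
  p <- (1 + sum(null >= obs - 1e-12, na.rm = TRUE)) / (n_perm + 1)
  list(rho = obs, p = p, n_perm = as.integer(n_perm))
}

#' Pairwise Rho matrix with transform and permutation p-values
#'
#' @param x an [mhc_dataset] or `diploid_panel`.
#' @param n_perm permutations per site pair (0 skips the tests).
#' @param seed integer RNG seed.
#' @param marker_label free-text label stored with the result.
#' @return Object of class `differentiation_matrix`: `sites`, `rho`,
#'   `rho_transformed`, `p_values` (all site x site), `global_rho`,
#'   `global_transformed`, `n_perm`, `marker_label`.
#' @export
rho_matrix <- function(x, n_perm = 999L, seed = 1L, marker_label = "") {
  pim <- pair_identity_matrix(x)
  sites <- unique(pim$sites)
  k <- length(sites)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(sites, sites))
  diag(rho) <- 0
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    r <- .rho_from_identity(pim$identity, pim$sites, sites[i], sites[j])
    rho[i, j] <- rho[j, i] <- r
    if (n_perm > 0L && !is.na(r)) {
      t <- rho_permutation_test(x, sites[i], sites[j], n_perm = n_perm,
                                seed = seed + i * k + j)
      p[i, j] <- p[j, i] <- t$p
    }
  }
  transformed <- ifelse(rho >= 1, Inf, rho / (1 - rho))
  g <- rho_global(x)
  structure(list(sites = sites, rho = rho, rho_transformed = transformed,
                 p_values = p, global_rho = g$rho,
                 global_transformed = g$transformed,
                 n_perm = as.integer(n_perm), marker_label = marker_label),
            class = "differentiation_matrix")
}

#' @export
print.differentiation_matrix <- function(x, ...) {
  cat("Differentiation (", x$marker_label, "): global Rho = ",
      sprintf("%.3f", x$global_rho), ", Rho/(1-Rho) = ",
      sprintf("%.3f", x$global_transformed), "\n", sep = "")
  print(round(x$rho_transformed, 3))
  invisible(x)
}

#' Write a differentiation matrix as TSV
#'
#' Transformed Rho above the diagonal, permutation p-values below.
#'
#' @param dm a `differentiation_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_differentiation_matrix <- function(dm, path) {
  m <- dm$rho_transformed
  m[lower.tri(m)] <- dm$p_values[lower.tri(m)]
  utils::write.table(cbind(site = rownames(m), as.data.frame(m)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.check_square <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  m
}

#' Mantel test (Pearson) between two site distance matrices
#'
#' Pearson correlation over the off-diagonal upper-triangle entries, with
#' significance from simultaneous row/column permutations and the add-one
#' one-tailed (upper) estimator. Thin wrapper around [vegan::mantel()]
#' seeded for reproducibility.
#'
#' @param m1,m2 symmetric matrices with zero diagonal, same site order.
#' @param n_perm matrix permutations (the study convention is 719).
#' @param seed integer RNG seed.
#' @return List with `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(m1, m2, n_perm = 719L, seed = 1L) {
  m1 <- .check_square(m1); m2 <- .check_square(m2)
  v1 <- m1[upper.tri(m1)]; v2 <- m2[upper.tri(m2)]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    warning("constant distance matrix; Mantel r undefined")
    return(list(r = NA_real_, p = NA_real_, n_perm = as.integer(n_perm)))
  }
  set.seed(seed)
  fit <- vegan::mantel(stats::as.dist(m1), stats::as.dist(m2),
                       method = "pearson",
                       permutations = permute::how(nperm = n_perm,
                                                   minperm = 1))
  list(r = unname(fit$statistic), p = fit$signif,
       n_perm = as.integer(n_perm))
}

#' Partial Mantel test controlling for a covariate matrix
#'
#' Partial Pearson correlation of `m1` and `m2` given `m3` on the
#' upper-triangle entries; permutations shuffle the first matrix.
#' Wrapper around [vegan::mantel.partial()]. A constant `m3` reduces to
#' the simple Mantel test; `m3` perfectly collinear with `m1` or `m2`
#' leaves the partial correlation undefined and is reported as `NA`.
#'
#' @inheritParams mantel_test
#' @param m3 covariate distance matrix.
#' @return List with `r`, `p`, `n_perm`, `method`.
#' @export
partial_mantel_test <- function(m1, m2, m3, n_perm = 719L, seed = 1L) {
  m1 <- .check_square(m1); m2 <- .check_square(m2); m3 <- .check_square(m3)
  v1 <- m1[upper.tri(m1)]; v3 <- m3[upper.tri(m3)]
  if (stats::sd(v3) == 0)  # constant covariate: plain Mantel
    return(c(mantel_test(m1, m2, n_perm = n_perm, seed = seed),
             method = "reduced to simple Mantel (constant covariate)"))
  r13 <- suppressWarnings(stats::cor(v1, v3))
  v2 <- m2[upper.tri(m2)]
  r23 <- suppressWarnings(stats::cor(v2, v3))
  if (isTRUE(all.equal(abs(r13), 1)) || isTRUE(all.equal(abs(r23), 1))) {
    warning("covariate collinear with an input matrix; partial r undefined")
    return(list(r = NA_real_, p = NA_real_, n_perm = as.integer(n_perm),
                method = "undefined (collinear covariate)"))
  }
  set.seed(seed)
  fit <- vegan::mantel.partial(stats::as.dist(m1), stats::as.dist(m2),
                               stats::as.dist(m3), method = "pearson",
                               permutations = permute::how(nperm = n_perm,
                                                           minperm = 1))
  list(r = unname(fit$statistic), p = fit$signif,
       n_perm = as.integer(n_perm),
       method = "partial Mantel, permutation of first matrix")
}

#' Geographic distance matrix between sites
#'
#' Great-circle (haversine, mean Earth radius 6371 km) distances for
#' lon/lat coordinates, Euclidean distances for planar ones.
#'
#' @param coords data frame with columns `site`, `x`, `y` (`x` =
#'   longitude when `lonlat`).
#' @param lonlat interpret coordinates as lon/lat degrees (default) or as
#'   planar.
#' @return Square symmetric matrix (km for lon/lat, coordinate units for
#'   planar) with site dimnames; attribute `units`.
#' @export
geographic_distance <- function(coords, lonlat = TRUE) {
  if (!all(c("site", "x", "y") %in% names(coords)))
    stop("coords must have columns site, x, y")
  xy <- as.matrix(coords[, c("x", "y")])
  if (lonlat) {
    m <- geosphere::distm(xy, fun = geosphere::distHaversine) / 1000
    # distm's default radius is equatorial; rescale to mean radius 6371 km
    m <- m * 6371 / 6378.137
    units <- "km"
  } else {
    m <- as.matrix(stats::dist(xy))
    units <- "coordinate units"
  }
  dimnames(m) <- list(coords$site, coords$site)
  attr(m, "units") <- units
  m
}
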