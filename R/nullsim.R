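#' Allele incidence spectrum of a site group
#'
#' The frequency notion available when allele dosage is unknown: the share
#' of individuals in the group that carry each allele. Alleles absent from
#' the group are omitted.
#'
#' @param dataset an [mhc_dataset].
#' @param sites site group (default: all sites).
#' @return Object of class `incidence_spectrum`: list with `freq` (named
#'   numeric in (0, 1]) and `n_source` (individuals in the group).
#' @export
incidence_spectrum <- function(dataset, sites = NULL) {
  inc <- incidence_matrix(dataset, sites = sites)
  freq <- colMeans(inc)
  freq <- freq[freq > 0]
  structure(list(freq = freq, n_source = nrow(inc)),
            class = "incidence_spectrum")
}

# Draw an n x A Bernoulli inclusion matrix with per-column probabilities p,
# rejecting and redrawing all-zero rows. Returns the logical matrix with
# the rejection count in attribute "rejections".
.bernoulli_genotypes <- function(n, p) {
  A <- length(p)
  draw <- function(k) matrix(stats::runif(k * A) < rep(p, each = k),
                             nrow = k, ncol = A)
  m <- draw(n)
  pre <- colMeans(m)  # marginals of the raw draw, before any rejection
  rejections <- 0L
  repeat {
    empty <- which(rowSums(m) == 0L)
    if (length(empty) == 0L) break
    rejections <- rejections + length(empty)
    m[empty, ] <- draw(length(empty))
  }
  attr(m, "rejections") <- rejections
  attr(m, "pre_rejection_marginals") <- pre
  m
}

.finish_ensemble <- function(inc, mode, linked_pairs, spectrum, seed,
                             rejections, model = NULL) {
  pre <- attr(inc, "pre_rejection_marginals")
  if (!is.null(pre)) names(pre) <- names(spectrum$freq)
  ens <- structure(
    list(mode = mode, linked_pairs = linked_pairs,
         incidence = inc, freq = spectrum$freq,
         pre_rejection_marginals = pre,
         n_genotypes = nrow(inc), rejections = rejections,
         seed = as.integer(seed), supertype_counts = NULL,
         histogram = NULL, mean_count = NULL),
    class = "null_ensemble")
  if (!is.null(model)) {
    cnt <- ensemble_supertype_counts(ens, model)
    ens$supertype_counts <- cnt
    ens$histogram <- table(cnt)
    ens$mean_count <- mean(cnt)
  }
  ens
}

#' Simulate a null ensemble of unlinked artificial genotypes
#'
#' Each artificial genotype includes each allele independently with
#' probability equal to its observed incidence frequency (Bernoulli
#' assembly, preserving marginal incidences); genotypes that draw zero
#' alleles are rejected and redrawn. The alternative `"fixed_counts"`
#' assembly draws each genotype's allele count from a supplied
#' distribution and then samples that many distinct alleles with
#' probability weights `freq / (1 - freq)` (Bernoulli inclusion
#' conditioned on the total).
#'
#' @param spectrum an [incidence_spectrum].
#' @param n_genotypes ensemble size (the study convention is 50,000).
#' @param seed integer RNG seed; identical seeds give identical ensembles.
#' @param model optional `supertype_model`; when supplied, per-genotype
#'   supertype counts, their histogram and mean are stored.
#' @param assembly `"bernoulli"` (default) or `"fixed_counts"`.
#' @param count_dist for `"fixed_counts"`: named numeric vector of
#'   probabilities over allele counts (names are counts).
#' @return Object of class `null_ensemble`.
#' @export
simulate_unlinked <- function(spectrum, n_genotypes = 50000L, seed = 1L,
                              model = NULL,
                              assembly = c("bernoulli", "fixed_counts"),
                              count_dist = NULL) {
  assembly <- match.arg(assembly)
  if (n_genotypes < 1L) stop("n_genotypes must be >= 1")
  p <- spectrum$freq
  if (all(p == 0)) stop("all incidence frequencies are zero")
  set.seed(seed)
  if (assembly == "bernoulli") {
    inc <- .bernoulli_genotypes(n_genotypes, p)
    rejections <- attr(inc, "rejections")
  } else {
    if (is.null(count_dist)) stop("fixed_counts assembly needs count_dist")
    counts <- as.integer(sample(as.integer(names(count_dist)), n_genotypes,
                                replace = TRUE, prob = count_dist))
    counts <- pmin(counts, length(p))
    w <- p / pmax(1 - p, 1e-12)
    inc <- matrix(FALSE, n_genotypes, length(p))
    for (i in seq_len(n_genotypes))
      inc[i, sample.int(length(p), counts[i], prob = w)] <- TRUE
    rejections <- 0L
  }
  colnames(inc) <- names(p)
  .finish_ensemble(inc, "unlinked", list(), spectrum, seed, rejections,
                   model)
}

#' Simulate a null ensemble with linked allele pairs
#'
#' Pairs flagged as significantly associated are treated as single
#' inclusion units: under `linkage_mode = "complete"` each pair enters a
#' genotype all-or-none with probability equal to the arithmetic mean of
#' its members' incidence frequencies; all remaining alleles are included
#' independently as in [simulate_unlinked]. Under `"proportional"`, each
#' pair behaves as a unit only for a fraction `strengths` of genotypes and
#' as independent alleles otherwise. Zero-allele genotypes are rejected
#' and redrawn.
#'
#' @inheritParams simulate_unlinked
#' @param linked_pairs list of length-2 character vectors of allele ids;
#'   pairs must be disjoint (no allele in two pairs) and present in the
#'   spectrum.
#' @param linkage_mode `"complete"` (default) or `"proportional"`.
#' @param strengths numeric vector in (0, 1], one per pair, used by
#'   `"proportional"` mode (e.g. the pairs' observed I_A values).
#' @return Object of class `null_ensemble`.
#' @export
simulate_linked <- function(spectrum, linked_pairs, n_genotypes = 50000L,
                            seed = 1L, model = NULL,
                            linkage_mode = c("complete", "proportional"),
                            strengths = NULL) {
  linkage_mode <- match.arg(linkage_mode)
  if (length(linked_pairs) == 0L)
    return(simulate_unlinked(spectrum, n_genotypes, seed, model))
  members <- unlist(linked_pairs)
  if (anyDuplicated(members))
    stop("linked pairs overlap; merging pairs into cliques is not supported")
  missing <- setdiff(members, names(spectrum$freq))
  if (length(missing))
    stop("linked-pair member absent from spectrum: ",
         paste(missing, collapse = ", "))
  if (linkage_mode == "proportional") {
    if (is.null(strengths) || length(strengths) != length(linked_pairs))
      stop("proportional mode needs one strength per pair")
    if (any(strengths <= 0 | strengths > 1))
      stop("strengths must lie in (0, 1]")
  } else {
    strengths <- rep(1, length(linked_pairs))
  }
  p <- spectrum$freq
  singles <- setdiff(names(p), members)
  pair_p <- vapply(linked_pairs, function(pr) mean(p[pr]), 0)
  set.seed(seed)
  A <- length(p)
  col_of <- stats::setNames(seq_len(A), names(p))
  n <- n_genotypes
  draw_block <- function(k) {
    inc <- matrix(FALSE, k, A)
    if (length(singles))
      inc[, col_of[singles]] <-
        matrix(stats::runif(k * length(singles)) <
                 rep(p[singles], each = k), nrow = k)
    for (j in seq_along(linked_pairs)) {
      pr <- linked_pairs[[j]]
      as_unit <- stats::runif(k) < strengths[j]
      unit_in <- stats::runif(k) < pair_p[j]
      both <- as_unit & unit_in
      inc[both, col_of[pr]] <- TRUE
      free <- which(!as_unit)
      if (length(free)) {
        inc[free, col_of[pr[1L]]] <- stats::runif(length(free)) < p[pr[1L]]
        inc[free, col_of[pr[2L]]] <- stats::runif(length(free)) < p[pr[2L]]
      }
    }
    inc
  }
  inc <- draw_block(n)
  rejections <- 0L
  repeat {
    empty <- which(rowSums(inc) == 0L)
    if (length(empty) == 0L) break
    rejections <- rejections + length(empty)
    inc[empty, ] <- draw_block(length(empty))
  }
  colnames(inc) <- names(p)
  .finish_ensemble(inc, "linked", linked_pairs, spectrum, seed, rejections,
                   model)
}

#' Per-genotype supertype counts of an ensemble
#' @param ensemble a `null_ensemble`.
#' @param model a `supertype_model` covering all ensemble alleles.
#' @return Integer vector, one count per simulated genotype.
#' @export
ensemble_supertype_counts <- function(ensemble, model) {
  ids <- colnames(ensemble$incidence)
  miss <- setdiff(ids, names(model$assignment))
  if (length(miss))
    stop("ensemble alleles without supertype assignment: ",
         paste(miss, collapse = ", "))
  st <- model$assignment[ids]
  membership <- outer(st, sort(unique(model$assignment)), "==")
  hits <- (ensemble$incidence %*% membership) > 0
  as.integer(rowSums(hits))
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat("Null ensemble (", x$mode, "): ", x$n_genotypes, " genotypes over ",
      ncol(x$incidence), " alleles; ", x$rejections,
      " zero-allele rejections\n", sep = "")
  if (!is.null(x$mean_count))
    cat("mean supertype count:", round(x$mean_count, 3), "\n")
  invisible(x)
}

#' Discrete two-sample style Kolmogorov-Smirnov test against a fixed null
#'
#' Treats the ensemble's empirical distribution as the fixed discrete
#' null. `D` is the sup-distance between the observed ECDF and the null
#' CDF over the joint support; because both CDFs are step functions with
#' jumps only at support points, evaluating there is exact. The p-value is
#' Monte-Carlo: `n_resample` samples of the observed size are drawn from
#' the null CDF and `p = (1 + #\{D* >= D\}) / (n_resample + 1)`; this
#' respects the discreteness that invalidates the asymptotic continuous
#' formula.
#'
#' @param observed_counts integer vector of observed per-individual
#'   supertype counts.
#' @param null_counts a `null_ensemble` with stored counts, or an integer
#'   vector of null counts.
#' @param n_resample Monte-Carlo replicates for the p-value.
#' @param seed integer RNG seed.
#' @return List of class `ks_comparison`: `D`, `p`, `method`, `n_obs`,
#'   `n_resample`.
#' @export
discrete_ks_test <- function(observed_counts, null_counts,
                             n_resample = 100000L, seed = 1L) {
  if (inherits(null_counts, "null_ensemble")) {
    if (is.null(null_counts$supertype_counts))
      stop("ensemble has no stored supertype counts; pass `model` when simulating")
    null_counts <- null_counts$supertype_counts
  }
  if (length(observed_counts) == 0L) stop("empty observed sample")
  support <- sort(unique(c(observed_counts, null_counts)))
  cdf_null <- stats::ecdf(null_counts)(support)
  n_obs <- length(observed_counts)
  cdf_obs <- stats::ecdf(observed_counts)(support)
  D <- max(abs(cdf_obs - cdf_null))
  probs <- diff(c(0, cdf_null))
  set.seed(seed)
  if (length(support) == 1L) {
    D_star <- rep(0, n_resample)
  } else {
    counts <- stats::rmultinom(n_resample, n_obs, probs)
    cum <- apply(counts, 2L, cumsum) / n_obs
    D_star <- apply(abs(cum - cdf_null), 2L, max)
  }
  p <- (1 + sum(D_star >= D - 1e-12)) / (n_resample + 1)
  structure(list(D = D, p = p,
                 method = "discrete KS, Monte-Carlo p against fixed null",
                 n_obs = n_obs, n_resample = as.integer(n_resample)),
            class = "ks_comparison")
}

#' Compare observed individual supertype counts with a null ensemble
#'
#' Reports the observed and simulated mean numbers of supertypes per
#' individual, both count histograms, the discrete KS comparison, and an
#' empirical one-tailed mean test (share of same-size null resamples whose
#' mean is at least the observed mean; add-one estimator, small values
#' flag an observed mean *above* the null).
#'
#' @param dataset an [mhc_dataset], or a named list of allele sets.
#' @param model a `supertype_model`.
#' @param ensemble a `null_ensemble` simulated from the matching spectrum.
#' @param sites optional site group when `dataset` is an [mhc_dataset].
#' @param n_resample Monte-Carlo replicates for both p-values.
#' @param seed integer RNG seed.
#' @return List of class `supertype_comparison`.
#' @export
compare_supertype_means <- function(dataset, model, ensemble, sites = NULL,
                                    n_resample = 100000L, seed = 1L) {
  sets <- if (inherits(dataset, "mhc_dataset"))
    genotype_sets(dataset, sites = sites) else dataset
  obs <- vapply(sets, count_supertypes, 0L, model = model)
  null_counts <- ensemble$supertype_counts
  if (is.null(null_counts))
    null_counts <- ensemble_supertype_counts(ensemble, model)
  ks <- discrete_ks_test(obs, null_counts, n_resample = n_resample,
                         seed = seed)
  set.seed(seed + 1L)
  support <- sort(unique(null_counts))
  probs <- as.numeric(table(factor(null_counts, levels = support))) /
    length(null_counts)
  draws <- stats::rmultinom(n_resample, length(obs), probs)
  null_means <- colSums(draws * support) / length(obs)
  mean_p_upper <- (1 + sum(null_means >= mean(obs) - 1e-12)) /
    (n_resample + 1)
  structure(
    list(observed_mean = mean(obs), null_mean = mean(null_counts),
         observed_hist = table(obs), null_hist = table(null_counts),
         ks = ks, mean_p_upper = mean_p_upper, n_obs = length(obs),
         ensemble_size = length(null_counts), mode = ensemble$mode,
         seed = as.integer(seed)),
    class = "supertype_comparison")
}

#' @export
print.supertype_comparison <- function(x, ...) {
  cat("Observed mean supertypes/individual:",
      sprintf("%.2f", x$observed_mean),
      "(n =", paste0(x$n_obs, ")"), "\n")
  cat("Null (", x$mode, ") mean: ", sprintf("%.2f", x$null_mean),
      " over ", x$ensemble_size, " genotypes\n", sep = "")
  cat("Discrete KS: D =", sprintf("%.3f", x$ks$D),
      ", p =", format(x$ks$p, digits = 3),
      "; mean-based upper-tail p =", format(x$mean_p_upper, digits = 3),
      "\n")
  invisible(x)
}
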