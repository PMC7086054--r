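#' Encode positively selected sites as physicochemical descriptors
#'
#' Each positively selected site (PSS) of every allele's translated
#' fragment is replaced by the five z-descriptors of its residue
#' ([Z_SCALES]), concatenated in PSS order. Alleles with identical
#' residues at all PSS therefore map to identical rows, which is the
#' point: clustering acts on antigen-binding biochemistry, not on
#' nucleotide identity.
#'
#' @param catalog an [allele_catalog].
#' @param pss_positions 1-based amino-acid positions within the translated
#'   fragment; typically the sites found under positive selection by
#'   codon-model tests (an input here, never inferred).
#' @return An object of class `pss_encoding`: list with `matrix`
#'   (alleles x 5*|PSS|) and `pss_positions`.
#' @export
encode_pss <- function(catalog, pss_positions) {
  pss_positions <- as.integer(pss_positions)
  pep_len <- nchar(catalog$peptides[[1L]])
  if (any(pss_positions < 1L | pss_positions > pep_len))
    stop("PSS position out of peptide range 1..", pep_len)
  ids <- allele_ids(catalog)
  m <- matrix(NA_real_, nrow = length(ids), ncol = 5L * length(pss_positions),
              dimnames = list(ids, paste0(
                rep(paste0("p", pss_positions), each = 5L), "_",
                rep(colnames(Z_SCALES), length(pss_positions)))))
  for (j in seq_along(pss_positions)) {
    res <- substr(catalog$peptides, pss_positions[j], pss_positions[j])
    bad <- ids[!res %in% rownames(Z_SCALES)]
    if (length(bad))
      stop("non-standard residue at PSS ", pss_positions[j], " in: ",
           paste(bad, collapse = ", "))
    m[, (5L * (j - 1L) + 1L):(5L * j)] <- Z_SCALES[res, , drop = FALSE]
  }
  structure(list(matrix = m, pss_positions = pss_positions),
            class = "pss_encoding")
}

# Best-of-n_starts k-means on a descriptor matrix; falls back to the
# distinct-row partition when k meets or exceeds the number of distinct rows.
.kmeans_best <- function(x, k, n_starts) {
  ux <- unique(x)
  if (k >= nrow(ux)) {
    key <- apply(x, 1L, paste, collapse = "\r")
    cl <- as.integer(factor(key, levels = unique(key)))
    return(list(cluster = cl, wss = 0))
  }
  fit <- stats::kmeans(x, centers = k, nstart = n_starts, iter.max = 100L)
  list(cluster = as.integer(fit$cluster), wss = fit$tot.withinss)
}

# Canonical labels: clusters renumbered by first appearance in row order,
# so the labelling is a deterministic function of the partition.
.canonical_labels <- function(cl) {
  as.integer(factor(cl, levels = unique(cl)))
}

#' Scan cluster numbers with k-means and BIC
#'
#' For each k in `k_range`, keeps the best of `n_starts` k-means solutions
#' (squared-Euclidean criterion) and scores it with
#' `BIC(k) = n * ln(WSS_k / n) + k * ln(n)`, n being the allele count and
#' WSS_k the total within-cluster sum of squares. A floor
#' `max(WSS, 1e-8)` keeps the score finite when k reaches the number of
#' distinct descriptor rows. Deterministic given `seed`.
#'
#' @param encoding a [pss_encoding].
#' @param k_range integer vector of cluster numbers to scan (>= 3
#'   consecutive values recommended so the elbow rule has context).
#' @param n_starts random restarts per k.
#' @param seed integer RNG seed.
#' @return Object of class `bic_scan`: list with `bic_curve` (named by k),
#'   `wss`, `assignments` (list of canonical label vectors per k),
#'   `n_starts`, `seed`.
#' @export
kmeans_bic_scan <- function(encoding, k_range, n_starts = 50L, seed = 1L) {
  stopifnot(inherits(encoding, "pss_encoding"))
  x <- encoding$matrix
  n <- nrow(x)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 1L) || any(k_range > n))
    stop("k_range must lie within [1, ", n, "]")
  if (n_starts < 1L) stop("n_starts must be >= 1")
  set.seed(seed)
  wss <- bic <- stats::setNames(numeric(length(k_range)), k_range)
  assignments <- vector("list", length(k_range))
  names(assignments) <- k_range
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    sol <- if (k == 1L) {
      ctr <- colMeans(x)
      list(cluster = rep(1L, n), wss = sum(sweep(x, 2L, ctr)^2))
    } else .kmeans_best(x, k, n_starts)
    wss[i] <- sol$wss
    bic[i] <- n * log(max(sol$wss, 1e-8) / n) + k * log(n)
    assignments[[i]] <- stats::setNames(.canonical_labels(sol$cluster),
                                        rownames(x))
  }
  structure(list(bic_curve = bic, wss = wss, assignments = assignments,
                 n_starts = as.integer(n_starts), seed = as.integer(seed)),
            class = "bic_scan")
}

#' Choose the cluster number from a BIC curve (elbow rule)
#'
#' Operationalizes "the minimal number of clusters after which the BIC
#' decreases by a negligible amount": returns the smallest k such that
#' *every* subsequent decrease of the curve is below `drop_threshold`
#' times its total range -- a single small step ahead of a large cliff
#' does not end the search, only a permanently flat tail does. A
#' monotone-increasing curve returns the smallest k with a warning; the
#' largest scanned k is returned when decreases stay substantial
#' throughout.
#'
#' @param bic_curve named numeric vector (names are k values) or a
#'   [kmeans_bic_scan] result.
#' @param drop_threshold fraction of the curve's total range below which a
#'   decrease counts as negligible.
#' @return Integer k.
#' @export
choose_k <- function(bic_curve, drop_threshold = 0.01) {
  if (inherits(bic_curve, "bic_scan")) bic_curve <- bic_curve$bic_curve
  ks <- as.integer(names(bic_curve))
  if (length(ks) < 2L) stop("BIC curve needs at least 2 k values")
  o <- order(ks)
  ks <- ks[o]; bic <- as.numeric(bic_curve)[o]
  rng <- diff(range(bic))
  if (rng == 0) return(ks[1L])  # flat curve
  drops <- -diff(bic)  # positive when BIC decreases
  if (all(drops <= 0)) {
    warning("BIC curve is monotone increasing; returning smallest k")
    return(ks[1L])
  }
  # largest decrease still ahead of each k; flat tails have none left
  ahead <- rev(cummax(rev(drops)))
  negligible <- ahead < drop_threshold * rng
  if (any(negligible)) ks[which(negligible)[1L]] else ks[length(ks)]
}

#' Assemble a supertype model at a chosen k
#'
#' @param scan a [kmeans_bic_scan] result.
#' @param k cluster number; defaults to [choose_k] on the scan's curve.
#' @param drop_threshold passed to [choose_k] when `k` is missing.
#' @return Object of class `supertype_model`: list with `k`, `assignment`
#'   (named integer, allele -> supertype 1..k), `bic_curve`, `seed`,
#'   `n_starts`.
#' @export
supertype_model <- function(scan, k = NULL, drop_threshold = 0.01) {
  stopifnot(inherits(scan, "bic_scan"))
  if (is.null(k)) k <- choose_k(scan$bic_curve, drop_threshold)
  key <- as.character(k)
  if (!key %in% names(scan$assignments))
    stop("k = ", k, " was not part of the scan")
  cl <- scan$assignments[[key]]
  structure(list(k = as.integer(max(cl)), assignment = cl,
                 bic_curve = scan$bic_curve, seed = scan$seed,
                 n_starts = scan$n_starts),
            class = "supertype_model")
}

#' Cluster a catalog's alleles into supertypes
#'
#' Convenience wrapper: encode PSS, scan k with BIC, pick k by the elbow
#' rule (or honour a manual override) and return the fitted model with
#' named assignments.
#'
#' @inheritParams encode_pss
#' @inheritParams kmeans_bic_scan
#' @param k optional manual override of the cluster number.
#' @param drop_threshold elbow-rule threshold, see [choose_k].
#' @return A `supertype_model` with `assignment` named by allele id.
#' @export
cluster_supertypes <- function(catalog, pss_positions, k_range = 1:15,
                               n_starts = 50L, seed = 1L, k = NULL,
                               drop_threshold = 0.01) {
  enc <- encode_pss(catalog, pss_positions)
  k_range <- k_range[k_range <= nrow(enc$matrix)]
  scan <- kmeans_bic_scan(enc, k_range, n_starts = n_starts, seed = seed)
  if (is.null(k)) k <- choose_k(scan$bic_curve, drop_threshold)
  cl <- scan$assignments[[as.character(k)]]
  names(cl) <- rownames(enc$matrix)
  structure(list(k = as.integer(max(cl)), assignment = cl,
                 bic_curve = scan$bic_curve, seed = scan$seed,
                 n_starts = scan$n_starts, pss_positions = enc$pss_positions),
            class = "supertype_model")
}

#' @export
print.supertype_model <- function(x, ...) {
  cat("Supertype model: k =", x$k, "supertypes over",
      length(x$assignment), "alleles\n")
  print(table(supertype = x$assignment))
  invisible(x)
}

#' Number of distinct supertypes in one genotype
#'
#' @param alleles character vector of allele ids (one individual's set).
#' @param model a `supertype_model` covering all of them.
#' @return Integer count, between 1 and `min(length(alleles), model$k)`.
#' @export
count_supertypes <- function(alleles, model) {
  miss <- setdiff(alleles, names(model$assignment))
  if (length(miss))
    stop("alleles without supertype assignment: ",
         paste(miss, collapse = ", "))
  length(unique(model$assignment[alleles]))
}

#' Write a supertype assignment map as TSV
#' @param model a `supertype_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_supertype_map <- function(model, path) {
  utils::write.table(
    data.frame(allele = names(model$assignment),
               supertype = unname(model$assignment)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
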