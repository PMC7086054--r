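#' Allele count and private alleles at a site
#'
#' @param dataset an [mhc_dataset].
#' @param site site id.
#' @return List with `A` (distinct alleles at the site) and `A_priv`
#'   (alleles found at this site and nowhere else in the dataset).
#' @export
allele_counts <- function(dataset, site) {
  if (!site %in% dataset$sites) stop("unknown site: ", site)
  g <- dataset$genotypes
  here <- unique(g$allele[g$site == site])
  elsewhere <- unique(g$allele[g$site != site])
  list(A = length(here), A_priv = length(setdiff(here, elsewhere)))
}

#' Rarefied allelic richness from presence records
#'
#' Individual-record rarefaction: with one record per individual-allele
#' presence, N total records at the site and `n_a` records of allele a,
#' the expected number of distinct alleles in a uniform subsample of g
#' records is `A_R = sum_a [1 - C(N - n_a, g) / C(N, g)]`. Computed on
#' log-binomials for stability. `A_R(g = N) = A` and `A_R(1) = 1` exactly;
#' monotone non-decreasing in g.
#'
#' @param dataset an [mhc_dataset].
#' @param site site id.
#' @param g subsample size in presence records, `1 <= g <= N`.
#' @return Expected allele number (numeric).
#' @export
rarefied_richness <- function(dataset, site, g) {
  if (!site %in% dataset$sites) stop("unknown site: ", site)
  gt <- dataset$genotypes
  recs <- gt$allele[gt$site == site]
  n_a <- table(recs)
  N <- length(recs)
  if (g < 1 || g > N) stop("g must lie in [1, ", N, "]")
  term <- function(na) {
    if (N - na < g) return(1)
    1 - exp(lchoose(N - na, g) - lchoose(N, g))
  }
  sum(vapply(as.numeric(n_a), term, 0))
}

.catalog_char_matrix <- function(catalog, alleles = NULL) {
  seqs <- catalog$sequences
  if (!is.null(alleles)) {
    miss <- setdiff(alleles, names(seqs))
    if (length(miss)) stop("unknown alleles: ", paste(miss, collapse = ", "))
    seqs <- seqs[alleles]
  }
  do.call(rbind, strsplit(seqs, ""))
}

#' Number of segregating nucleotide sites
#'
#' @param catalog an [allele_catalog].
#' @param alleles optional subset of allele ids (default: all).
#' @return Count of positions with more than one nucleotide state.
#' @export
segregating_sites <- function(catalog, alleles = NULL) {
  m <- .catalog_char_matrix(catalog, alleles)
  if (nrow(m) < 2L) stop("need at least 2 alleles")
  sum(apply(m, 2L, function(col) length(unique(col)) > 1L))
}

#' Nucleotide diversity per site
#'
#' Unweighted mean pairwise proportion of differing nucleotide positions
#' over all unordered pairs of the (unique) allele sequences; dosage being
#' unknown, no incidence weighting is applied by default. Optional
#' `weights` (e.g. incidence frequencies) switch to a weighted mean with
#' pair weight `w_i * w_j`.
#'
#' @inheritParams segregating_sites
#' @param weights optional named numeric weights per allele.
#' @return pi (numeric, in `[0, 1]`).
#' @export
nucleotide_diversity <- function(catalog, alleles = NULL, weights = NULL) {
  m <- .catalog_char_matrix(catalog, alleles)
  if (nrow(m) < 2L) stop("need at least 2 alleles")
  dna <- ape::as.DNAbin(m)
  d <- ape::dist.dna(dna, model = "raw")
  if (is.null(weights)) return(mean(d))
  ids <- rownames(m)
  w <- weights[ids]
  dm <- as.matrix(d)
  ww <- outer(w, w)
  sum(dm[upper.tri(dm)] * ww[upper.tri(ww)]) / sum(ww[upper.tri(ww)])
}

# --- Nei-Gojobori (1986) codon machinery -------------------------------

.codon_table <- function() {
  Biostrings::GENETIC_CODE
}

# Fraction of synonymous sites of one codon: per position, the share of
# the 3 single-base changes that preserve the amino acid; mutations to
# stop codons are not counted as synonymous (denominator stays 3).
.codon_syn_sites <- function(codon, code) {
  aa <- code[[codon]]
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(bases, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- b
      if (code[[alt]] != "*" && code[[alt]] == aa) s <- s + 1 / 3
    }
  }
  s
}

# Synonymous / nonsynonymous differences between two codons, averaged
# with equal weight over all minimal mutational pathways; pathways that
# pass through a stop codon are excluded (all-stop fallback keeps every
# pathway, counting stop steps as nonsynonymous).
.codon_path_diffs <- function(c1, c2, code) {
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(diff_pos)
  if (nd == 0L) return(c(syn = 0, nonsyn = 0))
  orders <- if (nd == 1L) list(diff_pos) else {
    perms <- function(v) {
      if (length(v) == 1L) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
      out
    }
    perms(diff_pos)
  }
  walk <- function(ord) {
    cur <- c1
    syn <- nonsyn <- 0
    ok <- TRUE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (code[[nxt]] == "*") ok <- FALSE
      if (code[[cur]] == code[[nxt]] && code[[nxt]] != "*")
        syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    list(syn = syn, nonsyn = nonsyn, ok = ok)
  }
  paths <- lapply(orders, walk)
  valid <- Filter(function(p) p$ok, paths)
  if (length(valid) == 0L) valid <- paths
  c(syn = mean(vapply(valid, `[[`, 0, "syn")),
    nonsyn = mean(vapply(valid, `[[`, 0, "nonsyn")))
}

.split_codons <- function(seq, frame_offset) {
  n_codons <- (nchar(seq) - frame_offset) %/% 3L
  substring(seq, frame_offset + 1L + 3L * (seq_len(n_codons) - 1L),
            frame_offset + 3L * seq_len(n_codons))
}

#' Synonymous and nonsynonymous nucleotide diversity (Nei-Gojobori)
#'
#' For every unordered allele pair, counts synonymous and nonsynonymous
#' sites (per-sequence site fractions averaged over the pair) and
#' differences (equal-weight average over minimal mutational pathways,
#' excluding pathways through stop codons), then averages the per-pair
#' proportions `syn diffs / syn sites` and `nonsyn diffs / nonsyn sites`
#' without any multiple-hit correction (p-distance style). Pairs whose
#' synonymous (or nonsynonymous) site count is zero are excluded from
#' that component's mean, with a warning.
#'
#' @inheritParams segregating_sites
#' @param frame_offset reading-frame offset; defaults to the catalog's.
#' @return List with `pi_syn`, `pi_nonsyn`, and `pairs`, a per-pair debug
#'   data frame (`syn_sites`, `nonsyn_sites`, `syn_diffs`, `nonsyn_diffs`).
#' @export
nei_gojobori <- function(catalog, alleles = NULL,
                         frame_offset = catalog$frame_offset) {
  seqs <- catalog$sequences
  if (!is.null(alleles)) seqs <- seqs[alleles]
  if (length(seqs) < 2L) stop("need at least 2 alleles")
  code <- as.list(.codon_table())
  codons <- lapply(seqs, .split_codons, frame_offset = frame_offset)
  L <- 3L * length(codons[[1L]])
  syn_sites_seq <- vapply(codons, function(cs)
    sum(vapply(cs, .codon_syn_sites, 0, code = code)), 0)
  ids <- names(seqs)
  pairs <- utils::combn(ids, 2L)
  res <- data.frame(allele_1 = pairs[1L, ], allele_2 = pairs[2L, ],
                    syn_sites = NA_real_, nonsyn_sites = NA_real_,
                    syn_diffs = NA_real_, nonsyn_diffs = NA_real_)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    S <- (syn_sites_seq[[a]] + syn_sites_seq[[b]]) / 2
    d <- mapply(function(c1, c2) .codon_path_diffs(c1, c2, code),
                codons[[a]], codons[[b]])
    res$syn_sites[j] <- S
    res$nonsyn_sites[j] <- L - S
    res$syn_diffs[j] <- sum(d["syn", ])
    res$nonsyn_diffs[j] <- sum(d["nonsyn", ])
  }
  syn_ok <- res$syn_sites > 0
  nonsyn_ok <- res$nonsyn_sites > 0
  if (!all(syn_ok))
    warning(sum(!syn_ok), " pair(s) with zero synonymous sites excluded")
  if (!all(nonsyn_ok))
    warning(sum(!nonsyn_ok), " pair(s) with zero nonsynonymous sites excluded")
  list(pi_syn = mean(res$syn_diffs[syn_ok] / res$syn_sites[syn_ok]),
       pi_nonsyn = mean(res$nonsyn_diffs[nonsyn_ok] /
                          res$nonsyn_sites[nonsyn_ok]),
       pairs = res)
}

#' Mean amino-acid p-distance at PSS within one individual
#'
#' @param alleles character vector of one individual's allele ids
#'   (>= 2 alleles).
#' @param catalog an [allele_catalog].
#' @param pss_positions 1-based positions within the translated fragment.
#' @return Mean over unordered allele pairs of the proportion of PSS with
#'   differing residues.
#' @export
individual_pss_distance <- function(alleles, catalog, pss_positions) {
  if (length(pss_positions) == 0L) stop("no PSS configured")
  if (length(alleles) < 2L) stop("genotype needs >= 2 alleles")
  pep <- catalog$peptides[alleles]
  res <- do.call(rbind, lapply(pep, function(p)
    strsplit(p, "")[[1]][pss_positions]))
  pr <- utils::combn(seq_along(alleles), 2L)
  mean(vapply(seq_len(ncol(pr)), function(j)
    mean(res[pr[1L, j], ] != res[pr[2L, j], ]), 0))
}

.site_diversity_row <- function(dataset, label, sites, model, pss_positions,
                                g) {
  gt <- dataset$genotypes[dataset$genotypes$site %in% sites, , drop = FALSE]
  sets <- split(gt$allele, gt$individual)
  alleles <- sort(unique(gt$allele))
  elsewhere <- unique(dataset$genotypes$allele[
    !dataset$genotypes$site %in% sites])
  sizes <- lengths(sets)
  A <- length(alleles)
  row <- data.frame(
    site = label, n = length(sets), A = A,
    A_priv = length(setdiff(alleles, elsewhere)),
    N_S = NA_integer_, A_R = NA_real_,
    IndA_mean = mean(sizes), IndA_sd = stats::sd(sizes),
    IndS_mean = NA_real_, S = NA_integer_, pi = NA_real_,
    pi_syn = NA_real_, pi_nonsyn = NA_real_, ind_p_distance = NA_real_)
  N_rec <- nrow(gt)
  if (!is.null(g) && g >= 1 && g <= N_rec) {
    n_a <- table(gt$allele)
    term <- function(na) if (N_rec - na < g) 1 else
      1 - exp(lchoose(N_rec - na, g) - lchoose(N_rec, g))
    row$A_R <- sum(vapply(as.numeric(n_a), term, 0))
  }
  if (!is.null(model)) {
    row$N_S <- length(unique(model$assignment[alleles]))
    row$IndS_mean <- mean(vapply(sets, count_supertypes, 0L, model = model))
  }
  if (A >= 2L) {
    row$S <- segregating_sites(dataset$catalog, alleles)
    row$pi <- nucleotide_diversity(dataset$catalog, alleles)
    ng <- suppressWarnings(nei_gojobori(dataset$catalog, alleles))
    row$pi_syn <- ng$pi_syn
    row$pi_nonsyn <- ng$pi_nonsyn
  }
  if (!is.null(pss_positions)) {
    multi <- sets[lengths(sets) >= 2L]
    if (length(multi))
      row$ind_p_distance <- mean(vapply(
        multi, individual_pss_distance, 0,
        catalog = dataset$catalog, pss_positions = pss_positions))
  }
  row
}

#' Per-site diversity table
#'
#' One row per site (plus optional pooled group rows) with the standard
#' multilocus-amplicon diversity columns: sample size, allele and private
#' allele counts, supertypes present, rarefied allelic richness, mean/SD
#' alleles per individual, mean supertypes per individual, segregating
#' sites, nucleotide diversity and its synonymous/nonsynonymous
#' components, and the mean within-individual amino-acid p-distance at
#' PSS. Sites with one individual or one allele get `NA` in the undefined
#' fields.
#'
#' @param dataset an [mhc_dataset].
#' @param model optional `supertype_model` (enables `N_S`, `IndS_mean`).
#' @param pss_positions optional PSS vector (enables `ind_p_distance`).
#' @param g rarefaction size in presence records; default is the smallest
#'   per-site record total.
#' @param groups optional named list of site-id vectors appended as pooled
#'   rows (e.g. `list(native = "FL", invasive = c("D1", ...))`).
#' @return Data frame, one row per site and group.
#' @export
diversity_table <- function(dataset, model = NULL, pss_positions = NULL,
                            g = NULL, groups = NULL) {
  per_site_records <- table(dataset$genotypes$site)
  if (is.null(g)) g <- min(per_site_records)
  rows <- lapply(dataset$sites, function(s)
    .site_diversity_row(dataset, s, s, model, pss_positions, g))
  if (!is.null(groups))
    rows <- c(rows, lapply(names(groups), function(nm)
      .site_diversity_row(dataset, nm, groups[[nm]], model,
                          pss_positions, g)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "g") <- g
  out
}

#' Write a diversity table as TSV
#' @param tab result of [diversity_table].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_diversity_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
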