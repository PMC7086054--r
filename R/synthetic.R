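# Synthetic-data generators with stored ground truth. Default shapes
# mirror the study system: ~20-90 alleles of 184 nt, ~10 supertype
# clusters in z-descriptor space, 2-6 alleles per individual, multi-site
# samples with a divergence knob and optional linked allele pairs.

.NONSTOP_CODONS <- local({
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  code <- Biostrings::GENETIC_CODE
  all_codons[code[all_codons] != "*"]
})

# Greedy max-min selection of k amino-acid "anchors" in z-space.
.anchor_residues <- function(k, separation) {
  d <- as.matrix(stats::dist(Z_SCALES))
  chosen <- which.max(rowSums(d))  # start from the most peripheral residue
  while (length(chosen) < k) {
    cand <- setdiff(seq_len(nrow(d)), chosen)
    mind <- apply(d[cand, chosen, drop = FALSE], 1L, min)
    chosen <- c(chosen, cand[which.max(mind)])
  }
  anchors <- rownames(Z_SCALES)[chosen]
  realized <- min(d[chosen, chosen][upper.tri(diag(length(chosen)))])
  if (realized < separation)
    stop("separation ", separation, " not attainable with 20 residues ",
         "(best min distance ", round(realized, 2), ")")
  anchors
}

.codons_for <- function(aa) {
  code <- Biostrings::GENETIC_CODE
  .NONSTOP_CODONS[code[.NONSTOP_CODONS] == aa]
}

#' Generate an allele catalog with planted supertype structure
#'
#' Residues at the PSS of each allele are taken from its supertype's
#' anchor amino acid -- anchors are chosen greedily so their pairwise
#' z-descriptor distances are at least `separation` apart. Non-PSS codons
#' descend from one random stop-free ancestral sequence, with each allele
#' replacing each codon independently at `codon_mut_rate`, giving the
#' moderate pairwise nucleotide diversity typical of MHC amplicon
#' catalogs rather than unrelated random sequences. Codon usage at PSS is
#' randomized (synonymous variation), so nucleotide identity differs even
#' where binding biochemistry does not. `separation = 0` plants no
#' structure (PSS residues uniform over all 20 amino acids), a negative
#' control under which clustering recovery is at chance level.
#'
#' @param n_alleles number of alleles (study scale: 89 pooled, 20-32 per
#'   range).
#' @param length_nt fragment length in nucleotides (default 184, the
#'   exon-2 amplicon length).
#' @param frame_offset reading-frame offset, 0-2.
#' @param planted_k number of planted supertypes (study scale: 10).
#' @param pss_positions 1-based amino-acid positions used as PSS (5 by
#'   default, matching the number of consistently selected sites).
#' @param separation minimal pairwise z-distance between supertype
#'   anchors; 0 disables planting. The default 4 is the largest value
#'   attainable for 10 anchors among 20 residues.
#' @param codon_mut_rate per-codon replacement probability off the
#'   ancestral sequence at non-PSS codons.
#' @param seed integer RNG seed.
#' @return List with `catalog` (an [allele_catalog]) and `truth` (list:
#'   `planted_k`, `assignment`, `pss_positions`, `separation`, `seed`).
#' @export
make_allele_catalog <- function(n_alleles = 89L, length_nt = 184L,
                                frame_offset = 0L, planted_k = 10L,
                                pss_positions = c(9L, 18L, 30L, 44L, 57L),
                                separation = 4, codon_mut_rate = 0.04,
                                seed = 1L) {
  if (planted_k > n_alleles) stop("planted_k cannot exceed n_alleles")
  n_codons <- (length_nt - frame_offset) %/% 3L
  if (any(pss_positions < 1L | pss_positions > n_codons))
    stop("PSS outside peptide length ", n_codons)
  set.seed(seed)
  anchors <- if (separation > 0) .anchor_residues(planted_k, separation)
  else NULL
  assignment <- rep_len(seq_len(planted_k), n_alleles)
  ids <- sprintf("syn-DRB*%02d", seq_len(n_alleles))
  ancestor <- sample(.NONSTOP_CODONS, n_codons, replace = TRUE)
  lead <- if (frame_offset > 0L)
    paste(sample(c("A", "C", "G", "T"), frame_offset, replace = TRUE),
          collapse = "") else ""
  tail_len <- length_nt - frame_offset - 3L * n_codons
  trail <- if (tail_len > 0L)
    paste(sample(c("A", "C", "G", "T"), tail_len, replace = TRUE),
          collapse = "") else ""
  make_one <- function(st) {
    codons <- ancestor
    mut <- which(stats::runif(n_codons) < codon_mut_rate)
    if (length(mut))
      codons[mut] <- sample(.NONSTOP_CODONS, length(mut), replace = TRUE)
    for (j in seq_along(pss_positions)) {
      aa <- if (is.null(anchors)) sample(rownames(Z_SCALES), 1L)
      else anchors[st]
      codons[pss_positions[j]] <- sample(.codons_for(aa), 1L)
    }
    paste0(lead, paste(codons, collapse = ""), trail)
  }
  seqs <- character(n_alleles)
  for (i in seq_len(n_alleles)) {
    for (attempt in 1:100) {
      s <- make_one(assignment[i])
      if (!s %in% seqs[seq_len(i - 1L)]) break
    }
    seqs[i] <- s
  }
  names(seqs) <- ids
  catalog <- allele_catalog(seqs, frame_offset = frame_offset)
  truth <- list(planted_k = as.integer(planted_k),
                assignment = stats::setNames(assignment, ids),
                pss_positions = as.integer(pss_positions),
                separation = separation, seed = as.integer(seed))
  list(catalog = catalog, truth = truth)
}

.rlogitnorm <- function(n, base, sd) {
  stats::plogis(stats::qlogis(base) + stats::rnorm(n, 0, sd))
}

#' Generate multi-site populations of multilocus genotypes
#'
#' Per site, allele incidence frequencies are drawn around dataset-level
#' base frequencies and perturbed on the logit scale with standard
#' deviation `divergence` (under `spatial = TRUE` each allele instead
#' follows a logit-linear frequency cline along the site order with slope
#' SD `divergence`, producing isolation by distance on a linear layout).
#' Individuals draw an allele count from
#' `allele_count_dist` (supported on 2-6, the observed range) and then
#' that many distinct alleles with conditional-Bernoulli weights
#' `f/(1-f)`. Linked pairs are sampled as all-or-none units with the
#' stated strength. With `min_supertypes`, genotypes are resampled until
#' they span at least that many planted supertypes (a divergent-allele-
#' advantage population).
#'
#' @param catalog an [allele_catalog] (or the list returned by
#'   [make_allele_catalog], whose truth supplies `assignment`).
#' @param n_sites number of sampling sites.
#' @param individuals_per_site integer vector (recycled) of sample sizes;
#'   the study layout is `c(16, 7, 35, 27, 107, 36, 89)`.
#' @param base_freq optional named base incidence frequencies; default
#'   draws Beta(0.7, 1.4) in `[0.03, 0.95]` (a few common, many rare).
#' @param allele_count_dist named probabilities over allele counts.
#' @param linked_pairs list of length-2 allele-id vectors.
#' @param linkage_strengths numeric in (0, 1], one per pair (1 = fully
#'   linked).
#' @param divergence logit-scale SD of site frequency perturbations
#'   (0 = exchangeable sites).
#' @param spatial couple divergence to the site order via frequency
#'   clines (isolation by distance).
#' @param min_supertypes optional minimum supertype span per genotype;
#'   needs `assignment`.
#' @param assignment named allele -> supertype vector (defaults to the
#'   catalog truth when available).
#' @param seed integer RNG seed.
#' @return List with `dataset` (an [mhc_dataset]) and `truth`.
#' @export
make_populations <- function(catalog, n_sites = 7L,
                             individuals_per_site = c(16L, 7L, 35L, 27L,
                                                      107L, 36L, 89L),
                             base_freq = NULL,
                             allele_count_dist = c(`2` = 0.25, `3` = 0.40,
                                                   `4` = 0.20, `5` = 0.10,
                                                   `6` = 0.05),
                             linked_pairs = list(),
                             linkage_strengths = NULL,
                             divergence = 0.5, spatial = FALSE,
                             min_supertypes = NULL, assignment = NULL,
                             seed = 1L) {
  if (is.list(catalog) && !inherits(catalog, "allele_catalog")) {
    if (is.null(assignment)) assignment <- catalog$truth$assignment
    catalog <- catalog$catalog
  }
  stopifnot(inherits(catalog, "allele_catalog"))
  ids <- allele_ids(catalog)
  counts_supported <- as.integer(names(allele_count_dist))
  if (min(counts_supported) < 1L)
    stop("allele counts must be >= 1")
  if (!is.null(min_supertypes) && is.null(assignment))
    stop("min_supertypes needs a supertype assignment")
  if (length(linked_pairs)) {
    members <- unlist(linked_pairs)
    if (anyDuplicated(members)) stop("linked pairs must be disjoint")
    if (!all(members %in% ids)) stop("linked pair member not in catalog")
    if (is.null(linkage_strengths))
      linkage_strengths <- rep(1, length(linked_pairs))
  }
  set.seed(seed)
  n_allele <- length(ids)
  if (is.null(base_freq)) {
    base_freq <- stats::setNames(
      pmin(pmax(stats::rbeta(n_allele, 0.7, 1.4), 0.03), 0.95), ids)
  }
  sizes <- rep_len(individuals_per_site, n_sites)
  site_ids <- sprintf("S%d", seq_len(n_sites))
  site_freq <- matrix(NA_real_, n_sites, n_allele,
                      dimnames = list(site_ids, ids))
  if (spatial) {
    # allele-specific frequency clines along the site order: differentiation
    # grows with distance between sites (isolation by distance on a linear
    # layout); slopes scale with `divergence` per unit site spacing
    slope <- stats::rnorm(n_allele, 0, divergence)
    pos <- seq_len(n_sites) - (n_sites + 1) / 2
    for (s in seq_len(n_sites))
      site_freq[s, ] <- stats::plogis(stats::qlogis(base_freq) +
                                        slope * pos[s])
  } else {
    for (s in seq_len(n_sites))
      site_freq[s, ] <- .rlogitnorm(n_allele, base_freq, divergence)
  }
  draw_individual <- function(freq) {
    for (attempt in 1:200) {
      c_target <- counts_supported[
        sample.int(length(counts_supported), 1L, prob = allele_count_dist)]
      # decide which pairs act as units for this individual
      unit_pairs <- if (length(linked_pairs))
        linked_pairs[stats::runif(length(linked_pairs)) <
                       linkage_strengths] else list()
      unit_members <- unlist(unit_pairs)
      free <- setdiff(ids, unit_members)
      units <- c(lapply(free, identity), unit_pairs)
      w <- c(freq[free] / pmax(1 - freq[free], 1e-9),
             vapply(unit_pairs, function(pr) {
               f <- mean(freq[pr]); f / max(1 - f, 1e-9)
             }, 0))
      picked <- character()
      ord <- sample.int(length(units), prob = w)
      for (u in ord) {
        picked <- c(picked, units[[u]])
        if (length(picked) >= c_target) break
      }
      if (length(picked) > max(counts_supported)) next
      return(picked)
    }
    stop("could not assemble a genotype within the count constraints")
  }
  rows <- list()
  ind <- 0L
  for (s in seq_len(n_sites)) {
    for (i in seq_len(sizes[s])) {
      ind <- ind + 1L
      repeat {
        alleles <- draw_individual(site_freq[s, ])
        if (is.null(min_supertypes) ||
            length(unique(assignment[alleles])) >= min_supertypes) break
      }
      rows[[ind]] <- data.frame(
        individual = sprintf("ind%04d", ind), site = site_ids[s],
        allele = alleles, stringsAsFactors = FALSE)
    }
  }
  genotypes <- do.call(rbind, rows)
  dataset <- suppressWarnings(
    mhc_dataset(catalog, genotypes, sites = site_ids))
  truth <- list(base_freq = base_freq, site_freq = site_freq,
                linked_pairs = linked_pairs,
                linkage_strengths = linkage_strengths,
                divergence = divergence, spatial = spatial,
                allele_count_dist = allele_count_dist,
                min_supertypes = min_supertypes, seed = as.integer(seed))
  list(dataset = dataset, truth = truth)
}

#' Generate a diploid codominant marker panel (microsatellite-like)
#'
#' Island-model draws: per locus, a global allele-frequency vector from a
#' symmetric Dirichlet; per site, frequencies redrawn from a Dirichlet
#' centred on the global vector with concentration `(1/divergence - 1) *
#' n_alleles` (larger divergence = more drift; `divergence = 0` copies the
#' global frequencies exactly). Two allele copies are then sampled per
#' individual and locus.
#'
#' @param n_loci number of loci (study panel: 9).
#' @param n_sites number of sites.
#' @param individuals_per_site integer vector (recycled).
#' @param n_alleles_per_locus alleles segregating per locus.
#' @param divergence in `[0, 1)`; monotone in realized Rho.
#' @param seed integer RNG seed.
#' @return List with `panel` (class `diploid_panel`: `alleles` array
#'   `individuals x loci x 2`, `sites`, `ids`) and `truth`.
#' @export
make_msat_panel <- function(n_loci = 9L, n_sites = 7L,
                            individuals_per_site = 20L,
                            n_alleles_per_locus = 8L, divergence = 0.2,
                            seed = 1L) {
  set.seed(seed)
  sizes <- rep_len(individuals_per_site, n_sites)
  n <- sum(sizes)
  site_ids <- sprintf("S%d", seq_len(n_sites))
  sites <- rep(site_ids, sizes)
  rdirichlet <- function(alpha) {
    x <- stats::rgamma(length(alpha), shape = alpha)
    x / sum(x)
  }
  arr <- array(NA_integer_, dim = c(n, n_loci, 2L))
  freqs <- vector("list", n_loci)
  for (l in seq_len(n_loci)) {
    global <- rdirichlet(rep(1, n_alleles_per_locus))
    site_f <- matrix(NA_real_, n_sites, n_alleles_per_locus)
    for (s in seq_len(n_sites)) {
      site_f[s, ] <- if (divergence <= 0) global else
        rdirichlet(global * (1 / divergence - 1) * n_alleles_per_locus)
    }
    freqs[[l]] <- site_f
    for (s in seq_len(n_sites)) {
      idx <- which(sites == site_ids[s])
      arr[idx, l, 1L] <- sample.int(n_alleles_per_locus, length(idx),
                                    replace = TRUE, prob = site_f[s, ])
      arr[idx, l, 2L] <- sample.int(n_alleles_per_locus, length(idx),
                                    replace = TRUE, prob = site_f[s, ])
    }
  }
  panel <- structure(
    list(alleles = arr, sites = sites,
         ids = sprintf("ind%04d", seq_len(n))),
    class = "diploid_panel")
  truth <- list(divergence = divergence, site_freqs = freqs,
                seed = as.integer(seed))
  list(panel = panel, truth = truth)
}

#' Generate site coordinates
#'
#' @param n_sites number of sites.
#' @param layout `"linear"` (evenly spaced on a line, enabling clean
#'   isolation-by-distance tests) or `"random"` (uniform in a unit
#'   square).
#' @param spacing distance between neighbours in the linear layout.
#' @param seed integer RNG seed (random layout only).
#' @return Data frame `site`, `x`, `y` (planar units).
#' @export
make_coords <- function(n_sites, layout = c("linear", "random"),
                        spacing = 1, seed = 1L) {
  layout <- match.arg(layout)
  site <- sprintf("S%d", seq_len(n_sites))
  if (layout == "linear") {
    data.frame(site = site, x = spacing * (seq_len(n_sites) - 1), y = 0)
  } else {
    set.seed(seed)
    data.frame(site = site, x = stats::runif(n_sites),
               y = stats::runif(n_sites))
  }
}

#' Serialize a generator's ground truth as JSON
#' @param truth a truth list from a `make_*` generator.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
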