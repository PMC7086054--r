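#' Assemble a multilocus genotype dataset
#'
#' A dataset couples an allele catalog with the unphased multilocus
#' genotypes of sampled individuals. Because MHC alleles cannot be assigned
#' to loci, a genotype is the *set* of alleles amplified in one individual
#' (dosage unknown, duplicates impossible); each individual belongs to one
#' sampling site.
#'
#' @param catalog an [allele_catalog].
#' @param genotypes data frame with columns `individual`, `site`, `allele`
#'   (long form; one row per allele presence).
#' @param sites optional character vector fixing site order; defaults to
#'   order of first appearance.
#' @param coords optional data frame with columns `site`, `x`, `y`
#'   (planar or lon/lat site coordinates).
#' @return An object of class `mhc_dataset`: list with `catalog`,
#'   `genotypes` (long data frame), `sites`, `coords`.
#' @export
mhc_dataset <- function(catalog, genotypes, sites = NULL, coords = NULL) {
  stopifnot(inherits(catalog, "allele_catalog"))
  need <- c("individual", "site", "allele")
  if (!all(need %in% names(genotypes)))
    stop("genotype table must have columns: ", paste(need, collapse = ", "))
  genotypes <- as.data.frame(genotypes)[need]
  genotypes[] <- lapply(genotypes, as.character)
  unknown <- setdiff(unique(genotypes$allele), allele_ids(catalog))
  if (length(unknown))
    stop("alleles absent from catalog: ", paste(unknown, collapse = ", "))
  if (anyDuplicated(genotypes))
    genotypes <- unique(genotypes)  # set semantics
  site_of <- tapply(genotypes$site, genotypes$individual,
                    function(s) length(unique(s)))
  if (any(site_of > 1L))
    stop("individuals assigned to more than one site: ",
         paste(names(site_of)[site_of > 1L], collapse = ", "))
  sizes <- table(genotypes$individual)
  if (any(sizes < 1L)) stop("empty genotype")
  odd <- names(sizes)[sizes < 2L | sizes > 6L]
  if (length(odd))
    warning("allele-set size outside the observed 2-6 range for: ",
            paste(odd, collapse = ", "))
  if (is.null(sites)) sites <- unique(genotypes$site)
  if (!all(genotypes$site %in% sites))
    stop("genotype refers to site not in `sites`")
  if (!is.null(coords)) {
    coords <- as.data.frame(coords)
    if (!all(c("site", "x", "y") %in% names(coords)))
      stop("coords must have columns site, x, y")
    missing_sites <- setdiff(sites, coords$site)
    if (length(missing_sites))
      stop("coords missing for sites: ", paste(missing_sites, collapse = ", "))
  }
  structure(
    list(catalog = catalog, genotypes = genotypes,
         sites = sites, coords = coords),
    class = "mhc_dataset"
  )
}

#' @export
print.mhc_dataset <- function(x, ...) {
  cat("MHC dataset:", length(unique(x$genotypes$individual)), "individuals,",
      length(x$sites), "sites,", length(x$catalog), "catalog alleles\n")
  invisible(x)
}

#' Per-individual allele sets
#' @param dataset an [mhc_dataset].
#' @param sites optional site filter.
#' @return Named list: individual id -> character vector of allele ids.
#' @export
genotype_sets <- function(dataset, sites = NULL) {
  g <- dataset$genotypes
  if (!is.null(sites)) {
    g <- g[g$site %in% sites, , drop = FALSE]
    if (nrow(g) == 0L) stop("no individuals in the requested sites")
  }
  split(g$allele, factor(g$individual, levels = unique(g$individual)))
}

#' Site label of each individual
#' @inheritParams genotype_sets
#' @return Named character vector individual -> site.
#' @export
individual_sites <- function(dataset) {
  g <- dataset$genotypes
  vapply(split(g$site, factor(g$individual, levels = unique(g$individual))),
         `[`, "", 1L)
}

#' Individuals-by-alleles incidence matrix
#'
#' The binary substrate of all presence/absence statistics: entry (i, a)
#' is 1 iff individual i carries allele a. Column order follows the
#' catalog; row sums equal per-individual allele counts.
#'
#' @inheritParams genotype_sets
#' @return Integer matrix with individual rownames and allele colnames.
#' @export
incidence_matrix <- function(dataset, sites = NULL) {
  sets <- genotype_sets(dataset, sites = sites)
  ids <- allele_ids(dataset$catalog)
  m <- matrix(0L, nrow = length(sets), ncol = length(ids),
              dimnames = list(names(sets), ids))
  for (i in seq_along(sets)) m[i, sets[[i]]] <- 1L
  m
}

guess_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a multilocus genotype table
#'
#' Accepts two dialects, comma- or tab-delimited: *long* form with columns
#' `individual`, `site`, `allele` (one row per allele presence), or *wide*
#' 0/1 incidence form with columns `individual`, `site` plus one column per
#' allele id. Wide form is detected by the presence of more than one
#' catalog-allele-named column.
#'
#' @param path delimited text file.
#' @param catalog an [allele_catalog]; every allele referenced must exist.
#' @param coords optional coordinates data frame or path to a `site,x,y`
#'   table.
#' @return An [mhc_dataset].
#' @export
read_genotype_table <- function(path, catalog, coords = NULL) {
  delim <- guess_delim(path)
  tab <- utils::read.delim(path, sep = delim, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!"site" %in% names(tab)) stop("missing site column in ", path)
  if (!"individual" %in% names(tab)) stop("missing individual column in ", path)
  allele_cols <- intersect(names(tab), allele_ids(catalog))
  if ("allele" %in% names(tab) && length(allele_cols) <= 1L) {
    long <- tab[c("individual", "site", "allele")]
  } else if (length(allele_cols) > 1L) {
    rows <- lapply(seq_len(nrow(tab)), function(i) {
      present <- allele_cols[as.numeric(tab[i, allele_cols]) > 0]
      if (length(present) == 0L)
        stop("empty genotype for individual ", tab$individual[i])
      data.frame(individual = tab$individual[i], site = tab$site[i],
                 allele = present, stringsAsFactors = FALSE)
    })
    long <- do.call(rbind, rows)
  } else {
    stop("table is neither long form (individual, site, allele) nor ",
         "wide 0/1 form with allele-named columns")
  }
  if (is.character(coords) && length(coords) == 1L)
    coords <- read_coords(coords)
  mhc_dataset(catalog, long, coords = coords)
}

#' Read site coordinates
#' @param path delimited file with columns `site`, `x`, `y`.
#' @return Data frame.
#' @export
read_coords <- function(path) {
  tab <- utils::read.delim(path, sep = guess_delim(path),
                           stringsAsFactors = FALSE)
  if (!all(c("site", "x", "y") %in% names(tab)))
    stop("coordinates file must have columns site, x, y")
  tab
}

#' Write a dataset's genotype table (long form, tab-separated)
#' @param dataset an [mhc_dataset].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(dataset, path) {
  utils::write.table(dataset$genotypes, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
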