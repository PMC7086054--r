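#' Build a run configuration
#'
#' Collects every tunable of the end-to-end analysis in one explicit
#' object. All randomness is controlled by `seed` (stage seeds are derived
#' from it deterministically); no wall-clock seeding anywhere. The
#' configuration is echoed verbatim into the output directory, so a run
#' is reproducible from its artifacts alone.
#'
#' @param fasta,genotypes,coords input paths (FASTA catalog, genotype
#'   table, optional site coordinates); leave `NULL` with
#'   `simulate = TRUE` to run on a generated demo dataset.
#' @param simulate generate the inputs with the synthetic module.
#' @param frame_offset reading-frame offset of the amplicon.
#' @param pss_positions positively selected amino-acid positions (input,
#'   never inferred).
#' @param k_range,bic_drop_threshold supertype scan controls.
#' @param groups named list of site groups for association tests and null
#'   simulations (site grouping is a user decision, informed by external
#'   structure analyses).
#' @param alpha family-wise level for the Bonferroni-corrected
#'   association screen.
#' @param n_perm_assoc,n_perm_rho,n_perm_mantel permutation counts.
#' @param ensemble_size simulated genotypes per null ensemble.
#' @param ks_resamples Monte-Carlo replicates for KS / mean p-values.
#' @param lonlat treat coordinates as lon/lat (else planar).
#' @param seed master integer seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(fasta = NULL, genotypes = NULL, coords = NULL,
                       simulate = is.null(fasta),
                       frame_offset = 0L,
                       pss_positions = c(9L, 18L, 30L, 44L, 57L),
                       k_range = 1:15, bic_drop_threshold = 0.01,
                       groups = NULL, alpha = 0.05,
                       n_perm_assoc = 9999L, n_perm_rho = 999L,
                       n_perm_mantel = 719L, ensemble_size = 50000L,
                       ks_resamples = 10000L, lonlat = FALSE, seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Load a run configuration from a YAML file
#' @param path YAML file whose keys are [run_config] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

.stage_seed <- function(seed, offset) (as.integer(seed) + offset) %% .Machine$integer.max

#' Run the full analysis pipeline
#'
#' Executes the stages in their scientific order -- supertype clustering,
#' allele-association screen, null genotype simulation per site group,
#' diversity table, Rho differentiation, Mantel isolation-by-distance --
#' and writes all report artifacts (TSV tables, JSON reports, run log with
#' the echoed configuration) to `out_dir`. Rerunning with the same
#' configuration gives bit-identical numeric outputs.
#'
#' @param config a [run_config] or path to a YAML file.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with every stage result (`dataset`, `model`,
#'   `associations`, `null_comparisons`, `diversity`, `rho_mhc`,
#'   `mantel`, ...).
#' @export
run_all <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  log <- list(config = unclass(config),
              r_version = as.character(getRversion()),
              package_version = as.character(utils::packageVersion("mhcdiv")))

  # --- inputs -----------------------------------------------------------
  if (isTRUE(config$simulate)) {
    cat_truth <- make_allele_catalog(seed = .stage_seed(seed, 11L))
    pop <- make_populations(cat_truth, seed = .stage_seed(seed, 13L))
    dataset <- pop$dataset
    dataset$coords <- make_coords(length(dataset$sites), "linear")
    write_truth(c(cat_truth["truth"], pop["truth"]),
                file.path(out_dir, "synthetic_truth.json"))
    catalog <- cat_truth$catalog
    log$inputs <- "synthetic demo dataset"
  } else {
    catalog <- read_allele_fasta(config$fasta,
                                 frame_offset = config$frame_offset)
    dataset <- read_genotype_table(config$genotypes, catalog,
                                   coords = config$coords)
    log$inputs <- list(fasta = config$fasta, genotypes = config$genotypes,
                       coords = config$coords)
  }
  groups <- config$groups
  if (is.null(groups))
    groups <- stats::setNames(as.list(dataset$sites), dataset$sites)

  # --- supertypes -------------------------------------------------------
  model <- cluster_supertypes(catalog, config$pss_positions,
                              k_range = config$k_range,
                              seed = .stage_seed(seed, 17L),
                              drop_threshold = config$bic_drop_threshold)
  write_supertype_map(model, file.path(out_dir, "supertypes.tsv"))
  utils::write.table(
    data.frame(k = as.integer(names(model$bic_curve)),
               bic = unname(model$bic_curve)),
    file.path(out_dir, "bic_curve.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  # --- associations & null simulations per group ------------------------
  associations <- list()
  null_comparisons <- list()
  for (gname in names(groups)) {
    gsites <- groups[[gname]]
    assoc <- suppressWarnings(
      significant_pairs(dataset, sites = gsites, alpha = config$alpha,
                        n_perm = config$n_perm_assoc,
                        seed = .stage_seed(seed, 19L)))
    associations[[gname]] <- assoc
    write_association_table(
      assoc, file.path(out_dir, paste0("association_", gname, ".tsv")))
    spectrum <- incidence_spectrum(dataset, sites = gsites)
    linked <- assoc[assoc$significant, , drop = FALSE]
    linked_pairs <- if (nrow(linked))
      lapply(seq_len(nrow(linked)),
             function(i) c(linked$allele_1[i], linked$allele_2[i]))
    else list()
    # overlapping significant pairs cannot be simulated jointly; keep the
    # strongest-first disjoint subset
    kept <- list(); used <- character()
    for (pr in linked_pairs)
      if (!any(pr %in% used)) { kept <- c(kept, list(pr)); used <- c(used, pr) }
    unlinked <- simulate_unlinked(spectrum, config$ensemble_size,
                                  seed = .stage_seed(seed, 23L),
                                  model = model)
    cmp <- list(
      unlinked = compare_supertype_means(
        dataset, model, unlinked, sites = gsites,
        n_resample = config$ks_resamples, seed = .stage_seed(seed, 29L)))
    if (length(kept)) {
      linked_ens <- simulate_linked(spectrum, kept, config$ensemble_size,
                                    seed = .stage_seed(seed, 31L),
                                    model = model)
      cmp$linked <- compare_supertype_means(
        dataset, model, linked_ens, sites = gsites,
        n_resample = config$ks_resamples, seed = .stage_seed(seed, 37L))
    }
    null_comparisons[[gname]] <- cmp
    report <- lapply(cmp, function(x) list(
      observed_mean = x$observed_mean, null_mean = x$null_mean,
      ks_D = x$ks$D, ks_p = x$ks$p, mean_p_upper = x$mean_p_upper,
      n_obs = x$n_obs, ensemble_size = x$ensemble_size, mode = x$mode))
    jsonlite::write_json(report,
                         file.path(out_dir, paste0("nullsim_", gname, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  # --- diversity --------------------------------------------------------
  div <- suppressWarnings(
    diversity_table(dataset, model = model,
                    pss_positions = config$pss_positions))
  write_diversity_table(div, file.path(out_dir, "diversity.tsv"))

  # --- differentiation --------------------------------------------------
  rho_mhc <- rho_matrix(dataset, n_perm = config$n_perm_rho,
                        seed = .stage_seed(seed, 41L),
                        marker_label = "MHC")
  write_differentiation_matrix(rho_mhc,
                               file.path(out_dir, "rho_mhc.tsv"))

  mantel_report <- NULL
  if (!is.null(dataset$coords)) {
    geo <- geographic_distance(dataset$coords, lonlat = config$lonlat)
    gt <- rho_mhc$rho_transformed
    mantel_report <- list(
      mhc_vs_geography = mantel_test(gt, geo,
                                     n_perm = config$n_perm_mantel,
                                     seed = .stage_seed(seed, 43L)))
    jsonlite::write_json(mantel_report,
                         file.path(out_dir, "mantel.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  log$seed <- seed
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(list(dataset = dataset, catalog = catalog, model = model,
                 associations = associations,
                 null_comparisons = null_comparisons, diversity = div,
                 rho_mhc = rho_mhc, mantel = mantel_report,
                 out_dir = out_dir))
}
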