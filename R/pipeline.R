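#' Run the full community-structure pipeline
#'
#' Sequences the whole analysis: load (or simulate) inputs, validate that
#' the tree, community and trait tables agree on the species set, compute
#' phylogenetic and functional distance matrices, alpha-structure SES
#' tables, the four null-standardized beta matrices, region contrasts,
#' phylogenetic-signal tests, temperature predictors, NMDS ordinations with
#' fitted temperature vectors, and Mantel tests between the beta matrices.
#' All stage outputs are written as CSV into `out_dir` along with a
#' `manifest.json` recording the configuration, seed, package version and
#' MD5 digests of every output, so a rerun with the same configuration can
#' be verified byte-for-byte.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   `out_dir` (required); either `scenario` (`"paperlike"`/`"neutral"`,
#'   with optional `n_species`, `n_sites`) or input paths `tree`, `comm`,
#'   `traits`, `sites`, `climate`; and optional `seed`, `n_null` (999),
#'   `n_perm` (999), `dnn_convention` (`"literal"`), `fluctuation`
#'   (`"sd"`).
#' @return Invisibly, a list with every stage result plus the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% stop("config needs 'out_dir'", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  n_null <- config$n_null %||% 999L
  n_perm <- config$n_perm %||% 999L
  convention <- config$dnn_convention %||% "literal"
  fluctuation <- config$fluctuation %||% "sd"

  if (!is.null(config$scenario)) {
    dat <- simulate_scenario(config$scenario,
                             n_species = config$n_species %||% 80,
                             n_sites = config$n_sites %||% 42,
                             seed = seed)
    tree <- dat$tree; comm <- dat$comm; traits <- dat$traits
    longitudes <- setNames(dat$sites$longitude, dat$sites$site)
    climate <- dat$climate
  } else {
    for (f in c("tree", "comm", "traits", "sites", "climate"))
      if (is.null(config[[f]]) || !file.exists(config[[f]]))
        stop("missing input file for '", f, "'", call. = FALSE)
    tree <- read_newick(file = config$tree)
    comm <- read_community(config$comm)
    traits <- read_traits(config$traits)
    longitudes <- read_sites(config$sites)
    climate <- read_climate(config$climate)
  }

  comm_sp <- colnames(comm)
  not_in_tree <- setdiff(comm_sp, tree$tip.label)
  not_in_traits <- setdiff(comm_sp, rownames(traits))
  if (length(not_in_tree) || length(not_in_traits))
    stop("community species absent from tree: {",
         paste(not_in_tree, collapse = ", "), "}; absent from traits: {",
         paste(not_in_traits, collapse = ", "), "}", call. = FALSE)
  extra <- setdiff(tree$tip.label, comm_sp)
  if (length(extra)) {
    message("pruning ", length(extra), " tree tip(s) not in the communities")
    tree <- ape::drop.tip(tree, extra)
  }
  regions <- assign_regions(longitudes[rownames(comm)])

  dist_phylo <- cophenetic_matrix(tree)
  dist_trait <- gower_matrix(traits[comm_sp, , drop = FALSE])

  # alpha structure: MPD/MNTD in both spaces
  alpha <- do.call(rbind, list(
    ses_alpha(comm, dist_phylo, "mpd", n_null = n_null, seed = seed + 1L),
    ses_alpha(comm, dist_phylo, "mntd", n_null = n_null, seed = seed + 2L),
    ses_alpha(comm, dist_trait, "mpd", n_null = n_null, seed = seed + 3L,
              metric_label = "traitMPD"),
    ses_alpha(comm, dist_trait, "mntd", n_null = n_null, seed = seed + 4L,
              metric_label = "traitMNTD")))
  alpha$region <- regions[alpha$site]
  utils::write.csv(alpha, file.path(out_dir, "alpha.csv"), row.names = FALSE)

  # beta structure: Dpw/Dnn in both spaces, tip-shuffle standardized
  beta_specs <- list(dpw = dist_phylo, dnn = dist_phylo,
                     traitdpw = dist_trait, traitdnn = dist_trait)
  beta <- list()
  contrasts <- list()
  for (i in seq_along(beta_specs)) {
    name <- names(beta_specs)[i]
    metric <- if (grepl("dpw", name)) "dpw" else "dnn"
    b <- beta_null_standardize(comm, beta_specs[[i]], metric,
                               convention = convention, n_null = n_null,
                               seed = seed + 10L + i)
    beta[[name]] <- b
    utils::write.csv(b$obs, file.path(out_dir, paste0("beta_", name, ".csv")))
    contrasts[[name]] <- region_contrast(b$obs, regions)
  }
  tukey <- do.call(rbind, lapply(names(contrasts), function(nm) {
    tk <- contrasts[[nm]]$tukey
    tk$metric <- nm
    tk
  }))
  utils::write.csv(tukey, file.path(out_dir, "region_contrast.csv"),
                   row.names = FALSE)

  # phylogenetic signal of the traits
  signal <- phylosignal_table(tree, traits[comm_sp, , drop = FALSE],
                              n_rand = 1000, seed = seed + 20L)
  utils::write.csv(signal, file.path(out_dir, "signal.csv"), row.names = FALSE)

  # temperature predictors, ordination and vector fitting per beta metric
  predictors <- temperature_predictors(climate[rownames(comm), , drop = FALSE],
                                       fluctuation = fluctuation)
  utils::write.csv(predictors, file.path(out_dir, "predictors.csv"))
  envfit_all <- list()
  ords <- list()
  for (nm in names(beta)) {
    ord <- nmds_ordination(beta[[nm]]$obs, seed = seed + 30L)
    ords[[nm]] <- ord
    ef <- envfit_vectors(ord, predictors, n_perm = n_perm, seed = seed + 40L)
    ef$metric <- nm
    ef$stress <- ord$stress
    envfit_all[[nm]] <- ef
  }
  envfit_df <- do.call(rbind, envfit_all)
  utils::write.csv(envfit_df, file.path(out_dir, "envfit.csv"),
                   row.names = FALSE)

  # Mantel tests: phylogenetic vs functional turnover, with and without
  # controlling for taxonomic (Bray-Curtis) dissimilarity
  td <- as.matrix(vegan::vegdist(comm, method = "bray"))
  mant <- rbind(
    data.frame(pair = "dpw~traitdpw", control = "none",
               as.data.frame(partial_mantel(beta$dpw$obs, beta$traitdpw$obs,
                                            n_perm = n_perm,
                                            seed = seed + 50L))),
    data.frame(pair = "dpw~traitdpw", control = "taxonomic",
               as.data.frame(partial_mantel(beta$dpw$obs, beta$traitdpw$obs,
                                            control = td, n_perm = n_perm,
                                            seed = seed + 51L))),
    data.frame(pair = "dnn~traitdnn", control = "none",
               as.data.frame(partial_mantel(beta$dnn$obs, beta$traitdnn$obs,
                                            n_perm = n_perm,
                                            seed = seed + 52L))))
  utils::write.csv(mant, file.path(out_dir, "mantel.csv"), row.names = FALSE)

  outputs <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
  manifest <- list(
    config = config[setdiff(names(config), "out_dir")],
    seed = seed,
    package_version = as.character(utils::packageVersion("commstruct")),
    outputs = as.list(tools::md5sum(outputs)),
    created = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(alpha = alpha, beta = beta, region_contrasts = contrasts,
                 signal = signal, predictors = predictors,
                 ordinations = ords, envfit = envfit_df, mantel = mant,
                 regions = regions, manifest = manifest))
}
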