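#' Simulation configuration
#'
#' Parameters of the synthetic reef-seawater dataset generator. Defaults
#' emulate the sampling design the pipeline targets: four sampling trips,
#' twelve reef sites per trip, four replicate samples per site, several
#' hundred genus-level taxa collapsing onto far fewer GO terms.
#'
#' The generative model works in log-abundance space. Each taxon has a
#' log-normal baseline; planted indicator features respond linearly (in
#' latent log units) to one designated environment variable; every trip
#' adds its own offsets both to the environment variables (seasonal signal)
#' and to taxon log-abundances (batch effect); counts are multinomial draws
#' over the softmax of the latent log-abundances.
#'
#' Functional redundancy is emulated by the taxon-to-GO map together with
#' trip-rotated signal expression: within an indicator GO group the member
#' taxon that most strongly carries the environmental signal rotates from
#' trip to trip (the designated member carries weight
#' `k / (1 + (k-1) * rotation_gamma)` scaled so the group sum responds with
#' slope `effect_size`, the remaining members carry `rotation_gamma` times
#' that). A GO term therefore associates with its variable in every trip,
#' while any single member taxon does so strongly in only one trip.
#'
#' @param n_trips number of sampling trips (independent studies).
#' @param sites_per_trip reef sites visited per trip (sites are unique to a
#'   trip).
#' @param replicates_per_site replicate seawater samples per site.
#' @param n_taxa number of genus-level taxa.
#' @param n_go number of GO terms; each GO term aggregates `redundancy`
#'   member taxa, so `redundancy * n_go` must not exceed `n_taxa`.
#' @param redundancy member taxa per GO term.
#' @param n_env number of environment variables (17 uses the canonical
#'   variable names of [env_variable_names()]).
#' @param n_indicator_go number of GO terms with a planted environmental
#'   association.
#' @param effect_size planted slope, in latent log-abundance (hence
#'   approximately CLR) units per standard deviation of the designated
#'   environment variable.
#' @param batch_sd standard deviation of trip-level additive offsets, both
#'   for environment block factors and per-taxon log abundances.
#' @param rotation_gamma relative signal weight of the non-designated
#'   members of an indicator group, in (0, 1].
#' @param noise_sd standard deviation of per-sample per-taxon latent noise.
#' @param library_size_mean expected reads per sample (Poisson).
#' @param env_block_cor within-block correlation of the two collinear
#'   environment blocks (particulate + pigments vs dissolved nutrients).
#' @param n_missing_env number of environment cells set missing at random.
#' @param seed integer RNG seed; generation is fully deterministic given it.
#'
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_trips = 4, sites_per_trip = 12,
                       replicates_per_site = 4, n_taxa = 600, n_go = 150,
                       redundancy = 4, n_env = 17, n_indicator_go = 40,
                       effect_size = 1, batch_sd = 1, rotation_gamma = 0.5,
                       noise_sd = 1, library_size_mean = 1e5,
                       env_block_cor = 0.7, n_missing_env = 2, seed = 1) {
  cfg <- list(n_trips = n_trips, sites_per_trip = sites_per_trip,
              replicates_per_site = replicates_per_site, n_taxa = n_taxa,
              n_go = n_go, redundancy = redundancy, n_env = n_env,
              n_indicator_go = n_indicator_go, effect_size = effect_size,
              batch_sd = batch_sd, rotation_gamma = rotation_gamma,
              noise_sd = noise_sd, library_size_mean = library_size_mean,
              env_block_cor = env_block_cor, n_missing_env = n_missing_env,
              seed = as.integer(seed))
  counts <- c("n_trips", "sites_per_trip", "replicates_per_site",
              "n_taxa", "n_go", "n_env")
  for (nm in counts)
    if (cfg[[nm]] < 1) stop(nm, " must be >= 1")
  if (cfg$redundancy < 1) stop("redundancy must be >= 1")
  if (cfg$n_indicator_go > cfg$n_go)
    stop("n_indicator_go cannot exceed n_go")
  if (cfg$redundancy * cfg$n_go > cfg$n_taxa)
    stop("redundancy * n_go exceeds n_taxa; the taxon-to-GO map is one ",
         "group per taxon")
  if (cfg$effect_size < 0) stop("effect_size must be >= 0")
  if (cfg$rotation_gamma <= 0 || cfg$rotation_gamma > 1)
    stop("rotation_gamma must be in (0, 1]")
  class(cfg) <- "sim_config"
  cfg
}

# Two collinear environment blocks plus three stand-alone variables.
# Particulate nutrients and pigments covary (phytoplankton biomass);
# dissolved N/P pools form the second block, anti-correlated with the first
# (uptake during production); TSS, temperature and salinity are generated
# independently apart from their own trip offsets.
.env_blocks <- function(vars) {
  list(particulate = intersect(
         c("Chl_a", "Phaeo", "PN", "POC", "PP", "DOC",
           "Chl_a_fluorescence"), vars),
       dissolved = intersect(
         c("PO4", "NH4", "NO2", "NO3", "Si", "TDN", "TDP"), vars))
}

# Plausible oligotrophic-reef baselines (location, spread) used to map the
# standardized latent variable onto measurement-like scales.
.env_baselines <- function(vars) {
  base <- c(Chl_a = 0.2, Phaeo = 0.2, PN = 1.1, POC = 7.5, PP = 0.05,
            DOC = 75, PO4 = 0.05, NH4 = 0.4, NO2 = 0.03, NO3 = 0.3,
            Si = 1.6, TDN = 5.6, TDP = 0.21, TSS = 0.3,
            Temperature = 27.5, Salinity = 35.2, Chl_a_fluorescence = 0.15)
  spread <- c(Chl_a = 0.05, Phaeo = 0.05, PN = 0.25, POC = 1.8, PP = 0.012,
              DOC = 7, PO4 = 0.012, NH4 = 0.1, NO2 = 0.008, NO3 = 0.08,
              Si = 0.4, TDN = 0.8, TDP = 0.03, TSS = 0.08,
              Temperature = 1.5, Salinity = 0.2, Chl_a_fluorescence = 0.04)
  if (!all(vars %in% names(base))) {
    extra <- setdiff(vars, names(base))
    base[extra] <- 1
    spread[extra] <- 0.25
  }
  list(base = base[vars], spread = spread[vars])
}

#' Generate a synthetic taxa/GO/environment dataset with known ground truth
#'
#' Draws one complete dataset under the model described in [sim_config()]:
#' an environment table with two collinear variable blocks and trip-level
#' seasonal offsets, a taxa count table whose planted indicator groups
#' respond linearly to designated environment variables (with the
#' signal-carrying member taxon rotating across trips), and a GO count
#' table obtained by summing member taxa, so that GO-level signals are
#' carried consistently across trips while taxon-level signals are
#' trip-specific.
#'
#' @param config a [sim_config()].
#' @return object of class `synthetic_dataset`: list with elements
#'   `taxa_counts` and `go_counts` ([count_table()]s), `env`
#'   ([env_table()]), `truth` (list with `indicator_go`, `indicator_taxa`,
#'   `taxon_go_map`, `feature_truth` data.frame, `trip_env_offsets`,
#'   `active_member`), and `config`.
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  n_sites <- cfg$n_trips * cfg$sites_per_trip
  n_samples <- n_sites * cfg$replicates_per_site

  ## ---- site / sample metadata -------------------------------------------
  trip_of_site <- rep(seq_len(cfg$n_trips), each = cfg$sites_per_trip)
  site_ids <- sprintf("S%02d", seq_len(n_sites))
  # Trips occupy distinct latitude sectors along a reef tract (geography is
  # confounded with trip, as in multi-leg voyages).
  trip_lat_center <- seq(-12, -23, length.out = cfg$n_trips)
  lat <- trip_lat_center[trip_of_site] + stats::rnorm(n_sites, 0, 0.8)
  lon <- 146 + (abs(lat) - 11) * 0.45 + stats::rnorm(n_sites, 0, 0.4)
  sites <- data.frame(site = site_ids, trip = trip_of_site,
                      lat = lat, lon = lon)

  samples <- data.frame(
    sample_id = sprintf("%s_r%d", rep(site_ids, each = cfg$replicates_per_site),
                        rep(seq_len(cfg$replicates_per_site), n_sites)),
    trip = rep(trip_of_site, each = cfg$replicates_per_site),
    site = rep(site_ids, each = cfg$replicates_per_site),
    replicate = rep(seq_len(cfg$replicates_per_site), n_sites),
    lat = rep(lat, each = cfg$replicates_per_site),
    lon = rep(lon, each = cfg$replicates_per_site))

  ## ---- environment ------------------------------------------------------
  vars <- if (cfg$n_env == 17) env_variable_names() else
    sprintf("env_%02d", seq_len(cfg$n_env))
  blocks <- .env_blocks(vars)
  rho <- cfg$env_block_cor

  # Site-level block factors: bivariate with cross-block correlation -0.4,
  # plus trip (seasonal) offsets of SD batch_sd.
  gA <- stats::rnorm(n_sites)
  gB <- -0.4 * gA + sqrt(1 - 0.4^2) * stats::rnorm(n_sites)
  sA <- stats::rnorm(cfg$n_trips, 0, cfg$batch_sd)
  sB <- stats::rnorm(cfg$n_trips, 0, cfg$batch_sd)
  fA <- sA[trip_of_site] + gA
  fB <- sB[trip_of_site] + gB

  z <- matrix(NA_real_, n_sites, cfg$n_env, dimnames = list(site_ids, vars))
  trip_var_offset <- matrix(stats::rnorm(cfg$n_trips * cfg$n_env, 0,
                                         cfg$batch_sd),
                            cfg$n_trips, cfg$n_env,
                            dimnames = list(NULL, vars))
  for (v in vars) {
    eps <- stats::rnorm(n_sites)
    if (v %in% blocks$particulate) {
      z[, v] <- sqrt(rho) * fA + sqrt(1 - rho) * eps
    } else if (v %in% blocks$dissolved) {
      z[, v] <- sqrt(rho) * fB + sqrt(1 - rho) * eps
    } else {
      z[, v] <- trip_var_offset[trip_of_site, v] + eps
    }
  }

  bl <- .env_baselines(vars)
  env_values <- sweep(sweep(z, 2, bl$spread, `*`), 2, bl$base, `+`)
  conc <- setdiff(vars, c("Temperature", "Salinity"))
  env_values[, conc] <- pmax(env_values[, conc], 0)
  if (cfg$n_missing_env > 0) {
    miss <- sample(length(env_values), min(cfg$n_missing_env,
                                           length(env_values)))
    env_values[miss] <- NA
  }
  env <- env_table(env_values, sites)

  ## ---- taxon -> GO map and planted signal -------------------------------
  mapped <- sample(cfg$n_taxa, cfg$redundancy * cfg$n_go)
  taxon_group <- rep(NA_integer_, cfg$n_taxa)
  taxon_group[mapped] <- rep(seq_len(cfg$n_go), each = cfg$redundancy)
  member_index <- rep(NA_integer_, cfg$n_taxa)
  member_index[mapped] <- rep(seq_len(cfg$redundancy), cfg$n_go)

  indicator_go <- sort(sample(cfg$n_go, cfg$n_indicator_go))
  signal_vars <- c(blocks$particulate, blocks$dissolved)
  if (length(signal_vars) == 0) signal_vars <- vars
  designated_var <- stats::setNames(rep(NA_character_, cfg$n_go),
                                    sprintf("GO_%04d", seq_len(cfg$n_go)))
  designated_var[indicator_go] <-
    signal_vars[(seq_along(indicator_go) - 1) %% length(signal_vars) + 1]

  # Signal weights: designated member w_d, others gamma * w_d, scaled so the
  # equal-share group sum responds with slope = effect_size.
  k <- cfg$redundancy
  w_d <- k / (1 + (k - 1) * cfg$rotation_gamma)
  w_o <- cfg$rotation_gamma * w_d

  ## ---- latent log abundances and counts ---------------------------------
  taxa_ids <- sprintf("Taxon_%04d", seq_len(cfg$n_taxa))
  go_ids <- sprintf("GO_%04d", seq_len(cfg$n_go))

  base <- stats::rnorm(cfg$n_taxa, 0, 1.5)
  # equal baselines within indicator groups so the group response is the
  # share-weighted mean of member responses
  grp_base <- stats::rnorm(cfg$n_go, 0, 1.5)
  ind_members <- !is.na(taxon_group) & taxon_group %in% indicator_go
  base[ind_members] <- grp_base[taxon_group[ind_members]]

  batch <- matrix(stats::rnorm(cfg$n_trips * cfg$n_taxa, 0, cfg$batch_sd),
                  cfg$n_trips, cfg$n_taxa)

  site_of_sample <- match(samples$site, site_ids)
  lambda <- matrix(rep(base, each = n_samples), n_samples, cfg$n_taxa)
  lambda <- lambda + batch[samples$trip, , drop = FALSE]

  active_member <- matrix(NA_integer_, cfg$n_trips, cfg$n_go)
  for (g in indicator_go) {
    members <- which(!is.na(taxon_group) & taxon_group == g)
    v <- designated_var[g]
    zv <- z[site_of_sample, v]
    for (t in seq_len(cfg$n_trips)) {
      act <- ((t - 1) %% k) + 1
      active_member[t, g] <- members[act]
      in_trip <- samples$trip == t
      for (m in seq_along(members)) {
        w <- if (m == act) w_d else w_o
        lambda[in_trip, members[m]] <- lambda[in_trip, members[m]] +
          cfg$effect_size * w * zv[in_trip]
      }
    }
  }
  lambda <- lambda + matrix(stats::rnorm(n_samples * cfg$n_taxa, 0,
                                         cfg$noise_sd),
                            n_samples, cfg$n_taxa)

  lib <- stats::rpois(n_samples, cfg$library_size_mean)
  counts <- matrix(0L, n_samples, cfg$n_taxa,
                   dimnames = list(samples$sample_id, taxa_ids))
  for (i in seq_len(n_samples)) {
    p <- exp(lambda[i, ] - max(lambda[i, ]))
    counts[i, ] <- stats::rmultinom(1, lib[i], p / sum(p))[, 1]
  }

  ## ---- annotations ------------------------------------------------------
  taxa_lineage <- sprintf(
    "Bacteria;Phylum_%02d;Class_%03d;Order_%03d;Family_%03d;%s",
    (seq_len(cfg$n_taxa) - 1) %/% 120 + 1,
    (seq_len(cfg$n_taxa) - 1) %/% 27 + 1,
    (seq_len(cfg$n_taxa) - 1) %/% 9 + 1,
    (seq_len(cfg$n_taxa) - 1) %/% 3 + 1,
    taxa_ids)
  taxa_features <- data.frame(feature_id = taxa_ids, lineage = taxa_lineage,
                              class = "bacteria")
  taxa_ct <- count_table(counts, samples, taxa_features,
                         ranks = c("domain", "phylum", "class", "order",
                                   "family", "genus"))

  go_lineage <- sprintf("R3_%02d;R4_%03d;%s",
                        (seq_len(cfg$n_go) - 1) %/% 9 + 1,
                        (seq_len(cfg$n_go) - 1) %/% 3 + 1,
                        go_ids)
  go_features <- data.frame(feature_id = go_ids, lineage = go_lineage,
                            class = "go")
  go_counts <- counts[, mapped, drop = FALSE] %*%
    stats::model.matrix(~ 0 + factor(taxon_group[mapped],
                                     levels = seq_len(cfg$n_go)))
  colnames(go_counts) <- go_ids
  go_ct <- count_table(go_counts, samples, go_features,
                       ranks = c("rank3", "rank4", "rank5"))

  ## ---- ground truth -----------------------------------------------------
  taxon_go_map <- data.frame(
    taxon = taxa_ids[mapped],
    go = go_ids[taxon_group[mapped]],
    member = member_index[mapped])
  feature_truth <- rbind(
    data.frame(feature_id = go_ids, type = "go",
               designated_var = unname(designated_var),
               slope = ifelse(seq_len(cfg$n_go) %in% indicator_go,
                              cfg$effect_size, 0)),
    data.frame(feature_id = taxa_ids, type = "taxon",
               designated_var = ifelse(is.na(taxon_group), NA,
                                       designated_var[taxon_group]),
               slope = ifelse(ind_members, cfg$effect_size, 0)))

  truth <- list(
    indicator_go = go_ids[indicator_go],
    indicator_taxa = taxa_ids[ind_members],
    taxon_go_map = taxon_go_map,
    feature_truth = feature_truth,
    trip_env_offsets = data.frame(trip = seq_len(cfg$n_trips),
                                  particulate = sA, dissolved = sB),
    active_member = active_member,
    env_z = z)

  structure(list(taxa_counts = taxa_ct, go_counts = go_ct, env = env,
                 truth = truth, config = cfg),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_dataset: %d samples (%d trips x %d sites x %d reps)\n",
    nrow(x$taxa_counts$counts), x$config$n_trips, x$config$sites_per_trip,
    x$config$replicates_per_site))
  cat(sprintf("  %d taxa -> %d GO terms (%d planted indicator GO terms)\n",
              x$config$n_taxa, x$config$n_go, x$config$n_indicator_go))
  invisible(x)
}

#' Write a synthetic dataset as delimited text
#'
#' Emits the dataset as plain TSV files (`samples.tsv`, `taxa_counts.tsv`,
#' `go_counts.tsv`, `taxa_annotation.tsv`, `go_annotation.tsv`, `env.tsv`,
#' `truth.tsv`) that round-trip losslessly through [read_count_table()] and
#' [read_env_table()]. Count tables are written features x samples, as
#' exported by read-annotation tools.
#'
#' @param ds a [generate_dataset()] result.
#' @param directory output directory, created if absent.
#' @return invisibly, a manifest data.frame (file, rows, cols).
#' @export
write_dataset <- function(ds, directory) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(directory, f)

  write_count_table(ds$taxa_counts, p("taxa_counts.tsv"),
                    p("taxa_annotation.tsv"))
  write_count_table(ds$go_counts, p("go_counts.tsv"),
                    p("go_annotation.tsv"))
  utils::write.table(ds$taxa_counts$samples, p("samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_env_table(ds$env, p("env.tsv"))
  utils::write.table(ds$truth$feature_truth, p("truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$truth$taxon_go_map, p("taxon_go_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- data.frame(
    file = c("taxa_counts.tsv", "go_counts.tsv", "samples.tsv", "env.tsv",
             "truth.tsv", "taxon_go_map.tsv"),
    rows = c(ncol(ds$taxa_counts$counts), ncol(ds$go_counts$counts),
             nrow(ds$taxa_counts$samples), nrow(ds$env$values),
             nrow(ds$truth$feature_truth), nrow(ds$truth$taxon_go_map)),
    cols = c(nrow(ds$taxa_counts$counts) + 1, nrow(ds$go_counts$counts) + 1,
             ncol(ds$taxa_counts$samples), ncol(ds$env$values) + 2,
             ncol(ds$truth$feature_truth), ncol(ds$truth$taxon_go_map)))
  utils::write.table(manifest, p("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
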