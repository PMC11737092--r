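test_that("generation is deterministic given the seed", {
  a <- generate_dataset(small_sim_config(seed = 4))
  b <- generate_dataset(small_sim_config(seed = 4))
  expect_identical(a$taxa_counts$counts, b$taxa_counts$counts)
  expect_identical(a$env$values, b$env$values)
  expect_identical(a$truth$feature_truth, b$truth$feature_truth)
  d <- generate_dataset(small_sim_config(seed = 5))
  expect_false(identical(a$taxa_counts$counts, d$taxa_counts$counts))
})

test_that("GO counts are the taxon-to-GO map column sums of taxa counts", {
  ds <- generate_dataset(small_sim_config(seed = 2))
  map <- ds$truth$taxon_go_map
  for (g in sample(colnames(ds$go_counts$counts), 5)) {
    members <- map$taxon[map$go == g]
    expect_equal(ds$go_counts$counts[, g],
                 rowSums(ds$taxa_counts$counts[, members, drop = FALSE]))
  }
})

test_that("row sums approximate the configured library size", {
  cfg <- small_sim_config(seed = 3)
  ds <- generate_dataset(cfg)
  lib <- rowSums(ds$taxa_counts$counts)
  expect_true(abs(mean(lib) - cfg$library_size_mean) <
                4 * sqrt(cfg$library_size_mean))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_indicator_go = 200, n_go = 100),
               "n_indicator_go")
  expect_error(sim_config(redundancy = 10, n_go = 100, n_taxa = 600),
               "exceeds n_taxa")
  expect_error(sim_config(effect_size = -1), "effect_size")
  expect_error(sim_config(n_trips = 0), "n_trips")
})

test_that("zero effect size leaves planted features inside the null band", {
  # oracle: direct Spearman correlation between each planted GO term's
  # relative abundance and its designated variable, over repeated seeds.
  # batch_sd = 0: trip-level batch shifts would otherwise induce genuine
  # (confounded) abundance-environment correlation even without a planted
  # effect — that confound is what the MINT integration exists to remove.
  inside <- total <- 0
  for (s in 1:8) {
    ds <- generate_dataset(small_sim_config(seed = 100 + s,
                                            effect_size = 0,
                                            batch_sd = 0))
    ra <- relative_abundance(ds$go_counts)
    env <- env_for_samples(ds$go_counts, impute_env_within_trip(ds$env))
    tt <- ds$truth$feature_truth
    n <- nrow(ra)
    for (g in ds$truth$indicator_go) {
      v <- tt$designated_var[tt$feature_id == g]
      rho <- suppressWarnings(cor(ra[, g], env[, v], method = "spearman"))
      inside <- inside + (abs(rho) < 3 / sqrt(n))
      total <- total + 1
    }
  }
  expect_gte(inside / total, 0.95)
})

test_that("GO terms track environment more consistently across trips than
           their member taxa (functional redundancy contrast)", {
  ds <- generate_dataset(small_sim_config(seed = 6))
  clr_go <- clr_transform(ds$go_counts)
  clr_tx <- clr_transform(ds$taxa_counts)
  z <- ds$truth$env_z
  smp <- ds$go_counts$samples
  site_of <- match(smp$site, rownames(z))
  tt <- ds$truth$feature_truth
  map <- ds$truth$taxon_go_map
  gap <- vapply(ds$truth$indicator_go, function(g) {
    v <- tt$designated_var[tt$feature_id == g]
    members <- map$taxon[map$go == g]
    per_trip <- vapply(sort(unique(smp$trip)), function(t) {
      idx <- smp$trip == t
      zz <- z[site_of[idx], v]
      c(abs(cor(clr_go[idx, g], zz)),
        mean(abs(cor(clr_tx[idx, members, drop = FALSE], zz))))
    }, numeric(2))
    mean(per_trip[1, ]) - mean(per_trip[2, ])
  }, numeric(1))
  expect_gt(mean(gap), 0)
  expect_gte(mean(gap > 0), 0.8)
})

test_that("planted slopes are recovered by OLS on CLR values", {
  cfg <- sim_config(sites_per_trip = 24, batch_sd = 0, n_missing_env = 0,
                    seed = 11)
  ds <- generate_dataset(cfg)
  clr <- clr_transform(ds$go_counts)
  env <- env_for_samples(ds$go_counts, ds$env)
  tt <- ds$truth$feature_truth
  slopes <- vapply(ds$truth$indicator_go, function(g) {
    v <- tt$designated_var[tt$feature_id == g]
    unname(coef(lm(clr[, g] ~ scale(env[, v])))[2])
  }, numeric(1))
  expect_true(all(abs(slopes - cfg$effect_size) <
                    0.25 * cfg$effect_size))
})

test_that("between-trip variance of PCA scores grows with batch_sd", {
  between_trip_var <- function(batch_sd, seed) {
    ds <- generate_dataset(small_sim_config(seed = seed,
                                            batch_sd = batch_sd))
    pc <- clr_pca(clr_transform(ds$taxa_counts), 2)
    centroids <- apply(pc$scores[, 1:2], 2,
                       tapply, ds$taxa_counts$samples$trip, mean)
    sum(apply(centroids, 2, var))
  }
  levels <- c(0, 1, 2)
  for (s in 1:3) {
    v <- vapply(levels, between_trip_var, numeric(1), seed = 200 + s)
    expect_true(all(diff(v) > 0),
                info = sprintf("seed %d: %s", s, paste(signif(v, 3),
                                                       collapse = " ")))
  }
})

test_that("write_dataset round-trips through the readers", {
  ds <- generate_dataset(small_sim_config(seed = 8))
  dir <- withr::local_tempdir()
  manifest <- write_dataset(ds, dir)

  taxa <- read_count_table(file.path(dir, "taxa_counts.tsv"),
                           file.path(dir, "taxa_annotation.tsv"),
                           file.path(dir, "samples.tsv"))
  expect_equal(taxa$counts, ds$taxa_counts$counts)
  expect_equal(taxa$features$lineage, ds$taxa_counts$features$lineage)
  env <- read_env_table(file.path(dir, "env.tsv"))
  expect_equal(env$values, ds$env$values)

  cfg <- ds$config
  core <- manifest[match(c("taxa_counts.tsv", "go_counts.tsv",
                           "samples.tsv", "env.tsv"), manifest$file), ]
  n_samples <- cfg$n_trips * cfg$sites_per_trip * cfg$replicates_per_site
  expect_equal(core$rows, c(cfg$n_taxa, cfg$n_go, n_samples,
                            cfg$n_trips * cfg$sites_per_trip))

  truth <- read.table(file.path(dir, "truth.tsv"), header = TRUE,
                      sep = "\t")
  go_rows <- truth[truth$type == "go", ]
  expect_true(all(go_rows$slope[go_rows$feature_id %in%
                                  ds$truth$indicator_go] ==
                    cfg$effect_size))
  expect_true(all(go_rows$slope[!go_rows$feature_id %in%
                                  ds$truth$indicator_go] == 0))
})
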