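test_that("within-study normalization gives every study block mean 0
           and unit SD", {
  set.seed(30)
  m <- matrix(rnorm(120, 5, 3), 30, 4)
  studies <- rep(1:3, each = 10)
  sc <- reefmarkers:::.mint_scale(m, studies)$m
  for (s in 1:3) {
    blk <- sc[studies == s, ]
    expect_lt(max(abs(colMeans(blk))), 1e-10)
    expect_lt(max(abs(apply(blk, 2, sd) - 1)), 1e-8)
  }
})

test_that("a single study reduces MINT to plain sPLS on scaled data", {
  set.seed(31)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("x", 1:3)))
  Y <- matrix(rnorm(100), 20, 5, dimnames = list(NULL, paste0("y", 1:5)))
  cfg <- spls_config(n_components = 2, keep_responses = 3)
  a <- mint_spls_fit(X, Y, rep(1, 20), cfg)
  b <- spls_fit(X, Y, cfg)
  expect_equal(a$loadings_x, b$loadings_x, tolerance = 1e-10)
  expect_equal(a$loadings_y, b$loadings_y, tolerance = 1e-10)
})

test_that("per-study constant offsets do not change the fit", {
  set.seed(32)
  X <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("x1", "x2")))
  Y <- matrix(rnorm(160), 40, 4, dimnames = list(NULL, paste0("y", 1:4)))
  studies <- rep(1:4, each = 10)
  cfg <- spls_config(n_components = 1, keep_responses = 2)
  base <- mint_spls_fit(X, Y, studies, cfg)
  X2 <- X + c(0, 5, -3, 100)[studies]
  Y2 <- Y; Y2[, 2] <- Y2[, 2] + c(10, 0, -7, 2)[studies]
  shifted <- mint_spls_fit(X2, Y2, studies, cfg)
  expect_equal(shifted$loadings_x, base$loadings_x, tolerance = 1e-10)
  expect_equal(shifted$loadings_y, base$loadings_y, tolerance = 1e-10)
})

test_that("cross-study-consistent features beat single-study features
           for selection", {
  # oracle: the covariance criterion computed directly on study-scaled
  # data is larger for the consistent feature, and MINT selects it
  set.seed(33)
  n_per <- 15; studies <- rep(1:4, each = n_per)
  x <- rnorm(60)
  X <- cbind(x1 = x)
  consistent <- 0.8 * x + rnorm(60, 0, 0.6)
  single <- ifelse(studies == 1, 0.8 * x, 0) + rnorm(60, 0, 0.6)
  Y <- cbind(cons = consistent, single = single,
             noise = rnorm(60))
  sx <- reefmarkers:::.mint_scale(X, studies)$m
  sy <- reefmarkers:::.mint_scale(Y, studies)$m
  crit <- abs(drop(crossprod(sx, sy)))
  expect_gt(crit["cons"], crit["single"])
  fit <- mint_spls_fit(X, Y, studies,
                       spls_config(n_components = 1, keep_responses = 1))
  expect_equal(selected_features(fit, 1), "cons")
})

test_that("studies with too few samples are rejected", {
  X <- matrix(rnorm(10), 5, 2)
  Y <- matrix(rnorm(15), 5, 3)
  expect_error(mint_spls_fit(X, Y, c(1, 1, 1, 2, 2)), ">= 3 samples")
})

test_that("LOGOCV scores are multiples of 1/n_studies with correct
           flags", {
  ds <- generate_dataset(small_sim_config(seed = 34))
  Y <- clr_transform(ds$go_counts)
  X <- env_for_samples(ds$go_counts, ds$env)
  cfg <- spls_config(n_components = 1, keep_responses = 10)
  sc <- logocv_stability(X, Y, ds$go_counts$samples$trip, cfg)
  expect_true(all(sc$score %in% c(0.25, 0.5, 0.75, 1)))
  flag_cols <- grep("^left_out_", names(sc))
  expect_length(flag_cols, 4)
  expect_equal(rowSums(sc[, flag_cols]) / 4, sc$score)
  expect_equal(sc$stable, sc$score >= 0.5)
  expect_error(logocv_stability(X, Y, rep(1, nrow(X)), cfg),
               "at least 2 studies")
})

test_that("scenario enumeration matches the binomial partition", {
  sc <- enumerate_logocv_scenarios(4)
  expect_equal(sc$total, 15)
  expect_equal(sc$by_score$patterns[sc$by_score$score == 0.5], 6)
  expect_equal(sc$by_score$patterns[sc$by_score$score == 0.75], 4)
  expect_equal(sc$by_score$patterns[sc$by_score$score == 1], 1)
  expect_equal(enumerate_logocv_scenarios(1)$total, 1)
  expect_error(enumerate_logocv_scenarios(0), ">= 1")
})

test_that("planted cross-trip indicators earn high LOGOCV scores", {
  hits <- total <- 0
  for (s in 1:2) {
    ds <- generate_dataset(small_sim_config(seed = 400 + s))
    Y <- clr_transform(ds$go_counts)
    X <- env_for_samples(ds$go_counts, impute_env_within_trip(ds$env))
    cfg <- spls_config(n_components = 1, keep_responses = 15)
    sc <- logocv_stability(X, Y, ds$go_counts$samples$trip, cfg)
    planted <- sc[sc$feature_id %in% ds$truth$indicator_go, ]
    hits <- hits + sum(planted$score >= 0.5)
    total <- total + length(ds$truth$indicator_go)
  }
  expect_gte(hits / total, 0.8)
})

test_that("the indicator report joins scores to heatmap clusters", {
  ds <- generate_dataset(small_sim_config(seed = 36))
  Y <- clr_transform(ds$go_counts)
  X <- env_for_samples(ds$go_counts, impute_env_within_trip(ds$env))
  cfg <- spls_config(n_components = 2, keep_responses = 12)
  fit <- suppressWarnings(mint_spls_fit(X, Y, ds$go_counts$samples$trip,
                                        cfg))
  sim <- suppressWarnings(similarity_matrix(fit, X, Y))
  sc <- logocv_stability(X, Y, ds$go_counts$samples$trip, cfg)
  rep <- stable_indicator_report(sc, sim)
  expect_equal(nrow(rep), ncol(sim))
  expect_equal(sort(unique(rep$cluster)), 1:3)
  expect_true(attr(rep, "enriched_cluster") %in% 1:3)
  # a score table with nothing stable yields zero stable indicators
  sc0 <- sc; sc0$score <- 0.25; sc0$stable <- FALSE
  rep0 <- stable_indicator_report(sc0, sim)
  expect_equal(sum(rep0$stable), 0)
})

test_that("GO indicators are at least as LOGOCV-stable as taxon
           indicators under trip-rotated redundancy", {
  wins <- 0
  for (s in 1:2) {
    ds <- generate_dataset(small_sim_config(seed = 500 + s))
    env <- impute_env_within_trip(ds$env)
    cfg <- spls_config(n_components = 1, keep_responses = 15)
    mean_planted_score <- function(ct, planted) {
      sc <- logocv_stability(env_for_samples(ct, env), clr_transform(ct),
                             ct$samples$trip, cfg)
      m <- match(planted, sc$feature_id)
      mean(ifelse(is.na(m), 0, sc$score[m]))
    }
    go_score <- mean_planted_score(ds$go_counts, ds$truth$indicator_go)
    taxa_score <- mean_planted_score(ds$taxa_counts,
                                     ds$truth$indicator_taxa)
    wins <- wins + (go_score >= taxa_score)
  }
  expect_equal(wins, 2)
})
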