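# Repeated k-fold cross-validation reselection stability of per-trip sPLS
# indicators, and the taxa-vs-GO stability contrast.

#' Reselection stability under repeated k-fold cross-validation
#'
#' The full-data sPLS fit defines the indicator set (the features selected
#' on component 1). Then, for each of `n_repeats` repeats, the samples are
#' partitioned at random into `n_folds` near-equal folds; for each fold
#' the model is refitted on the complement (same configuration) and the
#' component-1 selection recorded. A feature's stability is the fraction
#' of the `n_folds * n_repeats` runs in which it was reselected.
#'
#' @param X,Y numeric matrices, samples x predictors / responses.
#' @param cfg a [spls_config()]; component-1 selection only is used, so
#'   `n_components = 1` is sufficient and fastest.
#' @param n_folds folds per repeat (default 4).
#' @param n_repeats repeats (default 50, i.e. 200 runs).
#' @param seed master RNG seed; all fold partitions derive from it.
#' @return object of class `cv_stability`: list with `stability` (named
#'   vector over the full-fit indicator set), `full_table` (named vector
#'   over every feature, for diagnostics), `indicator_set`, `n_folds`,
#'   `n_repeats`, `runs`, `seed`.
#' @export
cv_stability <- function(X, Y, cfg = spls_config(n_components = 1),
                         n_folds = 4, n_repeats = 50, seed = 1) {
  X <- as.matrix(X); Y <- unclass(as.matrix(Y))
  n <- nrow(X)
  if (n < n_folds) stop("need at least n_folds samples")
  if (n / n_folds < 2) stop("folds would have fewer than 2 samples")
  full <- suppressWarnings(spls_fit(X, Y, cfg))
  indicator_set <- selected_features(full, 1)

  counts <- stats::setNames(numeric(ncol(Y)), colnames(Y))
  set.seed(seed)
  runs <- 0L
  for (r in seq_len(n_repeats)) {
    fold_id <- sample(rep(seq_len(n_folds), length.out = n))
    for (f in seq_len(n_folds)) {
      train <- fold_id != f
      fit <- suppressWarnings(
        spls_fit(X[train, , drop = FALSE], Y[train, , drop = FALSE], cfg))
      sel <- selected_features(fit, 1)
      counts[sel] <- counts[sel] + 1
      runs <- runs + 1L
    }
  }
  stab <- counts / runs
  structure(list(stability = stab[indicator_set], full_table = stab,
                 indicator_set = indicator_set, n_folds = n_folds,
                 n_repeats = n_repeats, runs = runs, seed = seed),
            class = "cv_stability")
}

#' @export
print.cv_stability <- function(x, ...) {
  cat(sprintf(
    "cv_stability: %d indicators, %d runs (%d-fold x %d repeats)\n",
    length(x$stability), x$runs, x$n_folds, x$n_repeats))
  cat(sprintf("  median stability %.3f (sd %.3f)\n",
              stats::median(x$stability), stats::sd(x$stability)))
  invisible(x)
}

#' Per-trip model grid: one sPLS model per (trip, dataset)
#'
#' Each model is restricted to the samples of one trip, so that
#' within-trip associations are assessed free of the geography/season
#' confound, for both the taxonomic and the functional dataset.
#'
#' @param taxa,go [count_table()]s sharing the same samples.
#' @param env an [env_table()].
#' @param trips trips to include (default: all in the metadata).
#' @return data.frame of class `model_grid`: trip, dataset, n_samples.
#' @export
build_model_grid <- function(taxa, go, env, trips = NULL) {
  stopifnot(inherits(taxa, "count_table"), inherits(go, "count_table"),
            inherits(env, "env_table"))
  if (is.null(trips)) trips <- sort(unique(taxa$samples$trip))
  grid <- expand.grid(trip = trips, dataset = c("taxonomy", "go"),
                      stringsAsFactors = FALSE)
  grid$n_samples <- vapply(grid$trip, function(t)
    sum(taxa$samples$trip == t), integer(1))
  class(grid) <- c("model_grid", "data.frame")
  grid
}

#' Pair sample-level response data with site-level environment predictors
#'
#' Each sample receives the environment row of its reef site (the site
#' medians are repeated across replicates).
#'
#' @param ct a [count_table()].
#' @param env an [env_table()] (imputed; no missing cells).
#' @return numeric matrix, one row per sample of `ct`.
#' @export
env_for_samples <- function(ct, env) {
  stopifnot(inherits(ct, "count_table"), inherits(env, "env_table"))
  idx <- match(ct$samples$site, env$sites$site)
  if (anyNA(idx))
    stop("samples reference sites absent from the env table: ",
         paste(unique(ct$samples$site[is.na(idx)]), collapse = ", "))
  out <- env$values[idx, , drop = FALSE]
  rownames(out) <- ct$samples$sample_id
  out
}

#' Run CV reselection stability for every (trip, dataset) model
#'
#' @param taxa,go [count_table()]s (already filtered).
#' @param env an [env_table()] with no missing cells (see
#'   [impute_env_within_trip()]).
#' @param cfg a [spls_config()]; defaults to one component with 50
#'   responses kept.
#' @param n_folds,n_repeats CV design (default fourfold x 50 = 200 runs).
#' @param seed master seed; each model uses `seed + model index`.
#' @param pseudocount CLR pseudocount for the response matrices.
#' @return list with `stability` (data.frame: trip, dataset, feature_id,
#'   stability) and `models` (the [cv_stability()] objects, named
#'   `<dataset>_trip<trip>`).
#' @export
run_cv_stability_grid <- function(taxa, go, env,
                                  cfg = spls_config(n_components = 1,
                                                    keep_responses = 50),
                                  n_folds = 4, n_repeats = 50, seed = 1,
                                  pseudocount = 1) {
  grid <- build_model_grid(taxa, go, env)
  models <- list()
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    t <- grid$trip[i]
    ct <- if (grid$dataset[i] == "taxonomy") taxa else go
    ct_t <- subset_table(ct, samples = which(ct$samples$trip == t))
    if (nrow(ct_t$counts) < n_folds)
      stop("trip ", t, " has fewer samples than n_folds")
    Y <- clr_transform(ct_t, pseudocount)
    X <- env_for_samples(ct_t, env)
    cv <- cv_stability(X, Y, cfg, n_folds = n_folds,
                       n_repeats = n_repeats, seed = seed + i)
    key <- sprintf("%s_trip%s", grid$dataset[i], t)
    models[[key]] <- cv
    rows[[key]] <- data.frame(trip = t, dataset = grid$dataset[i],
                              feature_id = names(cv$stability),
                              stability = unname(cv$stability))
  }
  list(stability = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       models = models)
}

#' Compare taxa vs GO indicator stability within one trip
#'
#' Two-sided Wilcoxon rank-sum test on the two per-indicator stability
#' vectors, with medians, SDs and significance stars.
#'
#' @param taxa_result,go_result [cv_stability()] results fitted on the
#'   same trip's samples.
#' @param trip optional trip label carried into the output.
#' @return data.frame with one row: trip, median/SD per dataset, Wilcoxon
#'   statistic, p, stars.
#' @export
compare_stability <- function(taxa_result, go_result, trip = NA) {
  stopifnot(inherits(taxa_result, "cv_stability"),
            inherits(go_result, "cv_stability"))
  if (taxa_result$runs != go_result$runs)
    stop("results come from different CV designs")
  w <- wilcoxon_rank_sum(taxa_result$stability, go_result$stability)
  data.frame(trip = trip,
             taxa_median = stats::median(taxa_result$stability),
             taxa_sd = stats::sd(taxa_result$stability),
             go_median = stats::median(go_result$stability),
             go_sd = stats::sd(go_result$stability),
             statistic = w$statistic, p = w$p,
             stars = significance_stars(w$p))
}
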