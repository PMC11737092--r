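# Multi-study (MINT) sparse PLS: per-study normalization with one globally
# shared loading set, and leave-one-group-out stability scoring.

# Center/scale every column within each study separately.
.mint_scale <- function(m, studies, center = TRUE, scale = TRUE,
                        warn = FALSE) {
  m <- unclass(as.matrix(m))
  out <- m
  params <- list()
  for (s in unique(studies)) {
    idx <- studies == s
    sc <- .scale_cols(m[idx, , drop = FALSE], center, scale, warn = warn)
    out[idx, ] <- sc$m
    params[[as.character(s)]] <- list(center = sc$center, scale = sc$scale)
  }
  list(m = out, params = params)
}

#' Multi-study (MINT) sparse PLS fit
#'
#' Every column of X and Y is centered and unit-variance scaled within
#' each study (sampling trip) separately, which removes trip-level batch
#' offsets by construction; the sparse PLS core then runs once on the
#' concatenated matrices, producing a single global loading set. Features
#' selected this way are those covarying with the environment consistently
#' across studies rather than within any single trip.
#'
#' @param X,Y numeric matrices, samples x predictors / responses.
#' @param studies study (trip) id per sample; at least 2 studies, each
#'   with at least 3 samples.
#' @param cfg a [spls_config()].
#' @return an `spls_model` additionally of class `mint_spls_model`, with a
#'   `studies` element and per-study scaling parameters.
#' @export
mint_spls_fit <- function(X, Y, studies, cfg = spls_config()) {
  stopifnot(length(studies) == nrow(as.matrix(X)))
  tab <- table(studies)
  if (any(tab < 3))
    stop("every study needs >= 3 samples")
  sx <- .mint_scale(X, studies, cfg$center, cfg$scale, warn = TRUE)
  sy <- .mint_scale(Y, studies, cfg$center, cfg$scale, warn = FALSE)
  core_cfg <- cfg
  core_cfg$center <- FALSE
  core_cfg$scale <- FALSE
  fit <- spls_fit(sx$m, sy$m, core_cfg)
  fit$config <- cfg
  fit$studies <- studies
  fit$x_study_params <- sx$params
  fit$y_study_params <- sy$params
  class(fit) <- c("mint_spls_model", class(fit))
  fit
}

#' Leave-one-group-out stability scores for MINT sPLS indicators
#'
#' One cross-validation fold equals one study: for each study, the MINT
#' model is refitted on the remaining studies (same keep values) and the
#' features selected on the given component are recorded. A feature's
#' stability score is the number of refits in which it was selected
#' divided by the total number of studies, so with four trips the scores
#' take the values 0.25 (trip-specific, unstable), 0.5, 0.75 or 1
#' (shared/stable).
#'
#' @param X,Y,studies,cfg as in [mint_spls_fit()].
#' @param component component whose selection is scored (default 1).
#' @return data.frame of class `logocv_scores`: `feature_id`, `score`,
#'   `stable` (score >= 0.5), plus one logical column `left_out_<study>`
#'   per iteration. Only features selected in at least one iteration
#'   appear.
#' @export
logocv_stability <- function(X, Y, studies, cfg = spls_config(),
                             component = 1) {
  ids <- unique(studies)
  if (length(ids) < 2) stop("need at least 2 studies")
  X <- as.matrix(X); Y <- unclass(as.matrix(Y))
  sel <- list()
  for (s in ids) {
    idx <- studies != s
    fit <- suppressWarnings(
      mint_spls_fit(X[idx, , drop = FALSE], Y[idx, , drop = FALSE],
                    studies[idx], cfg))
    sel[[as.character(s)]] <- selected_features(fit, component)
  }
  feats <- sort(unique(unlist(sel)))
  flags <- vapply(sel, function(f) feats %in% f,
                  logical(length(feats)))
  flags <- matrix(flags, nrow = length(feats),
                  dimnames = list(feats, paste0("left_out_", ids)))
  out <- data.frame(feature_id = feats,
                    score = rowSums(flags) / length(ids))
  out$stable <- out$score >= 0.5
  out <- cbind(out, as.data.frame(flags))
  rownames(out) <- NULL
  class(out) <- c("logocv_scores", "data.frame")
  out
}

#' Enumerate leave-one-group-out selection scenarios
#'
#' With `n` studies there are `2^n - 1` nonempty selection patterns,
#' partitioned by stability score `k/n` into `choose(n, k)` patterns each.
#'
#' @param n_studies number of studies (>= 1).
#' @return list with `total` and `by_score` (data.frame: k, score,
#'   patterns).
#' @export
enumerate_logocv_scenarios <- function(n_studies) {
  if (n_studies < 1) stop("n_studies must be >= 1")
  k <- seq_len(n_studies)
  list(total = 2^n_studies - 1,
       by_score = data.frame(k = k, score = k / n_studies,
                             patterns = choose(n_studies, k)))
}

#' Join stability scores to similarity-matrix clusters
#'
#' Cuts the complete-linkage Euclidean clustering of the similarity-matrix
#' columns (the selected features) into `k_clusters` community-type
#' clusters, joins the leave-one-group-out scores, and flags the cluster
#' most enriched in stable (score >= 0.5) features.
#'
#' @param scores a [logocv_stability()] result.
#' @param sim a [similarity_matrix()] computed with clustering.
#' @param k_clusters number of clusters to cut (default 3).
#' @return data.frame: feature_id, cluster, score, stable — one row per
#'   similarity-matrix column; features never selected in any
#'   leave-one-group-out iteration get score 0. Attribute
#'   `enriched_cluster` names the cluster with the highest proportion of
#'   stable features.
#' @export
stable_indicator_report <- function(scores, sim, k_clusters = 3) {
  stopifnot(inherits(sim, "similarity_matrix"))
  ch <- attr(sim, "col_hclust")
  if (is.null(ch)) stop("similarity matrix was not clustered")
  cl <- stats::cutree(ch, k = min(k_clusters, ncol(sim)))
  out <- data.frame(feature_id = colnames(sim), cluster = unname(cl))
  m <- match(out$feature_id, scores$feature_id)
  out$score <- ifelse(is.na(m), 0, scores$score[m])
  out$stable <- out$score >= 0.5
  prop <- tapply(out$stable, out$cluster, mean)
  attr(out, "enriched_cluster") <- as.integer(names(which.max(prop)))
  out
}
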