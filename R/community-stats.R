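# Diversity, within-site similarity, ordination and group tests used to
# summarize seawater communities.

#' Shannon diversity index (nats)
#'
#' `H = -sum(p_i * ln(p_i))` over the positive entries of the proportion
#' vector. Natural log, matching the log base used by the CLR transform.
#'
#' @param x nonnegative count or proportion vector, not all zero.
#' @return Shannon index in nats.
#' @export
shannon_index <- function(x) {
  if (any(x < 0)) stop("negative abundances")
  if (sum(x) == 0) stop("all-zero abundance vector")
  unname(vegan::diversity(x, index = "shannon", base = exp(1)))
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `1 - 2 * sum(min(a, b)) / (sum(a) + sum(b))`; the complement is the
#' Bray-Curtis similarity.
#'
#' @param a,b nonnegative vectors of equal length, not both all-zero.
#' @return dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (any(a < 0) || any(b < 0)) stop("negative abundances")
  tot <- sum(a) + sum(b)
  if (tot == 0) stop("both vectors are all-zero")
  1 - 2 * sum(pmin(a, b)) / tot
}

#' Bray-Curtis distance matrix
#'
#' @param m nonnegative matrix, samples in rows.
#' @return a [distance_matrix()] with metric `"bray_curtis"`.
#' @export
bray_curtis_matrix <- function(m) {
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  distance_matrix(d, metric = "bray_curtis")
}

#' Within-site Bray-Curtis similarity of replicate samples
#'
#' Collapses the table at the requested level, converts to relative
#' abundances, and computes `1 - Bray-Curtis` for every replicate pair
#' within each reef site (`C(r, 2)` values per site with `r` replicates).
#' Sites with fewer than two replicates are skipped with a warning.
#'
#' @param ct a [count_table()].
#' @param level lineage level to collapse at (default: the table's native,
#'   i.e. deepest, level).
#' @return list with `values` (data.frame: site, rep_a, rep_b, similarity)
#'   and `summary` (level, n_values, median, sd, min).
#' @export
within_site_similarity <- function(ct, level = NULL) {
  stopifnot(inherits(ct, "count_table"))
  if (is.null(level)) level <- ct$ranks[length(ct$ranks)]
  coll <- collapse_counts(ct, level)
  ra <- relative_abundance(coll)
  out <- list()
  for (s in unique(coll$samples$site)) {
    idx <- which(coll$samples$site == s)
    if (length(idx) < 2) {
      warning("site '", s, "' has fewer than 2 replicates; skipped")
      next
    }
    pr <- utils::combn(idx, 2)
    sim <- apply(pr, 2, function(p)
      1 - bray_curtis(ra[p[1], ], ra[p[2], ]))
    out[[s]] <- data.frame(site = s,
                           rep_a = coll$samples$sample_id[pr[1, ]],
                           rep_b = coll$samples$sample_id[pr[2, ]],
                           similarity = sim)
  }
  values <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  list(values = values,
       summary = data.frame(level = level, n_values = nrow(values),
                            median = stats::median(values$similarity),
                            sd = stats::sd(values$similarity),
                            min = min(values$similarity)))
}

#' Principal components analysis of a CLR matrix
#'
#' Column-centered singular value decomposition; used as the unsupervised
#' view of the main clustering patterns among samples.
#'
#' @param m numeric matrix (samples x features), typically a
#'   [clr_transform()] result.
#' @param n_components components to retain (default: all up to the rank).
#' @return object of class `pca_result`: list with `scores` (samples x
#'   components), `loadings`, `explained_variance` (fractions, all
#'   components regardless of `n_components`).
#' @export
clr_pca <- function(m, n_components = NULL) {
  m <- unclass(as.matrix(m))
  if (nrow(m) < 2) stop("need at least 2 samples")
  pr <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2 / sum(pr$sdev^2)
  if (all(pr$sdev < 1e-12)) stop("zero-variance input")
  k <- if (is.null(n_components)) sum(pr$sdev > 1e-12) else
    min(n_components, ncol(pr$x))
  structure(list(scores = pr$x[, seq_len(k), drop = FALSE],
                 loadings = pr$rotation[, seq_len(k), drop = FALSE],
                 explained_variance = ev),
            class = "pca_result")
}

#' Pairwise one-way PERMANOVA on a distance matrix
#'
#' For every pair of groups, runs a one-way permutational multivariate
#' analysis of variance on the distance matrix restricted to the pair
#' (via [vegan::adonis2()]); the permutation p-value is
#' `(1 + #permuted F >= observed) / (1 + n_perm)`. Bonferroni correction
#' multiplies p by the number of pairs, capped at 1.
#'
#' @param d a [distance_matrix()] (or plain symmetric matrix).
#' @param groups group label per item of `d`.
#' @param n_perm permutations per pair (default 999).
#' @param correction p-adjustment method (default `"bonferroni"`).
#' @param seed RNG seed for the permutations.
#' @return data.frame: group_a, group_b, SumOfSqs, MeanSqs, F, R2, p,
#'   p_adj.
#' @export
permanova_pairwise <- function(d, groups, n_perm = 999,
                               correction = "bonferroni", seed = 1) {
  d <- as.matrix(d)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(d))
  lev <- unique(groups)
  if (length(lev) < 2) stop("need at least 2 groups")
  small <- table(groups)
  if (any(small < 2)) stop("every group needs >= 2 members")
  pairs <- utils::combn(lev, 2)
  set.seed(seed)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    sel <- groups %in% pairs[, i]
    g <- factor(groups[sel])
    dd <- stats::as.dist(d[sel, sel])
    fit <- vegan::adonis2(dd ~ g, permutations = n_perm)
    data.frame(group_a = pairs[1, i], group_b = pairs[2, i],
               SumOfSqs = fit$SumOfSqs[1],
               MeanSqs = fit$SumOfSqs[1] / fit$Df[1],
               F = fit$F[1], R2 = fit$R2[1], p = fit$`Pr(>F)`[1])
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = correction)
  out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration when both samples have at most 8 observations and
#' there are no ties; normal approximation with tie correction otherwise.
#'
#' @param x,y numeric samples, each non-empty.
#' @return list with `statistic` (rank-sum W) and `p`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 8 && length(y) <= 8 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(statistic = unname(wt$statistic), p = min(1, wt$p.value),
       exact = exact)
}

#' Batched pairwise Wilcoxon rank-sum tests with p adjustment
#'
#' @param values numeric vector of observations.
#' @param groups group label per observation.
#' @param adjust p-adjustment method (default `"holm"`, the standard for
#'   batched pairwise rank tests; `"bonferroni"` available).
#' @return data.frame: group_a, group_b, statistic, p, p_adj, stars.
#' @export
pairwise_wilcoxon <- function(values, groups, adjust = "holm") {
  groups <- as.character(groups)
  lev <- unique(groups)
  pairs <- utils::combn(lev, 2)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    w <- wilcoxon_rank_sum(values[groups == pairs[1, i]],
                           values[groups == pairs[2, i]])
    data.frame(group_a = pairs[1, i], group_b = pairs[2, i],
               statistic = w$statistic, p = w$p)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = adjust)
  out$stars <- significance_stars(out$p_adj)
  out
}

#' Significance stars at the conventional thresholds
#'
#' `****` for p < 0.0001, `***` < 0.001, `**` < 0.01, `*` < 0.05,
#' `"ns"` otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns")) |> as.character()
}
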