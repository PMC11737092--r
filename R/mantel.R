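# Geography-corrected partial Mantel screen of community distances against
# each physico-chemical variable.

#' Great-circle distances between reef sites, in km
#'
#' Haversine formula on a sphere of radius 6371.0 km.
#'
#' @param latlon data.frame or matrix with columns `lat`, `lon` in decimal
#'   degrees; row names (or a `site` column) become item ids.
#' @return a [distance_matrix()] with metric `"geographic_km"`.
#' @export
geo_distance_km <- function(latlon) {
  latlon <- as.data.frame(latlon)
  ids <- if ("site" %in% names(latlon)) latlon$site else rownames(latlon)
  lat <- latlon$lat; lon <- latlon$lon
  if (any(abs(lat) > 90) || any(abs(lon) > 180))
    stop("invalid coordinates (|lat| <= 90, |lon| <= 180 required)")
  r <- 6371.0
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  n <- length(lat)
  dphi <- outer(phi, phi, `-`)
  dlam <- outer(lam, lam, `-`)
  a <- sin(dphi / 2)^2 + outer(cos(phi), cos(phi)) * sin(dlam / 2)^2
  d <- 2 * r * asin(pmin(sqrt(a), 1))
  dimnames(d) <- list(ids, ids)
  distance_matrix(d, metric = "geographic_km")
}

# lower-triangle vector of a symmetric matrix
.lt <- function(m) m[lower.tri(m)]

# Pearson correlation between two centered vectors, guarding zero variance
.safe_cor <- function(x, y) {
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) stop("constant distance matrix (zero variance)")
  stats::cor(x, y)
}

#' Partial Mantel test with permutation inference
#'
#' Statistic: rank (Spearman) correlation between the community and
#' environment distance matrices after removing the linear effect of the
#' geographic distance matrix from both — computed as the partial Pearson
#' correlation of the rank-transformed lower-triangle entries, which equals
#' the correlation of the residuals of the two rank regressions on
#' geography. The permutation null simultaneously permutes rows and
#' columns of the community matrix; the default alternative is one-sided
#' positive: `p = (1 + #{perm stat >= observed}) / (1 + n_perm)`.
#'
#' @param d_comm,d_env,d_geo conformable symmetric distance matrices over
#'   the same items.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed.
#' @param alternative `"greater"` (one-sided positive, default) or
#'   `"two.sided"`.
#' @return list of class `mantel_result`: `statistic` (rho), `p`,
#'   `n_perm`, `n_items`, `method`, `alternative`.
#' @export
partial_mantel <- function(d_comm, d_env, d_geo, method = "spearman",
                           n_perm = 10000, seed = 1,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  d_comm <- as.matrix(d_comm); d_env <- as.matrix(d_env)
  d_geo <- as.matrix(d_geo)
  n <- nrow(d_comm)
  if (!all(dim(d_env) == n) || !all(dim(d_geo) == n))
    stop("non-conformable distance matrices")

  tr <- function(m) {
    v <- .lt(m)
    if (method == "spearman") v <- rank(v)
    v
  }
  # rank-transform the full symmetric matrix once so permuted lower
  # triangles are re-indexings of the same ranks
  sym_rank <- function(m) {
    if (method != "spearman") return(m)
    out <- m
    out[lower.tri(m)] <- rank(.lt(m))
    out[upper.tri(out)] <- t(out)[upper.tri(out)]
    out
  }
  Rc <- sym_rank(d_comm)
  b <- tr(d_env)
  cc <- tr(d_geo)

  # a constant controlling matrix carries no information: the partial
  # statistic degenerates to the simple Mantel correlation
  geo_const <- stats::sd(cc) == 0
  partial_stat <- function(a) {
    r_ab <- .safe_cor(a, b)
    if (geo_const) return(r_ab)
    r_ac <- .safe_cor(a, cc)
    r_bc <- .safe_cor(b, cc)
    den <- sqrt((1 - r_ac^2) * (1 - r_bc^2))
    if (den == 0) stop("degenerate partial correlation (perfect collinearity)")
    (r_ab - r_ac * r_bc) / den
  }
  obs <- partial_stat(.lt(Rc))

  set.seed(seed)
  perm <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    p <- sample.int(n)
    perm[i] <- partial_stat(.lt(Rc[p, p]))
  }
  p_val <- if (alternative == "greater")
    (1 + sum(perm >= obs)) / (1 + n_perm)
  else
    (1 + sum(abs(perm) >= abs(obs))) / (1 + n_perm)

  structure(list(statistic = obs, p = p_val, n_perm = n_perm,
                 n_items = n, method = method, alternative = alternative),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("partial Mantel (%s, %s): rho = %.4f, p = %.4g (%d perms)\n",
              x$method, x$alternative, x$statistic, x$p, x$n_perm))
  invisible(x)
}

#' Partial Mantel screen of community tables against every env variable
#'
#' Aggregates each community table to site level (summing replicate
#' counts), computes Bray-Curtis dissimilarity on site relative abundances,
#' and for every (dataset, variable) combination runs a geography-corrected
#' [partial_mantel()] of the community distances against the Euclidean
#' distance of the (unit-SD standardized) variable. Sites missing a
#' variable are excluded pairwise from that variable's test. Bonferroni
#' adjustment is applied within the configured family.
#'
#' @param tables named list of [count_table()]s (e.g.
#'   `list(taxonomy = ..., go = ...)`).
#' @param env an [env_table()] whose sites carry `lat`/`lon`.
#' @param n_perm permutations per test (default 10000).
#' @param seed RNG seed.
#' @param family Bonferroni family: `"per_dataset"` (default; factor =
#'   number of variables) or `"global"` (factor = total number of tests).
#' @param alpha significance level applied to adjusted p-values.
#' @return data.frame: dataset, variable, rho, p, p_adj, n_sites,
#'   significant.
#' @export
mantel_screen <- function(tables, env, n_perm = 10000, seed = 1,
                          family = c("per_dataset", "global"),
                          alpha = 0.05) {
  family <- match.arg(family)
  stopifnot(inherits(env, "env_table"), is.list(tables),
            !is.null(names(tables)))
  vars <- colnames(env$values)
  if (!all(c("lat", "lon") %in% names(env$sites)))
    stop("env sites need lat/lon columns for the geographic matrix")

  d_geo_full <- geo_distance_km(env$sites[, c("site", "lat", "lon")])

  res <- list()
  for (ds_name in names(tables)) {
    ct <- tables[[ds_name]]
    site_counts <- rowsum(ct$counts, group = ct$samples$site)
    site_counts <- site_counts[env$sites$site, , drop = FALSE]
    ra <- relative_abundance(site_counts)
    for (v in vars) {
      ok <- !is.na(env$values[, v])
      x <- env$values[ok, v]
      s <- stats::sd(x)
      if (s == 0) stop("variable '", v, "' is constant")
      d_env <- distance_matrix(as.matrix(stats::dist(x / s)),
                               metric = "euclidean")
      d_comm <- bray_curtis_matrix(ra[ok, , drop = FALSE])
      mt <- partial_mantel(d_comm, d_env,
                           unclass(d_geo_full)[ok, ok, drop = FALSE],
                           n_perm = n_perm, seed = seed)
      res[[paste(ds_name, v)]] <- data.frame(
        dataset = ds_name, variable = v, rho = mt$statistic, p = mt$p,
        n_sites = sum(ok))
    }
  }
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  fam_size <- if (family == "per_dataset") length(vars) else nrow(out)
  out$p_adj <- pmin(1, out$p * fam_size)
  out$significant <- out$p_adj < alpha
  out
}
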