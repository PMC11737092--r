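# Sparse partial least squares regression with per-component feature
# selection (regression-mode deflation) and the partial-correlation
# similarity matrix used for indicator heatmaps.

#' sPLS configuration
#'
#' @param n_components number of components ("dimensions") to extract
#'   (default 2).
#' @param keep_predictors nonzero X-loadings retained per component
#'   (default `NULL` = all predictors); may be a vector, one per component.
#' @param keep_responses nonzero Y-loadings retained per component
#'   (default 50, the number of indicator features selected per dimension);
#'   may be a vector.
#' @param max_iterations cap on the alternating iterations per component.
#' @param tolerance convergence tolerance on the loading updates.
#' @param center,scale whether columns are centered / unit-variance scaled
#'   before fitting.
#' @return a `spls_config` list.
#' @export
spls_config <- function(n_components = 2, keep_predictors = NULL,
                        keep_responses = 50, max_iterations = 100,
                        tolerance = 1e-6, center = TRUE, scale = TRUE) {
  if (n_components < 1) stop("n_components must be >= 1")
  if (tolerance <= 0) stop("tolerance must be > 0")
  if (!is.null(keep_predictors) && any(keep_predictors < 1))
    stop("keep_predictors must be >= 1")
  if (!is.null(keep_responses) && any(keep_responses < 1))
    stop("keep_responses must be >= 1")
  structure(list(n_components = n_components,
                 keep_predictors = keep_predictors,
                 keep_responses = keep_responses,
                 max_iterations = max_iterations, tolerance = tolerance,
                 center = center, scale = scale),
            class = "spls_config")
}

# Keep the k largest-magnitude entries, soft-thresholded by the (k+1)-th
# magnitude; ties at the boundary are broken by position (lexicographic
# feature order). k >= length(v) leaves v untouched.
.soft_select <- function(v, k) {
  p <- length(v)
  if (is.null(k) || k >= p) return(v)
  ord <- order(-abs(v), seq_len(p))
  thr <- abs(v[ord[k + 1]])
  out <- numeric(p)
  kept <- ord[seq_len(k)]
  out[kept] <- sign(v[kept]) * pmax(abs(v[kept]) - thr, 0)
  out
}

# Column center/scale with explicit parameters; zero-variance columns are
# mapped to all-zero with (optionally) a warning.
.scale_cols <- function(m, center = TRUE, scale = TRUE, warn = TRUE) {
  mu <- if (center) colMeans(m) else rep(0, ncol(m))
  m <- sweep(m, 2, mu, `-`)
  sdv <- rep(1, ncol(m))
  if (scale) {
    sdv <- apply(m, 2, stats::sd)
    zero <- sdv == 0 | is.na(sdv)
    if (any(zero)) {
      if (warn)
        warning(sum(zero), " zero-variance column(s) set to 0")
      sdv[zero] <- 1
    }
    m <- sweep(m, 2, sdv, `/`)
  }
  list(m = m, center = mu, scale = sdv)
}

#' Fit a sparse PLS regression model
#'
#' Predictors X (environment variables) against responses Y (microbial
#' features). Per component: initialize the Y-loading as the dominant
#' right singular vector of `M = t(X) %*% Y`, then alternate
#' `a <- soft_select(M b)` and `b <- soft_select(t(M) a)` (each normalized
#' to unit length) until the update change falls below the tolerance;
#' scores are `t = X a`, `u = Y b`; X and Y are then deflated on `t`
#' (regression mode). The soft-selection operator keeps the `keep` largest
#' loadings and shrinks them by the next-largest magnitude.
#'
#' Sign convention: each component is flipped so the largest-magnitude
#' X-loading entry is positive.
#'
#' @param X numeric matrix, samples x predictors.
#' @param Y numeric matrix, samples x responses (row-matched to X).
#' @param cfg a [spls_config()].
#' @return object of class `spls_model`: list with `loadings_x` (p x H),
#'   `loadings_y` (q x H), `scores_x`, `scores_y` (n x H), `selected`
#'   (list of response-feature id vectors per component), scaling
#'   parameters, `iterations`, `converged`.
#' @export
spls_fit <- function(X, Y, cfg = spls_config()) {
  X <- as.matrix(X); Y <- unclass(as.matrix(Y))
  if (nrow(X) != nrow(Y)) stop("X and Y must be row-matched")
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(q))
  H <- cfg$n_components
  keepX <- if (is.null(cfg$keep_predictors)) rep(p, H) else
    rep_len(cfg$keep_predictors, H)
  keepY <- if (is.null(cfg$keep_responses)) rep(q, H) else
    rep_len(cfg$keep_responses, H)
  if (any(keepX > p) || any(keepY > q)) {
    keepX <- pmin(keepX, p); keepY <- pmin(keepY, q)
  }

  sx <- .scale_cols(X, cfg$center, cfg$scale, warn = TRUE)
  sy <- .scale_cols(Y, cfg$center, cfg$scale, warn = TRUE)
  Xd <- sx$m; Yd <- sy$m

  A <- matrix(0, p, H, dimnames = list(colnames(X), NULL))
  B <- matrix(0, q, H, dimnames = list(colnames(Y), NULL))
  Tm <- matrix(0, n, H, dimnames = list(rownames(X), NULL))
  Um <- matrix(0, n, H)
  iters <- integer(H); conv <- logical(H)
  selected <- vector("list", H)

  for (h in seq_len(H)) {
    M <- crossprod(Xd, Yd)
    sv <- svd(M, nu = 1, nv = 1)
    b <- sv$v[, 1]
    a <- sv$u[, 1]
    for (it in seq_len(cfg$max_iterations)) {
      a_old <- a; b_old <- b
      a <- .soft_select(drop(M %*% b), keepX[h])
      na <- sqrt(sum(a^2))
      if (na == 0) break
      a <- a / na
      b <- .soft_select(drop(crossprod(M, a)), keepY[h])
      nb <- sqrt(sum(b^2))
      if (nb == 0) break
      b <- b / nb
      # loadings are sign-indeterminate; compare up to a common flip
      if (sum(a * a_old) < 0) { a_flip <- -a; b_flip <- -b }
      else { a_flip <- a; b_flip <- b }
      if (max(abs(a_flip - a_old)) + max(abs(b_flip - b_old)) <
          cfg$tolerance) {
        conv[h] <- TRUE
        break
      }
    }
    iters[h] <- it
    if (!conv[h] && it == cfg$max_iterations)
      warning(sprintf("component %d did not converge in %d iterations",
                      h, cfg$max_iterations))
    # deterministic sign: largest-|a| entry positive
    flip <- sign(a[which.max(abs(a))])
    if (flip < 0) { a <- -a; b <- -b }
    t_h <- drop(Xd %*% a)
    u_h <- drop(Yd %*% b)
    tt <- sum(t_h^2)
    if (tt > 0) {
      Xd <- Xd - tcrossprod(t_h, drop(crossprod(Xd, t_h))) / tt
      Yd <- Yd - tcrossprod(t_h, drop(crossprod(Yd, t_h))) / tt
    }
    A[, h] <- a; B[, h] <- b; Tm[, h] <- t_h; Um[, h] <- u_h
    selected[[h]] <- colnames(Y)[b != 0]
  }

  structure(list(loadings_x = A, loadings_y = B, scores_x = Tm,
                 scores_y = Um, selected = selected,
                 x_center = sx$center, x_scale = sx$scale,
                 y_center = sy$center, y_scale = sy$scale,
                 iterations = iters, converged = conv, config = cfg),
            class = "spls_model")
}

#' @export
print.spls_model <- function(x, ...) {
  cat(sprintf("spls_model: %d component(s), %d predictors, %d responses\n",
              ncol(x$loadings_x), nrow(x$loadings_x), nrow(x$loadings_y)))
  for (h in seq_along(x$selected))
    cat(sprintf("  component %d: %d selected responses (%s)\n", h,
                length(x$selected[[h]]),
                if (x$converged[h]) sprintf("converged in %d it",
                                            x$iterations[h])
                else "not converged"))
  invisible(x)
}

#' Response features selected on a component
#'
#' @param m a fitted [spls_fit()] model.
#' @param component component index (default 1).
#' @return character vector of feature ids with nonzero Y-loading.
#' @export
selected_features <- function(m, component = 1) {
  stopifnot(inherits(m, "spls_model"))
  if (component < 1 || component > ncol(m$loadings_y))
    stop("component out of range")
  m$selected[[component]]
}

#' Partial-correlation similarity matrix between predictors and selected
#' responses
#'
#' `sim(i, j) = sum_h cor(X[, i], t_h) * cor(Y[, j], t_h)` over the
#' retained components, where `t_h` are the X-scores; computed only for
#' responses selected on at least one retained component. Rows and columns
#' are ordered by complete-linkage clustering on Euclidean distance when
#' `cluster = TRUE`.
#'
#' @param m a fitted [spls_fit()] (or MINT) model.
#' @param X,Y the data matrices the model was fitted on (raw scale; the
#'   model's scaling parameters are reapplied).
#' @param components components to sum over (default: all fitted).
#' @param cluster order rows/columns by complete-linkage Euclidean
#'   clustering.
#' @return matrix of class `similarity_matrix` (predictors x selected
#'   responses), with attributes `row_order`, `col_order`, `row_hclust`,
#'   `col_hclust` when clustered. Entries are bounded by the number of
#'   components in absolute value.
#' @export
similarity_matrix <- function(m, X, Y, components = NULL, cluster = TRUE) {
  stopifnot(inherits(m, "spls_model"))
  if (is.null(components)) components <- seq_len(ncol(m$loadings_x))
  X <- as.matrix(X); Y <- unclass(as.matrix(Y))
  Xs <- if (inherits(m, "mint_spls_model"))
    .mint_scale(X, m$studies, m$config$center, m$config$scale)$m
  else
    sweep(sweep(X, 2, m$x_center, `-`), 2, m$x_scale, `/`)
  Ys <- if (inherits(m, "mint_spls_model"))
    .mint_scale(Y, m$studies, m$config$center, m$config$scale)$m
  else
    sweep(sweep(Y, 2, m$y_center, `-`), 2, m$y_scale, `/`)

  feats <- unique(unlist(m$selected[components]))
  sim <- matrix(0, ncol(X), length(feats),
                dimnames = list(colnames(X), feats))
  safe_col_cor <- function(M, t_h) {
    sds <- apply(M, 2, stats::sd)
    zero <- sds == 0 | is.na(sds)
    if (any(zero))
      warning(sum(zero), " zero-variance column(s); correlations set to 0")
    r <- rep(0, ncol(M))
    if (any(!zero))
      r[!zero] <- drop(stats::cor(M[, !zero, drop = FALSE], t_h))
    r
  }
  for (h in components) {
    t_h <- m$scores_x[, h]
    cx <- safe_col_cor(Xs, t_h)
    cy <- safe_col_cor(Ys[, feats, drop = FALSE], t_h)
    sim <- sim + tcrossprod(cx, cy)
  }
  attrs <- list()
  if (cluster && nrow(sim) > 1 && ncol(sim) > 1) {
    rh <- stats::hclust(stats::dist(sim), method = "complete")
    ch <- stats::hclust(stats::dist(t(sim)), method = "complete")
    attrs <- list(row_order = rh$order, col_order = ch$order,
                  row_hclust = rh, col_hclust = ch)
  }
  structure(sim, row_order = attrs$row_order, col_order = attrs$col_order,
            row_hclust = attrs$row_hclust, col_hclust = attrs$col_hclust,
            class = c("similarity_matrix", "matrix"))
}
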