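# Post-annotation filtering, compositional transforms, hierarchical
# collapsing and environment-table preparation.

#' Filter annotated count tables
#'
#' Applies the post-annotation cleaning rules in order: (1) drop
#' unannotated features, (2) eukaryote-annotated features, (3) virus
#' features, (4) prokaryote features resolved to the domain level only;
#' then (5) drop rare features whose overall relative abundance (feature
#' total divided by the grand total of the counts remaining after the class
#' rules) is strictly below `min_rel_abundance`.
#'
#' The rare-feature threshold is interpreted against the whole dataset, not
#' per sample; `rule = "per_sample"` instead keeps a feature if it reaches
#' the threshold within at least one sample.
#'
#' @param ct a [count_table()].
#' @param min_rel_abundance removal threshold as a fraction
#'   (default `1e-6`, i.e. 0.0001 percent).
#' @param rule `"overall"` (default) or `"per_sample"`.
#' @return the filtered `count_table`, with a `removal_report` attribute:
#'   data.frame (rule, feature_id, value) listing every removed feature.
#' @export
filter_features <- function(ct, min_rel_abundance = 1e-6,
                            rule = c("overall", "per_sample")) {
  stopifnot(inherits(ct, "count_table"))
  rule <- match.arg(rule)
  drop_classes <- c(unannotated = "unannotated", eukaryote = "eukaryote",
                    virus = "virus", domain_only = "domain_only")
  report <- data.frame(rule = character(), feature_id = character(),
                       value = numeric())

  keep <- rep(TRUE, ncol(ct$counts))
  for (rn in names(drop_classes)) {
    hit <- keep & ct$features$class == drop_classes[[rn]]
    if (any(hit))
      report <- rbind(report, data.frame(
        rule = rn, feature_id = ct$features$feature_id[hit],
        value = colSums(ct$counts)[hit]))
    keep <- keep & !hit
    if (!any(keep))
      stop("filtering removed every feature (last rule: ", rn, ")")
  }

  totals <- colSums(ct$counts[, keep, drop = FALSE])
  grand <- sum(totals)
  if (rule == "overall") {
    rel <- totals / grand
    rare <- rel < min_rel_abundance
  } else {
    ra <- relative_abundance(subset_table(ct, features = which(keep)))
    rel <- apply(ra, 2, max)
    rare <- rel < min_rel_abundance
  }
  if (any(rare)) {
    ids <- colnames(ct$counts)[keep][rare]
    report <- rbind(report, data.frame(rule = "rare", feature_id = ids,
                                       value = rel[rare]))
    keep[match(ids, colnames(ct$counts))] <- FALSE
  }
  if (!any(keep))
    stop("rare-feature filter removed every feature (last rule: rare)")

  out <- subset_table(ct, features = which(keep))
  attr(out, "removal_report") <- report
  out
}

#' @rdname filter_features
#' @param x a filtered `count_table`.
#' @export
removal_report <- function(x) attr(x, "removal_report")

#' Per-sample relative abundance
#'
#' @param ct a [count_table()] or numeric matrix (samples x features).
#' @return matrix of proportions; every row sums to 1.
#' @export
relative_abundance <- function(ct) {
  m <- if (inherits(ct, "count_table")) ct$counts else as.matrix(ct)
  rs <- rowSums(m)
  zero <- rs == 0
  if (any(zero))
    stop("zero-sum sample(s): ",
         paste(rownames(m)[zero], collapse = ", "))
  sweep(m, 1, rs, `/`)
}

#' Centered log-ratio transform
#'
#' Per sample: `v_i = ln(x_i + pseudocount) - mean_j ln(x_j + pseudocount)`.
#' A pseudocount is added because the log of zero counts is undefined.
#' Rows of the result sum to zero (the CLR identity).
#'
#' @param ct a [count_table()] or numeric matrix (samples x features).
#' @param pseudocount positive value added to every count before the log
#'   (default 1, the usual convention for integer counts).
#' @return matrix of class `clr_matrix` with attribute `pseudocount`.
#' @export
clr_transform <- function(ct, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  m <- if (inherits(ct, "count_table")) ct$counts else as.matrix(ct)
  lg <- log(m + pseudocount)
  out <- lg - rowMeans(lg)
  structure(out, pseudocount = pseudocount,
            class = c("clr_matrix", "matrix"))
}

#' Collapse a count table at a higher hierarchical level
#'
#' Sums counts over features sharing the same label at the requested
#' lineage level (taxonomic rank for taxa tables, ontology rank for GO
#' tables). Features whose lineage does not reach the level are grouped
#' under the sentinel label `"unresolved"`.
#'
#' @param ct a [count_table()].
#' @param level one of `ct$ranks`.
#' @return a `count_table` with one feature per level label. Grand totals
#'   are conserved.
#' @export
collapse_counts <- function(ct, level) {
  stopifnot(inherits(ct, "count_table"))
  idx <- match(level, ct$ranks)
  if (is.na(idx))
    stop("unknown level '", level, "'; available: ",
         paste(ct$ranks, collapse = ", "))
  parts <- strsplit(ct$features$lineage, ";", fixed = TRUE)
  label <- vapply(parts, function(p)
    if (length(p) >= idx && nzchar(p[idx])) p[idx] else "unresolved",
    character(1))
  path <- vapply(parts, function(p)
    paste(p[seq_len(min(idx, length(p)))], collapse = ";"), character(1))

  groups <- unique(label)
  agg <- t(rowsum(t(ct$counts), label))[, groups, drop = FALSE]
  features <- data.frame(
    feature_id = groups,
    lineage = path[match(groups, label)],
    class = vapply(groups, function(g) {
      cls <- unique(ct$features$class[label == g])
      if (length(cls) == 1) cls else "mixed"
    }, character(1)))
  features$lineage[features$feature_id == "unresolved"] <- "unresolved"
  count_table(agg, ct$samples, features, ranks = ct$ranks[seq_len(idx)])
}

#' Aggregate replicate environment measurements to site medians
#'
#' @param raw data.frame with columns `site`, `trip` (and optionally
#'   `lat`, `lon`), then one column per variable; one row per replicate
#'   measurement. Missing replicates are ignored; a site/variable cell with
#'   no non-missing replicate stays `NA`.
#' @return an [env_table()] with one row per site.
#' @export
aggregate_env_medians <- function(raw) {
  meta_cols <- intersect(c("site", "trip", "lat", "lon"), names(raw))
  stopifnot(all(c("site", "trip") %in% meta_cols))
  var_cols <- setdiff(names(raw), c(meta_cols, "replicate"))
  sites <- unique(raw[, meta_cols, drop = FALSE])
  sites <- sites[!duplicated(sites$site), , drop = FALSE]
  vals <- matrix(NA_real_, nrow(sites), length(var_cols),
                 dimnames = list(sites$site, var_cols))
  for (i in seq_len(nrow(sites))) {
    sub <- raw[raw$site == sites$site[i], var_cols, drop = FALSE]
    vals[i, ] <- vapply(sub, function(x) {
      x <- x[!is.na(x)]
      if (length(x) == 0) NA_real_ else stats::median(x)
    }, numeric(1))
  }
  env_table(vals, sites)
}

#' Center and scale environment variables for heatmap display
#'
#' Per variable: subtract the median across sites and divide by the sample
#' standard deviation across sites (n-1 denominator). Missing cells
#' propagate as missing.
#'
#' @param env an [env_table()].
#' @return numeric matrix (sites x variables); each variable has median 0.
#' @export
scale_env_for_heatmap <- function(env) {
  stopifnot(inherits(env, "env_table"))
  v <- env$values
  out <- v
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    if (sum(!is.na(x)) < 2)
      stop("variable '", colnames(v)[j], "' has fewer than 2 measured sites")
    s <- stats::sd(x, na.rm = TRUE)
    if (s == 0)
      stop("variable '", colnames(v)[j], "' has zero standard deviation")
    out[, j] <- (x - stats::median(x, na.rm = TRUE)) / s
  }
  out
}

#' Impute missing environment cells by the within-trip median
#'
#' Used before sPLS, where a complete predictor matrix is required. A cell
#' missing for a whole trip falls back to the overall variable median.
#'
#' @param env an [env_table()].
#' @return an `env_table` with no missing cells (plus an `imputed`
#'   attribute listing the filled cells).
#' @export
impute_env_within_trip <- function(env) {
  stopifnot(inherits(env, "env_table"))
  v <- env$values
  filled <- which(is.na(v), arr.ind = TRUE)
  for (r in seq_len(nrow(filled))) {
    i <- filled[r, 1]; j <- filled[r, 2]
    same_trip <- env$sites$trip == env$sites$trip[i]
    med <- stats::median(v[same_trip, j], na.rm = TRUE)
    if (is.na(med)) med <- stats::median(v[, j], na.rm = TRUE)
    v[i, j] <- med
  }
  out <- env_table(v, env$sites)
  attr(out, "imputed") <- filled
  out
}
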