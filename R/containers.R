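#' Sample-by-feature count table with metadata
#'
#' Light container pairing an integer sample x feature count matrix with the
#' sample metadata (trip, reef site, replicate, coordinates) and a feature
#' annotation (taxonomic lineage or GO rank path plus an annotation class).
#' This is the unit every preprocessing and analysis step consumes.
#'
#' @param counts numeric matrix, samples in rows, features in columns.
#'   Dimnames are taken as sample/feature ids when `samples`/`features` are
#'   not supplied.
#' @param samples data.frame with columns `sample_id`, `trip`, `site`,
#'   `replicate`, `lat`, `lon` (one row per row of `counts`).
#' @param features data.frame with columns `feature_id`, `lineage`
#'   (semicolon-separated rank path, root first) and `class` (one of
#'   `"bacteria"`, `"archaea"`, `"eukaryote"`, `"virus"`, `"domain_only"`,
#'   `"unannotated"`, or `"go"` for functional tables).
#' @param ranks character vector naming the lineage levels of the rank path,
#'   root first (e.g. `c("domain", ..., "genus")` or
#'   `c("rank3", "rank4", "rank5")`).
#'
#' @return An object of class `count_table`: a list with elements `counts`,
#'   `samples`, `features`, `ranks`.
#' @export
count_table <- function(counts, samples = NULL, features = NULL,
                        ranks = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0, na.rm = TRUE))
    stop("counts must be nonnegative")
  if (is.null(samples)) {
    if (is.null(rownames(counts)))
      stop("either row names or a samples data.frame is required")
    samples <- data.frame(sample_id = rownames(counts),
                          trip = NA, site = NA, replicate = NA,
                          lat = NA_real_, lon = NA_real_)
  }
  if (is.null(features)) {
    if (is.null(colnames(counts)))
      stop("either column names or a features data.frame is required")
    features <- data.frame(feature_id = colnames(counts),
                           lineage = colnames(counts),
                           class = "bacteria")
  }
  stopifnot(nrow(samples) == nrow(counts), nrow(features) == ncol(counts))
  if (anyDuplicated(samples$sample_id))
    stop("sample ids must be unique")
  if (anyDuplicated(features$feature_id))
    stop("feature ids must be unique")
  rownames(counts) <- samples$sample_id
  colnames(counts) <- features$feature_id
  if (is.null(ranks))
    ranks <- paste0("level", seq_len(max(lengths(
      strsplit(features$lineage, ";", fixed = TRUE)))))
  structure(list(counts = counts, samples = samples, features = features,
                 ranks = ranks),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d features\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  trips: %s\n",
              paste(sort(unique(x$samples$trip)), collapse = ", ")))
  cat(sprintf("  ranks: %s\n", paste(x$ranks, collapse = " > ")))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Subset a count table by samples and/or features
#'
#' @param x a [count_table()].
#' @param samples,features logical, integer or character indices.
#' @return a `count_table` restricted to the requested rows/columns.
#' @export
subset_table <- function(x, samples = NULL, features = NULL) {
  stopifnot(inherits(x, "count_table"))
  if (!is.null(samples)) {
    if (is.character(samples))
      samples <- match(samples, x$samples$sample_id)
    x$counts <- x$counts[samples, , drop = FALSE]
    x$samples <- x$samples[samples, , drop = FALSE]
  }
  if (!is.null(features)) {
    if (is.character(features))
      features <- match(features, x$features$feature_id)
    x$counts <- x$counts[, features, drop = FALSE]
    x$features <- x$features[features, , drop = FALSE]
  }
  x
}

#' The 17 physico-chemical variable names
#'
#' Canonical column order for environment tables: pigments and particulate
#' nutrients (Chl-a, Phaeo, PN, POC, PP), dissolved pools (DOC, PO4, NH4,
#' NO2, NO3, Si, TDN, TDP), total suspended solids, and the underway-sensor
#' variables (temperature, salinity, Chl-a fluorescence).
#'
#' @return character vector of length 17.
#' @export
env_variable_names <- function() {
  c("Chl_a", "Phaeo", "PN", "POC", "PP", "DOC", "PO4", "NH4", "NO2",
    "NO3", "Si", "TDN", "TDP", "TSS", "Temperature", "Salinity",
    "Chl_a_fluorescence")
}

#' Reef-site environment table
#'
#' One row per reef site (each site belongs to exactly one sampling trip),
#' one column per physico-chemical variable. Missing measurements are `NA`.
#'
#' @param values numeric matrix or data.frame, sites x variables.
#' @param sites data.frame with columns `site`, `trip`, `lat`, `lon`
#'   (one row per row of `values`).
#' @return object of class `env_table`: list with elements `values`
#'   (matrix with site row names) and `sites`.
#' @export
env_table <- function(values, sites) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == nrow(sites),
            all(c("site", "trip") %in% names(sites)))
  if (anyDuplicated(sites$site))
    stop("one row per site expected; duplicated site ids found")
  rownames(values) <- sites$site
  structure(list(values = values, sites = sites), class = "env_table")
}

#' @export
print.env_table <- function(x, ...) {
  cat(sprintf("env_table: %d sites x %d variables (%d missing cells)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Typed distance matrix
#'
#' Wraps a symmetric nonnegative matrix with zero diagonal and records the
#' metric it was computed under.
#'
#' @param m symmetric numeric matrix.
#' @param metric label, e.g. `"bray_curtis"`, `"euclidean"`,
#'   `"geographic_km"`.
#' @return `m` with class `distance_matrix` and attribute `metric`.
#' @export
distance_matrix <- function(m, metric = "unknown") {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8)
    stop("distance matrix must be symmetric")
  diag(m) <- 0
  if (any(m < -1e-12)) stop("distances must be nonnegative")
  structure(m, metric = metric, class = c("distance_matrix", "matrix"))
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("distance_matrix (%s): %d items\n",
              attr(x, "metric"), nrow(x)))
  invisible(x)
}
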