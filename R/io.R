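# TSV dialect used throughout: UTF-8, tab-separated, '.' decimal, header
# row mandatory. Count tables on disk are features x samples (rows =
# features), the orientation read-annotation tools export.

#' Read a count table with annotation and sample metadata
#'
#' @param path counts TSV: first column `feature_id`, remaining columns one
#'   per sample, integer cells.
#' @param annotation_path feature annotation TSV with columns `feature_id`,
#'   `lineage`, `class`. Features present in the counts but absent from the
#'   annotation are classed `"unannotated"` (with a warning); extra
#'   annotation rows are warned about and dropped.
#' @param samples_path sample metadata TSV with columns `sample_id`,
#'   `trip`, `site`, `replicate`, `lat`, `lon`. Required: samples missing
#'   metadata are an error.
#' @param ranks lineage level names, root first; inferred from the deepest
#'   lineage path when `NULL` (`domain...genus` for 6 levels,
#'   `rank3/rank4/rank5` for 3).
#' @return a [count_table()].
#' @export
read_count_table <- function(path, annotation_path, samples_path,
                             ranks = NULL) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  fid <- as.character(raw[[1]])
  if (anyDuplicated(fid))
    stop("duplicate feature ids in ", path)
  m <- as.matrix(raw[, -1, drop = FALSE])
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-integer or negative count at feature '%s', sample '%s'",
                 fid[bad[1, 1]], colnames(m)[bad[1, 2]]))
  rownames(m) <- fid

  ann <- utils::read.table(annotation_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  extra <- setdiff(ann$feature_id, fid)
  if (length(extra) > 0)
    warning(length(extra), " annotation rows refer to unknown feature ids")
  ann <- ann[match(fid, ann$feature_id), ]
  missing_ann <- is.na(ann$feature_id)
  if (any(missing_ann)) {
    warning(sum(missing_ann), " features lack annotation; classed unannotated")
    ann$feature_id[missing_ann] <- fid[missing_ann]
    ann$lineage[missing_ann] <- fid[missing_ann]
    ann$class[missing_ann] <- "unannotated"
  }

  smp <- utils::read.table(samples_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  idx <- match(colnames(m), smp$sample_id)
  if (anyNA(idx))
    stop("samples missing metadata: ",
         paste(colnames(m)[is.na(idx)], collapse = ", "))
  smp <- smp[idx, ]

  if (is.null(ranks)) {
    depth <- max(lengths(strsplit(ann$lineage, ";", fixed = TRUE)))
    ranks <- if (depth == 6)
      c("domain", "phylum", "class", "order", "family", "genus")
    else if (depth == 3) c("rank3", "rank4", "rank5")
    else paste0("level", seq_len(depth))
  }
  count_table(t(m), smp, ann, ranks = ranks)
}

#' Write a count table (features x samples) plus its annotation
#'
#' @param ct a [count_table()].
#' @param path counts TSV destination.
#' @param annotation_path annotation TSV destination (skipped when `NULL`).
#' @return invisibly, `ct`.
#' @export
write_count_table <- function(ct, path, annotation_path = NULL) {
  stopifnot(inherits(ct, "count_table"))
  out <- data.frame(feature_id = colnames(ct$counts),
                    t(ct$counts), check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(annotation_path))
    utils::write.table(ct$features, annotation_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(ct)
}

#' Read / write a reef-site environment table
#'
#' The TSV has columns `site`, `trip`, `lat`, `lon`, then one column per
#' physico-chemical variable; missing cells are `NA`.
#'
#' @param path TSV path.
#' @return [read_env_table()]: an [env_table()].
#' @export
read_env_table <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- intersect(c("site", "trip", "lat", "lon"), names(raw))
  env_table(as.matrix(raw[, setdiff(names(raw), meta_cols), drop = FALSE]),
            raw[, meta_cols, drop = FALSE])
}

#' @rdname read_env_table
#' @param env an [env_table()].
#' @export
write_env_table <- function(env, path) {
  stopifnot(inherits(env, "env_table"))
  out <- cbind(env$sites, as.data.frame(env$values))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(env)
}
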