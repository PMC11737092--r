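# End-to-end driver reproducing the analysis sequence on synthetic or
# user-supplied data: filter -> CLR -> community summaries -> Mantel
# screen -> MINT sPLS + LOGOCV -> per-trip CV stability.

#' Pipeline configuration
#'
#' @param sim a [sim_config()] to generate inputs, or `NULL` to read them
#'   from `input_dir` (a directory written by [write_dataset()] or in the
#'   same layout).
#' @param input_dir directory with `taxa_counts.tsv`, `go_counts.tsv`,
#'   their annotations, `samples.tsv` and `env.tsv` (ignored when `sim` is
#'   given).
#' @param pseudocount CLR pseudocount.
#' @param min_rel_abundance rare-feature threshold.
#' @param keep_responses indicator features selected per sPLS component.
#' @param n_components MINT sPLS components.
#' @param mantel_permutations permutations per partial Mantel test.
#' @param permanova_permutations permutations per pairwise PERMANOVA.
#' @param cv_folds,cv_repeats per-trip CV stability design.
#' @param run_mantel,run_permanova,run_mint,run_stability stage toggles.
#' @param seed master seed; every stochastic stage derives its seed from
#'   it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), input_dir = NULL,
                            pseudocount = 1, min_rel_abundance = 1e-6,
                            keep_responses = 50, n_components = 2,
                            mantel_permutations = 999,
                            permanova_permutations = 999,
                            cv_folds = 4, cv_repeats = 50,
                            run_mantel = TRUE, run_permanova = TRUE,
                            run_mint = TRUE, run_stability = TRUE,
                            seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full indicator-mining pipeline
#'
#' Executes, in order: input generation or reading; feature filtering and
#' CLR; PCA, pairwise PERMANOVA across trips, Shannon diversity and
#' within-site Bray-Curtis similarity; the partial Mantel screen; MINT
#' sPLS with leave-one-group-out stability and the clustered indicator
#' report; and per-trip CV reselection stability with the taxa-vs-GO
#' comparison. Stage outputs are written as TSV under `outdir` together
#' with a machine-readable JSON run log (seeds, parameters, stage
#' timings). Input files are never modified; reruns with the same
#' configuration reproduce the same numbers.
#'
#' @param cfg a [pipeline_config()].
#' @param outdir output directory.
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(cfg = pipeline_config(), outdir = tempfile()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log <- list(seed = cfg$seed, started = format(Sys.time()), stages = list())
  res <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- expr
    log$stages[[name]] <<- list(seconds = round(
      proc.time()[["elapsed"]] - t0, 3))
    out
  }
  wtsv <- function(x, f)
    utils::write.table(x, file.path(outdir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)

  ## inputs
  ds <- stage("input", {
    if (!is.null(cfg$sim)) generate_dataset(cfg$sim)
    else {
      p <- function(f) file.path(cfg$input_dir, f)
      list(taxa_counts = read_count_table(p("taxa_counts.tsv"),
                                          p("taxa_annotation.tsv"),
                                          p("samples.tsv")),
           go_counts = read_count_table(p("go_counts.tsv"),
                                        p("go_annotation.tsv"),
                                        p("samples.tsv")),
           env = read_env_table(p("env.tsv")))
    }
  })

  ## preprocess
  taxa <- stage("filter", filter_features(ds$taxa_counts,
                                          cfg$min_rel_abundance))
  go <- filter_features(ds$go_counts, cfg$min_rel_abundance)
  wtsv(removal_report(taxa), "taxa_removal_report.tsv")
  clr_taxa <- clr_transform(taxa, cfg$pseudocount)
  clr_go <- clr_transform(go, cfg$pseudocount)
  env <- impute_env_within_trip(ds$env)
  res$taxa <- taxa; res$go <- go; res$env <- env

  ## community summaries
  res$pca <- stage("pca", clr_pca(clr_taxa))
  scores <- res$pca$scores
  wtsv(data.frame(sample_id = rownames(scores), scores[, 1:2]),
       "pca_scores.tsv")
  if (cfg$run_permanova) {
    res$permanova <- stage("permanova", permanova_pairwise(
      distance_matrix(as.matrix(stats::dist(scores)), "euclidean"),
      taxa$samples$trip, n_perm = cfg$permanova_permutations,
      seed = cfg$seed + 11))
    wtsv(res$permanova, "permanova_pairwise.tsv")
  }
  res$shannon <- stage("diversity", data.frame(
    sample_id = taxa$samples$sample_id, trip = taxa$samples$trip,
    shannon = apply(taxa$counts, 1, shannon_index)))
  wtsv(res$shannon, "shannon.tsv")
  res$within_site <- stage("within_site", {
    lv <- list()
    for (l in c("genus", "family", "order", "class", "phylum"))
      lv[[l]] <- within_site_similarity(taxa, l)
    for (l in c("rank5", "rank4", "rank3"))
      lv[[l]] <- within_site_similarity(go, l)
    lv
  })
  wtsv(do.call(rbind, lapply(res$within_site, `[[`, "summary")),
       "within_site_summary.tsv")

  ## partial Mantel screen
  if (cfg$run_mantel) {
    res$mantel <- stage("mantel", mantel_screen(
      list(taxonomy = taxa, go = go), ds$env,
      n_perm = cfg$mantel_permutations, seed = cfg$seed + 23))
    wtsv(res$mantel, "mantel_screen.tsv")
  }

  ## MINT sPLS + LOGOCV
  if (cfg$run_mint) {
    res$mint <- stage("mint", {
      out <- list()
      for (nm in c("taxonomy", "go")) {
        ct <- if (nm == "taxonomy") taxa else go
        Y <- clr_transform(ct, cfg$pseudocount)
        X <- env_for_samples(ct, env)
        scfg <- spls_config(n_components = cfg$n_components,
                            keep_responses = cfg$keep_responses)
        fit <- suppressWarnings(
          mint_spls_fit(X, Y, ct$samples$trip, scfg))
        sim <- suppressWarnings(similarity_matrix(fit, X, Y))
        scores <- logocv_stability(X, Y, ct$samples$trip, scfg)
        report <- stable_indicator_report(scores, sim)
        out[[nm]] <- list(fit = fit, similarity = sim, logocv = scores,
                          report = report)
        wtsv(report, sprintf("mint_indicators_%s.tsv", nm))
        utils::write.table(
          round(unclass(sim), 6), file.path(
            outdir, sprintf("mint_similarity_%s.tsv", nm)),
          sep = "\t", quote = FALSE, row.names = TRUE, col.names = NA)
      }
      out
    })
  }

  ## per-trip CV stability
  if (cfg$run_stability) {
    res$stability <- stage("stability", run_cv_stability_grid(
      taxa, go, env,
      cfg = spls_config(n_components = 1,
                        keep_responses = cfg$keep_responses),
      n_folds = cfg$cv_folds, n_repeats = cfg$cv_repeats,
      seed = cfg$seed + 37))
    wtsv(res$stability$stability, "cv_stability.tsv")
    cmp <- lapply(sort(unique(taxa$samples$trip)), function(t)
      compare_stability(res$stability$models[[sprintf("taxonomy_trip%s", t)]],
                        res$stability$models[[sprintf("go_trip%s", t)]],
                        trip = t))
    res$stability_comparison <- do.call(rbind, cmp)
    wtsv(res$stability_comparison, "cv_stability_comparison.tsv")
  }

  log$finished <- format(Sys.time())
  log$parameters <- cfg[setdiff(names(cfg), c("sim", "input_dir"))]
  if (!is.null(cfg$sim)) log$parameters$sim <- unclass(cfg$sim)
  jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
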