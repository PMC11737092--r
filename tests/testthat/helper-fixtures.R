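# Small in-code fixtures shared across test files.

# A tiny annotated count table: 4 samples (2 sites x 2 replicates, one
# trip each), 5 features spanning the annotation classes.
toy_count_table <- function() {
  counts <- matrix(c(10, 20, 30, 5, 1,
                     12, 18, 28, 6, 0,
                     40, 10, 15, 2, 3,
                     38, 12, 14, 3, 2),
                   nrow = 4, byrow = TRUE)
  samples <- data.frame(
    sample_id = c("A_r1", "A_r2", "B_r1", "B_r2"),
    trip = c(1, 1, 2, 2), site = c("A", "A", "B", "B"),
    replicate = c(1, 2, 1, 2),
    lat = c(-12, -12, -18, -18), lon = c(145, 145, 147, 147))
  features <- data.frame(
    feature_id = paste0("f", 1:5),
    lineage = c("Bacteria;P1;C1;O1;F1;G1", "Bacteria;P1;C1;O1;F1;G2",
                "Bacteria;P1;C1;O1;F2;G3", "Bacteria;P2;C2;O2;F3;G4",
                "Bacteria;P2;C2;O2;F3;G5"),
    class = "bacteria")
  count_table(counts, samples, features,
              ranks = c("domain", "phylum", "class", "order", "family",
                        "genus"))
}

# A small but full-structure synthetic dataset (fast to generate).
small_sim_config <- function(seed = 1, ...) {
  args <- list(sites_per_trip = 6, n_taxa = 120, n_go = 30,
               redundancy = 4, n_indicator_go = 10,
               library_size_mean = 2e4, n_missing_env = 0, seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# Random symmetric distance matrix over n items.
random_distance <- function(n, seed) {
  set.seed(seed)
  as.matrix(stats::dist(matrix(stats::rnorm(n * 3), n)))
}
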