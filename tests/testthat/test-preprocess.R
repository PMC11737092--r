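make_filter_table <- function(counts, classes) {
  n <- length(counts)
  count_table(matrix(counts, nrow = 1,
                     dimnames = list("s1", paste0("f", seq_len(n)))),
              data.frame(sample_id = "s1", trip = 1, site = "A",
                         replicate = 1, lat = 0, lon = 0),
              data.frame(feature_id = paste0("f", seq_len(n)),
                         lineage = paste0("Bacteria;G", seq_len(n)),
                         class = classes))
}

test_that("rare features are removed by overall relative abundance", {
  # grand total 10,000,000: 5 reads = 5e-7 < 1e-6 removed, 15 = 1.5e-6 kept
  ct <- make_filter_table(c(1e7 - 20, 5, 15), rep("bacteria", 3))
  out <- filter_features(ct, min_rel_abundance = 1e-6)
  expect_setequal(colnames(out$counts), c("f1", "f3"))
  rep <- removal_report(out)
  expect_equal(rep$feature_id, "f2")
  expect_equal(rep$rule, "rare")
  expect_equal(rep$value, 5 / 1e7)
})

test_that("class-based rules remove features regardless of abundance", {
  ct <- make_filter_table(c(100, 5000, 100, 100, 100),
                          c("bacteria", "virus", "eukaryote",
                            "domain_only", "unannotated"))
  out <- filter_features(ct, min_rel_abundance = 0)
  expect_equal(colnames(out$counts), "f1")
  expect_setequal(removal_report(out)$rule,
                  c("virus", "eukaryote", "domain_only", "unannotated"))
})

test_that("a clean table above threshold passes through unchanged", {
  ct <- make_filter_table(c(100, 200, 300), rep("bacteria", 3))
  out <- filter_features(ct)
  expect_equal(out$counts, ct$counts)
  expect_equal(nrow(removal_report(out)), 0)
})

test_that("the abundance denominator is the post-class-filter grand total", {
  # 96 bacterial reads + big viral feature; f2 at 96 reads of 1e6+96:
  # against the full total it would be rare, against the post-class total
  # (196) it is not
  ct <- make_filter_table(c(100, 96, 1e6), c("bacteria", "bacteria",
                                             "virus"))
  out <- filter_features(ct, min_rel_abundance = 1e-3)
  expect_setequal(colnames(out$counts), c("f1", "f2"))
})

test_that("filtering everything raises a rule-naming error", {
  ct <- make_filter_table(c(10, 10), c("virus", "eukaryote"))
  expect_error(filter_features(ct), "virus")
})

test_that("relative abundance normalizes rows to 1", {
  expect_equal(relative_abundance(matrix(c(2, 2), 1,
                                         dimnames = list("s", NULL)))[1, ],
               c(0.5, 0.5))
  expect_equal(relative_abundance(matrix(c(1, 3), 1,
                                         dimnames = list("s", NULL)))[1, ],
               c(0.25, 0.75))
  set.seed(1)
  m <- matrix(rpois(60, 20) + 1, 6, dimnames = list(paste0("s", 1:6), NULL))
  expect_equal(rowSums(relative_abundance(m)), rep(1, 6),
               tolerance = 1e-12, ignore_attr = TRUE)
  m[2, ] <- 0
  expect_error(relative_abundance(m), "s2")
})

test_that("clr transform matches the closed form and sums to zero", {
  even <- clr_transform(matrix(c(10, 10, 10, 10), 1,
                               dimnames = list("s", NULL)))
  expect_equal(unclass(even)[1, ], rep(0, 4))
  # [1,3] + pseudocount 1 -> ln(2/sqrt(8)), ln(4/sqrt(8))
  v <- clr_transform(matrix(c(1, 3), 1, dimnames = list("s", NULL)))
  expect_equal(unclass(v)[1, ], c(log(2 / sqrt(8)), log(4 / sqrt(8))),
               tolerance = 1e-5)
  expect_equal(unname(round(unclass(v)[1, ], 5)), c(-0.34657, 0.34657))
  set.seed(2)
  m <- matrix(rpois(200, 50), 10, dimnames = list(paste0("s", 1:10), NULL))
  expect_lt(max(abs(rowSums(clr_transform(m)))), 1e-9)
  expect_error(clr_transform(m, pseudocount = 0), "pseudocount")
})

test_that("clr is scale-invariant for positive data as pseudocount -> 0", {
  set.seed(3)
  m <- matrix(runif(40, 1, 100), 4, dimnames = list(paste0("s", 1:4), NULL))
  a <- clr_transform(m, pseudocount = 1e-9)
  b <- clr_transform(7.3 * m, pseudocount = 1e-9)
  expect_equal(unclass(a), unclass(b), tolerance = 1e-6)
})

test_that("collapsing sums counts within the level label", {
  ct <- toy_count_table()
  fam <- collapse_counts(ct, "family")
  # f1, f2 share family F1: counts add
  expect_equal(fam$counts[, "F1"], ct$counts[, "f1"] + ct$counts[, "f2"])
  expect_equal(sum(fam$counts), sum(ct$counts))
  # native level is the identity up to labels
  gen <- collapse_counts(ct, "genus")
  expect_equal(unname(gen$counts), unname(ct$counts))
  expect_error(collapse_counts(ct, "kingdom"), "unknown level")
})

test_that("features not reaching the level collapse into the sentinel", {
  ct <- toy_count_table()
  ct$features$lineage[5] <- "Bacteria;P2"
  out <- collapse_counts(ct, "genus")
  expect_true("unresolved" %in% colnames(out$counts))
  expect_equal(out$counts[, "unresolved"], ct$counts[, "f5"])
})

test_that("collapse commutes with relative abundance", {
  ct <- toy_count_table()
  a <- relative_abundance(collapse_counts(ct, "family"))
  ra <- relative_abundance(ct)
  fam_label <- vapply(strsplit(ct$features$lineage, ";"), `[`, "",  5)
  b <- t(rowsum(t(ra), fam_label))
  expect_equal(a[, colnames(b)], b)
})

test_that("site medians aggregate replicates and respect missingness", {
  raw <- data.frame(site = rep(c("A", "B"), each = 3),
                    trip = 1, replicate = rep(1:3, 2),
                    NO3 = c(1, 2, 10, NA, NA, NA),
                    PO4 = c(0.5, NA, 0.7, 0.2, 0.4, 0.3))
  env <- aggregate_env_medians(raw)
  expect_equal(env$values["A", "NO3"], 2)        # median of 1, 2, 10
  expect_equal(env$values["A", "PO4"], 0.6)      # NA ignored
  expect_true(is.na(env$values["B", "NO3"]))     # all missing -> masked
  single <- aggregate_env_medians(
    data.frame(site = "C", trip = 1, NO3 = 4.2))
  expect_equal(single$values["C", "NO3"], 4.2)
})

test_that("heatmap scaling centers on the median with unit sample SD", {
  env <- env_table(cbind(v1 = c(1, 2, 3), v2 = c(5, 7, 100)),
                   data.frame(site = c("A", "B", "C"), trip = 1))
  sc <- scale_env_for_heatmap(env)
  expect_equal(sc[, "v1"], c(A = -1, B = 0, C = 1))
  expect_equal(median(sc[, "v2"]), 0)
  bad <- env_table(cbind(v1 = c(2, 2, 2)),
                   data.frame(site = c("A", "B", "C"), trip = 1))
  expect_error(scale_env_for_heatmap(bad), "v1")
})

test_that("missing env cells are imputed by the within-trip median", {
  env <- env_table(cbind(v1 = c(1, NA, 5, 10, 20, NA)),
                   data.frame(site = paste0("S", 1:6),
                              trip = rep(1:2, each = 3)))
  out <- impute_env_within_trip(env)
  expect_equal(out$values["S2", "v1"], 3)   # median of 1, 5
  expect_equal(out$values["S6", "v1"], 15)  # median of 10, 20
  expect_false(anyNA(out$values))
})
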