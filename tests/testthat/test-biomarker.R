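test_that("fold-change is a TIC-normalized mean ratio with pseudo-count", {
  # column totals equalized so TIC normalization is a common factor
  M <- rbind(c(12, 12, 2, 2),
             c(8, 8, 18, 18))
  rownames(M) <- c("FA", "FB")
  colnames(M) <- c("p1", "p2", "n1", "n2")
  ft <- make_ft(M)
  fc <- fold_change(ft, c("p1", "p2"), c("n1", "n2"), epsilon = 1e-9)
  expect_equal(unname(fc[["FA"]]), 6, tolerance = 1e-6)

  # equal means -> exactly 1
  M2 <- matrix(5, 2, 4, dimnames = list(c("a", "b"), c("p1", "p2", "n1", "n2")))
  fc2 <- fold_change(make_ft(M2), c("p1", "p2"), c("n1", "n2"), epsilon = 0.01)
  expect_equal(as.numeric(fc2), c(1, 1))

  # absent in negatives: FC = (m + eps) / eps, finite
  M3 <- rbind(c(0.6, 0.6, 0, 0), c(0.4, 0.4, 1, 1))
  rownames(M3) <- c("hit", "bg"); colnames(M3) <- c("p1", "p2", "n1", "n2")
  eps <- 0.001
  fc3 <- fold_change(make_ft(M3), c("p1", "p2"), c("n1", "n2"), epsilon = eps)
  expect_equal(unname(fc3[["hit"]]), (0.6 + eps) / eps)
  expect_true(all(is.finite(fc3)))

  expect_error(fold_change(ft, c("p1"), c("p1", "n1")), "disjoint")
  expect_error(fold_change(ft, "nope", "n1"), "unknown sample")
})

test_that("the VIP/fold-change co-filter applies strict and inclusive bounds", {
  vip <- c(a = 5.0, b = 5.0, c = 3.9, d = 4.0, e = 7.0)
  fc <- c(a = 10, b = 2, c = 10, d = 10, e = 6)
  sel <- select_biomarkers(vip, fc, vip_threshold = 4.0, fold_threshold = 6.0)
  expect_setequal(sel, c("a", "e"))   # VIP strict (>4), FC inclusive (>=6)
  # brute-force filter over random vectors
  set.seed(5)
  for (rep in 1:20) {
    v <- runif(50, 0, 8); f <- runif(50, 0, 12)
    names(v) <- names(f) <- sprintf("x%02d", 1:50)
    expect_setequal(select_biomarkers(v, f, 4, 6),
                    names(v)[v > 4 & f >= 6 & f > 1])
  }
  expect_error(select_biomarkers(vip, fc[1:3]), "equal length")
})

test_that("learn_library recovers planted markers on synthetic reference data", {
  ref <- simulate_reference(small_synth_config(seed = 101))
  lib <- learn_library(ref$table, ref$ontology, ref$spectra,
                       vip_threshold = 1.5, fold_threshold = 6)
  planted <- unlist(ref$truth)
  sel <- unique(lib$entries$feature_id)
  expect_gte(sum(sel %in% planted) / length(planted), 0.9)
  expect_lte(sum(!sel %in% planted) / max(length(sel), 1), 0.1)
  # every entry satisfies its own thresholds (self-consistency)
  expect_true(all(lib$entries$vip > lib$parameters$vip_threshold))
  expect_true(all(lib$entries$fold_change >= lib$parameters$fold_threshold))
  expect_equal(nrow(lib$run_log), 4L)
})

test_that("a dataset with no enriched features yields an empty library", {
  set.seed(9)
  M <- matrix(rlnorm(80 * 12, log(1e5), 0.3), 80, 12)
  rownames(M) <- sprintf("F%03d", 1:80)
  colnames(M) <- sprintf("s%02d", 1:12)
  nodes <- data.frame(category_id = c("r", "A", "B"), name = c("r", "A", "B"),
                      parent_id = c(NA, "r", "r"), stringsAsFactors = FALSE)
  onto <- food_ontology(nodes, setNames(rep(c("A", "B"), each = 6), colnames(M)))
  lib <- learn_library(make_ft(M), onto, NULL, vip_threshold = 4, fold_threshold = 6)
  expect_equal(nrow(lib$entries), 0L)
})

test_that("branch-level and leaf-level markers are both learned on 2-level data", {
  cfg <- synth_config(n_categories = 4L, ontology_depth = 2L,
                      samples_per_category = 6L, planted_per_category = 10L,
                      background_features = 100L,
                      branch_planted_per_branch = 8L, seed = 77)
  ref <- simulate_reference(cfg)
  expect_equal(nrow(ref$ontology$nodes), 7L)  # root + 2 branches + 4 leaves
  lib <- learn_library(ref$table, ref$ontology, ref$spectra,
                       vip_threshold = 1.5, fold_threshold = 4)
  expect_setequal(unique(lib$entries$level), c(1L, 2L))
  br <- lib$entries[lib$entries$category_id == "branch_1", ]
  expect_gte(sum(ref$truth$branch_1 %in% br$feature_id), 6L)
  leaf <- lib$entries[lib$entries$category_id == "cat_01", ]
  expect_gte(sum(ref$truth$cat_01 %in% leaf$feature_id), 8L)
})

test_that("selection is monotone in both thresholds and column-permutation invariant", {
  ref <- simulate_reference(small_synth_config(seed = 55))
  key <- function(lib) sort(paste(lib$entries$feature_id, lib$entries$category_id))
  base <- learn_library(ref$table, ref$ontology, NULL,
                        vip_threshold = 1.0, fold_threshold = 4)
  higher_vip <- learn_library(ref$table, ref$ontology, NULL,
                              vip_threshold = 2.0, fold_threshold = 4)
  higher_fc <- learn_library(ref$table, ref$ontology, NULL,
                             vip_threshold = 1.0, fold_threshold = 8)
  expect_true(all(key(higher_vip) %in% key(base)))
  expect_true(all(key(higher_fc) %in% key(base)))

  perm <- sample(ncol(ref$table$intensities))
  tab_perm <- feature_table(ref$table$features,
                            ref$table$intensities[, perm],
                            ref$table$sample_ids[perm])
  lib_perm <- learn_library(tab_perm, ref$ontology, NULL,
                            vip_threshold = 1.0, fold_threshold = 4)
  expect_equal(key(lib_perm), key(base))
})

test_that("library JSON+MGF serialization round-trips and audits on load", {
  ref <- simulate_reference(small_synth_config(seed = 13))
  lib <- learn_library(ref$table, ref$ontology, ref$spectra,
                       vip_threshold = 1.5, fold_threshold = 6)
  d <- withr::local_tempdir()
  path <- file.path(d, "library.json")
  write_library(lib, path)
  back <- read_library(path)
  expect_equal(back$entries, lib$entries, tolerance = 1e-9)
  expect_equal(back$parameters$vip_threshold, lib$parameters$vip_threshold)
  expect_setequal(names(back$spectra), names(lib$spectra))
  s0 <- lib$spectra[[1]]
  expect_equal(back$spectra[[s0$spectrum_id]]$peaks, s0$peaks, tolerance = 1e-6)

  # tampering with an entry breaks the self-consistency audit
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc$entries$vip[1] <- 0.1
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null")
  expect_error(read_library(path), "self-consistency")
})
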