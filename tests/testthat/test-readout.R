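test_that("match-to-feature linking honors explicit ids, tolerances and logging", {
  M <- matrix(1, 2, 2, dimnames = list(c("F7", "F8"), c("s1", "s2")))
  qt <- make_ft(M, mz = c(250.101, 250.100), rt = c(118, 400))
  sp_explicit <- ms_spectrum("q1", 999.9, cbind(100, 1), feature_id = "F7")
  sp_tol <- ms_spectrum("q2", 250.100, cbind(100, 1), retention_time = 120)
  sp_lost <- ms_spectrum("q3", 800.0, cbind(100, 1), retention_time = 120)
  matches <- data.frame(query_spectrum_id = c("q1", "q2", "q3"),
                        library_spectrum_id = "L", score = 0.9,
                        matched_peaks = 5L, stringsAsFactors = FALSE)
  expect_message(
    links <- link_matches_to_features(matches, qt,
                                      list(sp_explicit, sp_tol, sp_lost),
                                      mz_tol = 0.01, rt_tol = 30),
    "1 matched")
  expect_equal(links[["q1"]], "F7")       # explicit link wins despite m/z
  expect_equal(links[["q2"]], "F7")       # (250.101, 118 s) within both tols
  expect_false("q3" %in% names(links))
  expect_equal(attr(links, "n_dropped"), 1L)
})

test_that("tolerance linking equals brute-force nearest-within-tolerance", {
  set.seed(71)
  for (rep in 1:10) {
    p <- 30
    mz <- runif(p, 100, 110)
    rt <- runif(p, 0, 600)
    qt <- make_ft(matrix(1, p, 2,
                         dimnames = list(sprintf("F%02d", 1:p), c("a", "b"))),
                  mz = mz, rt = rt)
    spectra <- lapply(1:15, function(i)
      ms_spectrum(sprintf("q%02d", i), runif(1, 100, 110), cbind(150, 1),
                  retention_time = runif(1, 0, 600)))
    matches <- data.frame(query_spectrum_id = sprintf("q%02d", 1:15),
                          library_spectrum_id = "L", score = 1,
                          matched_peaks = 4L, stringsAsFactors = FALSE)
    links <- suppressMessages(
      link_matches_to_features(matches, qt, spectra, mz_tol = 0.5, rt_tol = 100))
    for (s in spectra) {
      dmz <- abs(mz - s$precursor_mz)
      drt <- abs(rt - s$retention_time)
      ok <- dmz <= 0.5 & drt <= 100
      if (!any(ok)) {
        expect_false(s$spectrum_id %in% names(links))
      } else {
        cand <- which(ok)
        expect_equal(links[[s$spectrum_id]],
                     sprintf("F%02d", cand[order(dmz[cand], drt[cand])][1]))
      }
    }
  }
})

test_that("dietary scores implement both fill rules on the stated arithmetic", {
  M <- matrix(c(2, 4, 9, 9), 4, 1,
              dimnames = list(c("B1", "B2", "X1", "X2"), "s1"))
  qt <- make_ft(M)
  lib <- toy_library(c("B1", "B2", "B3"))   # B3 absent from the query table
  sc_zero <- dietary_scores(qt, lib, matches = NULL, fill = "zeros")
  sc_det <- dietary_scores(qt, lib, matches = NULL, fill = "detected_only")
  expect_equal(unname(sc_zero["s1", "catA"]), 2)     # (2 + 4 + 0) / 3
  expect_equal(unname(sc_det["s1", "catA"]), 3)      # (2 + 4) / 2

  # sample with nothing detected -> all-zero row
  lib_none <- toy_library(c("Z1", "Z2"))
  sc_none <- dietary_scores(qt, lib_none, matches = NULL)
  expect_equal(unname(sc_none["s1", ]), 0)
})

test_that("spectral-match mode uses best-scoring match per biomarker", {
  qt <- make_ft(matrix(c(10, 30), 2, 1,
                       dimnames = list(c("QF1", "QF2"), "s1")))
  ref_sp <- ms_spectrum("L1", 300, cbind(c(100, 200), c(1, 1)), feature_id = "B1")
  lib <- toy_library("B1", spectra = list(ref_sp))
  matches <- data.frame(
    query_spectrum_id = c("q_low", "q_high"),
    library_spectrum_id = "L1",
    score = c(0.8, 0.95), matched_peaks = 4L, stringsAsFactors = FALSE)
  links <- c(q_low = "QF1", q_high = "QF2")
  sc <- dietary_scores(qt, lib, matches, links)
  expect_equal(unname(sc["s1", "catA"]), 30)   # intensity of the 0.95 match
})

test_that("score invariants: linearity, fill ordering, monotone dilution", {
  set.seed(83)
  p <- 12
  M <- matrix(rlnorm(p * 3), p, 3,
              dimnames = list(sprintf("B%02d", 1:p), c("s1", "s2", "s3")))
  qt <- make_ft(M)
  lib <- toy_library(c(sprintf("B%02d", 1:8), "MISSING1", "MISSING2"))
  z <- dietary_scores(qt, lib, matches = NULL, fill = "zeros")
  d <- dietary_scores(qt, lib, matches = NULL, fill = "detected_only")
  expect_true(all(z <= d + 1e-12))
  # doubling one sample doubles its raw score, leaves proportions unchanged
  M2 <- M; M2[, "s2"] <- 2 * M2[, "s2"]
  z2 <- dietary_scores(make_ft(M2), lib, matches = NULL)
  expect_equal(unname(z2["s2", ]), unname(2 * z["s2", ]), tolerance = 1e-12)
  expect_equal(unname(z2["s1", ]), unname(z["s1", ]), tolerance = 1e-12)
  # an extra undetected biomarker dilutes fill=zeros scores
  lib_more <- toy_library(c(sprintf("B%02d", 1:8), "MISSING1", "MISSING2", "MISSING3"))
  z_more <- dietary_scores(qt, lib_more, matches = NULL)
  expect_true(all(z_more <= z + 1e-12))
})

test_that("proportion normalization is per-level, row-stochastic, zero-preserving", {
  sc <- structure(matrix(c(2, 0, 6, 0), 2, 2,
                         dimnames = list(c("s1", "s2"), c("A", "B"))),
                  levels = c(A = 1L, B = 1L), fill = "zeros",
                  normalized = FALSE,
                  class = c("dietary_scores", "matrix", "array"))
  ns <- normalize_scores(sc, 1)
  expect_equal(unname(ns["s1", ]), c(0.25, 0.75))
  expect_equal(unname(ns["s2", ]), c(0, 0))          # all-zero row unchanged
  expect_error(normalize_scores(sc, 3), "no categories")

  set.seed(97)
  for (rep in 1:100) {
    m <- matrix(rexp(8) * rbinom(8, 1, 0.7), 2, 4,
                dimnames = list(c("x", "y"), letters[1:4]))
    s <- structure(m, levels = setNames(rep(1L, 4), letters[1:4]),
                   fill = "zeros", normalized = FALSE,
                   class = c("dietary_scores", "matrix", "array"))
    rs <- rowSums(normalize_scores(s, 1))
    expect_true(all(abs(rs - 1) < 1e-9 | rs == 0))
  }
})

test_that("score matrices round-trip through TSV with their sidecar", {
  sc <- structure(matrix(runif(6), 3, 2,
                         dimnames = list(c("s1", "s2", "s3"), c("A", "B"))),
                  levels = c(A = 1L, B = 2L), fill = "detected_only",
                  normalized = FALSE,
                  class = c("dietary_scores", "matrix", "array"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_scores(sc, f)
  back <- read_scores(f)
  expect_equal(unclass(back), unclass(sc), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(attr(back, "levels"), attr(sc, "levels"))
  expect_equal(attr(back, "fill"), "detected_only")
})
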