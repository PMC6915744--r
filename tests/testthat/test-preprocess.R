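test_that("BED loading round-trips records and rejects malformed lines", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t101\t0.4",
               "chr2\t50\t51\t-0.35",
               "chr1\t200\t201\t0.1"), f)
  dms <- load_dms_bed(f)
  expect_equal(nrow(dms), 3L)
  expect_equal(dms$delta_beta, c(0.4, -0.35, 0.1))
  expect_equal(dms$chrom, c("chr1", "chr2", "chr1"))
  expect_equal(dms$end, dms$start + 1L)

  # start >= end rejected, others kept; non-numeric score skipped with warning
  writeLines(c("chr1\t100\t101\t0.4",
               "chr1\t300\t300\t0.2",
               "chr1\t400\t401\tnotanumber",
               "chr1\t500\t501\t-0.1"), f)
  expect_warning(dms <- load_dms_bed(f), "skipped 2")
  expect_equal(dms$start, c(100L, 500L))
  expect_equal(attr(dms, "skipped_lines"), c(2L, 3L))

  writeLines(character(0), f)
  expect_warning(empty <- load_dms_bed(f), "no valid records")
  expect_equal(nrow(empty), 0L)
})

test_that("intensity and count conversions follow their defining formulas", {
  expect_equal(beta_from_intensities(0, 0), 0)
  expect_equal(beta_from_intensities(900, 0), 0.9)
  expect_equal(beta_from_intensities(1000, 1000), 1000 / 2100)
  expect_error(beta_from_intensities(-1, 0), "non-negative")

  expect_equal(beta_from_counts(5, 10, min_depth = 5), 0.5)
  expect_true(is.na(beta_from_counts(3, 4, min_depth = 5)))
  expect_true(is.na(beta_from_counts(0, 0, min_depth = 1)))
  expect_error(beta_from_counts(5, 4), "<=")
})

test_that("M/beta conversion is the logistic pair with exact round-trip", {
  expect_equal(m_to_beta(0), 0.5)
  expect_equal(m_to_beta(1), 2 / 3)
  expect_equal(beta_to_m(m_to_beta(-2.7)), -2.7, tolerance = 1e-12)
  # strictly increasing on a grid
  g <- seq(-8, 8, length.out = 101)
  expect_true(all(diff(m_to_beta(g)) > 0))
  expect_error(beta_to_m(0), "undefined")
  expect_error(beta_to_m(1), "undefined")
})

test_that("BH adjustment matches the textbook step-up oracle", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  set.seed(11)
  for (len in 1:12) {
    for (rep in 1:30) {
      p <- round(runif(len), 3)
      expect_equal(p.adjust(p, "BH"), oracle_bh(p))
    }
  }
  # monotone over sorted p-values
  p <- sort(runif(50))
  expect_true(all(diff(p.adjust(p, "BH")) >= -1e-15))
})

test_that("differential_filter recovers a planted site and only that site", {
  set.seed(5)
  n_null <- 99
  vals <- matrix(rbeta(n_null * 20, 2, 2), nrow = n_null)
  planted <- c(pmin(pmax(rnorm(10, 0.8, 0.02), 0), 1),
               pmin(pmax(rnorm(10, 0.2, 0.02), 0), 1))
  vals <- rbind(planted, vals)
  rownames(vals) <- paste0("s", seq_len(nrow(vals)))
  bm <- beta_matrix(vals, rep(c("case", "ctrl"), each = 10))
  res <- differential_filter(bm)
  expect_equal(res$site_id, "s1")
  expect_equal(res$status, "hyper")
  expect_gt(res$delta_beta, 0.5)
  # independent oracle: plain t.test on the planted row
  expect_equal(res$p_value, t.test(planted[1:10], planted[11:20])$p.value,
               tolerance = 1e-12)
})

test_that("differential_filter edge behavior: null case, full return, exclusions", {
  vals <- matrix(rep(seq(0.1, 0.9, length.out = 5), each = 8), nrow = 5,
                 byrow = TRUE)
  rownames(vals) <- paste0("s", 1:5)
  bm <- beta_matrix(vals, rep(c("a", "b"), each = 4))
  expect_warning(res <- differential_filter(bm), regexp = NA)
  expect_equal(nrow(res), 0L)   # both groups identical per site

  set.seed(1)
  vals <- matrix(rbeta(40, 2, 2), nrow = 4,
                 dimnames = list(paste0("s", 1:4), NULL))
  bm <- beta_matrix(vals, rep(c("a", "b"), each = 5))
  all_back <- differential_filter(bm, min_abs_delta = 0, max_p = 1.01,
                                  max_fdr = 1.01)
  expect_equal(nrow(all_back), 4L)

  vals[1, 1:4] <- NA  # one usable case sample only
  bm <- beta_matrix(vals, rep(c("a", "b"), each = 5))
  expect_warning(res <- differential_filter(bm, min_abs_delta = 0,
                                            max_p = 1.01, max_fdr = 1.01),
                 "excluded")
  expect_equal(nrow(res), 3L)
})

test_that("vectorized Welch path agrees with stats::t.test row by row", {
  set.seed(21)
  vals <- matrix(rbeta(200, 2, 5), nrow = 10)
  rownames(vals) <- paste0("s", 1:10)
  bm <- beta_matrix(vals, rep(c("a", "b"), each = 10))
  res <- differential_filter(bm, min_abs_delta = 0, max_p = 1.01, max_fdr = 1.01)
  st <- attr(res, "stats")
  for (i in 1:10) {
    tt <- t.test(vals[i, 1:10], vals[i, 11:20])
    expect_equal(st$p_value[i], tt$p.value, tolerance = 1e-12)
    expect_equal(st$delta_beta[i], unname(diff(rev(tt$estimate))), tolerance = 1e-12)
  }
})

test_that("small-cohort null rejection rate stays near nominal", {
  # 200 null Beta(2,2) sites, n = 10/10 per group: the observed fraction of
  # raw p < 0.01 stays inside the 99% binomial band around the nominal rate
  # (band computed at this run's number of trials).
  set.seed(77)
  reps <- 100L; n_sites <- 200L
  hits <- 0L
  for (r in seq_len(reps)) {
    vals <- matrix(rbeta(n_sites * 20L, 2, 2), nrow = n_sites)
    rownames(vals) <- paste0("s", seq_len(n_sites))
    bm <- beta_matrix(vals, rep(c("a", "b"), each = 10))
    st <- attr(differential_filter(bm, min_abs_delta = 0, max_p = 1.01,
                                   max_fdr = 1.01), "stats")
    hits <- hits + sum(st$p_value < 0.01)
  }
  n_trials <- reps * n_sites
  rate <- hits / n_trials
  expect_gte(rate, qbinom(0.005, n_trials, 0.01) / n_trials)
  expect_lte(rate, qbinom(0.995, n_trials, 0.01) / n_trials)
})

test_that("subsampling is a reproducible uniform subset", {
  dms <- dms_frame(rep("chr1", 2000), 0:1999, 1:2000, delta_beta = 0)
  expect_identical(subsample_dms(dms[1:500, ], n_max = 1000), dms[1:500, ])
  s1 <- subsample_dms(dms, n_max = 1000, seed = 9)
  s2 <- subsample_dms(dms, n_max = 1000, seed = 9)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 1000L)
  expect_true(all(s1$site_id %in% dms$site_id))
  expect_false(any(duplicated(s1$site_id)))
  s3 <- subsample_dms(dms, n_max = 1000, seed = 10)
  expect_false(identical(s1$site_id, s3$site_id))
})

test_that("beta_matrix validates its invariants", {
  v <- matrix(runif(20), nrow = 5)
  expect_error(beta_matrix(v * 2, rep(c("a", "b"), 2)), "\\[0, 1\\]")
  expect_error(beta_matrix(v, rep("a", 4)), "two groups")
  expect_error(beta_matrix(v, c("a", "b", "c", "a")), "two groups")
  expect_error(beta_matrix(v, c("a", "b")), "one group label per sample")
})
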