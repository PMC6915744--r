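# PFM parsing and PWM construction ----------------------------------------

test_that("JASPAR parsing normalizes rows and validates matrices", {
  f <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">M1 TFA",
               "A [ 1 2 3 4 ]",
               "C [ 4 3 2 1 ]",
               "G [ 0 0 5 0 ]",
               "T [ 5 5 0 5 ]",
               ">M2 TFB",
               "C [ 9 0 1 0 ]",
               "A [ 0 9 0 1 ]",
               "T [ 1 0 0 9 ]",
               "G [ 0 1 9 0 ]"), f)
  pfms <- load_jaspar_pfms(f)
  expect_equal(length(pfms), 2L)
  expect_equal(rownames(pfms$M1$counts), c("A", "C", "G", "T"))
  expect_equal(dim(pfms$M1$counts), c(4L, 4L))
  # labeled rows reordered correctly
  expect_equal(pfms$M2$counts["A", ], c(0, 9, 0, 1))
  expect_equal(pfm_consensus(pfms$M2), "CAGT")

  writeLines(c(">M3", "A [ 0 1 ]", "C [ 0 1 ]", "G [ 0 1 ]", "T [ 0 1 ]"), f)
  expect_error(load_jaspar_pfms(f), "M3")
})

test_that("pfm_to_pwm produces background log-odds with recorded extrema", {
  flat <- matrix(25, nrow = 4, ncol = 5, dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- pfm_to_pwm(flat)
  expect_true(all(abs(pwm$matrix) < 1e-12))
  single <- matrix(0, nrow = 4, ncol = 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  single[cbind(c(1, 3, 2, 4), 1:4)] <- 100
  pwm <- pfm_to_pwm(single)
  expect_equal(apply(pwm$matrix, 2, which.max), c(1, 3, 2, 4))
  expect_equal(pwm$max_score, sum(apply(pwm$matrix, 2, max)))
  # exhaustive check that max_score is attained and is the maximum over all L-mers
  L <- 4
  kmers <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), L)))
  scores <- vapply(kmers, function(k) {
    ch <- strsplit(k, "")[[1]]
    sum(vapply(1:L, function(j) pwm$matrix[ch[j], j], numeric(1)))
  }, numeric(1))
  expect_equal(max(scores), pwm$max_score, tolerance = 1e-12)
  expect_equal(min(scores), pwm$min_score, tolerance = 1e-12)
  expect_error(pfm_to_pwm(single, background = c(0.5, 0.5, 0, 0)), "positive")
})

# PWM scanning -------------------------------------------------------------

test_that("scan_pwm finds a planted consensus at relative score 1", {
  pwms <- fixture_pwms()
  cons <- pfm_consensus(load_jaspar_pfms(system.file(
    "extdata", "motifs_synthetic.jaspar", package = "methsig"))[[1]])
  set.seed(201)
  s <- paste0(random_dna(40, gc = 0), cons, random_dna(40, gc = 0))
  hits <- scan_pwm(s, pwms[[1]])
  expect_true(any(hits$start == 40 & abs(hits$rel_score - 1) < 1e-12))
  # threshold boundary: at min_rel_score = 1 only exact consensus remains
  hits1 <- scan_pwm(s, pwms[[1]], min_rel_score = 1)
  expect_true(all(abs(hits1$rel_score - 1) < 1e-12))
  expect_error(scan_pwm(s, pwms[[1]], min_rel_score = 1.2), "\\[0, 1\\]")
})

test_that("scan_pwm matches the naive rescoring oracle and is strand-consistent", {
  pwms <- fixture_pwms()
  set.seed(202)
  for (i in 1:60) {
    s <- random_dna(sample(60:120, 1), gc = runif(1, 0.35, 0.65))
    for (p in pwms[1:2]) {
      got <- scan_pwm(s, p, min_rel_score = 0.715)
      want <- oracle_scan_pwm(s, p, min_rel_score = 0.715)
      expect_equal(got[, c("start", "strand")], want[, c("start", "strand")],
                   ignore_attr = TRUE)
      expect_equal(got$score, want$score, tolerance = 1e-9)
    }
  }
  # mirrored hit set on the reverse complement
  s <- paste0(random_dna(30), pfm_consensus(load_jaspar_pfms(system.file(
    "extdata", "motifs_synthetic.jaspar", package = "methsig"))[[2]]),
    random_dna(30))
  h <- scan_pwm(s, pwms[[2]], min_rel_score = 0.8)
  hrc <- scan_pwm(revcomp(s), pwms[[2]], min_rel_score = 0.8)
  L <- ncol(pwms[[2]]$matrix)
  expect_equal(sort(nchar(s) - h$start - L), sort(hrc$start))
  expect_equal(nrow(h), nrow(hrc))
})

test_that("N placements are skipped and thresholding is monotone", {
  pwms <- fixture_pwms()
  s <- paste0(strrep("A", 20), "NNNN", strrep("A", 20))
  L <- ncol(pwms[[1]]$matrix)
  # placements overlapping the 4 N bases are skipped on each strand
  expect_equal(nrow(scan_pwm(s, pwms[[1]], min_rel_score = 0)),
               nrow(scan_pwm(gsub("N", "A", s), pwms[[1]], min_rel_score = 0)) -
                 2 * (L + 4 - 1))
  set.seed(203)
  s <- random_dna(120)
  h_hi <- scan_pwm(s, pwms[[1]], min_rel_score = 0.85)
  h_lo <- scan_pwm(s, pwms[[1]], min_rel_score = 0.7)
  key <- function(h) paste(h$start, h$strand)
  expect_true(all(key(h_hi) %in% key(h_lo)))
})

# Splice sites -------------------------------------------------------------

test_that("ss_score spans [0, 100] from anti-consensus to consensus", {
  don <- fixture_donor()
  cons <- paste(c("A", "C", "G", "T")[apply(don$freq, 2, which.max)], collapse = "")
  anti <- paste(c("A", "C", "G", "T")[apply(don$freq, 2, which.min)], collapse = "")
  expect_equal(ss_score(cons, don), 100)
  expect_equal(ss_score(anti, don), 0)
  expect_equal(cons, "CAGGTAAGT")
  # hand-computed mixed k-mer
  kmer <- "AAGGTAAGT"
  t_obs <- sum(vapply(1:9, function(j)
    don$freq[substr(kmer, j, j), j], numeric(1)))
  tmin <- sum(apply(don$freq, 2, min)); tmax <- sum(apply(don$freq, 2, max))
  expect_equal(ss_score(kmer, don), 100 * (t_obs - tmin) / (tmax - tmin))
  expect_error(ss_score("ACGT", don), "length")
  expect_error(ss_score("NAGGTAAGT", don), "non-ACGT")
})

test_that("splice models validate their column sums", {
  bad <- matrix(0.3, nrow = 4, ncol = 9, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_error(splice_model(bad, "donor"), "sum to 1")
  acc <- fixture_acceptor()
  expect_equal(acc$length, 15L)
  expect_equal(fixture_donor()$length, 9L)
})

test_that("find_splice_sites detects planted consensi and matches the oracle", {
  don <- fixture_donor(); acc <- fixture_acceptor()
  res <- find_splice_sites(strrep("A", 60), don, acc)
  expect_false(res$any_hit)
  expect_equal(nrow(res$hits), 0L)

  set.seed(204)
  s <- paste0(random_dna(25, gc = 0.2), "CAGGTAAGT", random_dna(25, gc = 0.2))
  res <- find_splice_sites(s, don, acc, min_score = 85)
  expect_true(res$any_hit)
  expect_true(any(res$hits$site_type == "donor" & res$hits$start == 25))

  for (i in 1:40) {
    s <- random_dna(sample(40:100, 1), gc = runif(1, 0.35, 0.65))
    got <- find_splice_sites(s, don, acc, min_score = 76.3)
    for (model in list(don, acc)) {
      want <- oracle_splice_hits(s, model, min_score = 76.3)
      sub <- got$hits[got$hits$site_type == model$site_type, ]
      expect_equal(sub[, c("start", "strand")], want[, c("start", "strand")],
                   ignore_attr = TRUE)
      expect_equal(sub$score, want$score, tolerance = 1e-9)
    }
  }
})

# Annotation tracks --------------------------------------------------------

test_that("region restriction and overlap counting follow half-open semantics", {
  tr <- annotation_track(data.frame(chrom = "chr1", start = 100, end = 200),
                         kind = "promoter")
  sites <- dms_frame("chr1", c(150, 99, 200, 199), c(151, 100, 201, 200))
  kept <- restrict_to_regions(sites, tr)
  expect_equal(kept$start, c(150, 199))  # 200 excluded: half-open end
  empty <- annotation_track(data.frame(chrom = character(0), start = integer(0),
                                       end = integer(0)), kind = "promoter")
  expect_equal(nrow(restrict_to_regions(sites, empty)), 0L)
  expect_error(restrict_to_regions(sites, annotation_track(
    data.frame(chrom = "chr1", start = 1, end = 2), kind = "alt_splicing")),
    "promoter or cpg_island")
})

test_that("count_track_overlaps matches the quadratic oracle", {
  w <- data.frame(chrom = "chr1", window_start = 1000, window_end = 1100)
  tr <- annotation_track(data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(950, 1090, 1100, 1000), end = c(1001, 1200, 1200, 1100)),
    kind = "conserved_tfbs")
  expect_equal(count_track_overlaps(w, tr), 2)  # [1100,1200) does not intersect
  set.seed(205)
  win <- data.frame(chrom = sample(c("c1", "c2"), 300, TRUE),
                    window_start = sample(0:5000, 300, TRUE))
  win$window_end <- win$window_start + 100
  ivs <- data.frame(chrom = sample(c("c1", "c2"), 800, TRUE),
                    start = sample(0:5000, 800, TRUE))
  ivs$end <- ivs$start + sample(5:400, 800, TRUE)
  tr <- annotation_track(ivs, kind = "alt_splicing")
  got <- count_track_overlaps(win, tr)
  expect_equal(as.numeric(got), oracle_overlap_counts(win, tr))
  # symmetric in input order
  perm <- sample(nrow(win))
  expect_equal(count_track_overlaps(win[perm, ], tr), got[perm])
})

test_that("BED track loading sorts per chromosome and keeps labels", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr2\t10\t20\tevA", "chr1\t50\t60\tevB", "chr1\t5\t15"), f)
  tr <- read_bed_track(f, kind = "alt_splicing")
  expect_equal(tr$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(tr$start, c(5, 50, 10))
  expect_equal(tr$label, c(".", "evB", "evA"))
  expect_equal(attr(tr, "kind"), "alt_splicing")
})
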