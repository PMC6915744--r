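fake_features <- function(g4, pals = 0, tfbs = 0, ctfbs = 0,
                          donor = FALSE, acceptor = FALSE, altspl = 0,
                          shape_p = 1) {
  n <- length(g4)
  rec <- function(x) rep_len(x, n)
  shp <- matrix(rec(shape_p), nrow = n, ncol = 4)
  colnames(shp) <- paste0("shape_", c("MGW", "Roll", "ProT", "HelT"), "_p")
  cbind(data.frame(site_id = paste0("s", seq_len(n)), G4 = g4,
                   Pals = rec(pals), TFBS = rec(tfbs), cTFBS = rec(ctfbs),
                   donor_hit = rec(donor), acceptor_hit = rec(acceptor),
                   altspl = rec(altspl), stringsAsFactors = FALSE),
        as.data.frame(shp))
}

test_that("map_attributes applies min-max to counts and join rules to logicals", {
  ft <- fake_features(g4 = c(0, 2, 4))
  expect_warning(map_attributes(ft, attrs = c("G4", "Pals")), "Pals is constant")
  sg <- suppressWarnings(map_attributes(ft))
  expect_equal(unname(sg$values[, "G4"]), c(0, 0.5, 1))
  expect_true(all(sg$values >= 0 & sg$values <= 1))
  expect_equal(sg$mapping$G4$min, 0)
  expect_equal(sg$mapping$G4$max, 4)

  # degenerate single site: counts map to 0, logicals unaffected
  ft1 <- fake_features(g4 = 3, donor = TRUE)
  sg1 <- suppressWarnings(map_attributes(ft1))
  expect_equal(unname(sg1$values[1, "G4"]), 0)
  expect_equal(unname(sg1$values[1, "splicing"]), 1)

  # join rule: donor only -> 1; none -> 0; shape: any p < 0.05
  ft2 <- fake_features(g4 = c(1, 2), donor = c(TRUE, FALSE),
                       shape_p = c(0.01, 0.9))
  sg2 <- suppressWarnings(map_attributes(ft2))
  expect_equal(unname(sg2$values[, "splicing"]), c(1, 0))
  expect_equal(unname(sg2$values[, "shape"]), c(1, 0))
})

test_that("genomic_index is the weighted sum with validation", {
  row <- c(G4 = 1, Pals = 1, TFBS = 0.5, cTFBS = 0, splicing = 1, shape = 0)
  expect_equal(genomic_index(row), 3.5)
  expect_equal(genomic_index(setNames(rep(0, 6), names(row))), 0)
  w2 <- weight_scheme(2)
  expect_equal(genomic_index(row, w2), 7)
  expect_error(genomic_index(row, setNames(c(-1, rep(1, 5)), names(row))),
               "negative")
  expect_error(weight_scheme(0), "positive weight")
})

test_that("rank_sites orders by index with documented tie-breaking", {
  ft <- fake_features(g4 = c(0, 4, 2, 2))
  sg <- suppressWarnings(map_attributes(ft, attrs = "G4"))
  dms <- dms_frame("chr1", c(10, 20, 30, 40), c(11, 21, 31, 41),
                   delta_beta = c(0.1, 0.9, 0.3, 0.5),
                   site_id = paste0("s", 1:4))
  rk <- rank_sites(sg, weight_scheme(1, "G4"), dms = dms)
  expect_equal(rk$site_id, c("s2", "s4", "s3", "s1"))  # tie s3/s4 -> |db| 0.5 first
  expect_equal(rk$rank, 1:4)
  # order independence
  sg_perm <- suppressWarnings(map_attributes(ft[c(3, 1, 4, 2), ], attrs = "G4"))
  rk2 <- rank_sites(sg_perm, weight_scheme(1, "G4"), dms = dms)
  expect_equal(rk2$site_id, rk$site_id)
  expect_equal(rk2$genomic_index, rk$genomic_index)
})

test_that("signature algebra properties hold on randomized feature tables", {
  set.seed(301)
  for (i in 1:40) {
    n <- sample(3:30, 1)
    ft <- fake_features(g4 = rpois(n, 2), pals = rpois(n, 5),
                        tfbs = rpois(n, 3), ctfbs = rpois(n, 1),
                        donor = runif(n) < 0.3, acceptor = runif(n) < 0.2,
                        altspl = rpois(n, 0.2), shape_p = runif(n))
    sg <- suppressWarnings(map_attributes(ft))
    w <- weight_scheme(setNames(runif(6, 0, 2), colnames(sg$values)))
    idx <- genomic_index(sg, w)
    # range: 0 <= idx <= sum of weights
    expect_true(all(idx >= -1e-12 & idx <= sum(w) + 1e-12))
    # linearity: doubling weights doubles indices
    expect_equal(genomic_index(sg, weight_scheme(2 * unclass(w))), 2 * idx)
    # weight zero equals attribute removal
    w0 <- unclass(w); w0["Pals"] <- 0
    sub <- suppressWarnings(map_attributes(ft, attrs = setdiff(colnames(sg$values), "Pals")))
    expect_equal(genomic_index(sg, weight_scheme(w0)),
                 genomic_index(sub, weight_scheme(w0[names(w0) != "Pals"])))
    # purity: identical recomputation
    expect_identical(genomic_index(suppressWarnings(map_attributes(ft)), w)[1],
                     genomic_index(sg, w)[1])
  }
})

test_that("raising one site's raw count never drops it below unchanged sites", {
  set.seed(302)
  for (i in 1:20) {
    n <- 12
    ft <- fake_features(g4 = rpois(n, 2), pals = rpois(n, 4))
    sg <- suppressWarnings(map_attributes(ft, attrs = c("G4", "Pals")))
    w <- weight_scheme(1, c("G4", "Pals"))
    rk <- rank_sites(sg, w)
    target <- "s3"
    below_max <- ft$site_id[ft$G4 < max(ft$G4) & ft$site_id != target]
    ft2 <- ft
    ft2$G4[ft2$site_id == target] <- ft2$G4[ft2$site_id == target] + 2L
    rk2 <- rank_sites(suppressWarnings(map_attributes(ft2, attrs = c("G4", "Pals"))), w)
    pos <- function(r, id) which(r$site_id == id)
    for (other in below_max) {
      before <- pos(rk, target) < pos(rk, other)
      after <- pos(rk2, target) < pos(rk2, other)
      expect_false(before & !after)  # never newly overtaken by an unchanged site
    }
  }
})

test_that("signature export round-trips indices and metadata", {
  ft <- fake_features(g4 = c(0, 3, 1), pals = c(2, 0, 5), donor = c(TRUE, FALSE, FALSE))
  sg <- suppressWarnings(map_attributes(ft))
  dms <- dms_frame("chr1", c(5, 15, 25), c(6, 16, 26),
                   delta_beta = c(-0.4, 0.35, 0.5), site_id = paste0("s", 1:3))
  w <- weight_scheme(c(G4 = 1, Pals = 0.5, TFBS = 1, cTFBS = 1,
                       splicing = 2, shape = 1))
  rk <- rank_sites(sg, w, dms = dms)
  f <- withr::local_tempfile(fileext = ".tsv")
  export_signatures(rk, sg, f, features = ft, weights = w)
  back <- read_signatures(f)
  expect_equal(nrow(back$table), 3L)
  expect_equal(back$table$genomic_index,
               rk$genomic_index, tolerance = 1e-9)
  expect_true(any(grepl("weights:", back$header)))
  expect_true(any(grepl("splicing=2", back$header)))
  expect_true(any(grepl("mapping G4: minmax", back$header)))
  # mapped values present so indices are reproducible from the file
  mapped <- as.matrix(back$table[, paste0("mapped_", colnames(sg$values))])
  expect_equal(as.numeric(mapped %*% unclass(w)[colnames(sg$values)]),
               back$table$genomic_index, tolerance = 1e-9)
})
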