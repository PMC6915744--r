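# Loading, validation, conversion and differential filtering of methylation
# data into a canonical table of differentially methylated sites (DMS).
#
# Coordinate convention: BED-style 0-based half-open everywhere. A DMS is the
# single base of the CpG cytosine, so end = start + 1.

#' Construct and validate a DMS table
#'
#' A DMS table is a plain `data.frame` with one row per differentially
#' methylated site and columns `chrom`, `start`, `end` (0-based half-open,
#' `end = start + 1` for a CpG cytosine), `delta_beta` (signed, in
#' \eqn{[-1, 1]}), and optionally `p_value`, `fdr`, `site_id`, `status`.
#'
#' @param chrom Character vector of chromosome names (nonempty strings).
#' @param start,end Integer vectors; 0-based half-open with `start < end`.
#' @param delta_beta Numeric in \eqn{[-1, 1]} (NA allowed).
#' @param p_value,fdr Optional numerics in \eqn{[0, 1]}.
#' @param site_id Optional character identifiers; defaults to
#'   `chrom:start` labels.
#' @return A validated `data.frame` of class `dms_frame`.
#' @export
dms_frame <- function(chrom, start, end, delta_beta = NA_real_,
                      p_value = NA_real_, fdr = NA_real_, site_id = NULL) {
  n <- length(start)
  if (is.null(site_id)) site_id <- if (n) paste0(chrom, ":", start) else character(0)
  df <- data.frame(
    site_id = as.character(site_id),
    chrom = rep_len(as.character(chrom), n),
    start = as.integer(start),
    end = as.integer(end),
    delta_beta = rep_len(as.numeric(delta_beta), n),
    p_value = rep_len(as.numeric(p_value), n),
    fdr = rep_len(as.numeric(fdr), n),
    stringsAsFactors = FALSE
  )
  validate_dms(df)
  class(df) <- c("dms_frame", "data.frame")
  df
}

validate_dms <- function(df) {
  if (any(is.na(df$chrom) | !nzchar(df$chrom)))
    .stopf("DMS table: chromosome names must be nonempty")
  if (any(df$start >= df$end))
    .stopf("DMS table: start must be < end (0-based half-open)")
  bad <- !is.na(df$delta_beta) & abs(df$delta_beta) > 1
  if (any(bad))
    .stopf("DMS table: |delta_beta| must be <= 1 (offending site %s)",
           df$site_id[which(bad)[1]])
  invisible(df)
}

#' Load DMS intervals from a BED3/BED4 file
#'
#' Reads a tab-separated BED file (0-based half-open). An optional fourth
#' column is parsed as the per-site score. Whether that score is a
#' \eqn{\Delta\beta} in \eqn{[-1,1]} or an M-value difference is declared
#' explicitly via `score_type`; M-differences are carried through unchanged
#' in `delta_beta` only after conversion of the *group means* is impossible,
#' so they are stored in an `m_diff` column instead and `delta_beta` is NA.
#' No unit autodetection is performed.
#'
#' Malformed lines (wrong column count, non-numeric coordinates or score,
#' `start >= end`) are skipped; their line numbers are collected into a
#' single summary warning.
#'
#' @param path Path to the BED file.
#' @param score_type `"delta_beta"` (default) or `"m_difference"`.
#' @return A `dms_frame` (possibly zero rows), rows in file order. The
#'   integer vector of skipped line numbers is attached as
#'   `attr(x, "skipped_lines")`.
#' @export
load_dms_bed <- function(path, score_type = c("delta_beta", "m_difference")) {
  score_type <- match.arg(score_type)
  if (!file.exists(path)) .stopf("BED file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  keep_chrom <- character(0); keep_start <- integer(0); keep_end <- integer(0)
  keep_score <- numeric(0); keep_id <- character(0)
  skipped <- integer(0)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) { skipped <- c(skipped, i); next }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end) || start >= end || !nzchar(f[1])) {
      skipped <- c(skipped, i); next
    }
    score <- NA_real_
    if (length(f) >= 4L) {
      score <- suppressWarnings(as.numeric(f[4]))
      if (is.na(score) && nzchar(f[4])) { skipped <- c(skipped, i); next }
      if (score_type == "delta_beta" && !is.na(score) && abs(score) > 1) {
        skipped <- c(skipped, i); next
      }
    }
    keep_chrom <- c(keep_chrom, f[1]); keep_start <- c(keep_start, start)
    keep_end <- c(keep_end, end); keep_score <- c(keep_score, score)
    keep_id <- c(keep_id, paste0(f[1], ":", start))
  }
  if (length(skipped))
    .warnf("load_dms_bed: skipped %d malformed line(s): %s", length(skipped),
           paste(utils::head(skipped, 10), collapse = ", "))
  if (!length(keep_chrom)) {
    .warnf("load_dms_bed: no valid records in %s", path)
    out <- dms_frame(character(0), integer(0), integer(0))
  } else if (score_type == "delta_beta") {
    out <- dms_frame(keep_chrom, keep_start, keep_end, delta_beta = keep_score,
                     site_id = keep_id)
  } else {
    out <- dms_frame(keep_chrom, keep_start, keep_end, site_id = keep_id)
    out$m_diff <- keep_score
  }
  attr(out, "skipped_lines") <- skipped
  out
}

#' Beta value from array probe intensities
#'
#' \eqn{\beta = M / (M + U + \alpha)} where `M` and `U` are the methylated
#' and unmethylated probe intensities and `alpha` (default 100) regularizes
#' low-intensity probes.
#'
#' @param meth_intensity,unmeth_intensity Non-negative numerics (vectorized).
#' @param alpha Regularization offset, default 100.
#' @return Beta values in \eqn{[0, 1)}.
#' @export
beta_from_intensities <- function(meth_intensity, unmeth_intensity, alpha = 100) {
  if (any(meth_intensity < 0, na.rm = TRUE) ||
      any(unmeth_intensity < 0, na.rm = TRUE))
    .stopf("beta_from_intensities: intensities must be non-negative")
  meth_intensity / (meth_intensity + unmeth_intensity + alpha)
}

#' Convert between M values and beta values
#'
#' `m_to_beta` maps the logit-scale M value to a methylation fraction,
#' \eqn{\beta = 2^M / (2^M + 1)}; `beta_to_m` is its inverse,
#' \eqn{M = \log_2(\beta / (1 - \beta))}, undefined at \eqn{\beta \in \{0, 1\}}.
#'
#' @param M Finite numeric vector of M values.
#' @param beta Numeric vector of beta values strictly inside \eqn{(0, 1)}.
#' @return Numeric vector of the converted values.
#' @export
m_to_beta <- function(M) {
  if (any(!is.finite(M))) .stopf("m_to_beta: M must be finite")
  1 / (1 + 2^(-M))
}

#' @rdname m_to_beta
#' @export
beta_to_m <- function(beta) {
  if (any(beta <= 0 | beta >= 1, na.rm = TRUE))
    .stopf("beta_to_m: undefined at beta <= 0 or beta >= 1")
  log2(beta / (1 - beta))
}

#' Beta values from bisulfite read counts with depth masking
#'
#' \eqn{\beta} = methylated reads / total reads; sites with
#' `total_reads < min_depth` (including zero-depth sites) are masked as NA
#' rather than producing a division error.
#'
#' @param meth_reads,total_reads Non-negative integer vectors or matrices
#'   with `meth_reads <= total_reads`.
#' @param min_depth Positive integer minimum read depth.
#' @return Numeric beta values with low-depth entries set to NA.
#' @export
beta_from_counts <- function(meth_reads, total_reads, min_depth = 10L) {
  if (!.is_count1(min_depth)) .stopf("beta_from_counts: min_depth must be a positive integer")
  if (any(meth_reads < 0, na.rm = TRUE) || any(total_reads < 0, na.rm = TRUE))
    .stopf("beta_from_counts: read counts must be non-negative")
  if (any(meth_reads > total_reads, na.rm = TRUE))
    .stopf("beta_from_counts: meth_reads must be <= total_reads")
  beta <- ifelse(total_reads >= min_depth & total_reads > 0,
                 meth_reads / total_reads, NA_real_)
  if (is.matrix(meth_reads)) dim(beta) <- dim(meth_reads)
  beta
}

#' Construct a beta matrix with a two-group sample annotation
#'
#' @param values Numeric matrix, sites in rows (rownames = site ids),
#'   samples in columns; non-missing values must lie in \eqn{[0, 1]}.
#' @param groups Factor or character of length `ncol(values)` with exactly
#'   two distinct labels. The *first level* is the case group: per-site
#'   \eqn{\Delta\beta} is mean(case) - mean(control).
#' @param sites Optional `data.frame` with columns `site_id`, `chrom`,
#'   `start`, `end` giving coordinates for each row of `values`.
#' @return A list of class `beta_matrix` with elements `values`, `groups`,
#'   `sites`.
#' @export
beta_matrix <- function(values, groups, sites = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("site_", seq_len(nrow(values)))
  if (any(values < 0 | values > 1, na.rm = TRUE))
    .stopf("beta_matrix: beta values must lie in [0, 1]")
  if (length(groups) != ncol(values))
    .stopf("beta_matrix: one group label per sample required")
  if (anyNA(groups)) .stopf("beta_matrix: every sample needs a group label")
  groups <- if (is.factor(groups)) droplevels(groups) else factor(groups, levels = unique(groups))
  if (nlevels(groups) != 2L)
    .stopf("beta_matrix: exactly two groups required, got %d", nlevels(groups))
  if (!is.null(sites)) {
    if (nrow(sites) != nrow(values))
      .stopf("beta_matrix: sites table must have one row per site")
    if (!all(c("site_id", "chrom", "start", "end") %in% names(sites)))
      .stopf("beta_matrix: sites needs columns site_id, chrom, start, end")
    rownames(values) <- sites$site_id
  }
  structure(list(values = values, groups = groups, sites = sites),
            class = "beta_matrix")
}

#' Read a beta matrix and its group annotation from TSV files
#'
#' The matrix file is tab-separated with a header row of sample ids and the
#' site id in the first column. The annotation file has two tab-separated
#' columns, sample id and group label (no header); the group of the first
#' annotation line is taken as the case group.
#'
#' @param matrix_path,groups_path File paths.
#' @param sites Optional site coordinate table (see [beta_matrix()]).
#' @return A `beta_matrix`.
#' @export
read_beta_matrix <- function(matrix_path, groups_path, sites = NULL) {
  if (!file.exists(matrix_path)) .stopf("beta matrix file not found: %s", matrix_path)
  if (!file.exists(groups_path)) .stopf("group annotation file not found: %s", groups_path)
  tab <- utils::read.delim(matrix_path, header = TRUE, row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE)
  ann <- utils::read.delim(groups_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(ann) < 2L) .stopf("group annotation needs two columns: sample, group")
  m <- as.matrix(tab)
  idx <- match(colnames(m), ann[[1]])
  if (anyNA(idx))
    .stopf("samples missing from annotation: %s",
           paste(colnames(m)[is.na(idx)], collapse = ", "))
  groups <- factor(ann[[2]][idx], levels = unique(ann[[2]]))
  if (!is.null(sites)) {
    si <- match(rownames(m), sites$site_id)
    if (anyNA(si))
      .stopf("sites table missing coordinates for: %s",
             paste(utils::head(rownames(m)[is.na(si)], 5), collapse = ", "))
    sites <- sites[si, , drop = FALSE]
  }
  beta_matrix(m, groups, sites = sites)
}

# Vectorized per-row Welch t-test: returns delta (meanA - meanB), p, and the
# usable sample sizes. Rows with fewer than 2 usable values in either group
# get NA statistics.
.row_welch <- function(values, ia, ib) {
  a <- values[, ia, drop = FALSE]
  b <- values[, ib, drop = FALSE]
  na <- rowSums(!is.na(a)); nb <- rowSums(!is.na(b))
  ma <- rowMeans(a, na.rm = TRUE); mb <- rowMeans(b, na.rm = TRUE)
  va <- rowSums((a - ma)^2, na.rm = TRUE) / pmax(na - 1, 1)
  vb <- rowSums((b - mb)^2, na.rm = TRUE) / pmax(nb - 1, 1)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  # Degenerate rows: both groups constant -> se2 = 0; define p = 1 when the
  # means are equal (no evidence), otherwise p = 0 in the limit.
  zero <- !is.na(se2) & se2 == 0
  p[zero] <- ifelse(ma[zero] == mb[zero], 1, 0)
  bad <- na < 2 | nb < 2
  p[bad] <- NA_real_
  list(delta = ma - mb, p = p, n_a = na, n_b = nb, usable = !bad)
}

.row_wilcox <- function(values, ia, ib) {
  n <- nrow(values)
  p <- rep(NA_real_, n)
  na <- rowSums(!is.na(values[, ia, drop = FALSE]))
  nb <- rowSums(!is.na(values[, ib, drop = FALSE]))
  usable <- na >= 2 & nb >= 2
  for (i in which(usable)) {
    p[i] <- suppressWarnings(stats::wilcox.test(
      values[i, ia], values[i, ib], exact = FALSE, correct = TRUE)$p.value)
  }
  ma <- rowMeans(values[, ia, drop = FALSE], na.rm = TRUE)
  mb <- rowMeans(values[, ib, drop = FALSE], na.rm = TRUE)
  list(delta = ma - mb, p = p, n_a = na, n_b = nb, usable = usable)
}

#' Differential filtering of a beta matrix into DMS
#'
#' Computes per-site \eqn{\Delta\beta} = mean(case) - mean(control), a
#' two-sided two-sample test p-value (Welch's t-test by default, Mann-Whitney
#' via `test = "wilcoxon"`), and Benjamini-Hochberg FDR across all testable
#' sites; then retains sites with
#' \eqn{|\Delta\beta| \ge} `min_abs_delta` AND `p < max_p` AND `fdr < max_fdr`.
#' Retained sites are labeled `"hyper"` (\eqn{\Delta\beta > 0}) or `"hypo"`.
#'
#' Missing values are removed pairwise per site; sites with fewer than two
#' usable samples in either group are excluded from testing with a warning.
#'
#' @param matrix A [beta_matrix()].
#' @param min_abs_delta Minimum \eqn{|\Delta\beta|}, default 0.3.
#' @param max_p Maximum raw p-value, default 0.01 (strict).
#' @param max_fdr Maximum BH FDR, default 0.01 (strict).
#' @param test `"t"` (Welch, default) or `"wilcoxon"`.
#' @return A `dms_frame` of retained sites (with `status` column); the full
#'   per-site statistics table is attached as `attr(x, "stats")`.
#' @export
differential_filter <- function(matrix, min_abs_delta = 0.3, max_p = 0.01,
                                max_fdr = 0.01, test = c("t", "wilcoxon")) {
  stopifnot(inherits(matrix, "beta_matrix"))
  test <- match.arg(test)
  g <- matrix$groups
  ia <- which(g == levels(g)[1]); ib <- which(g == levels(g)[2])
  res <- if (test == "t") .row_welch(matrix$values, ia, ib)
         else .row_wilcox(matrix$values, ia, ib)
  if (any(!res$usable))
    .warnf("differential_filter: %d site(s) with < 2 usable samples in a group excluded from testing",
           sum(!res$usable))
  fdr <- rep(NA_real_, length(res$p))
  fdr[res$usable] <- stats::p.adjust(res$p[res$usable], method = "BH")
  stats_tab <- data.frame(
    site_id = rownames(matrix$values),
    delta_beta = res$delta, p_value = res$p, fdr = fdr,
    tested = res$usable, stringsAsFactors = FALSE
  )
  pass <- res$usable & abs(res$delta) >= min_abs_delta &
    res$p < max_p & fdr < max_fdr
  pass[is.na(pass)] <- FALSE
  if (!is.null(matrix$sites)) {
    s <- matrix$sites[pass, , drop = FALSE]
    out <- dms_frame(s$chrom, s$start, s$end,
                     delta_beta = res$delta[pass], p_value = res$p[pass],
                     fdr = fdr[pass], site_id = s$site_id)
  } else {
    out <- data.frame(site_id = rownames(matrix$values)[pass],
                      delta_beta = res$delta[pass], p_value = res$p[pass],
                      fdr = fdr[pass], stringsAsFactors = FALSE)
  }
  out$status <- ifelse(out$delta_beta > 0, "hyper", "hypo")
  attr(out, "stats") <- stats_tab
  out
}

#' Uniform subsampling of DMS records
#'
#' If more than `n_max` records are supplied, draws a uniform sample without
#' replacement, reproducible under `seed`; otherwise returns all records.
#' Output preserves the input row order.
#'
#' @param records A DMS table (`data.frame`).
#' @param n_max Maximum number of sites to keep, default 1000.
#' @param seed Integer seed (required when subsampling occurs).
#' @return Subset of `records`.
#' @export
subsample_dms <- function(records, n_max = 1000L, seed = NULL) {
  if (!.is_count1(n_max)) .stopf("subsample_dms: n_max must be a positive integer")
  if (nrow(records) <= n_max) return(records)
  if (is.null(seed)) .stopf("subsample_dms: seed required when subsampling")
  idx <- withr_seed(seed, sample.int(nrow(records), n_max))
  records[sort(idx), , drop = FALSE]
}

# Evaluate `expr` under a local RNG seed without disturbing the caller's
# random state.
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
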