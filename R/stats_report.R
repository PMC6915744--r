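# Group-level statistics: feature enrichment between DMS classes,
# beta-stratified comparisons, and genomic-index-vs-expression association.

#' Stratify sites by group-mean beta value
#'
#' Splits sites into an unmethylated set (group-mean \eqn{\beta \le}
#' `low_max`) and a methylated set (group-mean \eqn{\beta \ge} `high_min`);
#' intermediate sites are excluded.
#'
#' @param matrix A [beta_matrix()].
#' @param group Group label whose samples define the mean (default: all
#'   samples).
#' @param low_max Upper bound of the unmethylated stratum, default 0.1.
#' @param high_min Lower bound of the methylated stratum, default 0.9.
#' @return List with character vectors `low` and `high` of site ids and the
#'   numeric `means` used.
#' @export
stratify_by_beta <- function(matrix, group = NULL, low_max = 0.1, high_min = 0.9) {
  stopifnot(inherits(matrix, "beta_matrix"))
  if (low_max >= high_min)
    .stopf("stratify_by_beta: low_max must be < high_min")
  cols <- if (is.null(group)) seq_len(ncol(matrix$values))
          else which(matrix$groups == group)
  if (!length(cols)) .stopf("stratify_by_beta: no samples in group '%s'", group)
  means <- rowMeans(matrix$values[, cols, drop = FALSE], na.rm = TRUE)
  low <- rownames(matrix$values)[!is.na(means) & means <= low_max]
  high <- rownames(matrix$values)[!is.na(means) & means >= high_min]
  if (!length(low) && !length(high))
    .warnf("stratify_by_beta: all sites intermediate; both strata empty")
  list(low = low, high = high, means = means)
}

#' Compare a feature between two site groups
#'
#' Two-sided two-sample comparison of per-site feature values: Welch t-test
#' (default) or Mann-Whitney. When both groups have zero variance the
#' t-test is degenerate and p is defined as 1 with a warning.
#'
#' @param features_a,features_b Numeric vectors of per-site values, or
#'   feature tables (then `feature_name` selects the column).
#' @param feature_name Column to compare when tables are given.
#' @param test `"t"` (default) or `"wilcoxon"`.
#' @return A one-row `data.frame`: `feature`, `mean_a`, `sd_a`, `n_a`,
#'   `mean_b`, `sd_b`, `n_b`, `test`, `p_value`.
#' @export
compare_feature_groups <- function(features_a, features_b, feature_name = NULL,
                                   test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  pick <- function(x) {
    if (is.data.frame(x)) {
      if (is.null(feature_name)) .stopf("compare_feature_groups: feature_name required for tables")
      as.numeric(x[[feature_name]])
    } else as.numeric(x)
  }
  a <- pick(features_a); b <- pick(features_b)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    .stopf("compare_feature_groups: each group needs >= 2 values")
  if (test == "t") {
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      .warnf("compare_feature_groups: zero variance in both groups; p defined as 1")
      p <- 1
    } else {
      p <- stats::t.test(a, b)$p.value
    }
  } else {
    p <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    if (is.na(p)) p <- 1
  }
  data.frame(feature = if (is.null(feature_name)) NA_character_ else feature_name,
             mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
             mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b),
             test = test, p_value = p, stringsAsFactors = FALSE)
}

#' Association between genomic index and differential expression
#'
#' Splits site-gene links into high and low \eqn{|log_2FC|} groups (median
#' split by default, or a fixed threshold), compares the genomic index
#' between the groups with a two-sided t-test, and fits an ordinary
#' least-squares regression of \eqn{|log_2FC|} on the genomic index.
#'
#' @param links `data.frame` with columns `site_id`, `gene`, `log2fc`,
#'   `genomic_index` (>= 4 rows).
#' @param split `"median"` (default) or `"threshold"`.
#' @param threshold \eqn{|log_2FC|} cut when `split = "threshold"`.
#' @return List with `comparison` (a [compare_feature_groups()] row on the
#'   index, high vs low group), `fit` (`slope`, `intercept`; NA with a
#'   warning when the index is constant), and `groups` (the per-link
#'   high/low assignment).
#' @export
index_vs_expression <- function(links, split = c("median", "threshold"),
                                threshold = NULL) {
  split <- match.arg(split)
  need <- c("site_id", "log2fc", "genomic_index")
  if (!all(need %in% names(links)))
    .stopf("index_vs_expression: links need columns %s", paste(need, collapse = ", "))
  if (nrow(links) < 4L) .stopf("index_vs_expression: >= 4 links required")
  afc <- abs(links$log2fc)
  cut <- if (split == "median") stats::median(afc)
         else { if (is.null(threshold)) .stopf("index_vs_expression: threshold required"); threshold }
  grp <- ifelse(afc > cut, "high", "low")
  if (length(unique(grp)) < 2L) {
    # median split with heavy ties: fall back to >= to keep both groups
    grp <- ifelse(afc >= cut, "high", "low")
  }
  idx <- links$genomic_index
  if (stats::sd(idx) == 0) {
    .warnf("index_vs_expression: constant genomic index; slope undefined")
    fit <- list(slope = NA_real_, intercept = NA_real_)
    cmp <- compare_feature_groups(idx[grp == "high"], idx[grp == "low"],
                                  feature_name = "genomic_index")
  } else {
    lmfit <- stats::lm(afc ~ idx)
    fit <- list(slope = unname(stats::coef(lmfit)[2]),
                intercept = unname(stats::coef(lmfit)[1]))
    cmp <- compare_feature_groups(idx[grp == "high"], idx[grp == "low"],
                                  feature_name = "genomic_index")
  }
  list(comparison = cmp, fit = fit, groups = grp)
}

#' Per-feature comparison table for hyper- vs hypomethylated sites
#'
#' For each feature column, the class means, standard deviations and the
#' two-sided test p-value between the hypermethylated (DMS+) and
#' hypomethylated (DMS-) feature tables, plus the mean G+C content and CpG
#' observed/expected ratio per class when those columns are present.
#'
#' @param dms_plus_features,dms_minus_features Feature tables (from
#'   [build_feature_table()]) for the two classes; both nonempty.
#' @param features Feature columns to compare, default
#'   `c("G4", "Pals", "TFBS", "cTFBS", "altspl")`.
#' @param test `"t"` or `"wilcoxon"`.
#' @return List with `table` (one row per feature: `feature`, `mean_plus`,
#'   `sd_plus`, `mean_minus`, `sd_minus`, `test`, `p_value`) and
#'   `composition` (per-class mean `gc` and `cpg_oe`, or NULL).
#' @export
summarize_table1 <- function(dms_plus_features, dms_minus_features,
                             features = c("G4", "Pals", "TFBS", "cTFBS", "altspl"),
                             test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  if (!nrow(dms_plus_features) || !nrow(dms_minus_features))
    .stopf("summarize_table1: both classes must be nonempty")
  features <- intersect(features, intersect(names(dms_plus_features),
                                            names(dms_minus_features)))
  rows <- lapply(features, function(f) {
    cmp <- compare_feature_groups(dms_plus_features, dms_minus_features,
                                  feature_name = f, test = test)
    data.frame(feature = f, mean_plus = cmp$mean_a, sd_plus = cmp$sd_a,
               mean_minus = cmp$mean_b, sd_minus = cmp$sd_b,
               test = test, p_value = cmp$p_value, stringsAsFactors = FALSE)
  })
  comp <- NULL
  if (all(c("gc", "cpg_oe") %in% names(dms_plus_features)) &&
      all(c("gc", "cpg_oe") %in% names(dms_minus_features))) {
    comp <- data.frame(
      class = c("plus", "minus"),
      gc = c(mean(dms_plus_features$gc, na.rm = TRUE),
             mean(dms_minus_features$gc, na.rm = TRUE)),
      cpg_oe = c(mean(dms_plus_features$cpg_oe, na.rm = TRUE),
                 mean(dms_minus_features$cpg_oe, na.rm = TRUE)),
      stringsAsFactors = FALSE)
  }
  list(table = do.call(rbind, rows), composition = comp)
}
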