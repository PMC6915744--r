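# Genomic signatures: assemble per-site raw feature vectors, map them to
# the unit interval, and rank sites by the weighted-sum genomic index.
#
# Attribute roster (defaults): four counts (G4, Pals, TFBS, cTFBS), the
# joined splicing logical (any donor hit, acceptor hit or
# alternative-splicing overlap) and the joined shape logical (any DNA shape
# change with p < 0.05). Counts are min-max normalized across the analyzed
# dataset; logicals are already {0, 1} and bypass normalization.

COUNT_ATTRS <- c("G4", "Pals", "TFBS", "cTFBS")
DEFAULT_ATTRS <- c(COUNT_ATTRS, "splicing", "shape")

#' Compute the raw feature table for a set of windows
#'
#' Runs every detector over each window and collects the raw per-site
#' readouts: G-quadruplex count, palindrome count, PWM hit count over the
#' motif set, conserved-TFBS track overlap count, donor/acceptor splice-site
#' logicals, alternative-splicing overlap count, per-shape p-values, and the
#' compositional statistics (G+C content, CpG observed/expected ratio).
#'
#' @param windows Windows table from [fetch_windows()].
#' @param pwms List of `pwm` objects (may be empty; then `TFBS` is 0).
#' @param ctfbs_track,altspl_track Optional `annotation_track`s (NULL gives
#'   zero counts).
#' @param shape_table Optional `shape_table` (NULL gives NA shape p-values).
#' @param donor,acceptor `splice_model`s, defaults bundled.
#' @param g4_params,pal_params Named lists overriding detector defaults.
#' @param min_rel_score PWM relative-score threshold, default 0.8.
#' @param min_ss_score Splice-site score threshold, default 80.
#' @param shape_default Default for pentamers absent from the shape table.
#' @return `data.frame` with one row per site: `site_id`, `G4`, `Pals`,
#'   `TFBS`, `cTFBS`, `donor_hit`, `acceptor_hit`, `altspl`, shape p-value
#'   columns `shape_MGW_p` .. `shape_HelT_p`, `shape_flag`, `gc`, `cpg_oe`.
#' @export
build_feature_table <- function(windows, pwms = list(),
                                ctfbs_track = NULL, altspl_track = NULL,
                                shape_table = NULL,
                                donor = default_donor_model(),
                                acceptor = default_acceptor_model(),
                                g4_params = list(), pal_params = list(),
                                min_rel_score = 0.8, min_ss_score = 80,
                                shape_default = NULL) {
  n <- nrow(windows)
  g4 <- integer(n); pals <- integer(n); tfbs <- integer(n)
  dhit <- logical(n); ahit <- logical(n)
  shp <- matrix(NA_real_, nrow = n, ncol = 4,
                dimnames = list(NULL, paste0("shape_", SHAPE_NAMES, "_p")))
  for (i in seq_len(n)) {
    s <- windows$seq[i]
    g4[i] <- do.call(g4_count, c(list(s), g4_params))
    pals[i] <- do.call(palindrome_count, c(list(s), pal_params))
    if (length(pwms))
      tfbs[i] <- tfbs_count(s, pwms, min_rel_score = min_rel_score)
    ss <- find_splice_sites(s, donor, acceptor, min_score = min_ss_score)
    dhit[i] <- any(ss$hits$site_type == "donor")
    ahit[i] <- any(ss$hits$site_type == "acceptor")
    if (!is.null(shape_table)) {
      w <- structure(list(chrom = windows$chrom[i],
                          window_start = windows$window_start[i],
                          window_end = windows$window_end[i],
                          center = windows$center[i], clipped = windows$clipped[i],
                          seq = s), class = "seq_window")
      c1 <- w$center + 1L
      has_cpg <- nchar(s) >= c1 + 1L && substr(s, c1, c1 + 1L) == "CG"
      if (has_cpg) {
        ds <- shape_deltas_all(w, shape_table, default = shape_default)
        shp[i, ] <- vapply(ds, function(d) d$p_value, numeric(1))
      }
    }
  }
  ctfbs <- if (!is.null(ctfbs_track)) count_track_overlaps(windows, ctfbs_track)
           else integer(n)
  altspl <- if (!is.null(altspl_track)) count_track_overlaps(windows, altspl_track)
            else integer(n)
  out <- data.frame(site_id = windows$site_id,
                    G4 = g4, Pals = pals, TFBS = tfbs, cTFBS = as.integer(ctfbs),
                    donor_hit = dhit, acceptor_hit = ahit,
                    altspl = as.integer(altspl),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(shp))
  out$shape_flag <- apply(shp, 1, function(p) any(!is.na(p) & p < 0.05))
  out$gc <- gc_content(windows$seq)
  out$cpg_oe <- cpg_oe_ratio(windows$seq)
  out
}

#' Map raw features to the unit-interval signature matrix
#'
#' Applies the per-attribute mapping functions: each count attribute (G4,
#' Pals, TFBS, cTFBS) is min-max normalized to \eqn{[0, 1]} across the
#' analyzed dataset (a constant column maps to 0 with a warning, and fixed
#' global bounds may be supplied via `bounds`); the splicing attribute is 1
#' when any of donor hit, acceptor hit, or alternative-splicing overlap is
#' present; the shape attribute is 1 when any shape change has
#' p < `shape_alpha`. Logical attributes bypass min-max.
#'
#' @param features Feature table from [build_feature_table()] (columns for
#'   every requested attribute must be present for all sites).
#' @param attrs Attribute subset, default
#'   `c("G4","Pals","TFBS","cTFBS","splicing","shape")`.
#' @param shape_alpha Per-shape significance level for the joined shape
#'   logical, default 0.05.
#' @param bounds Optional named list `attr = c(min, max)` fixing the
#'   normalization bounds of count attributes (for cross-dataset
#'   comparability).
#' @return A list of class `signature_matrix` with `values` (sites x
#'   attributes, all in \eqn{[0, 1]}), `site_id`, `mapping` (per-attribute
#'   metadata sufficient to reproduce the mapped values from raw ones).
#' @export
map_attributes <- function(features, attrs = DEFAULT_ATTRS, shape_alpha = 0.05,
                           bounds = NULL) {
  if (!nrow(features)) .stopf("map_attributes: empty feature table")
  need_raw <- c(intersect(attrs, COUNT_ATTRS),
                if ("splicing" %in% attrs) c("donor_hit", "acceptor_hit", "altspl"),
                if ("shape" %in% attrs) paste0("shape_", SHAPE_NAMES, "_p"))
  miss <- setdiff(need_raw, names(features))
  if (length(miss))
    .stopf("map_attributes: feature column(s) missing for some attributes: %s",
           paste(miss, collapse = ", "))
  n <- nrow(features)
  values <- matrix(NA_real_, nrow = n, ncol = length(attrs),
                   dimnames = list(features$site_id, attrs))
  mapping <- list()
  for (a in attrs) {
    if (a %in% COUNT_ATTRS) {
      x <- as.numeric(features[[a]])
      if (any(is.na(x))) .stopf("map_attributes: NA in count attribute %s", a)
      if (any(x < 0)) .stopf("map_attributes: negative count in attribute %s", a)
      rng <- if (!is.null(bounds[[a]])) as.numeric(bounds[[a]]) else range(x)
      if (rng[1] == rng[2]) {
        .warnf("map_attributes: attribute %s is constant (%s); mapped to 0", a, rng[1])
        values[, a] <- 0
      } else {
        values[, a] <- pmin(1, pmax(0, (x - rng[1]) / (rng[2] - rng[1])))
      }
      mapping[[a]] <- list(type = "minmax", min = rng[1], max = rng[2])
    } else if (a == "splicing") {
      values[, a] <- as.numeric(features$donor_hit | features$acceptor_hit |
                                  features$altspl > 0)
      mapping[[a]] <- list(type = "logical_join",
                           rule = "donor_hit | acceptor_hit | altspl > 0")
    } else if (a == "shape") {
      p <- as.matrix(features[, paste0("shape_", SHAPE_NAMES, "_p"), drop = FALSE])
      values[, a] <- as.numeric(apply(p, 1, function(z) any(!is.na(z) & z < shape_alpha)))
      mapping[[a]] <- list(type = "logical_join",
                           rule = sprintf("any shape p < %s", shape_alpha))
    } else {
      .stopf("map_attributes: unknown attribute %s", a)
    }
  }
  structure(list(values = values, site_id = features$site_id, mapping = mapping),
            class = "signature_matrix")
}

#' Construct a weight scheme
#'
#' @param weights Named non-negative numeric vector (one weight per
#'   attribute) or a single value recycled over `attrs`. At least one weight
#'   must be positive.
#' @param attrs Attribute names when `weights` is unnamed.
#' @return Named numeric vector of class `weight_scheme`.
#' @export
weight_scheme <- function(weights = 1, attrs = DEFAULT_ATTRS) {
  if (is.null(names(weights))) weights <- stats::setNames(rep_len(weights, length(attrs)), attrs)
  if (any(weights < 0)) .stopf("weight_scheme: weights must be non-negative")
  if (!any(weights > 0)) .stopf("weight_scheme: at least one positive weight required")
  structure(weights, class = "weight_scheme")
}

#' Genomic index of mapped signature rows
#'
#' \eqn{idx_i = \sum_j w_j a'_{ij}}: the weighted sum of the mapped
#' attribute values. With the default six equal-weighted attributes the
#' index lies in \eqn{[0, 6]}.
#'
#' @param signature Either a `signature_matrix` or a numeric vector/matrix
#'   of mapped values with attribute names.
#' @param weights A [weight_scheme()] (or named non-negative vector)
#'   covering all attributes of `signature`.
#' @return Numeric vector of non-negative indices (one per site).
#' @export
genomic_index <- function(signature, weights = weight_scheme()) {
  v <- if (inherits(signature, "signature_matrix")) signature$values
       else if (is.matrix(signature)) signature
       else matrix(signature, nrow = 1, dimnames = list(NULL, names(signature)))
  if (any(weights < 0)) .stopf("genomic_index: negative weight")
  miss <- setdiff(colnames(v), names(weights))
  if (length(miss))
    .stopf("genomic_index: weights missing for attribute(s): %s",
           paste(miss, collapse = ", "))
  as.numeric(v %*% weights[colnames(v)])
}

#' Rank sites by genomic index
#'
#' Sites are ordered by descending genomic index; ties are broken by
#' \eqn{|\Delta\beta|} descending, then by (chrom, start) ascending, making
#' the ranking deterministic and independent of input order.
#'
#' @param matrix A `signature_matrix`.
#' @param weights A [weight_scheme()].
#' @param dms Optional DMS table supplying `delta_beta` and coordinates for
#'   tie-breaking (matched by `site_id`).
#' @return `data.frame` of class `ranked_result`, in rank order, with
#'   columns `site_id`, `genomic_index`, `rank` plus available tie-break
#'   keys (`delta_beta`, `chrom`, `start`).
#' @export
rank_sites <- function(matrix, weights = weight_scheme(), dms = NULL) {
  stopifnot(inherits(matrix, "signature_matrix"))
  idx <- genomic_index(matrix, weights)
  out <- data.frame(site_id = matrix$site_id, genomic_index = idx,
                    stringsAsFactors = FALSE)
  if (!is.null(dms)) {
    m <- match(out$site_id, dms$site_id)
    out$delta_beta <- dms$delta_beta[m]
    out$chrom <- dms$chrom[m]
    out$start <- dms$start[m]
  } else {
    out$delta_beta <- NA_real_
    out$chrom <- NA_character_
    out$start <- NA_integer_
  }
  abs_db <- ifelse(is.na(out$delta_beta), -Inf, abs(out$delta_beta))
  ord <- order(-out$genomic_index, -abs_db, out$chrom, out$start, out$site_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("ranked_result", "data.frame")
  out
}

#' Export ranked signatures to TSV
#'
#' Writes one row per site (coordinates, delta-beta, raw features, mapped
#' attribute values, genomic index, rank) preceded by `#`-prefixed header
#' lines recording the weight vector and the per-attribute mapping metadata,
#' so the mapped values and indices are reproducible from the file alone.
#'
#' @param results A `ranked_result` from [rank_sites()].
#' @param matrix The `signature_matrix` the ranking was computed from.
#' @param path Output TSV path.
#' @param features Optional raw feature table to include.
#' @param weights The [weight_scheme()] used (recorded in the header).
#' @return Invisibly, the exported `data.frame`.
#' @export
export_signatures <- function(results, matrix, path, features = NULL,
                              weights = weight_scheme()) {
  stopifnot(inherits(results, "ranked_result"), inherits(matrix, "signature_matrix"))
  mv <- as.data.frame(matrix$values[match(results$site_id, matrix$site_id), ,
                                    drop = FALSE])
  names(mv) <- paste0("mapped_", colnames(matrix$values))
  out <- cbind(results, mv)
  if (!is.null(features)) {
    f <- features[match(results$site_id, features$site_id), , drop = FALSE]
    f$site_id <- NULL
    names(f) <- paste0("raw_", names(f))
    out <- cbind(out, f)
  }
  hdr <- c(
    sprintf("# weights: %s",
            paste(sprintf("%s=%s", names(weights), format(as.numeric(weights), digits = 15)),
                  collapse = " ")),
    vapply(names(matrix$mapping), function(a) {
      m <- matrix$mapping[[a]]
      if (m$type == "minmax")
        sprintf("# mapping %s: minmax min=%s max=%s", a,
                format(m$min, digits = 15), format(m$max, digits = 15))
      else sprintf("# mapping %s: %s", a, m$rule)
    }, character(1))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  suppressWarnings(utils::write.table(out, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE, col.names = TRUE))
  invisible(out)
}

#' Read back an exported signature TSV
#'
#' @param path File written by [export_signatures()].
#' @return A list with `table` (the data) and `header` (the `#` lines).
#' @export
read_signatures <- function(path) {
  if (!file.exists(path)) .stopf("signature file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[grepl("^#", lines)]
  tab <- utils::read.delim(text = lines[!grepl("^#", lines)], header = TRUE,
                           stringsAsFactors = FALSE)
  list(table = tab, header = hdr)
}
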