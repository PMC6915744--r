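# Shapiro-Senapathy percentile scoring of splice donor and acceptor sites.
#
# A splice-site model is a 4 x L per-position base-frequency matrix
# (columns sum to 1): L = 9 for donors (exon -3..-1 | intron +1..+6) and
# L = 15 for acceptors (pyrimidine tract, branch-proximal positions, the
# invariant AG and the first exonic base). The models ship as editable TSV
# files under inst/extdata and can be replaced by user-supplied tables.

#' Load a splice-site frequency model from TSV
#'
#' Expected columns: `pos` plus numeric `A`, `C`, `G`, `T` per-position
#' frequencies; each row (position) must sum to 1 within 1e-6.
#'
#' @param path TSV file path.
#' @param site_type `"donor"` or `"acceptor"`.
#' @return A list of class `splice_model` with `site_type`, `freq`
#'   (4 x L matrix, rownames A,C,G,T), `length`.
#' @export
read_splice_model <- function(path, site_type = c("donor", "acceptor")) {
  site_type <- match.arg(site_type)
  if (!file.exists(path)) .stopf("splice model not found: %s", path)
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("A", "C", "G", "T")
  if (!all(need %in% names(tab)))
    .stopf("splice model needs columns A, C, G, T")
  freq <- t(as.matrix(tab[, need]))
  rownames(freq) <- need
  splice_model(freq, site_type)
}

#' Construct and validate a splice-site model
#'
#' @param freq 4 x L numeric matrix (rownames A,C,G,T); every column must
#'   sum to 1 within 1e-6.
#' @param site_type `"donor"` or `"acceptor"`.
#' @return A `splice_model`.
#' @export
splice_model <- function(freq, site_type = c("donor", "acceptor")) {
  site_type <- match.arg(site_type)
  stopifnot(is.matrix(freq), nrow(freq) == 4L)
  if (any(abs(colSums(freq) - 1) > 1e-6))
    .stopf("splice_model: every position's frequencies must sum to 1")
  if (any(freq < 0)) .stopf("splice_model: negative frequency")
  structure(list(site_type = site_type, freq = freq, length = ncol(freq)),
            class = "splice_model")
}

#' Bundled splice-site models
#'
#' Load the donor (9 positions) or acceptor (15 positions) frequency table
#' shipped with the package.
#'
#' @return A `splice_model`.
#' @export
default_donor_model <- function() {
  read_splice_model(system.file("extdata", "splice_donor.tsv",
                                package = "methsig", mustWork = TRUE), "donor")
}

#' @rdname default_donor_model
#' @export
default_acceptor_model <- function() {
  read_splice_model(system.file("extdata", "splice_acceptor.tsv",
                                package = "methsig", mustWork = TRUE), "acceptor")
}

#' Shapiro-Senapathy percentile score of a k-mer
#'
#' \eqn{100 (t - t_{min}) / (t_{max} - t_{min})} where `t` is the sum over
#' positions of the frequency of the observed base and `t_min`/`t_max` are
#' the sums of the column minima/maxima. Consensus k-mers score 100,
#' anti-consensus k-mers 0.
#'
#' @param sequence_kmer DNA string whose length equals the model length; no
#'   N allowed.
#' @param model A `splice_model`.
#' @return Numeric score in \eqn{[0, 100]}.
#' @export
ss_score <- function(sequence_kmer, model) {
  stopifnot(inherits(model, "splice_model"))
  L <- model$length
  if (nchar(sequence_kmer) != L)
    .stopf("ss_score: k-mer length %d does not match model length %d",
           nchar(sequence_kmer), L)
  codes <- .encode_dna(sequence_kmer)
  if (anyNA(codes)) .stopf("ss_score: k-mer contains non-ACGT characters")
  t <- sum(model$freq[cbind(codes, seq_len(L))])
  tmin <- sum(apply(model$freq, 2, min))
  tmax <- sum(apply(model$freq, 2, max))
  100 * (t - tmin) / (tmax - tmin)
}

# All-offset scores of a model along one strand; NA where the placement
# covers a non-ACGT base.
.ss_scan_strand <- function(seq, model) {
  codes <- .encode_dna(seq)
  sc <- .scan_scores(codes, model$freq)
  tmin <- sum(apply(model$freq, 2, min))
  tmax <- sum(apply(model$freq, 2, max))
  100 * (sc - tmin) / (tmax - tmin)
}

#' Scan a window for putative splice sites
#'
#' Slides the donor and acceptor models over both strands and reports every
#' offset with Shapiro-Senapathy score at or above `min_score`. The logical
#' `any_hit` (any donor or acceptor hit) is the splice-site component of the
#' joined splicing attribute; combined downstream with alternative-splicing
#' track overlap.
#'
#' @param window A `seq_window` or DNA string of length >= 15.
#' @param donor,acceptor `splice_model` objects (defaults: bundled models).
#' @param min_score Minimum score in \eqn{[0, 100]}, default 80.
#' @param both_strands Scan the minus strand too, default TRUE.
#' @return A list with `any_hit` (logical) and `hits` (`data.frame`:
#'   `site_type`, `start` 0-based window-relative, `strand`, `score`).
#' @export
find_splice_sites <- function(window, donor = default_donor_model(),
                              acceptor = default_acceptor_model(),
                              min_score = 80, both_strands = TRUE) {
  seq <- if (inherits(window, "seq_window")) window$seq else window
  if (nchar(seq) < 15L) .stopf("find_splice_sites: window length must be >= 15")
  n <- nchar(seq)
  rows <- list()
  for (model in list(donor, acceptor)) {
    L <- model$length
    strands <- if (both_strands) c("+", "-") else "+"
    for (strand in strands) {
      s <- if (strand == "+") seq else revcomp(seq)
      sc <- .ss_scan_strand(s, model)
      hit <- which(!is.na(sc) & sc >= min_score)
      if (!length(hit)) next
      start0 <- if (strand == "+") hit - 1L else n - (hit - 1L) - L
      rows[[length(rows) + 1L]] <- data.frame(
        site_type = model$site_type, start = start0, strand = strand,
        score = sc[hit], stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows)
          else data.frame(site_type = character(0), start = integer(0),
                          strand = character(0), score = numeric(0),
                          stringsAsFactors = FALSE)
  hits <- hits[order(hits$start, hits$site_type, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  list(any_hit = nrow(hits) > 0L, hits = hits)
}
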