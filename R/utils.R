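# Internal helpers shared across modules.

#' Reverse complement of DNA character strings
#'
#' Vectorized reverse complement over the alphabet A, C, G, T, N (either
#' case; N maps to N). Agrees with [Biostrings::reverseComplement()] on
#' this alphabet while avoiding per-call XStringSet construction, which
#' matters in the inner scanning loops.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements (uppercase preserved per
#'   input case).
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(chartr("ACGTacgt", "TGCAtgca", x),
         function(s) intToUtf8(rev(utf8ToInt(s))),
         character(1), USE.NAMES = FALSE)
}

# Complement of a character vector of single bases; anything outside ACGT
# (notably N) maps to "X" so that it can never satisfy a base-pair test.
.comp_base <- function(b) {
  out <- c(A = "T", C = "G", G = "C", T = "A")[b]
  out[is.na(out)] <- "X"
  unname(out)
}

.split1 <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# Base -> integer code (A=1, C=2, G=3, T=4), NA for anything else.
.encode_dna <- function(seq) {
  match(.split1(toupper(seq)), c("A", "C", "G", "T"))
}

.is_count1 <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == as.integer(x)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
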