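# DNA palindrome (inverted repeat) detection.
#
# A palindrome is a left arm whose sequence equals the reverse complement of
# the right arm, the two arms separated by a loop of length 0..max_loop.
# Only maximal matches are reported: a match is suppressed when it can be
# extended either outward (both arms grown by one base, loop unchanged) or
# inward (both arms grown by one base, loop shrunk by two) and still satisfy
# the definition. Inward suppression stops one physical hairpin from being
# counted once per nested arm/loop re-parameterization.

#' Find maximal DNA palindromes
#'
#' @param sequence Nonempty DNA string (A/C/G/T/N; case-insensitive). N
#'   never base-pairs, so arms cannot cross N.
#' @param min_arm Minimum arm length (>= 2), default 6.
#' @param max_loop Maximum loop length (>= 0), default 10.
#' @return `data.frame` with columns `arm_start` (0-based position of the
#'   left arm), `arm_length`, `loop_length`.
#' @export
find_palindromes <- function(sequence, min_arm = 6L, max_loop = 10L) {
  if (!nzchar(sequence)) .stopf("find_palindromes: sequence must be nonempty")
  if (min_arm < 2L) .stopf("find_palindromes: min_arm must be >= 2")
  if (max_loop < 0L) .stopf("find_palindromes: max_loop must be >= 0")
  chars <- .split1(toupper(sequence))
  n <- length(chars)
  comp <- .comp_base(chars)
  out_s <- integer(0); out_a <- integer(0); out_l <- integer(0)
  for (l in 0:max_loop) {
    # i = 1-based position just after the left arm (loop occupies i..i+l-1).
    # Pairing condition for arm extension k (k = 0, 1, ...):
    #   chars[i - 1 - k] pairs with chars[i + l + k]
    #   i.e. comp[i - 1 - k] == chars[i + l + k]
    is <- seq_len(n)
    is <- is[is - 1L >= 1L & is + l <= n]
    if (!length(is)) next
    arm <- integer(length(is))
    alive <- rep(TRUE, length(is))
    k <- 0L
    while (any(alive)) {
      ii <- is[alive]
      left <- ii - 1L - k
      right <- ii + l + k
      ok <- left >= 1L & right <= n
      ok[ok] <- comp[left[ok]] == chars[right[ok]]
      arm[alive][ok] <- k + 1L
      alive[alive] <- ok
      k <- k + 1L
    }
    keep <- arm >= min_arm
    if (!any(keep)) next
    ii <- is[keep]; aa <- arm[keep]
    # arm is already outward-maximal by construction (extension stopped).
    # Inward suppression: the innermost loop pair must not itself pair.
    if (l >= 2L) {
      inner <- comp[ii] == chars[ii + l - 1L]
      ii <- ii[!inner]; aa <- aa[!inner]
    }
    if (!length(ii)) next
    out_s <- c(out_s, ii - aa - 1L)   # 0-based left-arm start
    out_a <- c(out_a, aa)
    out_l <- c(out_l, rep(l, length(ii)))
  }
  out <- data.frame(arm_start = out_s, arm_length = out_a, loop_length = out_l)
  out[order(out$arm_start, out$loop_length), , drop = FALSE]
}

#' Palindrome count in a sequence window
#'
#' Number of maximal palindromes from [find_palindromes()]; feeds the
#' signature attribute `Pals`.
#'
#' @param window A `seq_window` or DNA string.
#' @inheritParams find_palindromes
#' @return Non-negative integer.
#' @export
palindrome_count <- function(window, min_arm = 6L, max_loop = 10L) {
  s <- if (inherits(window, "seq_window")) window$seq else window
  nrow(find_palindromes(s, min_arm, max_loop))
}
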