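#' Enumerate every candidate motif shared by a pair of l-mers
#'
#' Streams the intersection of the two radius-`d` Hamming balls around `x`
#' and `x_prime` — exactly the words that could have both as instances —
#' each element emitted once, in a fixed deterministic order. The traversal
#' visits one disjoint subset per admissible `(alpha, beta)` signature
#' (see [mapping_relation()]): starting from `y = x_prime`, it flips
#' `alpha` matched positions to one of the three non-`x` bases, flips
#' `beta` mismatched positions to one of the two bases differing from both
#' words, and resets `k` further mismatched positions to `x`'s base, with
#' `k` bounded so both distances stay within `d`.
#'
#' @param x,x_prime DNA words of equal length (up to 32 bases).
#' @param d Maximum mutations per motif instance.
#' @return Character vector of candidate motifs; empty when the pair
#'   distance exceeds `2d`. Its length equals
#'   `candidate_count(l, d, hamming_dist(x, x_prime))`.
#' @examples
#' length(enumerate_candidates("AAAAAAAGGGGGGGG", "AAAAAAACCCCCCCC", 4))  # 70
#' @export
enumerate_candidates <- function(x, x_prime, d) {
  stopifnot(is.character(x), is.character(x_prime),
            length(x) == 1, length(x_prime) == 1)
  if (nchar(x) != nchar(x_prime)) {
    stop("x and x_prime must have equal lengths", call. = FALSE)
  }
  check_params(nchar(x), d)
  cpp_enumerate(x, x_prime, as.integer(d))
}
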