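#' Encode an l-mer as a 2-bit-per-base integer code
#'
#' Each base maps to two bits (A = 00, C = 01, G = 10, T = 11), base `i` of
#' the word occupying bits `2i` and `2i + 1` of the code. The encoding is a
#' bijection between l-mers and the integers `0 .. 4^l - 1`, and is the unit
#' on which all Hamming-distance computations operate internally.
#'
#' Codes are returned as doubles, which represent the `2l`-bit integers
#' exactly for `l <= 26`; longer words are rejected here, although every
#' string-based operation in the package (distances, enumeration, search)
#' supports `l` up to 32.
#'
#' @param word Character vector of DNA words over A/C/G/T (case-insensitive).
#'   All words must have the same length.
#' @return Numeric vector of codes, one per word.
#' @examples
#' encode_lmer("AAAA")    # 0
#' decode_lmer(encode_lmer("ACGT"), 4)
#' @seealso [decode_lmer()], [hamming_dist()]
#' @export
encode_lmer <- function(word) {
  stopifnot(is.character(word), length(word) >= 1)
  if (length(unique(nchar(word))) != 1) {
    stop("all words must have the same length", call. = FALSE)
  }
  cpp_encode(word)
}

#' Decode a 2-bit integer code back to an l-mer
#'
#' @param code Numeric vector of codes as produced by [encode_lmer()].
#' @param l Word length in bases.
#' @return Character vector of DNA words.
#' @export
decode_lmer <- function(code, l) {
  stopifnot(is.numeric(code), length(l) == 1, l >= 1, l <= 26)
  if (any(code < 0 | code >= 4^l)) {
    stop("codes must lie in [0, 4^l)", call. = FALSE)
  }
  cpp_decode(as.numeric(code), as.integer(l))
}

#' Hamming distance between equal-length DNA words
#'
#' Computed on the 2-bit encoding: the XOR of two codes is scanned one byte
#' (four base positions) at a time against a precomputed 256-entry table
#' holding the number of non-00 2-bit fields per byte, so a distance costs
#' `ceiling(l/4)` table lookups. Identical in value to a position-by-position
#' character comparison.
#'
#' @param x,y Character vectors of DNA words; recycled to a common length.
#'   Paired words must have equal lengths (up to 32 bases).
#' @return Integer vector of Hamming distances.
#' @examples
#' hamming_dist("AAAAAAAGGGGGGGG", "AAAAAAACCCCCCCC")  # 8
#' @export
hamming_dist <- function(x, y) {
  stopifnot(is.character(x), is.character(y))
  cpp_hamming(x, y)
}

#' Partition alignment positions of three words into the four classes
#'
#' For words `x`, `x_prime` and `z` of equal length, each position falls in
#' one of four classes: `p11` (`x` and `x_prime` agree, `z` matches them),
#' `p10` (they agree, `z` differs), `p01` (they differ, `z` matches one of
#' them), `p00` (they differ, `z` matches neither). These counts drive the
#' second filtering rule and the candidate traversal: `p01 + p00` always
#' equals the distance between `x` and `x_prime`, and the four counts sum
#' to the word length.
#'
#' @param x,x_prime,z DNA words of equal length.
#' @return A one-row tibble with integer columns `p11`, `p10`, `p01`, `p00`.
#' @examples
#' partition_counts("AAAAAAAGGGGGGGG", "AAAAAAACCCCCCCC", "AAAAAAATTTTTTTT")
#' @export
partition_counts <- function(x, x_prime, z) {
  stopifnot(is.character(x), is.character(x_prime), is.character(z),
            length(x) == 1, length(x_prime) == 1, length(z) == 1)
  p <- cpp_partition(x, x_prime, z)
  tibble::tibble(p11 = p[["p11"]], p10 = p[["p10"]],
                 p01 = p[["p01"]], p00 = p[["p00"]])
}
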