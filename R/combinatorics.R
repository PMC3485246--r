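check_params <- function(l, d) {
  stopifnot(length(l) == 1, length(d) == 1, l == as.integer(l),
            d == as.integer(d))
  if (!(d >= 0 && d < l)) {
    stop("parameters must satisfy 0 <= d < l", call. = FALSE)
  }
  invisible(list(l = as.integer(l), d = as.integer(d)))
}

#' Admissible (alpha, beta) signatures for a pair of l-mers
#'
#' Any word `y` lying within Hamming distance `d` of both members of a pair
#' `(x, x')` at mutual distance `h` can be classified by the signature
#' `(alpha, beta)` = (number of positions where `x = x'` but `y` differs,
#' number of positions where `x != x'` and `y` matches neither). Since
#' `d_H(y,x) + d_H(y,x') = 2*alpha + 2*beta + (h - beta) <= 2d`, the
#' admissible signatures are exactly those with `alpha <= l - h`,
#' `beta <= h` and `2*alpha + beta + h <= 2d` — determined by `h` alone for
#' fixed `(l, d)`. The set is empty precisely when `h > 2d`.
#'
#' @param l Motif length in bases.
#' @param d Maximum mutations per motif instance.
#' @param h Hamming distance between the pair, `0 <= h <= l`.
#' @return Tibble with integer columns `alpha`, `beta`, sorted
#'   lexicographically; zero rows when `h > 2d`.
#' @examples
#' mapping_relation(15, 4, 8)   # single signature (0, 0)
#' mapping_relation(15, 4, 5)
#' @export
mapping_relation <- function(l, d, h) {
  check_params(l, d)
  stopifnot(length(h) == 1, h == as.integer(h), h >= 0, h <= l)
  if (h > 2 * d) {
    return(tibble::tibble(alpha = integer(), beta = integer()))
  }
  grid <- tidyr::expand_grid(alpha = 0:(l - h), beta = 0:h)
  dplyr::filter(grid, 2 * .data$alpha + .data$beta + h <= 2 * d)
}

#' Exact size of the candidate set shared by a pair of l-mers
#'
#' Counts the words within Hamming distance `d` of both members of a pair at
#' mutual distance `h` — the intersection of their two radius-`d` Hamming
#' balls. The count depends only on `(l, d, h)`: summing over admissible
#' signatures `(alpha, beta)` (see [mapping_relation()]) and over the number
#' `k` of mismatch positions reset to the first word's base,
#' \deqn{\sum_{(\alpha,\beta)} \binom{l-h}{\alpha} 3^\alpha
#'       \binom{h}{\beta} 2^\beta \sum_k \binom{h-\beta}{k}}
#' with `max(0, alpha + h - d) <= k <= min(h - beta, d - alpha - beta)`.
#' For `h = 0` this reduces to the radius-`d` ball size
#' `sum_i choose(l, i) 3^i`. Counts are exact integers held in doubles
#' (exact below 2^53, i.e. for all `l <= 26`).
#'
#' @inheritParams mapping_relation
#' @param h Integer vector of pair distances.
#' @return Numeric vector of exact counts; 0 where `h > 2d`.
#' @examples
#' candidate_count(15, 4, c(8, 5))  # 70, 2970
#' @export
candidate_count <- function(l, d, h) {
  check_params(l, d)
  stopifnot(all(h == as.integer(h)), all(h >= 0), all(h <= l))
  vapply(as.integer(h), function(hi) {
    rel <- mapping_relation(l, d, hi)
    if (nrow(rel) == 0) return(0)
    sum(purrr::map2_dbl(rel$alpha, rel$beta, function(a, b) {
      klo <- max(0, a + hi - d)
      khi <- min(hi - b, d - a - b)
      choose(l - hi, a) * 3^a * choose(hi, b) * 2^b *
        sum(choose(hi - b, klo:khi))
    }))
  }, numeric(1))
}

#' Cached candidate-count table for all admissible pair distances
#'
#' The search engine selects reference sequences by summing these counts
#' over scanned windows, so they are precomputed once per `(l, d)`.
#'
#' @inheritParams mapping_relation
#' @return Tibble with columns `h` (0..2d) and `count`.
#' @export
candidate_count_table <- function(l, d) {
  check_params(l, d)
  h <- 0:(2 * d)
  tibble::tibble(h = h, count = candidate_count(l, d, h))
}

#' Probability that two random l-mers lie within Hamming distance k
#'
#' For i.i.d. uniform DNA, each position mismatches with probability 3/4,
#' so the distance is Binomial(l, 3/4) and
#' \deqn{p_k = \sum_{i=0}^{k} \binom{l}{i} (3/4)^i (1/4)^{l-i}.}
#' Evaluated at `k = 2d` this measures how hard a planted `(l, d)` instance
#' is: large `p_{2d}` means spurious candidate motifs abound ("weak"
#' instances).
#'
#' @param l Word length in bases.
#' @param k Integer vector of distance thresholds, `0 <= k <= l`.
#' @return Numeric vector of probabilities in \[0, 1\], nondecreasing in `k`.
#' @examples
#' neighborhood_probability(15, 8)   # difficulty of the (15, 4) instance
#' @export
neighborhood_probability <- function(l, k) {
  stopifnot(length(l) == 1, l == as.integer(l), l >= 1,
            all(k == as.integer(k)), all(k >= 0), all(k <= l))
  vapply(as.integer(k), function(ki) {
    i <- 0:ki
    sum(choose(l, i) * (3 / 4)^i * (1 / 4)^(l - i))
  }, numeric(1))
}
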