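#' Extract each sequence's best instance of a motif
#'
#' For every sequence, the window minimizing the Hamming distance to the
#' motif (leftmost on ties). Errors if any sequence has no window within
#' `d` — the motif contract guarantees one in every sequence.
#'
#' @param seqs Sequence set: character vector or tibble with `id`, `seq`.
#' @param motif The motif word.
#' @param d Maximum mutations per instance.
#' @return Tibble with columns `id`, `position` (0-based), `instance`,
#'   `distance` — one row per sequence, in input order.
#' @export
extract_instances <- function(seqs, motif, d) {
  stopifnot(is.character(motif), length(motif) == 1)
  check_params(nchar(motif), d)
  seqs <- as_sequence_set(seqs, l = nchar(motif))
  rows <- purrr::map2_dfr(seqs$id, seqs$seq, function(id, s) {
    bw <- cpp_best_window(motif, s)
    if (bw[1] < 0 || bw[2] > d) {
      stop("sequence ", id, " has no window within d = ", d,
           " of the motif", call. = FALSE)
    }
    tibble::tibble(id = id, position = bw[1],
                   instance = substr(s, bw[1] + 1, bw[1] + nchar(motif)),
                   distance = bw[2])
  })
  rows
}

instance_words <- function(instances) {
  if (is.data.frame(instances)) {
    if (!"instance" %in% names(instances)) {
      stop("expected an `instance` column", call. = FALSE)
    }
    instances <- instances$instance
  }
  stopifnot(is.character(instances), length(instances) >= 1)
  if (length(unique(nchar(instances))) != 1) {
    stop("instances must all have the same length", call. = FALSE)
  }
  toupper(instances)
}

# 4 x l base-count matrix of an instance alignment
count_matrix <- function(words) {
  l <- nchar(words[1])
  mat <- matrix(unlist(strsplit(words, "")), nrow = length(words),
                byrow = TRUE)
  vapply(seq_len(l), function(j) {
    vapply(c("A", "C", "G", "T"), function(b) sum(mat[, j] == b),
           numeric(1))
  }, numeric(4))
}

#' Consensus score of an instance alignment
#'
#' Sum over motif columns of the count of the most frequent base across
#' the aligned instances. Ranges from `l * ceiling(t/4)` (maximally
#' spread columns) to `l * t` (all instances identical).
#'
#' @param instances Character vector of aligned instance words, or a
#'   tibble with an `instance` column (as from [extract_instances()]).
#' @return Integer score.
#' @examples
#' consensus_score(c("ACG", "ACG", "ATG"))  # 3 + 2 + 3 = 8
#' @export
consensus_score <- function(instances) {
  words <- instance_words(instances)
  cm <- count_matrix(words)
  as.integer(sum(apply(cm, 2, max)))
}

#' Relative entropy of an instance alignment against a background
#'
#' Kullback–Leibler divergence, in bits, of the per-column base
#' frequencies from a background distribution, summed over columns:
#' `sum_cols sum_bases f * log2(f / b)`. Column frequencies are computed
#' from counts with an additive pseudocount. Nonnegative whenever the
#' background is a proper distribution; larger means the alignment is
#' more sharply distinguished from background.
#'
#' @inheritParams consensus_score
#' @param background `"uniform"`, or a positive numeric vector of 4
#'   A/C/G/T frequencies (normalized internally). The search engine's
#'   ranking uses whole-dataset frequencies by default.
#' @param pseudocount Additive count per base per column (default 0.25).
#' @return Nonnegative numeric score in bits.
#' @examples
#' relative_entropy(c("AAAA", "AAAA"), background = "uniform",
#'                  pseudocount = 0)  # 2 bits per column = 8
#' @export
relative_entropy <- function(instances, background = "uniform",
                             pseudocount = 0.25) {
  words <- instance_words(instances)
  t <- length(words)
  stopifnot(length(pseudocount) == 1, pseudocount >= 0)
  if (identical(background, "uniform")) {
    bg <- rep(0.25, 4)
  } else {
    stopifnot(is.numeric(background), length(background) == 4)
    if (any(background <= 0)) {
      stop("background frequencies must be strictly positive",
           call. = FALSE)
    }
    bg <- background / sum(background)
  }
  cm <- count_matrix(words)
  f <- (cm + pseudocount) / (t + 4 * pseudocount)
  terms <- f * log2(f / bg)
  terms[f == 0] <- 0  # 0 * log(0) := 0 (possible only with pseudocount 0)
  sum(terms)
}

#' Nucleotide-level correlation coefficient
#'
#' Matthews-type correlation between predicted and true binding-site
#' nucleotides:
#' `(nTP*nTN - nFN*nFP) / sqrt((nTP+nFN)(nTN+nFP)(nTP+nFP)(nTN+nFN))`,
#' in \[-1, 1\]: +1 for perfect agreement, -1 for perfect anticorrelation.
#' When any denominator factor is zero the coefficient is undefined and
#' `NA` is returned with a warning (never silently 0).
#'
#' @param ntp,ntn,nfn,nfp Confusion counts over nucleotide positions.
#'   Alternatively pass a data frame with these columns as `ntp` (e.g.
#'   the output of [confusion_from_positions()]).
#' @return Numeric value in \[-1, 1\], or `NA` when undefined.
#' @examples
#' ncc(ntp = 5, ntn = 90, nfn = 2, nfp = 3)
#' @export
ncc <- function(ntp, ntn = NULL, nfn = NULL, nfp = NULL) {
  if (is.data.frame(ntp)) {
    df <- ntp
    stopifnot(all(c("ntp", "ntn", "nfn", "nfp") %in% names(df)))
    ntn <- df$ntn; nfn <- df$nfn; nfp <- df$nfp; ntp <- df$ntp
  }
  stopifnot(ntp >= 0, ntn >= 0, nfn >= 0, nfp >= 0)
  den2 <- (ntp + nfn) * (ntn + nfp) * (ntp + nfp) * (ntn + nfn)
  if (any(den2 == 0)) {
    warning("nCC undefined: a denominator factor is zero", call. = FALSE)
    return(ifelse(den2 == 0, NA_real_,
                  (ntp * ntn - nfn * nfp) / sqrt(den2)))
  }
  (ntp * ntn - nfn * nfp) / sqrt(den2)
}

#' Nucleotide confusion counts from predicted and true windows
#'
#' Compares one predicted window per sequence against one true window per
#' sequence, both of length `l` on sequences of length `n`, and counts
#' nucleotide positions covered by both (TP), prediction only (FP), truth
#' only (FN) or neither (TN), summed over sequences.
#'
#' @param predicted,truth Integer vectors of 0-based window start
#'   positions, one per sequence (equal lengths).
#' @param l Window (motif) length.
#' @param n Sequence length (scalar or per-sequence vector).
#' @return One-row tibble with columns `ntp`, `ntn`, `nfn`, `nfp`;
#'   the four sum to `sum(n)`.
#' @examples
#' confusion_from_positions(predicted = c(10, 21), truth = c(10, 20),
#'                          l = 8, n = 100)
#' @export
confusion_from_positions <- function(predicted, truth, l, n) {
  stopifnot(length(predicted) == length(truth), l >= 1,
            length(n) == 1 || length(n) == length(predicted))
  n <- rep_len(as.integer(n), length(predicted))
  if (any(predicted < 0 | predicted > n - l) ||
      any(truth < 0 | truth > n - l)) {
    stop("window positions must lie in [0, n - l]", call. = FALSE)
  }
  overlap <- pmax(0L, l - abs(as.integer(predicted) - as.integer(truth)))
  tibble::tibble(
    ntp = sum(overlap),
    ntn = sum(n - 2L * l + overlap),
    nfn = sum(l - overlap),
    nfp = sum(l - overlap)
  )
}

#' Rank motifs by objective functions
#'
#' Scores each motif by consensus score and relative entropy over its
#' per-sequence best instances and returns a ranked tibble, ordered by
#' the chosen objective (descending). When a ground-truth manifest is
#' supplied, the nucleotide-level correlation coefficient of each motif's
#' predicted instance positions is included.
#'
#' @param motifs Character vector of motif words (all verified (l,d)
#'   motifs of the sequence set).
#' @param seqs Sequence set: character vector or tibble with `id`, `seq`.
#' @param d Maximum mutations per instance.
#' @param rank_by `"relative_entropy"` (default) or `"consensus_score"`.
#' @param background Background for relative entropy: `"dataset"`
#'   (default, whole-dataset base frequencies), `"uniform"`, or a numeric
#'   4-vector.
#' @param manifest Optional ground-truth tibble with columns `id`,
#'   `position` (as from [simulate_planted()]); adds an `ncc` column.
#' @return Tibble with columns `motif`, `consensus_score`,
#'   `relative_entropy`, optionally `ncc`, sorted by the objective.
#' @export
score_motifs <- function(motifs, seqs, d,
                         rank_by = c("relative_entropy", "consensus_score"),
                         background = "dataset", manifest = NULL) {
  stopifnot(is.character(motifs), length(motifs) >= 1)
  rank_by <- match.arg(rank_by)
  seqs <- as_sequence_set(seqs, l = nchar(motifs[1]))
  bg <- if (identical(background, "dataset")) base_frequencies(seqs)
        else background
  rows <- purrr::map_dfr(motifs, function(m) {
    inst <- extract_instances(seqs, m, d)
    out <- tibble::tibble(
      motif = m,
      consensus_score = consensus_score(inst),
      relative_entropy = relative_entropy(inst, background = bg)
    )
    if (!is.null(manifest)) {
      joined <- dplyr::inner_join(inst, manifest[c("id", "position")],
                                  by = "id", suffix = c("", "_true"))
      conf <- confusion_from_positions(joined$position,
                                       joined$position_true,
                                       l = nchar(m),
                                       n = nchar(seqs$seq)[match(joined$id,
                                                                 seqs$id)])
      out$ncc <- ncc(conf)
    }
    out
  })
  dplyr::arrange(rows, dplyr::desc(.data[[rank_by]]), .data$motif)
}
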