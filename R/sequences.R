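# Sequence sets travel as tibbles with columns `id` and `seq`; bare
# character vectors are promoted with generated ids.
as_sequence_set <- function(seqs, l = NULL) {
  if (is.character(seqs)) {
    seqs <- tibble::tibble(
      id = paste0("seq", seq_along(seqs)),
      seq = unname(seqs)
    )
  }
  if (!is.data.frame(seqs) || !all(c("id", "seq") %in% names(seqs))) {
    stop("sequences must be a character vector or a data frame with ",
         "columns `id` and `seq`", call. = FALSE)
  }
  seqs <- tibble::as_tibble(seqs[c("id", "seq")])
  if (nrow(seqs) == 0) stop("empty sequence set", call. = FALSE)
  seqs$seq <- toupper(seqs$seq)
  if (!is.null(l)) {
    short <- nchar(seqs$seq) < l
    if (any(short)) {
      stop("sequence(s) shorter than l = ", l, ": ",
           paste(seqs$id[short], collapse = ", "), call. = FALSE)
    }
  }
  seqs
}

#' Nucleotide frequencies of a sequence set
#'
#' @param seqs Sequence set: character vector or tibble with `id`, `seq`.
#' @return Named numeric vector of A/C/G/T frequencies summing to 1
#'   (non-ACGT characters are ignored).
#' @export
base_frequencies <- function(seqs) {
  seqs <- as_sequence_set(seqs)
  chars <- strsplit(paste(seqs$seq, collapse = ""), "")[[1]]
  counts <- vapply(c("A", "C", "G", "T"), function(b) sum(chars == b),
                   numeric(1))
  if (sum(counts) == 0) stop("no A/C/G/T characters found", call. = FALSE)
  counts / sum(counts)
}
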