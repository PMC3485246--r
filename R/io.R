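#' Read DNA sequences from a FASTA file
#'
#' Wraps `Biostrings::readDNAStringSet()` and returns the tidy sequence-set
#' form used throughout the package. Sequences are uppercased; headers are
#' truncated at the first whitespace.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @return Tibble with columns `id` and `seq`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) stop("no sequences in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(ss))
  tibble::tibble(id = ids, seq = unname(toupper(as.character(ss))))
}

#' Write a sequence set to a FASTA file
#'
#' @param seqs Sequence set: character vector or tibble with `id`, `seq`.
#' @param path Output path.
#' @param width Line width for wrapping (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  seqs <- as_sequence_set(seqs)
  ss <- Biostrings::DNAStringSet(setNames(seqs$seq, seqs$id))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Write a motif report as tab-separated text
#'
#' One row per motif: the motif string, the number of supporting
#' sequences, the maximum per-sequence instance distance, consensus score
#' and relative entropy, then one `pos:distance` column per sequence
#' giving the best instance (0-based position).
#'
#' @param fit A `pair_search` object (see [pair_search()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_report <- function(fit, path) {
  stopifnot(inherits(fit, "pair_search"))
  inst <- fit$instances
  mot <- fit$motifs
  if (nrow(mot) > 0) {
    wide <- inst |>
      dplyr::mutate(cell = paste0(.data$position, ":", .data$distance)) |>
      dplyr::select("motif", "id", "cell") |>
      tidyr::pivot_wider(names_from = "id", values_from = "cell")
    out <- mot |>
      dplyr::mutate(n_sequences = fit$params$t, .after = "motif") |>
      dplyr::left_join(wide, by = "motif")
  } else {
    out <- dplyr::mutate(mot, n_sequences = integer())
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a motif report written by [write_motif_report()]
#'
#' @param path Path to the tab-separated report.
#' @return Tibble, one row per motif.
#' @export
read_motif_report <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      check.names = FALSE,
                                      colClasses = "character")) |>
    dplyr::mutate(dplyr::across(dplyr::any_of(
      c("n_sequences", "max_distance", "consensus_score")), as.integer)) |>
    dplyr::mutate(dplyr::across(dplyr::any_of("relative_entropy"),
                                as.numeric))
}
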