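#' Create a marker reference sequence
#'
#' A marker reference anchors all downstream coordinates: strains are
#' represented by their substitutions relative to it, and codon positions
#' are computed from its reading-frame offset. Amplicon markers in this
#' design are short (under 500 bp) protein-coding fragments.
#'
#' @param length Sequence length in bp; must be in `[30, 500)`.
#' @param frame_offset Integer 0--2, number of bases before the first
#'   complete codon.
#' @param seed Integer seed; the sequence is deterministic given the seed.
#' @param marker_name Name of the marker (e.g. `"guaA"`).
#' @return An object of class `marker_reference` with fields `marker_name`,
#'   `sequence` and `frame_offset`.
#' @examples
#' ref <- make_marker_reference(450, frame_offset = 0, seed = 1,
#'                              marker_name = "guaA")
#' nchar(ref$sequence)
#' @export
make_marker_reference <- function(length, frame_offset = 0L, seed = 1L,
                                  marker_name = "marker") {
  stop_if_not_scalar_number(length, "length")
  if (length < 30 || length >= 500) {
    stop("marker length must be >= 30 and < 500 bp", call. = FALSE)
  }
  if (!frame_offset %in% 0:2) stop("frame_offset must be 0, 1 or 2", call. = FALSE)
  sequence <- local_seed(seed, paste0(
    sample(DNA_BASES, length, replace = TRUE), collapse = ""))
  structure(
    list(marker_name = as.character(marker_name),
         sequence = sequence,
         frame_offset = as.integer(frame_offset)),
    class = "marker_reference")
}

#' @export
print.marker_reference <- function(x, ...) {
  cat(sprintf("<marker_reference> %s: %d bp, frame offset %d\n",
              x$marker_name, nchar(x$sequence), x$frame_offset))
  invisible(x)
}

as_reference_list <- function(references) {
  if (inherits(references, "marker_reference")) references <- list(references)
  if (!length(references) || !all(vapply(references, inherits, logical(1),
                                         "marker_reference"))) {
    stop("'references' must be a marker_reference or a list of them",
         call. = FALSE)
  }
  names(references) <- vapply(references, `[[`, character(1), "marker_name")
  if (anyDuplicated(names(references))) stop("duplicated marker names", call. = FALSE)
  references
}

#' Write marker references to FASTA with a frame-offset sidecar
#'
#' @param references A `marker_reference` or list of them.
#' @param fasta_file Output FASTA path.
#' @param offsets_file Output tab-separated sidecar path
#'   (columns `marker`, `frame_offset`); defaults to
#'   `<fasta_file>.offsets.tsv`.
#' @return Invisibly, the FASTA path.
#' @export
write_marker_references <- function(references, fasta_file,
                                    offsets_file = paste0(fasta_file, ".offsets.tsv")) {
  references <- as_reference_list(references)
  seqs <- Biostrings::DNAStringSet(vapply(references, `[[`, character(1), "sequence"))
  names(seqs) <- names(references)
  Biostrings::writeXStringSet(seqs, fasta_file)
  utils::write.table(
    data.frame(marker = names(references),
               frame_offset = vapply(references, `[[`, integer(1), "frame_offset")),
    offsets_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fasta_file)
}

#' Read marker references from FASTA (plus frame-offset sidecar)
#'
#' @param fasta_file FASTA path.
#' @param offsets_file Optional sidecar path as written by
#'   [write_marker_references()]; when missing all offsets default to 0.
#' @return A named list of `marker_reference` objects.
#' @export
read_marker_references <- function(fasta_file,
                                   offsets_file = paste0(fasta_file, ".offsets.tsv")) {
  seqs <- Biostrings::readDNAStringSet(fasta_file)
  offsets <- if (file.exists(offsets_file)) {
    tab <- utils::read.delim(offsets_file, stringsAsFactors = FALSE)
    stats::setNames(tab$frame_offset, tab$marker)
  } else {
    stats::setNames(rep(0L, length(seqs)), names(seqs))
  }
  refs <- lapply(names(seqs), function(nm) {
    structure(list(marker_name = nm,
                   sequence = as.character(seqs[[nm]]),
                   frame_offset = as.integer(offsets[[nm]] %||% 0L)),
              class = "marker_reference")
  })
  names(refs) <- names(seqs)
  refs
}
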