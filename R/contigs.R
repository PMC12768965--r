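#' Read contigs from a FASTA file
#'
#' Reads a (possibly gzipped) multi-record FASTA file and returns the contigs
#' as a named character vector of uppercase DNA sequences. Sequence names are
#' truncated at the first whitespace, matching common assembly conventions.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @return Named character vector of uppercase sequences over `{A,C,G,T,N}`.
#' @export
read_contigs <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  validate_contigs(seqs)
}

#' Write contigs to a FASTA file
#'
#' @param contigs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_contigs <- function(contigs, path, width = 70L) {
  stopifnot(!is.null(names(contigs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(contigs)) {
    writeLines(paste0(">", id), con)
    s <- contigs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Validate a set of contigs
#'
#' Uppercases sequences, checks the alphabet is `{A,C,G,T,N}`, requires
#' non-empty sequences and unique ids.
#'
#' @param contigs Named character vector.
#' @return The validated (uppercased) vector.
#' @export
validate_contigs <- function(contigs) {
  if (is.null(names(contigs)) || any(!nzchar(names(contigs))))
    stop("contigs must be a named character vector with non-empty ids")
  if (anyDuplicated(names(contigs)))
    stop("duplicate contig ids: ",
         paste(unique(names(contigs)[duplicated(names(contigs))]), collapse = ", "))
  contigs <- toupper(contigs)
  if (any(nchar(contigs) < 1L)) stop("empty contig sequence")
  bad <- gsub("[ACGTN]", "", contigs)
  if (any(nzchar(bad))) {
    ch <- substr(bad[nzchar(bad)][1], 1, 1)
    stop("sequence contains character outside {A,C,G,T,N}: '", ch, "'")
  }
  contigs
}

#' Reverse-complement a DNA string
#'
#' @param seq A DNA string over `{A,C,G,T,N}`.
#' @return The reverse complement.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
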