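#' Call genes on a contig with the bundled ORF scanner
#'
#' The bundled caller is a deterministic naive ORF scanner: in each of the six
#' reading frames, an ORF runs from the first start codon (ATG/GTG/TTG) after
#' the previous in-frame stop to the next in-frame stop (stop codon included),
#' with a minimum length of 90 nt. Codons containing N cannot be spanned by a
#' gene. Coordinates are 0-based, half-open, on the forward strand for both
#' strands; the strand is recorded separately. The initiator codon is
#' translated as M regardless of whether it is ATG, GTG or TTG.
#'
#' An external gene caller (for example a Prodigal-compatible one) can be
#' plugged in by supplying `caller`: a function taking the uppercased
#' sequence and returning a data frame with columns `start`, `end`, `strand`
#' following the same coordinate conventions.
#'
#' @param contig A single DNA string (optionally named) over `{A,C,G,T,N}`.
#' @param caller Optional replacement gene caller.
#' @param min_len Minimum ORF length in nt, stop codon included.
#' @return A data frame with columns `contig_id`, `start`, `end`, `strand`,
#'   `nt_seq`, `aa_seq`, sorted by `start`.
#' @examples
#' genes <- call_genes(c(x = paste0("ATG", strrep("AAA", 32), "TAA")))
#' genes$aa_seq  # "M" followed by 32 lysines
#' @export
call_genes <- function(contig, caller = NULL, min_len = 90L) {
  id <- if (!is.null(names(contig))) names(contig)[1] else "contig"
  seq <- validate_contigs(setNames(as.character(contig)[1], id))[[1]]
  coords <- if (is.null(caller)) orf_scan_cpp(seq, as.integer(min_len))
            else caller(seq)
  coords <- as.data.frame(coords)
  if (nrow(coords) == 0L) {
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      nt_seq = character(), aa_seq = character(),
                      stringsAsFactors = FALSE))
  }
  stopifnot(all(coords$start >= 0), all(coords$end <= nchar(seq)),
            all((coords$end - coords$start) %% 3 == 0))
  nt <- substring(seq, coords$start + 1L, coords$end)
  neg <- coords$strand == "-"
  if (any(neg)) nt[neg] <- vapply(nt[neg], revcomp, character(1), USE.NAMES = FALSE)
  aa <- translate_orfs(nt)
  data.frame(contig_id = id, start = coords$start, end = coords$end,
             strand = coords$strand, nt_seq = nt, aa_seq = aa,
             stringsAsFactors = FALSE)
}

# Translate ORF nucleotide sequences (standard code), dropping the trailing
# stop and forcing the initiator residue to M.
translate_orfs <- function(nt) {
  if (length(nt) == 0L) return(character())
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(nt),
                                           no.init.codon = TRUE))
  aa <- sub("\\*$", "", aa)
  substr(aa, 1L, 1L) <- "M"
  aa
}
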