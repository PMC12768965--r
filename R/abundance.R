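#' Read a per-contig read-count table
#'
#' TSV with header columns `sample_id`, `contig_id`, `role` (`phage` or
#' `host`), `mapped_reads`, `contig_length`. Any mapper's idxstats-style
#' output can be converted to this layout.
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_count_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "contig_id", "role", "mapped_reads", "contig_length")
  miss <- setdiff(need, colnames(x))
  if (length(miss)) stop("count table missing columns: ", paste(miss, collapse = ", "))
  stopifnot(all(x$mapped_reads >= 0), all(x$contig_length > 0))
  x
}

#' Length- and library-size-normalized abundances
#'
#' Pools reads and lengths per role within each sample (multi-contig hosts
#' are summed before normalization) and computes, per role,
#' `abundance = reads * 1e6 / library_size / (length / 1e3)` — reads per
#' kilobase per million mapped reads — together with the fraction of the
#' library's reads mapping to that role. The library size is the sum of
#' mapped reads over the sample's records, so fractions over the sample's
#' roles sum to 1.
#'
#' @param counts Count table (see [read_count_table()]) for one or more
#'   samples.
#' @return Data frame `sample_id`, `role`, `mapped_reads`, `total_length`,
#'   `normalized_abundance`, `read_fraction`.
#' @export
abundance_table <- function(counts) {
  stopifnot(nrow(counts) >= 1L)
  rows <- lapply(split(counts, counts$sample_id), function(cs) {
    libsize <- sum(cs$mapped_reads)
    if (libsize == 0) stop("library size 0 in sample ", cs$sample_id[1])
    agg <- do.call(rbind, lapply(split(cs, cs$role), function(r)
      data.frame(sample_id = r$sample_id[1], role = r$role[1],
                 mapped_reads = sum(r$mapped_reads),
                 total_length = sum(r$contig_length))))
    agg$normalized_abundance <- agg$mapped_reads * 1e6 / libsize /
      (agg$total_length / 1e3)
    agg$read_fraction <- agg$mapped_reads / libsize
    agg
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Phage-to-host abundance ratio
#'
#' The ratio of the phage role's normalized abundance to the host's, per
#' sample. Because both abundances are per-base and per-million-reads, a
#' ratio of 1 corresponds to equal per-base coverage — about one phage
#' genome per host genome, the temperate baseline. The log10 ratio is
#' reported alongside. A sample whose host received no reads is reported as
#' `host_not_detected` rather than an infinite ratio.
#'
#' @param abundances Output of [abundance_table()] with both roles present.
#' @return Data frame `sample_id`, `ratio`, `log10_ratio`, `status`.
#' @export
phage_host_ratio <- function(abundances) {
  rows <- lapply(split(abundances, abundances$sample_id), function(ab) {
    ph <- ab[ab$role == "phage", ]
    ho <- ab[ab$role == "host", ]
    if (nrow(ph) != 1L || nrow(ho) != 1L)
      stop("sample ", ab$sample_id[1], " must have exactly one phage and one host role")
    if (ho$normalized_abundance == 0)
      return(data.frame(sample_id = ab$sample_id[1], ratio = NA_real_,
                        log10_ratio = NA_real_, status = "host_not_detected"))
    r <- ph$normalized_abundance / ho$normalized_abundance
    data.frame(sample_id = ab$sample_id[1], ratio = r, log10_ratio = log10(r),
               status = "ok", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
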