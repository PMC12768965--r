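CODONS <- sort(as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                     paste0), c("A", "C", "G", "T"), paste0)))
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
HYDROPHOBIC <- c("A", "C", "F", "I", "L", "M", "V", "W")
FEATURE_SCHEMA_VERSION <- "1"
NEIGHBOR_DIST_CLIP <- 5000L
DENSITY_HALF_WINDOW <- 5000L

#' The per-gene feature schema
#'
#' The fixed, versioned schema of 93 per-gene features used by the triplet
#' classifier: gene length (nt); GC fraction; GC skew (G-C)/(G+C); the 64
#' codon frequencies (computed over all codons of the gene, stop included);
#' the 20 amino-acid frequencies; the hydrophobic-residue fraction
#' (A,C,F,I,L,M,V,W); strand agreement with the previous/next gene (1/0,
#' sentinel 0 at contig ends); intergenic distance to the previous/next gene
#' (bp, negative overlaps floored at 0, clipped at 5,000, sentinel 0 at
#' ends); and local gene density (genes whose midpoints fall within a 10 kb
#' window centred on the gene).
#'
#' @return A data frame with columns `index`, `name`, `description`.
#' @export
feature_schema <- function() {
  n <- c("gene_length", "gc", "gc_skew",
         paste0("codon_", CODONS), paste0("aa_", AA20),
         "hydrophobic_frac", "strand_agree_prev", "strand_agree_next",
         "dist_prev", "dist_next", "gene_density_10kb")
  d <- c("gene length in nt (stop codon included)",
         "fraction of G+C in the coding sequence",
         "(G - C) / (G + C), 0 when no G or C",
         paste0("frequency of codon ", CODONS),
         paste0("frequency of amino acid ", AA20),
         "fraction of hydrophobic residues (A,C,F,I,L,M,V,W)",
         "1 if same strand as previous gene, else 0 (0 for first gene)",
         "1 if same strand as next gene, else 0 (0 for last gene)",
         "bp to previous gene end, floored at 0, clipped at 5000 (0 for first)",
         "bp to next gene start, floored at 0, clipped at 5000 (0 for last)",
         "genes per 10 kb window centred on this gene's midpoint")
  data.frame(index = seq_along(n), name = n, description = d,
             stringsAsFactors = FALSE)
}

#' Fingerprint of the triplet feature schema
#'
#' A hash over the schema version and the ordered triplet feature names.
#' Models refuse to score feature tables produced under a different schema.
#'
#' @return A 16-character hex string.
#' @export
schema_hash <- function() {
  fnv1a_hex_cpp(paste(c(FEATURE_SCHEMA_VERSION, triplet_feature_names()),
                      collapse = ";"))
}

triplet_feature_names <- function() {
  as.vector(vapply(c("g1_", "g2_", "g3_"),
                   function(p) paste0(p, feature_schema()$name),
                   character(nrow(feature_schema()))))
}

#' Compute per-gene feature vectors for one contig
#'
#' Computes the [feature_schema()] feature matrix for the genes of one
#' contig. Neighbour-dependent features (strand agreement, intergenic
#' distances) use sentinel 0 for the first and last gene.
#'
#' @param genes Gene table from [call_genes()] (one contig, sorted by start).
#' @param contig_length Length of the contig in bp (used only by the density
#'   feature's documentation; the window is centred on gene midpoints).
#' @return Numeric matrix, one row per gene, columns named by the schema.
#' @examples
#' g <- call_genes(c(x = paste0("ATG", strrep("GGG", 40), "TAA")))
#' compute_gene_features(g)[, "gc"]
#' @export
compute_gene_features <- function(genes, contig_length = NULL) {
  schema <- feature_schema()$name
  n <- nrow(genes)
  if (n == 0L) {
    m <- matrix(numeric(), 0, length(schema))
    colnames(m) <- schema
    return(m)
  }
  if (any(nchar(genes$nt_seq) < 3L)) stop("gene shorter than one codon")
  dss <- Biostrings::DNAStringSet(genes$nt_seq)
  len <- nchar(genes$nt_seq)
  gcount <- Biostrings::letterFrequency(dss, "G")[, 1]
  ccount <- Biostrings::letterFrequency(dss, "C")[, 1]
  gc <- (gcount + ccount) / len
  skew <- ifelse(gcount + ccount > 0, (gcount - ccount) / (gcount + ccount), 0)
  codon <- Biostrings::oligonucleotideFrequency(dss, width = 3, step = 3)
  codon <- codon[, CODONS, drop = FALSE] / rowSums(codon)
  aas <- Biostrings::AAStringSet(genes$aa_seq)
  aafreq <- Biostrings::letterFrequency(aas, AA20)
  aafreq <- aafreq / pmax(1L, nchar(genes$aa_seq))
  colnames(aafreq) <- AA20
  hydro <- rowSums(aafreq[, HYDROPHOBIC, drop = FALSE])
  same <- if (n > 1L) as.numeric(genes$strand[-1] == genes$strand[-n]) else numeric()
  agree_prev <- c(0, same)
  agree_next <- c(same, 0)
  gap <- if (n > 1L) pmin(pmax(genes$start[-1] - genes$end[-n], 0L),
                          NEIGHBOR_DIST_CLIP) else numeric()
  dist_prev <- c(0, gap)
  dist_next <- c(gap, 0)
  mid <- (genes$start + genes$end) / 2
  density <- vapply(mid, function(m) sum(abs(mid - m) <= DENSITY_HALF_WINDOW),
                    numeric(1))
  m <- cbind(gene_length = len, gc = gc, gc_skew = skew, codon, aafreq,
             hydrophobic_frac = hydro, strand_agree_prev = agree_prev,
             strand_agree_next = agree_next, dist_prev = dist_prev,
             dist_next = dist_next, gene_density_10kb = density)
  colnames(m) <- schema
  if (any(!is.finite(m))) stop("non-finite feature value")
  m
}

#' Build overlapping gene-triplet rows
#'
#' Slides a window of three consecutive genes (stride 1) over the ordered
#' per-gene feature rows of one contig and concatenates each window into a
#' single triplet row. A contig with g genes yields max(0, g - 2) rows.
#'
#' @param rows Per-gene feature matrix from [compute_gene_features()].
#' @param contig_id Contig identifier attached to every row.
#' @param label Optional class label (`"phage"`, `"bacterial"`, `"unlabeled"`).
#' @return Numeric matrix with `3 * ncol(rows)` columns named `g1_*`, `g2_*`,
#'   `g3_*`; attributes `contig_id`, `label`, `first_gene` (0-based index of
#'   each window's first gene).
#' @export
build_triplets <- function(rows, contig_id = "contig", label = "unlabeled") {
  n <- nrow(rows)
  k <- max(0L, n - 2L)
  if (k == 0L) {
    m <- matrix(numeric(), 0, 3L * ncol(rows))
  } else {
    m <- cbind(rows[seq_len(k), , drop = FALSE],
               rows[seq_len(k) + 1L, , drop = FALSE],
               rows[seq_len(k) + 2L, , drop = FALSE])
  }
  colnames(m) <- triplet_feature_names()
  rownames(m) <- NULL
  attr(m, "contig_id") <- rep(contig_id, k)
  attr(m, "label") <- rep(label, k)
  attr(m, "first_gene") <- seq_len(k) - 1L
  m
}

#' Full contig-to-triplet feature pipeline
#'
#' Convenience wrapper: gene calling, per-gene features and triplet rows for
#' a set of contigs, row-bound into one matrix.
#'
#' @param contigs Named character vector of contig sequences.
#' @param label Label attached to every row.
#' @param caller Optional gene caller passed to [call_genes()].
#' @return Triplet feature matrix with attributes `contig_id`, `label`, and
#'   `n_genes` (named per-contig gene counts).
#' @export
contig_triplets <- function(contigs, label = "unlabeled", caller = NULL) {
  contigs <- validate_contigs(contigs)
  n_genes <- integer(length(contigs))
  names(n_genes) <- names(contigs)
  parts <- lapply(names(contigs), function(id) {
    genes <- call_genes(contigs[id], caller = caller)
    n_genes[[id]] <<- nrow(genes)
    build_triplets(compute_gene_features(genes), contig_id = id, label = label)
  })
  m <- do.call(rbind, parts)
  colnames(m) <- triplet_feature_names()
  attr(m, "contig_id") <- unlist(lapply(parts, attr, "contig_id"))
  attr(m, "label") <- rep(label, nrow(m))
  attr(m, "n_genes") <- n_genes
  m
}

#' Write the feature schema sidecar
#'
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_schema <- function(path) {
  write.table(feature_schema(), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
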