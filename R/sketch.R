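#' Bottom-s MinHash sketch of a genome
#'
#' Hashes every canonical k-mer (lexicographic minimum of the k-mer and its
#' reverse complement) with a fixed 64-bit mixing function and keeps the s
#' smallest distinct hash values. K-mers containing N are skipped. Sketches
#' are deterministic: the hash function is fixed, not seeded per run.
#'
#' @param genome A single (optionally named) DNA string of length >= k.
#' @param k K-mer size (default 21).
#' @param s Sketch size (default 1000).
#' @return A `genome_sketch` list: `genome_id`, `k`, `s`, `hashes` (sorted,
#'   strictly increasing numeric), `genome_length`.
#' @export
sketch_genome <- function(genome, k = 21L, s = 1000L) {
  id <- if (!is.null(names(genome))) names(genome)[1] else "genome"
  seq <- validate_contigs(setNames(as.character(genome)[1], id))[[1]]
  if (nchar(seq) < k) stop("genome shorter than k")
  out <- list(genome_id = id, k = as.integer(k), s = as.integer(s),
              hashes = minhash_sketch_cpp(seq, as.integer(k), as.integer(s)),
              genome_length = nchar(seq))
  class(out) <- "genome_sketch"
  out
}

#' Sketch every contig in a set
#'
#' @param contigs Named character vector.
#' @inheritParams sketch_genome
#' @return Named list of `genome_sketch` objects.
#' @export
sketch_genomes <- function(contigs, k = 21L, s = 1000L) {
  contigs <- validate_contigs(contigs)
  sk <- lapply(names(contigs), function(id) sketch_genome(contigs[id], k, s))
  names(sk) <- names(contigs)
  sk
}

#' Jaccard similarity estimated from two sketches
#'
#' The merged bottom-s estimator: among the `min(s, |union|)` smallest hash
#' values of the union of the two sketches, the fraction present in both.
#' Symmetric; equals 1 for identical sketches and 0 for disjoint ones.
#'
#' @param a,b `genome_sketch` objects with matching `k` and `s`.
#' @return Estimated Jaccard index in \[0, 1\].
#' @export
jaccard_estimate <- function(a, b) {
  if (a$k != b$k || a$s != b$s) stop("sketches have mismatched k or s")
  u <- sort(unique(c(a$hashes, b$hashes)))
  if (length(u) == 0L) stop("empty sketches")
  u <- u[seq_len(min(a$s, length(u)))]
  sum(u %in% a$hashes & u %in% b$hashes) / length(u)
}

#' Mash distance from a Jaccard estimate
#'
#' The standard Mash transform `d = -(1/k) * log(2j / (1 + j))`, clamped to
#' \[0, 1\]; j = 0 maps to the cap 1 (the transform diverges there).
#'
#' @param j Jaccard estimate in \[0, 1\].
#' @param k K-mer size used for the sketches.
#' @return Distance in \[0, 1\].
#' @export
mash_distance <- function(j, k = 21L) {
  stopifnot(all(j >= 0 & j <= 1))
  d <- ifelse(j > 0, -(1 / k) * log(2 * j / (1 + j)), 1)
  pmin(pmax(d, 0), 1) + 0  # + 0 normalizes the -0 arising at j = 1
}

#' Mash distance between two sketches
#'
#' @param a,b `genome_sketch` objects.
#' @return Distance in \[0, 1\].
#' @export
sketch_distance <- function(a, b) mash_distance(jaccard_estimate(a, b), a$k)

pairwise_distances <- function(sketches) {
  ids <- names(sketches)
  n <- length(ids)
  if (n < 2L) return(data.frame(a = character(), b = character(),
                                distance = numeric()))
  pairs <- utils::combn(n, 2)
  data.frame(a = ids[pairs[1, ]], b = ids[pairs[2, ]],
             distance = apply(pairs, 2, function(p)
               sketch_distance(sketches[[p[1]]], sketches[[p[2]]])),
             stringsAsFactors = FALSE)
}

#' Build a thresholded phage network
#'
#' Computes all-vs-all Mash distances and connects genomes at distance at
#' most `threshold` (the figure convention is 0.1). Connected components
#' are labelled by their lexicographically smallest member, making
#' component ids deterministic.
#'
#' @param sketches Named list of `genome_sketch` objects.
#' @param threshold Maximum edge distance.
#' @param node_attrs Optional data frame of node attributes keyed by
#'   `genome_id` (for example origin and host genus).
#' @return A `phage_network` list: `nodes` (data frame `genome_id`, `size`,
#'   `component`, plus any attributes), `edges` (data frame `a`, `b`,
#'   `distance`), `threshold`.
#' @export
build_network <- function(sketches, threshold = 0.1, node_attrs = NULL) {
  stopifnot(length(sketches) >= 1L)
  ids <- names(sketches)
  d <- pairwise_distances(sketches)
  edges <- d[d$distance <= threshold, , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges[, c("a", "b")], directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  comp_label <- vapply(split(names(comp), comp), min, character(1))
  nodes <- data.frame(genome_id = ids,
                      size = vapply(sketches, function(s) s$genome_length,
                                    numeric(1)),
                      component = unname(comp_label[as.character(comp[ids])]),
                      stringsAsFactors = FALSE)
  if (!is.null(node_attrs))
    nodes <- merge(nodes, node_attrs, by = "genome_id", all.x = TRUE,
                   sort = FALSE)
  out <- list(nodes = nodes, edges = edges, threshold = threshold)
  class(out) <- "phage_network"
  out
}

#' @export
print.phage_network <- function(x, ...) {
  cat("phage_network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges (d <=", x$threshold, "),",
      length(unique(x$nodes$component)), "components\n")
  invisible(x)
}

#' Cluster genomes into ANI clouds
#'
#' Single-linkage clustering of the graph whose edges connect genomes with
#' estimated ANI (1 - Mash distance) at or above `ani_threshold`. Cluster
#' ids are the lexicographically smallest member, so the clustering is
#' deterministic and order-independent.
#'
#' @param sketches Named list of `genome_sketch` objects.
#' @param ani_threshold Minimum ANI for an edge (default 0.95).
#' @return Named character vector: contig id -> cluster id.
#' @export
ani_cluster <- function(sketches, ani_threshold = 0.95) {
  net <- build_network(sketches, threshold = 1 - ani_threshold)
  setNames(net$nodes$component, net$nodes$genome_id)
}

#' Match candidate genomes against a reference set at two thresholds
#'
#' For each reference genome, counts and lists the candidates within the
#' loose Mash-distance tier (default <= 0.2, "closely associated") and the
#' strict tier (default <= 0.05, "strongly associated"). Strict matches are
#' by construction a subset of loose matches.
#'
#' @param references,candidates Named lists of `genome_sketch` objects.
#' @param loose,strict Distance thresholds, `strict <= loose`.
#' @return Data frame `reference_id`, `n_loose`, `n_strict`, `loose_ids`,
#'   `strict_ids` (comma-separated id strings).
#' @export
match_reference_set <- function(references, candidates, loose = 0.2,
                                strict = 0.05) {
  stopifnot(loose >= 0, loose <= 1, strict >= 0, strict <= loose)
  rows <- lapply(names(references), function(rid) {
    d <- vapply(candidates, function(cs)
      sketch_distance(references[[rid]], cs), numeric(1))
    lo <- names(candidates)[d <= loose]
    st <- names(candidates)[d <= strict]
    data.frame(reference_id = rid, n_loose = length(lo), n_strict = length(st),
               loose_ids = paste(sort(lo), collapse = ","),
               strict_ids = paste(sort(st), collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Total non-overlapping match length
#'
#' Given alignment intervals of one query-subject pair, drops intervals
#' failing the identity/length floors (defaults: >= 90% identity and
#' >= 500 bp) and returns the length of the union of the remaining
#' `[q_start, q_end)` intervals, so repeated or overlapping matches are not
#' double-counted.
#'
#' @param intervals Data frame with columns `q_start`, `q_end` (0-based,
#'   half-open) and `percent_identity`.
#' @param min_identity Identity floor (percent).
#' @param min_length Alignment length floor (bp).
#' @return Total union length in bp.
#' @export
nonoverlapping_match_length <- function(intervals, min_identity = 90,
                                        min_length = 500) {
  if (is.null(intervals) || nrow(intervals) == 0L) return(0L)
  stopifnot(all(intervals$q_start < intervals$q_end))
  keep <- intervals$percent_identity >= min_identity &
    (intervals$q_end - intervals$q_start) >= min_length
  intervals <- intervals[keep, , drop = FALSE]
  if (nrow(intervals) == 0L) return(0L)
  ir <- IRanges::reduce(IRanges::IRanges(start = intervals$q_start + 1L,
                                         end = intervals$q_end))
  sum(IRanges::width(ir))
}

#' Write sketches to a JSON container
#'
#' @param sketches Named list of `genome_sketch` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sketches <- function(sketches, path) {
  obj <- list(format = "bapscan-sketch/1",
              sketches = lapply(unname(sketches), function(s)
                list(genome_id = s$genome_id, k = s$k, s = s$s,
                     genome_length = s$genome_length, hashes = s$hashes)))
  # I(17) keeps 17 significant digits so 53-bit hash values survive exactly
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17)), path)
  invisible(path)
}

#' Read a sketch container written by [write_sketches()]
#'
#' @param path JSON path.
#' @return Named list of `genome_sketch` objects.
#' @export
read_sketches <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  sk <- lapply(obj$sketches, function(s) {
    out <- list(genome_id = s$genome_id, k = as.integer(s$k),
                s = as.integer(s$s), hashes = as.numeric(unlist(s$hashes)),
                genome_length = s$genome_length)
    class(out) <- "genome_sketch"
    out
  })
  names(sk) <- vapply(sk, function(s) s$genome_id, character(1))
  sk
}
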