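CASCADE_LABELS <- c("non_candidate", "bacterial", "plasmid", "temperate",
                    "lytic", "phage_like_undetermined")

#' Length gate for candidate contigs
#'
#' Contigs longer than 1,000,000 bp are flagged as true bacterial
#' chromosomes; contigs shorter than 5,000 bp are too short to be complete
#' phage genomes and are dropped as non-candidates. The 5 kb-1 Mb interval
#' is closed: exactly 5,000 or exactly 1,000,000 bp is a candidate
#' ("exceeding 1,000,000 bp" is read strictly).
#'
#' @param length Contig length(s) in bp.
#' @return Character vector over `{bacterial, non_candidate, candidate}`.
#' @export
length_gate <- function(length) {
  ifelse(length > 1e6, "bacterial",
         ifelse(length < 5e3, "non_candidate", "candidate"))
}

#' Phage-likeness score gate
#'
#' Contigs scoring below the threshold (default 0.8) are excluded; "below"
#' is strict, so a score of exactly 0.8 passes.
#'
#' @param score Score(s) in \[0, 1\].
#' @param threshold Gate threshold.
#' @return Character vector over `{pass, fail}`.
#' @export
phager_gate <- function(score, threshold = 0.8) {
  stopifnot(all(score >= 0 & score <= 1))
  ifelse(score < threshold, "fail", "pass")
}

#' Classify one contig from its reference-database hits
#'
#' Rules, applied in order on a hit table sorted top hit first:
#' 1. *bacterial*: the top `nucleotide_ref` hit has subject length
#'    > 1,200,000 bp and alignment length > 2,100 bp.
#' 2. *plasmid*: any hit whose description contains "plasmid"
#'    (case-insensitive).
#' 3. *phage_db_match*: any hit from a phage database, or any hit whose
#'    description contains "phage" but not "prophage" (case-insensitive;
#'    "prophage" always suppresses the match for that hit).
#' 4. otherwise *no_call*; an empty hit table is a no_call, not an error.
#'
#' @param hits Data frame with columns `subject_id`, `subject_length`,
#'   `alignment_length`, `percent_identity`, `subject_description`,
#'   `source_db` (values `nucleotide_ref` or `phage_db`), sorted so the top
#'   hit is first (bit-score descending, supplied upstream).
#' @return One of `"bacterial"`, `"plasmid"`, `"phage_db_match"`, `"no_call"`.
#' @export
classify_by_hits <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) return("no_call")
  top <- hits[1, ]
  if (identical(top$source_db, "nucleotide_ref") &&
      top$subject_length > 1.2e6 && top$alignment_length > 2100)
    return("bacterial")
  desc <- tolower(hits$subject_description)
  if (any(grepl("plasmid", desc, fixed = TRUE))) return("plasmid")
  is_phage_desc <- grepl("phage", desc, fixed = TRUE) &
    !grepl("prophage", desc, fixed = TRUE)
  if (any(hits$source_db == "phage_db") || any(is_phage_desc))
    return("phage_db_match")
  "no_call"
}

MARKER_CLASSES <- c("terL", "integrase", "transposase", "anti_repressor")

#' Read a lifestyle-marker FASTA
#'
#' Protein FASTA whose headers are `>marker_id class` with `class` one of
#' `terL`, `integrase`, `transposase`, `anti_repressor` (additional classes
#' are accepted and treated as lysogeny markers).
#'
#' @param path FASTA path.
#' @return Data frame `marker`, `class`, `aa_seq`.
#' @export
read_marker_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  parts <- strsplit(names(set), "\\s+")
  data.frame(marker = vapply(parts, `[`, character(1), 1L),
             class = vapply(parts, `[`, character(1), 2L),
             aa_seq = as.character(set), stringsAsFactors = FALSE)
}

aa_kmers <- function(seq, k = 5L) {
  n <- nchar(seq)
  if (n < k) return(character())
  unique(substring(seq, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
}

#' Screen predicted proteins for lifestyle markers
#'
#' Each predicted protein is compared to each marker sequence by amino-acid
#' 5-mer containment: the fraction of the marker's distinct 5-mers present
#' in the protein. A marker class is flagged when any protein reaches the
#' containment floor (default 0.5). A precomputed hit table (columns
#' `gene_id`, `class`) from an external tool such as an HMM search may be
#' supplied instead via `hit_table`.
#'
#' @param aa_seqs Named character vector of predicted protein sequences
#'   (names are gene ids); may be empty.
#' @param marker_ref Marker data frame from [read_marker_fasta()] (or with
#'   the same columns).
#' @param k Amino-acid k-mer size.
#' @param floor Containment floor in \[0, 1\].
#' @param hit_table Optional precomputed marker hits.
#' @return One-row data frame: `has_terL`, `has_integrase`,
#'   `has_transposase`, `has_anti_repressor`, `has_other_lysogeny`, with an
#'   `evidence` attribute (data frame `marker`, `class`, `gene_id`,
#'   `containment`, `method`).
#' @export
screen_markers <- function(aa_seqs, marker_ref = NULL, k = 5L, floor = 0.5,
                           hit_table = NULL) {
  if (is.null(hit_table)) {
    if (is.null(marker_ref) || nrow(marker_ref) == 0L)
      stop("empty marker reference")
    ev <- list()
    if (length(aa_seqs) > 0L) {
      if (is.null(names(aa_seqs))) names(aa_seqs) <- paste0("gene", seq_along(aa_seqs))
      gene_kmers <- lapply(aa_seqs, aa_kmers, k = k)
      for (i in seq_len(nrow(marker_ref))) {
        mk <- aa_kmers(marker_ref$aa_seq[i], k = k)
        if (length(mk) == 0L) next
        cont <- vapply(gene_kmers, function(g) mean(mk %in% g), numeric(1))
        hit <- which(cont >= floor)
        if (length(hit) > 0L)
          ev[[length(ev) + 1L]] <- data.frame(
            marker = marker_ref$marker[i], class = marker_ref$class[i],
            gene_id = names(aa_seqs)[hit], containment = cont[hit],
            method = "kmer_containment", stringsAsFactors = FALSE)
      }
    }
    evidence <- if (length(ev)) do.call(rbind, ev) else
      data.frame(marker = character(), class = character(),
                 gene_id = character(), containment = numeric(),
                 method = character(), stringsAsFactors = FALSE)
  } else {
    evidence <- data.frame(marker = NA_character_, class = hit_table$class,
                           gene_id = hit_table$gene_id, containment = NA_real_,
                           method = "hit_table", stringsAsFactors = FALSE)
  }
  classes <- unique(evidence$class)
  prof <- data.frame(has_terL = "terL" %in% classes,
                     has_integrase = "integrase" %in% classes,
                     has_transposase = "transposase" %in% classes,
                     has_anti_repressor = "anti_repressor" %in% classes,
                     has_other_lysogeny = length(setdiff(classes, MARKER_CLASSES)) > 0L)
  attr(prof, "evidence") <- evidence
  prof
}

#' Propagate temperate status across ANI clusters
#'
#' Any cluster containing even a single integrase-bearing member is labelled
#' temperate as a whole; additional (non-standard) lysogeny marker classes
#' behave like integrase. Contigs absent from the cluster map are treated as
#' singleton clusters.
#'
#' @param clusters Data frame `contig_id`, `cluster_id` (or a named vector).
#' @param profiles Data frame keyed by `contig_id` with at least
#'   `has_integrase` (and optionally `has_other_lysogeny`).
#' @return Character vector of temperate contig ids.
#' @export
propagate_temperate <- function(clusters, profiles) {
  if (!is.data.frame(clusters))
    clusters <- data.frame(contig_id = names(clusters),
                           cluster_id = as.character(clusters))
  tainted_by <- profiles$has_integrase
  if (!is.null(profiles$has_other_lysogeny))
    tainted_by <- tainted_by | profiles$has_other_lysogeny
  tainted_contigs <- profiles$contig_id[tainted_by]
  cl <- setNames(clusters$cluster_id, clusters$contig_id)
  # singletons for contigs missing from the map
  ids <- union(profiles$contig_id, clusters$contig_id)
  cl_full <- cl[ids]
  missing <- is.na(cl_full)
  cl_full[missing] <- paste0("__singleton__", ids[missing])
  names(cl_full) <- ids
  tainted_clusters <- unique(cl_full[names(cl_full) %in% tainted_contigs])
  names(cl_full)[cl_full %in% tainted_clusters]
}

#' Assign phage lifestyle from a marker profile
#'
#' A contig is *temperate* if its cluster is temperate-tainted or it carries
#' an integrase (or another lysogeny marker class); *lytic* if it carries a
#' terminase large subunit (terL) while lacking integrase, transposase and
#' anti-repressor evidence and not being temperate by cluster; otherwise
#' *phage_like_undetermined*.
#'
#' @param profile One-row data frame from [screen_markers()].
#' @param is_temperate_by_cluster Logical.
#' @return One of `"temperate"`, `"lytic"`, `"phage_like_undetermined"`.
#' @export
assign_lifestyle <- function(profile, is_temperate_by_cluster = FALSE) {
  other <- isTRUE(profile$has_other_lysogeny)
  if (is_temperate_by_cluster || profile$has_integrase || other)
    return("temperate")
  if (profile$has_terL && !profile$has_transposase && !profile$has_anti_repressor)
    return("lytic")
  "phage_like_undetermined"
}

#' Run the full classification cascade
#'
#' Applies, in order: the length gate (> 1 Mb bacterial, < 5 kb
#' non-candidate), the phage-likeness score gate (below `threshold`
#' excluded), reference-hit classification (bacterial, then plasmid), and
#' marker-based lifestyle assignment with cluster-wide temperate
#' propagation. Every contig receives exactly one label and the stage that
#' fired.
#'
#' @param contig_lengths Named integer vector of contig lengths (bp).
#' @param scores Data frame `contig_id`, `score` (and optionally `flag`).
#' @param hits Hit table (see [classify_by_hits()]) with a `query_id`
#'   column; rows per query must be ordered top hit first.
#' @param clusters Data frame `contig_id`, `cluster_id`; contigs absent are
#'   singletons.
#' @param profiles Marker profile data frame with a `contig_id` column and
#'   the flags of [screen_markers()]; contigs absent get all-false profiles.
#' @param threshold Score gate (default 0.8).
#' @return Data frame `contig_id`, `label`, `stage`, `cluster_id`, `score`,
#'   with attribute `summary` (named per-label counts).
#' @export
run_cascade <- function(contig_lengths, scores, hits = NULL, clusters = NULL,
                        profiles = NULL, threshold = 0.8) {
  ids <- names(contig_lengths)
  if (is.null(ids) || anyDuplicated(ids)) stop("contig ids missing or duplicated")
  score <- setNames(scores$score, scores$contig_id)[ids]
  if (anyNA(score)) stop("missing score for: ",
                         paste(head(ids[is.na(score)], 3), collapse = ", "))
  if (is.null(profiles))
    profiles <- data.frame(contig_id = character(), has_terL = logical(),
                           has_integrase = logical(), has_transposase = logical(),
                           has_anti_repressor = logical(),
                           has_other_lysogeny = logical())
  if (is.null(clusters))
    clusters <- data.frame(contig_id = character(), cluster_id = character())
  cluster_of <- setNames(as.character(clusters$cluster_id), clusters$contig_id)
  temperate_ids <- propagate_temperate(clusters, profiles)

  label <- stage <- setNames(rep(NA_character_, length(ids)), ids)
  gate1 <- length_gate(contig_lengths)
  label[gate1 == "bacterial"] <- "bacterial"
  label[gate1 == "non_candidate"] <- "non_candidate"
  stage[gate1 != "candidate"] <- "length_gate"

  todo <- ids[is.na(label)]
  fail <- todo[phager_gate(score[todo], threshold) == "fail"]
  label[fail] <- "non_candidate"
  stage[fail] <- "phager_gate"

  todo <- ids[is.na(label)]
  for (id in todo) {
    h <- if (!is.null(hits)) hits[hits$query_id == id, , drop = FALSE] else NULL
    call <- classify_by_hits(h)
    if (call == "bacterial") { label[id] <- "bacterial"; stage[id] <- "hit_bacterial" }
    else if (call == "plasmid") { label[id] <- "plasmid"; stage[id] <- "hit_plasmid" }
  }

  todo <- ids[is.na(label)]
  for (id in todo) {
    prof <- profiles[profiles$contig_id == id, , drop = FALSE]
    if (nrow(prof) == 0L)
      prof <- data.frame(has_terL = FALSE, has_integrase = FALSE,
                         has_transposase = FALSE, has_anti_repressor = FALSE,
                         has_other_lysogeny = FALSE)
    by_cluster <- id %in% temperate_ids
    label[id] <- assign_lifestyle(prof, is_temperate_by_cluster = by_cluster)
    stage[id] <- switch(label[id],
                        temperate = if (by_cluster && !prof$has_integrase &&
                                        !isTRUE(prof$has_other_lysogeny))
                                      "lifestyle_cluster" else "lifestyle_marker",
                        lytic = "lifestyle_marker",
                        phage_like_undetermined = "lifestyle_marker")
  }

  out <- data.frame(contig_id = ids, label = unname(label),
                    stage = unname(stage),
                    cluster_id = unname(cluster_of[ids]),
                    score = unname(score), stringsAsFactors = FALSE)
  attr(out, "summary") <- table(factor(out$label, levels = CASCADE_LABELS))
  out
}

#' Read a reference-hit table
#'
#' TSV with header columns `query_id`, `subject_id`, `subject_length`,
#' `alignment_length`, `percent_identity`, `subject_description`,
#' `source_db` — a BLAST outfmt-6-like table with two added columns, rows
#' per query ordered top hit first.
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_hit_table <- function(path) {
  h <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("query_id", "subject_id", "subject_length", "alignment_length",
            "percent_identity", "subject_description", "source_db")
  miss <- setdiff(need, colnames(h))
  if (length(miss)) stop("hit table missing columns: ", paste(miss, collapse = ", "))
  stopifnot(all(h$alignment_length >= 0),
            all(h$percent_identity >= 0 & h$percent_identity <= 100))
  h
}
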