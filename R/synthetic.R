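SENSE_CODONS <- setdiff(CODONS, c("TAA", "TAG", "TGA"))
STOP_CODONS <- c("TAA", "TAG", "TGA")

# Synthetic lifestyle-marker ORFs (random sense codons, frozen once).
# These are NOT real phage proteins: they exist so the marker-screening and
# lifestyle-rule machinery can be exercised end to end without shipping any
# real gene content.
TOY_MARKER_NT <- c(
  terL = "ATGCACGACATCACTCCCAAGTCGTTGTTGTCTCCCTGTCCGTCGAAGATCGGATGCCGAAATGAAGTATCGCCCATGTTTTTAACTTGCCGGAAACGATATTTAAGTCCTCGTGTCGGGCGGCCGTTCAGGATACCAGGGCAACCGAATACATTATTGAGTTATCACCTCATTTTCCTTGCGGTAAGCCTCTTCAGGAATCTTGCAAGACGGCATCCCCGTGTTCATGGGATCTTATAA",
  integrase = "ATGAGAGAAGTTCGTTGGGAATGCGTCGAAAAACGGGGGGTAGTCGCATGTGGTGCCTTCCGGACTTATGCGGAATCTTTGATTGACCCTTTTGCTCGGCCAGACCACGGCTTAAAGGGGCTCACTGCCAATCCAGTATCTAAAGCCTTGACACCGAGAGTACGTTACGTAGTGCATCGAAGTAGCCGCGCTTTACTCGCAACCCAAGCCGTCTCCATGAGAATAACGCGGTGCTACTAA",
  transposase = "ATGCACTCAGCCCTGAGGTGCCCTAAACGCACAAACTTGCTGATAAACGGTACTTCCCACATTATCGTTGAATGCCCGCGGGTTATGCTTGTTGTTGATGGCGTGTGCAATTATGCCAAGACGCACAGTCTGTTTACACCGTTGAGATCCTGCCAGAGCCATCTCACGGCCCTATCTATGAATATGTGCATAAATTTGGCACAAGCAACGCTAGGCTGTCCAATTCTACTGCAACACTAA",
  anti_repressor = "ATGACCAGGAGATTAAATTTGGCTAAACGACTGAGGCTTCTGAACAGTTTGCGCACCTGCGCTAGTGCAGAGGTCGACGTTTACAGGTTGTGTTGCGGGGAGGAGGCCACTTGCGCGACTGGGGCAATAATGCTGATGCATAACAACTCACCCACCCTGTCTCTTAAGGACCATCAAAATAGGTGTCATGGCTGTAGGGCCAGAACATCGCACAATGATCCTCTTAGCTCGGGCGATTAA"
)

#' Synthetic lifestyle-marker genes
#'
#' Four synthetic marker ORFs (terL, integrase, transposase,
#' anti-repressor): random sense-codon sequences, explicitly not real phage
#' proteins, used to exercise marker screening and the lifestyle rules.
#'
#' @return Named character vector of nucleotide ORF sequences
#'   (ATG ... stop).
#' @export
toy_marker_genes <- function() TOY_MARKER_NT

#' Synthetic marker reference table
#'
#' The translations of [toy_marker_genes()] in the layout expected by
#' [screen_markers()].
#'
#' @return Data frame `marker`, `class`, `aa_seq`.
#' @export
toy_marker_ref <- function() {
  nt <- toy_marker_genes()
  data.frame(marker = paste0(names(nt), "_synthetic"), class = names(nt),
             aa_seq = translate_orfs(unname(nt)), stringsAsFactors = FALSE)
}

codon_gc_fraction <- function(codons = CODONS) {
  vapply(strsplit(codons, ""), function(b) mean(b %in% c("G", "C")), numeric(1))
}

# Reweight codon probabilities by exp(t * gc_codon) so the expected GC of a
# sampled codon hits the target; solved by uniroot, deterministic.
gc_calibrate <- function(probs, target) {
  gcf <- codon_gc_fraction(names(probs))
  f <- function(t) {
    w <- probs * exp(t * gcf)
    sum(w / sum(w) * gcf) - target
  }
  t <- stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
  w <- probs * exp(t * gcf)
  w / sum(w)
}

#' A synthetic genome composition model
#'
#' Two default compositional classes emulate the signal a phage-likeness
#' classifier exploits: `phage_like` (GC 0.42, denser genes, shorter
#' intergenic gaps, strong strand coherence) and `host_like` (GC 0.52,
#' sparser genes, longer gaps, weaker strand coherence). Codon usage is a
#' GC-consistent base distribution perturbed by a model-specific, fixed-seed
#' Dirichlet draw whose spread is set by `codon_jitter`; after perturbation
#' the table is recalibrated so expected codon GC still matches `gc`. The
#' jitter makes the two classes differ in codon usage beyond GC alone; 0
#' disables it.
#'
#' @param name `"phage_like"` or `"host_like"`.
#' @param gc GC target in (0, 1); default 0.42 / 0.52 by class.
#' @param codon_jitter Spread of the codon-usage perturbation (>= 0).
#' @param gene_len_meanlog,gene_len_sdlog Log-normal gene length (nt).
#' @param gap_mean Mean intergenic gap (bp, geometric).
#' @param strand_forward_prob Per-gene probability of the forward strand.
#' @return A `composition_model` list.
#' @export
composition_model <- function(name = c("phage_like", "host_like"),
                              gc = NULL, codon_jitter = 0.5,
                              gene_len_meanlog = log(800),
                              gene_len_sdlog = 0.3,
                              gap_mean = NULL,
                              strand_forward_prob = NULL) {
  name <- match.arg(name)
  defaults <- list(
    phage_like = list(gc = 0.42, gap_mean = 40, fwd = 0.95, pseed = 101L),
    host_like = list(gc = 0.52, gap_mean = 150, fwd = 0.75, pseed = 202L))
  d <- defaults[[name]]
  if (is.null(gc)) gc <- d$gc
  if (is.null(gap_mean)) gap_mean <- d$gap_mean
  if (is.null(strand_forward_prob)) strand_forward_prob <- d$fwd
  stopifnot(gc > 0, gc < 1, codon_jitter >= 0)
  base_probs <- setNames(rep(1, length(SENSE_CODONS)), SENSE_CODONS)
  base_probs <- gc_calibrate(base_probs / sum(base_probs), gc)
  if (codon_jitter > 0) {
    # log-normal multiplicative jitter: sdlog = codon_jitter, so the knob is
    # directly the log-scale spread of per-codon usage between the classes
    pert <- withr::with_seed(d$pseed,
                             exp(stats::rnorm(length(SENSE_CODONS),
                                              0, codon_jitter)))
    probs <- base_probs * pert
    probs <- gc_calibrate(probs / sum(probs), gc)
  } else {
    probs <- base_probs
  }
  out <- list(name = name, gc = gc, codon_probs = probs,
              codon_jitter = codon_jitter,
              gene_len_meanlog = gene_len_meanlog,
              gene_len_sdlog = gene_len_sdlog, gap_mean = gap_mean,
              strand_forward_prob = strand_forward_prob)
  class(out) <- "composition_model"
  out
}

sample_bases <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a synthetic genome with known gene coordinates
#'
#' Alternates intergenic gaps (geometric length, GC-matched random bases)
#' with genes: an ATG start, codons drawn from the model's codon table, and
#' a sampled stop codon. Reverse-strand genes are inserted as the reverse
#' complement of the generated ORF. The true gene coordinates are returned
#' so feature extraction can be tested against ground truth. Deterministic
#' per seed.
#'
#' @param model A [composition_model()].
#' @param length Target genome length in bp (>= 1,000).
#' @param seed Integer seed.
#' @param id Contig id (default derived from model name and seed).
#' @return A `synthetic_genome` list: `id`, `sequence`, `genes` (data frame
#'   `start`, `end`, `strand`, 0-based half-open), `model`, `seed`.
#' @export
generate_genome <- function(model, length, seed, id = NULL) {
  if (length < 1000) stop("genome length must be >= 1,000 bp")
  if (is.null(id)) id <- paste0(model$name, "_s", seed)
  withr::with_seed(seed, {
    parts <- character()
    starts <- ends <- integer()
    strands <- character()
    pos <- 0L
    repeat {
      gap <- stats::rgeom(1, 1 / (model$gap_mean + 1))
      n_codons <- max(40L, round(stats::rlnorm(1, model$gene_len_meanlog,
                                               model$gene_len_sdlog) / 3))
      gene_nt <- 3L * n_codons + 6L
      if (pos + gap + gene_nt > length) break
      if (gap > 0L) parts <- c(parts, sample_bases(gap, model$gc))
      orf <- paste0("ATG",
                    paste(sample(SENSE_CODONS, n_codons, replace = TRUE,
                                 prob = model$codon_probs), collapse = ""),
                    sample(STOP_CODONS, 1))
      strand <- if (stats::runif(1) < model$strand_forward_prob) "+" else "-"
      parts <- c(parts, if (strand == "+") orf else revcomp(orf))
      starts <- c(starts, pos + gap)
      ends <- c(ends, pos + gap + gene_nt)
      strands <- c(strands, strand)
      pos <- pos + gap + gene_nt
    }
    if (pos < length) parts <- c(parts, sample_bases(length - pos, model$gc))
  })
  out <- list(id = id, sequence = paste(parts, collapse = ""),
              genes = data.frame(start = starts, end = ends, strand = strands,
                                 stringsAsFactors = FALSE),
              model = model$name, seed = as.integer(seed))
  class(out) <- "synthetic_genome"
  out
}

#' Generate a two-class synthetic corpus
#'
#' @param n_per_class Genomes per class.
#' @param length Genome length in bp.
#' @param seed Base seed; genome i of class c uses `seed * 1000 + offset`.
#' @param phage_model,host_model Composition models.
#' @return List `pos`, `neg`: named character vectors of sequences.
#' @export
generate_corpus <- function(n_per_class, length = 20000L, seed = 1L,
                            phage_model = composition_model("phage_like"),
                            host_model = composition_model("host_like")) {
  gen <- function(model, offset, prefix) {
    g <- lapply(seq_len(n_per_class), function(i)
      generate_genome(model, length, seed * 1000L + offset + i,
                      id = sprintf("%s_%03d", prefix, i)))
    setNames(vapply(g, function(x) x$sequence, character(1)),
             vapply(g, function(x) x$id, character(1)))
  }
  list(pos = gen(phage_model, 0L, "phage"),
       neg = gen(host_model, 500L, "host"))
}

#' Implant a marker gene into a synthetic genome
#'
#' Inserts a marker ORF at a position on a gene boundary (not inside any
#' existing gene); downstream gene coordinates shift by the marker length.
#' The marker is recoverable by [screen_markers()] on the called genes.
#'
#' @param genome A `synthetic_genome`.
#' @param marker_nt Marker ORF (nucleotides, ATG ... stop), e.g. one of
#'   [toy_marker_genes()].
#' @param position Insertion point (0-based); defaults to the end of the
#'   first gene.
#' @param marker_name Recorded marker name.
#' @return The modified `synthetic_genome`; the marker's row in `genes`
#'   carries its name in a `marker` column.
#' @export
implant_marker <- function(genome, marker_nt, position = NULL,
                           marker_name = "marker") {
  L <- nchar(genome$sequence)
  if (is.null(position))
    position <- if (nrow(genome$genes) > 0L) genome$genes$end[1] else 0L
  if (position < 0L || position > L) stop("position out of bounds")
  inside <- genome$genes$start < position & position < genome$genes$end
  if (any(inside)) stop("position falls inside an existing gene")
  w <- nchar(marker_nt)
  genome$sequence <- paste0(substr(genome$sequence, 1, position), marker_nt,
                            substring(genome$sequence, position + 1))
  genes <- genome$genes
  if (!"marker" %in% colnames(genes)) genes$marker <- NA_character_
  shift <- genes$start >= position
  genes$start[shift] <- genes$start[shift] + w
  genes$end[shift] <- genes$end[shift] + w
  genes <- rbind(genes, data.frame(start = position, end = position + w,
                                   strand = "+", marker = marker_name,
                                   stringsAsFactors = FALSE))
  genome$genes <- genes[order(genes$start), ]
  rownames(genome$genes) <- NULL
  genome
}

#' Simulate mapped-read counts at known copy numbers
#'
#' Allocates `libsize` reads multinomially across contigs with probability
#' proportional to `copy_number * length`, emulating even per-base coverage
#' at the given genome copy ratios.
#'
#' @param truth Data frame `contig_id`, `role`, `length`, `copy_number`.
#' @param libsize Total reads (> 0).
#' @param seed Integer seed.
#' @param sample_id Sample label for the output.
#' @return Count table as in [read_count_table()].
#' @export
simulate_counts <- function(truth, libsize, seed, sample_id = "sample1") {
  if (libsize <= 0) stop("libsize must be positive")
  stopifnot(all(truth$copy_number > 0), all(truth$length > 0))
  p <- truth$copy_number * truth$length
  reads <- withr::with_seed(seed,
                            as.vector(stats::rmultinom(1, libsize, p / sum(p))))
  data.frame(sample_id = sample_id, contig_id = truth$contig_id,
             role = truth$role, mapped_reads = reads,
             contig_length = truth$length, stringsAsFactors = FALSE)
}

# A sequence with no ORF >= 90 nt in any frame on either strand: "TTAA"
# repeats put a stop codon in every reading frame within 12 bp, and the
# motif is its own reverse complement.
orf_free_sequence <- function(length) {
  substr(strrep("TTAA", ceiling(length / 4)), 1, length)
}

#' Build the 12-contig cascade fixture suite
#'
#' A seeded suite covering every branch of the classification cascade:
#' a > 1 Mb contig (bacterial by length), a < 5 kb contig (non-candidate),
#' a low-scoring contig (score gate), a bacterial reference hit, a
#' "plasmid"-keyword hit, a "prophage"-keyword trap, a phage-database match
#' with terL (lytic), terL + integrase (temperate), an integrase
#' cluster-propagation pair, terL + transposase (undetermined), and an
#' ORF-free contig with too few genes. Marker profiles are computed by
#' actually calling genes and screening the implanted synthetic markers,
#' so the fixture closes the loop from sequence to label. Expected labels
#' are recorded alongside. Byte-identical under a fixed seed.
#'
#' @param seed Integer seed (default 7).
#' @return A `fixture_suite` list: `contigs`, `scores`, `hits`, `clusters`,
#'   `profiles`, `expected` (data frame `contig_id`, `label`, `stage`),
#'   `seed`.
#' @export
make_fixture_suite <- function(seed = 7L) {
  ph <- composition_model("phage_like")
  ho <- composition_model("host_like")
  mk <- toy_marker_genes()
  g <- function(model, len, i) generate_genome(model, len, seed * 100L + i)
  plant <- function(genome, classes) {
    pos <- genome$genes$end[1]
    for (cl in classes) {
      genome <- implant_marker(genome, mk[[cl]], position = pos,
                               marker_name = cl)
      pos <- pos + nchar(mk[[cl]])
    }
    genome
  }
  genomes <- list(
    c01_megacontig = g(ho, 1020000L, 1L),
    c02_short = g(ph, 3000L, 2L),
    c03_lowscore = g(ho, 12000L, 3L),
    c04_bact_hit = g(ho, 12000L, 4L),
    c05_plasmid_hit = g(ho, 12000L, 5L),
    c06_prophage_trap = g(ph, 12000L, 6L),
    c07_lytic = plant(g(ph, 15000L, 7L), "terL"),
    c08_temperate = plant(g(ph, 15000L, 8L), c("terL", "integrase")),
    c09_cluster_integrase = plant(g(ph, 15000L, 9L), "integrase"),
    c10_cluster_partner = plant(g(ph, 15000L, 10L), "terL"),
    c11_transposase = plant(g(ph, 15000L, 11L), c("terL", "transposase")),
    c12_few_genes = list(id = "c12_few_genes",
                         sequence = orf_free_sequence(6000L),
                         genes = data.frame(start = integer(), end = integer(),
                                            strand = character())))
  contigs <- vapply(genomes, function(x) x$sequence, character(1))
  names(contigs) <- names(genomes)

  scores <- data.frame(
    contig_id = names(contigs),
    score = c(0.55, 0.85, 0.35, 0.9, 0.88, 0.92, 0.97, 0.96, 0.95, 0.94,
              0.93, 0),
    flag = c(rep("ok", 11), "too_few_genes"), stringsAsFactors = FALSE)

  hits <- data.frame(
    query_id = c("c04_bact_hit", "c05_plasmid_hit", "c06_prophage_trap",
                 "c07_lytic"),
    subject_id = c("NZ_BIG001", "NC_PLAS01", "NC_PRO01", "PHDB_S16"),
    subject_length = c(1500000L, 90000L, 45000L, 160000L),
    alignment_length = c(3000L, 4000L, 2500L, 12000L),
    percent_identity = c(97.5, 96.0, 95.0, 98.2),
    subject_description = c("Escherichia coli chromosome, complete genome",
                            "Salmonella enterica plasmid pSLT",
                            "Escherichia prophage region",
                            "Salmonella phage S16"),
    source_db = c("nucleotide_ref", "nucleotide_ref", "nucleotide_ref",
                  "phage_db"), stringsAsFactors = FALSE)

  clusters <- data.frame(
    contig_id = c("c07_lytic", "c08_temperate", "c09_cluster_integrase",
                  "c10_cluster_partner", "c11_transposase"),
    cluster_id = c("CL_A", "CL_B", "CL_C", "CL_C", "CL_D"),
    stringsAsFactors = FALSE)

  ref <- toy_marker_ref()
  profiles <- do.call(rbind, lapply(names(contigs), function(id) {
    genes <- call_genes(contigs[id])
    prof <- screen_markers(setNames(genes$aa_seq,
                                    sprintf("%s_g%d", id, seq_len(nrow(genes)))),
                           marker_ref = ref)
    cbind(data.frame(contig_id = id, stringsAsFactors = FALSE), prof)
  }))

  expected <- data.frame(
    contig_id = names(contigs),
    label = c("bacterial", "non_candidate", "non_candidate", "bacterial",
              "plasmid", "phage_like_undetermined", "lytic", "temperate",
              "temperate", "temperate", "phage_like_undetermined",
              "non_candidate"),
    stage = c("length_gate", "length_gate", "phager_gate", "hit_bacterial",
              "hit_plasmid", "lifestyle_marker", "lifestyle_marker",
              "lifestyle_marker", "lifestyle_marker", "lifestyle_cluster",
              "lifestyle_marker", "phager_gate"),
    stringsAsFactors = FALSE)

  out <- list(contigs = contigs, scores = scores, hits = hits,
              clusters = clusters, profiles = profiles, expected = expected,
              seed = as.integer(seed))
  class(out) <- "fixture_suite"
  out
}

#' Write a fixture suite to a directory
#'
#' Writes `contigs.fasta`, `scores.tsv`, `hits.tsv`, `clusters.tsv`,
#' `profiles.tsv` and `expected_labels.tsv`.
#'
#' @param suite A `fixture_suite` from [make_fixture_suite()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture_suite <- function(suite, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_contigs(suite$contigs, file.path(dir, "contigs.fasta"))
  tsv <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  tsv(suite$scores, "scores.tsv")
  tsv(suite$hits, "hits.tsv")
  tsv(suite$clusters, "clusters.tsv")
  tsv(suite$profiles, "profiles.tsv")
  tsv(suite$expected, "expected_labels.tsv")
  invisible(dir)
}
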