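# Independent oracles and small generators shared across the test files.
# Everything here is deliberately brute-force and kept separate from the
# implementation paths it checks.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Exact canonical k-mer set by direct enumeration (lexicographic min of
# k-mer and reverse complement, N-containing k-mers dropped).
canonical_kmer_set <- function(seq, k = 21L) {
  n <- nchar(seq)
  if (n < k) return(character())
  km <- substring(seq, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  rc_all <- substring(revcomp(seq), seq_len(n - k + 1L),
                      seq_len(n - k + 1L) + k - 1L)
  rc <- rev(rc_all)
  keep <- !grepl("N", km, fixed = TRUE)
  unique(pmin(km[keep], rc[keep]))
}

# Exact Jaccard index on full canonical k-mer sets.
exact_jaccard <- function(a, b, k = 21L) {
  sa <- canonical_kmer_set(a, k)
  sb <- canonical_kmer_set(b, k)
  length(intersect(sa, sb)) / length(union(sa, sb))
}

# Per-base bitmap union length (0-based half-open intervals).
bitmap_union_length <- function(q_start, q_end) {
  if (length(q_start) == 0L) return(0L)
  v <- logical(max(q_end))
  for (i in seq_along(q_start)) v[(q_start[i] + 1L):q_end[i]] <- TRUE
  sum(v)
}

# Brute-force Mann-Whitney AUC: enumerate all positive/negative pairs,
# ties count one half.
brute_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# Seeded per-base substitution mutation.
mutate_seq <- function(seq, rate, seed) {
  withr::with_seed(seed, {
    b <- strsplit(seq, "")[[1]]
    hit <- which(runif(length(b)) < rate)
    for (i in hit) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
    paste(b, collapse = "")
  })
}

# A small trained model shared across test files (built once per run).
.shared_cache <- new.env(parent = emptyenv())

shared_small_corpus <- function() {
  if (is.null(.shared_cache$corpus)) {
    raw <- generate_corpus(25, length = 15000L, seed = 11L)
    .shared_cache$raw <- raw
    .shared_cache$corpus <- build_training_corpus(raw$pos, raw$neg)
  }
  .shared_cache$corpus
}

shared_small_model <- function() {
  if (is.null(.shared_cache$model))
    .shared_cache$model <- train_phager(shared_small_corpus(), seed = 11L)
  .shared_cache$model
}
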