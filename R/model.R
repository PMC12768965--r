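PHAGER_VERSION <- "bapscan-phager/0.1"

#' Excise intervals from a genome sequence
#'
#' Removes the union of 0-based half-open intervals (for example prophage
#' regions reported by an external prophage finder) from a genome and
#' concatenates the remaining segments. The returned sequence carries a
#' `coord_map` attribute: a data frame mapping each kept segment to its
#' original coordinates (`new_start`, `new_end`, `old_start`, `old_end`).
#'
#' @param genome A single (optionally named) DNA string.
#' @param regions Two-column matrix or data frame of `start`, `end` (0-based,
#'   half-open) intervals; may overlap.
#' @return The masked sequence (named as input) with attribute `coord_map`.
#' @export
mask_regions <- function(genome, regions = NULL) {
  id <- if (!is.null(names(genome))) names(genome)[1] else "genome"
  seq <- as.character(genome)[1]
  L <- nchar(seq)
  if (is.null(regions) || NROW(regions) == 0L) {
    out <- setNames(seq, id)
    attr(out, "coord_map") <- data.frame(new_start = 0L, new_end = L,
                                         old_start = 0L, old_end = L)
    return(out)
  }
  regions <- as.data.frame(regions)
  colnames(regions)[1:2] <- c("start", "end")
  if (any(regions$start < 0 | regions$end > L | regions$start >= regions$end))
    stop("mask region out of bounds or empty")
  ir <- IRanges::reduce(IRanges::IRanges(start = regions$start + 1L,
                                         end = regions$end))
  keep <- IRanges::setdiff(IRanges::IRanges(1L, L), ir)
  if (length(keep) == 0L) {
    warning("mask regions cover the whole genome")
    out <- setNames("", id)
    attr(out, "coord_map") <- data.frame(new_start = integer(),
                                         new_end = integer(),
                                         old_start = integer(),
                                         old_end = integer())
    return(out)
  }
  pieces <- substring(seq, IRanges::start(keep), IRanges::end(keep))
  w <- IRanges::width(keep)
  new_end <- cumsum(w)
  out <- setNames(paste(pieces, collapse = ""), id)
  attr(out, "coord_map") <- data.frame(new_start = new_end - w,
                                       new_end = new_end,
                                       old_start = IRanges::start(keep) - 1L,
                                       old_end = IRanges::end(keep))
  out
}

#' Sample genome fragments matching a length distribution
#'
#' Draws `n` contiguous fragments from a (prophage-masked) bacterial genome
#' with lengths resampled from an empirical length distribution — typically
#' the lengths of the positive phage genomes — so negatives and positives
#' span the same size range. Fragments longer than the genome are clipped to
#' the full genome and flagged.
#'
#' @param genome A single (optionally named) DNA string.
#' @param lengths Numeric vector: the empirical length distribution to
#'   resample from.
#' @param n Number of fragments.
#' @param seed Integer seed; fragment coordinates are deterministic given it.
#' @return Named character vector of `n` fragments (ids
#'   `<genome>_frag<i>`), with attributes `coords` (data frame `start`,
#'   `end`) and `clipped` (logical vector).
#' @export
sample_negative_fragments <- function(genome, lengths, n, seed) {
  if (n <= 0) stop("n must be positive")
  if (length(lengths) == 0L || any(lengths < 1)) stop("invalid length distribution")
  id <- if (!is.null(names(genome))) names(genome)[1] else "genome"
  seq <- as.character(genome)[1]
  L <- nchar(seq)
  withr::with_seed(seed, {
    want <- as.integer(lengths)[sample.int(length(lengths), n, replace = TRUE)]
    clipped <- want > L
    take <- pmin(want, L)
    start <- vapply(take, function(w) {
      if (w >= L) 0L else sample.int(L - w + 1L, 1L) - 1L
    }, integer(1))
  })
  frags <- substring(seq, start + 1L, start + take)
  names(frags) <- sprintf("%s_frag%d", id, seq_len(n))
  attr(frags, "coords") <- data.frame(start = start, end = start + take)
  attr(frags, "clipped") <- clipped
  frags
}

#' Assemble a triplet training corpus
#'
#' Extracts triplet feature rows from positive (phage) and negative
#' (bacterial-fragment) contigs and bundles them with labels and provenance.
#' A contig id may not appear in both classes.
#'
#' @param pos,neg Named character vectors of contig sequences.
#' @param caller Optional gene caller passed through to [call_genes()].
#' @return A `phager_corpus` list: `x` (feature matrix), `y` (1 = phage),
#'   `contig_id`, `schema_hash`.
#' @export
build_training_corpus <- function(pos, neg, caller = NULL) {
  both <- intersect(names(pos), names(neg))
  if (length(both) > 0L)
    stop("contig ids in both classes: ", paste(head(both, 3), collapse = ", "))
  mp <- contig_triplets(pos, label = "phage", caller = caller)
  mn <- contig_triplets(neg, label = "bacterial", caller = caller)
  corpus <- list(x = rbind(mp, mn),
                 y = c(rep(1L, nrow(mp)), rep(0L, nrow(mn))),
                 contig_id = c(attr(mp, "contig_id"), attr(mn, "contig_id")),
                 schema_hash = schema_hash())
  class(corpus) <- "phager_corpus"
  corpus
}

#' Default phage-classifier hyperparameters
#'
#' 500 boosting rounds, maximum depth 8, learning rate 0.05, binary log-loss,
#' early stopping (30 rounds) on a seeded 10% validation split, single
#' thread. Defaults are recorded in the model file.
#'
#' @param ... Overrides.
#' @return Named list of hyperparameters.
#' @export
phager_hyperparams <- function(...) {
  hp <- list(nrounds = 500L, max_depth = 8L, eta = 0.05,
             objective = "binary:logistic", early_stopping_rounds = 30L,
             validation_fraction = 0.1, max_neg_ratio = 3, nthread = 1L)
  utils::modifyList(hp, list(...))
}

#' Train the gradient-boosted triplet classifier
#'
#' Trains a boosted-tree binary classifier (xgboost, binary log-loss) on
#' triplet feature rows. Negatives are downsampled (seeded) to at most
#' `max_neg_ratio` times the positives; 10% of the remaining rows form a
#' validation split for early stopping. With `nthread = 1` training is
#' deterministic given the seed.
#'
#' @param corpus A `phager_corpus` from [build_training_corpus()], or a list
#'   with elements `x`, `y`, `contig_id`.
#' @param hyperparams See [phager_hyperparams()].
#' @param seed Integer seed for downsampling, the validation split and tree
#'   construction.
#' @return A `phager_model` object.
#' @export
train_phager <- function(corpus, hyperparams = phager_hyperparams(), seed = 1L) {
  x <- corpus$x; y <- corpus$y
  if (length(unique(y)) < 2L) {
    missing <- if (all(y == 1L)) "bacterial" else "phage"
    stop("training corpus has no ", missing, " rows")
  }
  hp <- hyperparams
  withr::with_seed(seed, {
    pos <- which(y == 1L)
    neg <- which(y == 0L)
    if (length(neg) > hp$max_neg_ratio * length(pos))
      neg <- sort(sample(neg, hp$max_neg_ratio * length(pos)))
    keep <- c(pos, neg)
    x <- x[keep, , drop = FALSE]; y <- y[keep]
    n_val <- max(1L, floor(hp$validation_fraction * length(y)))
    val <- sort(sample(length(y), n_val))
  })
  dtrain <- xgboost::xgb.DMatrix(x[-val, , drop = FALSE], label = y[-val],
                                 nthread = hp$nthread)
  dval <- xgboost::xgb.DMatrix(x[val, , drop = FALSE], label = y[val],
                               nthread = hp$nthread)
  params <- list(objective = hp$objective, max_depth = hp$max_depth,
                 eta = hp$eta, nthread = hp$nthread, seed = seed,
                 eval_metric = "logloss")
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = hp$nrounds,
                                evals = list(val = dval),
                                early_stopping_rounds = hp$early_stopping_rounds,
                                verbose = 0)
  model <- list(raw = xgboost::xgb.save.raw(booster),
                schema_hash = if (!is.null(corpus$schema_hash)) corpus$schema_hash
                              else schema_hash(),
                seed = as.integer(seed), hyperparams = hp,
                version = PHAGER_VERSION,
                n_pos = sum(y == 1L), n_neg = sum(y == 0L))
  class(model) <- "phager_model"
  model
}

booster_of <- function(model) xgboost::xgb.load.raw(model$raw)

#' @export
print.phager_model <- function(x, ...) {
  cat("phager_model", x$version, "\n",
      " schema:", x$schema_hash, " seed:", x$seed, "\n",
      " trained on", x$n_pos, "phage /", x$n_neg, "bacterial triplets\n")
  invisible(x)
}

#' Score triplet rows with a trained model
#'
#' @param model A `phager_model`.
#' @param triplets Triplet feature matrix (schema must match the model's).
#' @return Numeric vector of per-triplet phage probabilities in \[0, 1\].
#' @export
predict_triplets <- function(model, triplets) {
  if (!identical(model$schema_hash, schema_hash()))
    stop("feature schema hash mismatch: model ", model$schema_hash,
         " vs current ", schema_hash())
  if (nrow(triplets) == 0L) return(numeric())
  stats::predict(booster_of(model),
                 xgboost::xgb.DMatrix(triplets, nthread = model$hyperparams$nthread))
}

#' Aggregate triplet probabilities into a contig score
#'
#' The contig-level phage-likeness score is the arithmetic mean of the
#' per-triplet probabilities; contigs with fewer than three genes have no
#' triplets and score 0 with flag `too_few_genes`.
#'
#' @param probs Numeric vector of triplet probabilities.
#' @return List with `score` and `flag`.
#' @export
aggregate_triplet_scores <- function(probs) {
  if (length(probs) == 0L) return(list(score = 0, flag = "too_few_genes"))
  list(score = mean(probs), flag = "ok")
}

#' Score contigs for phage-likeness
#'
#' Runs the full pipeline — gene calling, per-gene features, overlapping
#' triplets, model prediction, mean aggregation — and returns one score per
#' contig.
#'
#' @param model A `phager_model`.
#' @param contigs Named character vector of contig sequences.
#' @param caller Optional gene caller.
#' @return Data frame `contig_id`, `score`, `n_triplets`, `flag`.
#' @export
score_contigs <- function(model, contigs, caller = NULL) {
  contigs <- validate_contigs(contigs)
  rows <- lapply(names(contigs), function(id) {
    trip <- contig_triplets(contigs[id], caller = caller)
    p <- predict_triplets(model, trip)
    agg <- aggregate_triplet_scores(p)
    data.frame(contig_id = id, score = agg$score, n_triplets = length(p),
               flag = agg$flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with midrank tie handling: ties between a
#' positive and a negative count 1/2, so a constant score gives AUC 0.5.
#'
#' @param scores Numeric scores.
#' @param labels Logical or 0/1; `TRUE`/1 marks the positive class.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a model on labelled contigs
#'
#' Scores the contigs and reports contig-level AUC plus precision, recall
#' and confusion counts at each threshold (0.8, the cascade's gate, is
#' always included).
#'
#' @param model A `phager_model`.
#' @param contigs Named character vector.
#' @param labels Character vector (`"phage"` / `"bacterial"`) parallel to
#'   `contigs`, or named.
#' @param thresholds Score thresholds to tabulate.
#' @return List with `auc`, `scores` (data frame) and `metrics` (data frame
#'   with one row per threshold).
#' @export
evaluate_model <- function(model, contigs, labels, thresholds = c(0.5, 0.8)) {
  if (length(contigs) == 0L) stop("no contigs to evaluate")
  if (!is.null(names(labels))) labels <- labels[names(contigs)]
  stopifnot(all(labels %in% c("phage", "bacterial")))
  sc <- score_contigs(model, contigs)
  sc$label <- labels
  if (!0.8 %in% thresholds) thresholds <- sort(c(thresholds, 0.8))
  pos <- sc$label == "phage"
  metrics <- do.call(rbind, lapply(thresholds, function(t) {
    call_pos <- sc$score >= t
    tp <- sum(call_pos & pos); fp <- sum(call_pos & !pos)
    fn <- sum(!call_pos & pos); tn <- sum(!call_pos & !pos)
    data.frame(threshold = t, tp = tp, fp = fp, fn = fn, tn = tn,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = tp / (tp + fn))
  }))
  list(auc = auc_score(sc$score, pos), scores = sc, metrics = metrics)
}

#' Write a trained model to a single-file archive
#'
#' The model file is JSON: base64-encoded xgboost raw bytes plus the feature
#' schema (names and hash), hyperparameters, training seed and version. A
#' reloaded model reproduces predictions bit for bit.
#'
#' @param model A `phager_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phager_model <- function(model, path) {
  obj <- list(version = model$version,
              schema_hash = model$schema_hash,
              feature_names = triplet_feature_names(),
              seed = model$seed,
              hyperparams = model$hyperparams,
              n_pos = model$n_pos, n_neg = model$n_neg,
              booster_b64 = jsonlite::base64_enc(as.raw(model$raw)))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17)), path)
  invisible(path)
}

#' Read a model archive written by [write_phager_model()]
#'
#' @param path Model file path.
#' @return A `phager_model`.
#' @export
read_phager_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  model <- list(raw = jsonlite::base64_dec(obj$booster_b64),
                schema_hash = obj$schema_hash,
                seed = as.integer(obj$seed),
                hyperparams = obj$hyperparams,
                version = obj$version,
                n_pos = obj$n_pos, n_neg = obj$n_neg)
  class(model) <- "phager_model"
  model
}
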