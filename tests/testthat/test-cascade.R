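test_that("length gate applies the documented boundary conventions", {
  expect_equal(length_gate(1200000), "bacterial")
  expect_equal(length_gate(4000), "non_candidate")
  expect_equal(length_gate(5000), "candidate")
  expect_equal(length_gate(1000000), "candidate")
  expect_equal(length_gate(1000001), "bacterial")
})

test_that("score gate excludes strictly below the threshold", {
  expect_equal(phager_gate(0.79), "fail")
  expect_equal(phager_gate(0.8), "pass")
  expect_equal(phager_gate(1.0), "pass")
  expect_equal(phager_gate(0.85, threshold = 0.9), "fail")
  expect_error(phager_gate(1.2), "score")
})

hit_row <- function(desc, subject_length = 50000, alignment_length = 1000,
                    source_db = "nucleotide_ref", query_id = "q") {
  data.frame(query_id = query_id, subject_id = "s",
             subject_length = subject_length,
             alignment_length = alignment_length, percent_identity = 95,
             subject_description = desc, source_db = source_db,
             stringsAsFactors = FALSE)
}

test_that("hit classification follows the bacterial > plasmid > phage order", {
  expect_equal(classify_by_hits(
    hit_row("Escherichia coli chromosome", 1500000, 3000)), "bacterial")
  # both thresholds must be exceeded
  expect_equal(classify_by_hits(
    hit_row("Escherichia coli chromosome", 1500000, 2000)), "no_call")
  expect_equal(classify_by_hits(
    hit_row("Escherichia coli chromosome", 1100000, 3000)), "no_call")
  expect_equal(classify_by_hits(
    hit_row("Salmonella enterica plasmid pSLT")), "plasmid")
  expect_equal(classify_by_hits(hit_row("Salmonella phage S16")),
               "phage_db_match")
  expect_equal(classify_by_hits(hit_row("Escherichia prophage region")),
               "no_call")
  expect_equal(classify_by_hits(hit_row("uncultured organism",
                                        source_db = "phage_db")),
               "phage_db_match")
  expect_equal(classify_by_hits(NULL), "no_call")
  expect_equal(classify_by_hits(hit_row("x")[0, ]), "no_call")
  # keyword matching is case-insensitive
  expect_equal(classify_by_hits(hit_row("Novel PHAGE isolate")),
               "phage_db_match")
})

test_that("marker screening flags exact toy markers and nothing else", {
  ref <- toy_marker_ref()
  terL_aa <- ref$aa_seq[ref$class == "terL"]
  intg_aa <- ref$aa_seq[ref$class == "integrase"]
  p1 <- screen_markers(c(g1 = terL_aa), marker_ref = ref)
  expect_true(p1$has_terL)
  expect_false(any(p1$has_integrase, p1$has_transposase,
                   p1$has_anti_repressor, p1$has_other_lysogeny))
  ev <- attr(p1, "evidence")
  expect_equal(ev$gene_id, "g1")
  expect_equal(ev$containment, 1)
  p0 <- screen_markers(character(), marker_ref = ref)
  expect_false(any(unlist(p0)))
  p2 <- screen_markers(c(g1 = terL_aa, g2 = intg_aa), marker_ref = ref)
  expect_true(p2$has_terL && p2$has_integrase)
  expect_error(screen_markers(c(g1 = terL_aa), marker_ref = ref[0, ]), "empty")
  # extra marker classes are accepted and count as lysogeny markers
  extra <- rbind(ref, data.frame(marker = "exc", class = "excisionase",
                                 aa_seq = strrep("WYWYHHH", 12)))
  p3 <- screen_markers(c(g1 = strrep("WYWYHHH", 12)), marker_ref = extra)
  expect_true(p3$has_other_lysogeny)
  expect_equal(assign_lifestyle(p3), "temperate")
})

test_that("precomputed marker hit tables are accepted", {
  p <- screen_markers(character(),
                      hit_table = data.frame(gene_id = "g7", class = "terL"))
  expect_true(p$has_terL)
  expect_false(p$has_integrase)
})

test_that("temperate status propagates to whole clusters", {
  profiles <- data.frame(
    contig_id = c("A", "B", "C", "D", "E"),
    has_terL = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    has_integrase = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    has_transposase = FALSE, has_anti_repressor = FALSE,
    has_other_lysogeny = FALSE)
  clusters <- data.frame(contig_id = c("A", "B", "C", "D"),
                         cluster_id = c("c1", "c1", "c1", "c2"))
  temp <- propagate_temperate(clusters, profiles)
  expect_setequal(temp, c("A", "B", "C"))   # one integrase taints all of c1
  # no integrase anywhere: nothing propagates
  prof2 <- profiles
  prof2$has_integrase <- FALSE
  expect_length(propagate_temperate(clusters, prof2), 0L)
  # contig absent from the map is its own singleton
  prof3 <- profiles[profiles$contig_id == "E", ]
  prof3$has_integrase <- TRUE
  expect_equal(propagate_temperate(clusters[0, ], prof3), "E")
})

test_that("lifestyle rules never call a lysogeny-marked contig lytic", {
  combos <- expand.grid(terL = c(TRUE, FALSE), intg = c(TRUE, FALSE),
                        tnp = c(TRUE, FALSE), anti = c(TRUE, FALSE),
                        clust = c(TRUE, FALSE))
  for (i in seq_len(nrow(combos))) {
    cb <- combos[i, ]
    prof <- data.frame(has_terL = cb$terL, has_integrase = cb$intg,
                       has_transposase = cb$tnp, has_anti_repressor = cb$anti,
                       has_other_lysogeny = FALSE)
    lab <- assign_lifestyle(prof, is_temperate_by_cluster = cb$clust)
    if (cb$intg || cb$clust) {
      expect_equal(lab, "temperate")
    } else if (cb$terL && !cb$tnp && !cb$anti) {
      expect_equal(lab, "lytic")
    } else {
      expect_equal(lab, "phage_like_undetermined")
    }
  }
})

test_that("the cascade reproduces the fixture's expected labels exactly", {
  suite <- make_fixture_suite(seed = 7L)
  res <- run_cascade(setNames(nchar(suite$contigs), names(suite$contigs)),
                     suite$scores, suite$hits, suite$clusters, suite$profiles)
  expect_equal(res$label, suite$expected$label)
  expect_equal(res$stage, suite$expected$stage)
  # partition: one label per contig, counts sum to the input size
  expect_equal(sum(attr(res, "summary")), length(suite$contigs))
  # permuting the input order leaves the per-contig labels unchanged
  perm <- withr::with_seed(1, sample(length(suite$contigs)))
  res2 <- run_cascade(setNames(nchar(suite$contigs), names(suite$contigs))[perm],
                      suite$scores, suite$hits, suite$clusters, suite$profiles)
  expect_equal(setNames(res2$label, res2$contig_id)[res$contig_id],
               setNames(res$label, res$contig_id))
  expect_error(
    run_cascade(setNames(c(6000, 6000), c("a", "a")),
                data.frame(contig_id = "a", score = 0.9)), "duplicated")
})

test_that("short-only inputs yield no phage calls", {
  lens <- setNames(rep(3000, 4), paste0("s", 1:4))
  scores <- data.frame(contig_id = names(lens), score = rep(0.99, 4))
  res <- run_cascade(lens, scores)
  expect_true(all(res$label == "non_candidate"))
})

test_that("raising the score gate never increases lytic calls", {
  suite <- make_fixture_suite(seed = 7L)
  lens <- setNames(nchar(suite$contigs), names(suite$contigs))
  n_lytic <- vapply(c(0.5, 0.8, 0.9, 0.96, 0.99), function(t) {
    res <- run_cascade(lens, suite$scores, suite$hits, suite$clusters,
                       suite$profiles, threshold = t)
    sum(res$label == "lytic")
  }, numeric(1))
  expect_true(all(diff(n_lytic) <= 0))
})
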