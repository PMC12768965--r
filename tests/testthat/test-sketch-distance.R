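test_that("sketching is canonical, deterministic and size-bounded", {
  set.seed(41)
  s <- random_dna(2000)
  sk1 <- sketch_genome(c(a = s))
  sk2 <- sketch_genome(c(b = s))
  expect_identical(sk1$hashes, sk2$hashes)
  skrc <- sketch_genome(c(rc = revcomp(s)))
  expect_identical(sk1$hashes, skrc$hashes)
  # |hashes| = min(s, number of distinct canonical k-mers), by enumeration
  n_distinct <- length(canonical_kmer_set(s, 21))
  expect_equal(length(sk1$hashes), min(1000L, n_distinct))
  small <- random_dna(300)
  expect_equal(length(sketch_genome(c(x = small))$hashes),
               length(canonical_kmer_set(small, 21)))
  expect_true(all(diff(sk1$hashes) > 0))
  expect_error(sketch_genome(c(x = "ACGT"), k = 21), "shorter")
})

test_that("k-mers containing N are skipped", {
  set.seed(42)
  s <- random_dna(500)
  s_with_n <- paste0(substr(s, 1, 250), "N", substring(s, 251))
  expect_equal(sort(sketch_genome(c(a = s_with_n))$hashes),
               sort(unique(c(sketch_genome(c(l = substr(s, 1, 250)))$hashes,
                             sketch_genome(c(r = substring(s, 251)))$hashes))))
})

test_that("sketch Jaccard tracks the brute-force exact Jaccard", {
  set.seed(43)
  # identical and disjoint extremes
  a <- random_dna(5000)
  ska <- sketch_genome(c(a = a))
  expect_equal(jaccard_estimate(ska, ska), 1.0)
  b <- random_dna(5000)
  skb <- sketch_genome(c(b = b))
  if (exact_jaccard(a, b) == 0) expect_equal(jaccard_estimate(ska, skb), 0)
  # shared 2,500 bp block
  core <- random_dna(2500)
  x <- paste0(core, random_dna(2500))
  y <- paste0(random_dna(2500), core)
  est <- jaccard_estimate(sketch_genome(c(x = x)), sketch_genome(c(y = y)))
  expect_lt(abs(est - exact_jaccard(x, y)), 0.05)
  expect_error(jaccard_estimate(ska, sketch_genome(c(b = b), k = 15)),
               "mismatch")
})

test_that("the Mash transform matches its closed form and conventions", {
  expect_identical(mash_distance(1, 21), 0)
  expect_identical(mash_distance(0, 21), 1)
  expect_equal(mash_distance(0.5, 21), -(1 / 21) * log(2 * 0.5 / 1.5))
  expect_equal(mash_distance(0.5, 21), 0.01931, tolerance = 1e-3)
  # metric sanity on random sketches
  set.seed(44)
  sk <- sketch_genomes(setNames(vapply(1:4, function(i) random_dna(3000),
                                       character(1)), paste0("g", 1:4)))
  for (i in 1:4) expect_equal(sketch_distance(sk[[i]], sk[[i]]), 0)
  for (i in 1:3) for (j in (i + 1):4) {
    d <- sketch_distance(sk[[i]], sk[[j]])
    expect_equal(d, sketch_distance(sk[[j]], sk[[i]]))
    expect_true(d >= 0 && d <= 1)
  }
})

test_that("mutation load increases Mash distance monotonically", {
  set.seed(45)
  base <- random_dna(8000)
  skb <- sketch_genome(c(base = base))
  d <- vapply(c(0, 0.02, 0.05, 0.1), function(rate) {
    med <- vapply(1:3, function(r) {
      m <- mutate_seq(base, rate, seed = 100 * rate + r)
      sketch_distance(skb, sketch_genome(c(m = m)))
    }, numeric(1))
    median(med)
  }, numeric(1))
  expect_true(all(diff(d) > 0))
  expect_equal(d[1], 0)
})

test_that("thresholded networks have the expected component structure", {
  set.seed(46)
  s <- random_dna(4000)
  same <- setNames(rep(s, 4), paste0("dup", 1:4))
  net <- build_network(sketch_genomes(same), threshold = 0.1)
  expect_equal(nrow(net$edges), 4 * 3 / 2)
  expect_equal(length(unique(net$nodes$component)), 1L)
  expect_equal(unique(net$nodes$component), "dup1")
  # two unrelated families: no cross edges
  fam1 <- setNames(vapply(1:3, function(i) mutate_seq(s, 0.02, i), character(1)),
                   paste0("a", 1:3))
  s2 <- random_dna(4000)
  fam2 <- setNames(vapply(1:3, function(i) mutate_seq(s2, 0.02, i), character(1)),
                   paste0("b", 1:3))
  sks <- sketch_genomes(c(fam1, fam2))
  cross <- outer(names(fam1), names(fam2), Vectorize(function(x, y)
    sketch_distance(sks[[x]], sks[[y]])))
  expect_true(all(cross > 0.1))  # brute-force check before trusting components
  net2 <- build_network(sks, threshold = 0.1)
  expect_gte(length(unique(net2$nodes$component)), 2L)
  expect_false(any(net2$edges$a %in% names(fam1) & net2$edges$b %in% names(fam2)))
  # threshold 0: only identical sketches connect
  net0 <- build_network(sketch_genomes(c(same[1:2], x1 = s2)), threshold = 0)
  expect_equal(nrow(net0$edges), 1L)
})

test_that("ANI clouds are single-linkage and order-independent", {
  set.seed(47)
  a <- random_dna(10000)
  b <- mutate_seq(a, 0.035, seed = 1)
  c_ <- mutate_seq(b, 0.035, seed = 2)
  sks <- sketch_genomes(c(A = a, B = b, C = c_))
  dab <- sketch_distance(sks$A, sks$B)
  dbc <- sketch_distance(sks$B, sks$C)
  dac <- sketch_distance(sks$A, sks$C)
  expect_true(dab <= 0.05 && dbc <= 0.05 && dac > 0.05)
  cl <- ani_cluster(sks, ani_threshold = 0.95)
  expect_equal(length(unique(cl)), 1L)  # chain closes transitively
  # far-apart genomes stay singletons
  lone <- sketch_genomes(c(L1 = random_dna(4000), L2 = random_dna(4000)))
  expect_equal(length(unique(ani_cluster(lone))), 2L)
  # permutation invariance
  cl2 <- ani_cluster(sks[c("C", "A", "B")], ani_threshold = 0.95)
  expect_equal(cl2[names(cl)], cl)
})

test_that("reference matching nests strict matches inside loose matches", {
  set.seed(48)
  ref <- random_dna(10000)
  copies <- setNames(vapply(1:5, function(i) mutate_seq(ref, 0.02, i),
                            character(1)), paste0("copy", 1:5))
  unrelated <- setNames(vapply(1:5, function(i) random_dna(10000),
                               character(1)), paste0("rand", 1:5))
  refs <- sketch_genomes(c(therapy1 = ref))
  cands <- sketch_genomes(c(copies, unrelated))
  m <- match_reference_set(refs, cands)
  expect_equal(m$n_loose, 5L)
  expect_setequal(strsplit(m$loose_ids, ",")[[1]], names(copies))
  expect_true(all(strsplit(m$strict_ids, ",")[[1]] %in%
                  strsplit(m$loose_ids, ",")[[1]]))
  # identical candidate lands in both tiers
  m2 <- match_reference_set(refs, sketch_genomes(c(dup = ref)))
  expect_equal(m2$n_loose, 1L)
  expect_equal(m2$n_strict, 1L)
  expect_error(match_reference_set(refs, cands, loose = 0.05, strict = 0.2))
})

test_that("non-overlapping match length equals the bitmap oracle", {
  expect_equal(nonoverlapping_match_length(
    data.frame(q_start = integer(), q_end = integer(),
               percent_identity = numeric())), 0L)
  # merged overlap without floors
  iv <- data.frame(q_start = c(0, 50), q_end = c(100, 150),
                   percent_identity = c(99, 99))
  expect_equal(nonoverlapping_match_length(iv, min_length = 0), 150L)
  # identity floor drops the second interval
  iv2 <- data.frame(q_start = c(0, 700), q_end = c(600, 1100),
                    percent_identity = c(95, 80))
  expect_equal(nonoverlapping_match_length(iv2), 600L)
  # length floor: a 499 bp hit is excluded, 500 bp is kept
  iv3 <- data.frame(q_start = c(0, 1000), q_end = c(499, 1500),
                    percent_identity = c(99, 99))
  expect_equal(nonoverlapping_match_length(iv3), 500L)
  set.seed(49)
  for (i in 1:20) {
    n <- sample(1:12, 1)
    st <- sample(0:5000, n, replace = TRUE)
    iv <- data.frame(q_start = st, q_end = st + sample(500:1500, n, TRUE),
                     percent_identity = runif(n, 85, 100))
    keep <- iv$percent_identity >= 90
    expect_equal(nonoverlapping_match_length(iv),
                 bitmap_union_length(iv$q_start[keep], iv$q_end[keep]))
  }
})

test_that("sketch containers round-trip through JSON", {
  set.seed(50)
  sks <- sketch_genomes(setNames(c(random_dna(2000), random_dna(2000)),
                                 c("g1", "g2")))
  path <- withr::local_tempfile(fileext = ".json")
  write_sketches(sks, path)
  back <- read_sketches(path)
  expect_equal(names(back), names(sks))
  expect_identical(back$g1$hashes, sks$g1$hashes)
  expect_equal(back$g2$k, 21L)
})
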