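test_that("score_genome counts matches plus weights, mismatches score 0", {
  g <- pfam_profile("g", pf(c(1, 2, 5)))
  s <- pfam_profile("s", pf(1:4))
  w <- build_weight_vector(disc = pf(2), w_disc = 0.0012)
  expect_equal(score_genome(g, s, w), 2.0012)
  expect_equal(score_genome(pfam_profile("empty"), s, w), 0)
  expect_equal(score_genome(s, s, NULL), 4)
})

test_that("iterative_select runs the documented greedy hand example", {
  genomes <- mat_from_sets(list(G1 = pf(1:2), G2 = pf(3), G3 = pf(2:3)),
                           universe = pf(1:4))
  sample <- pfam_profile("s", pf(1:4))
  tr <- suppressMessages(iterative_select(sample, genomes, depth = 2))
  # iter 1: G1 and G3 both score 2, tie broken lexicographically -> G1
  # iter 2: P1, P2 masked; G2 and G3 both score 1 -> G2
  expect_identical(tr$picks$genome_id, c("G1", "G2"))
  expect_equal(tr$picks$score, c(2, 1))
  expect_identical(tr$picks$new_pfams_covered, c(2L, 1L))
})

test_that("iterative_select stops early and validates inputs", {
  genomes <- mat_from_sets(list(G1 = pf(1:3)), universe = pf(1:3))
  tr <- iterative_select(pfam_profile("s", pf(1:3)), genomes, depth = 5)
  expect_identical(nrow(tr$picks), 1L)

  disjoint <- mat_from_sets(list(G1 = pf(10), G2 = pf(11)),
                            universe = pf(c(1, 10, 11)))
  expect_message(
    tr2 <- iterative_select(pfam_profile("s", pf(1)), disjoint, depth = 3),
    "early stop")
  expect_identical(nrow(tr2$picks), 0L)
  expect_error(iterative_select(pfam_profile("s", pf(1)), genomes, depth = 0),
               "depth")
})

test_that("greedy picks equal the brute-force argmax at every iteration", {
  set.seed(13)
  for (rep in 1:5) {
    n <- sample(5:15, 1)
    sets <- stats::setNames(
      lapply(seq_len(n), function(i) random_profile_set(40, sample(3:15, 1))),
      sprintf("g%02d", seq_len(n)))
    genomes <- mat_from_sets(sets, universe = pf(1:40))
    sample_pf <- random_profile_set(40, 25)
    wv <- build_weight_vector(core = random_profile_set(40, 10))
    tr <- suppressMessages(
      iterative_select(pfam_profile("s", sample_pf), genomes, wv, depth = 6))
    remaining <- sample_pf
    unpicked <- sets
    prev_remaining <- length(remaining)
    for (k in seq_len(nrow(tr$picks))) {
      best <- oracle_best_genome(unpicked, remaining, wv)
      expect_identical(tr$picks$genome_id[k], best$id)
      expect_equal(tr$picks$score[k], best$score, tolerance = 1e-9)
      remaining <- setdiff(remaining, sets[[best$id]])
      unpicked[[best$id]] <- NULL
      # coverage strictly decreases on every positive-score pick
      expect_lt(length(remaining), prev_remaining)
      prev_remaining <- length(remaining)
    }
    # no remaining genome with positive score was left unpicked before depth
    if (nrow(tr$picks) < 6 && length(unpicked) > 0) {
      expect_null(oracle_best_genome(unpicked, remaining, wv))
    }
  }
})

make_trace <- function(sample_id, ids) {
  structure(list(sample_id = sample_id, depth = 20L,
                 picks = data.frame(genome_id = ids,
                                    score = rev(seq_along(ids)),
                                    new_pfams_covered = rev(seq_along(ids)),
                                    stringsAsFactors = FALSE)),
            class = "selection_trace")
}

test_that("shortlist keeps strains at inclusive threshold prevalence", {
  traces <- c(lapply(1:2, function(i) make_trace(paste0("s", i), c("A", "B"))),
              lapply(3:6, function(i) make_trace(paste0("s", i), "A")))
  # A in 6/6, B in 2/6 >= 1/3 kept
  expect_identical(shortlist(traces), c("A", "B"))
  traces[[2]] <- make_trace("s2", "A")  # B now 1/6 < 1/3
  expect_identical(shortlist(traces), "A")
  expect_identical(shortlist(list(make_trace("s1", c("Z", "C")))), c("C", "Z"))
})

test_that("enumerate_candidates yields binomial(n, k) sets in lexicographic order", {
  expect_identical(ncol(enumerate_candidates(LETTERS[1:4], 2)), 6L)
  expect_identical(ncol(enumerate_candidates(LETTERS[1:5], 5)), 1L)
  cand <- enumerate_candidates(c("b", "a", "c"), 2)
  expect_identical(cand[, 1], c("a", "b"))
  expect_identical(cand[, 2], c("a", "c"))
  expect_identical(cand[, 3], c("b", "c"))
  for (n in c(6, 9, 12)) {
    k <- sample(seq_len(n), 1)
    cand <- enumerate_candidates(sprintf("g%02d", 1:n), k)
    expect_identical(ncol(cand), as.integer(choose(n, k)))
    expect_identical(anyDuplicated(apply(cand, 2, paste, collapse = "+")), 0L)
  }
  expect_error(enumerate_candidates(LETTERS[1:3], 5), "prevalence threshold")
  expect_error(enumerate_candidates(LETTERS[1:20], 10, max_combinations = 100),
               "max_combinations")
})

test_that("taxonomic_filter drops same-species pairs, keeps unassigned", {
  ids <- c("g1", "g2", "g3", "g4")
  tax <- toy_taxonomy(ids, species = c("s__Phocaeicola vulgatus",
                                       "s__Phocaeicola vulgatus",
                                       "s__Other species", "s__"))
  cand <- enumerate_candidates(ids, 2)   # 6 pairs
  kept <- taxonomic_filter(cand, tax, "species")
  keys <- apply(kept, 2, paste, collapse = "+")
  expect_false("g1+g2" %in% keys)        # same species
  expect_true("g1+g3" %in% keys)
  expect_identical(ncol(kept), 5L)
  # two unassigned species never collide
  tax2 <- toy_taxonomy(ids, species = c("s__", "s__", "s__A", "s__B"))
  expect_identical(ncol(taxonomic_filter(cand, tax2, "species")), 6L)
  # filtering at genus level collapses everything (shared genus "G")
  expect_identical(ncol(taxonomic_filter(cand, tax, "genus")), 0L)
  expect_error(taxonomic_filter(matrix(c("g1", "gX"), 2), tax), "gX")
})

test_that("group_score averages the combined-vector score over samples", {
  genomes <- mat_from_sets(list(m1 = pf(1:2), m2 = pf(2:3)),
                           universe = pf(1:4))
  samples1 <- mat_from_sets(list(s1 = pf(1:3)), universe = pf(1:4))
  gs <- group_score(c("m1", "m2"), genomes, samples1)
  expect_equal(gs$group_score, 3)   # combined {1,2,3} equals the sample
  expect_identical(gs$combined_profile$pfams, pf(1:3))

  samples2 <- mat_from_sets(list(s1 = pf(1:2), s2 = pf(2:4)),
                            universe = pf(1:4))
  expect_equal(group_score(c("m1", "m2"), genomes, samples2)$group_score,
               mean(c(2, 2)))
  # adding a member with no new Pfams leaves the score unchanged
  genomes3 <- mat_from_sets(list(m1 = pf(1:2), m2 = pf(2:3), m3 = pf(2)),
                            universe = pf(1:4))
  expect_equal(group_score(c("m1", "m2", "m3"), genomes3, samples2)$group_score,
               group_score(c("m1", "m2"), genomes3, samples2)$group_score)
  expect_error(group_score("m1", genomes, mat_from_sets(list())), "samples")
})

test_that("group score never decreases when a member is added", {
  set.seed(21)
  sets <- stats::setNames(
    lapply(1:8, function(i) random_profile_set(30, sample(4:12, 1))),
    sprintf("g%d", 1:8))
  genomes <- mat_from_sets(sets, universe = pf(1:30))
  samples <- mat_from_sets(list(s1 = random_profile_set(30, 15),
                                s2 = random_profile_set(30, 15)),
                           universe = pf(1:30))
  wv <- build_weight_vector(core = random_profile_set(30, 8))
  for (i in 1:10) {
    base <- sample(names(sets), 3)
    extra <- sample(setdiff(names(sets), base), 1)
    expect_gte(group_score(c(base, extra), genomes, samples, wv)$group_score,
               group_score(base, genomes, samples, wv)$group_score - 1e-12)
  }
})

test_that("functional_redundancy counts uniquely encoded Pfams", {
  fr <- functional_redundancy(list(pfam_profile("a", pf(1:2)),
                                   pfam_profile("b", pf(2:3))))
  expect_equal(fr$pct_unique, 100 * 2 / 3)
  expect_identical(unname(fr$redundancy_histogram), c(2L, 1L))
  expect_equal(functional_redundancy(list(pfam_profile("a", pf(1:5))))$pct_unique,
               100)
  same <- list(pfam_profile("a", pf(1:4)), pfam_profile("b", pf(1:4)))
  expect_equal(functional_redundancy(same)$pct_unique, 0)
})

test_that("rank_candidates orders by score then lexicographic members", {
  genomes <- mat_from_sets(list(g1 = pf(1:3), g2 = pf(1:3), g3 = pf(4)),
                           universe = pf(1:5))
  samples <- mat_from_sets(list(s = pf(1:4)), universe = pf(1:5))
  cand <- enumerate_candidates(c("g1", "g2", "g3"), 2)
  ranked <- rank_candidates(cand, genomes, samples)
  # g1+g3 and g2+g3 both cover {1,2,3,4} (score 4); g1+g2 covers 3
  expect_equal(ranked$group_score, c(4, 4, 3))
  expect_identical(ranked$members, c("g1+g3", "g2+g3", "g1+g2"))
  expect_identical(ranked$rank, 1:3)
})

test_that("top-ranked candidate equals brute-force search on tiny instances", {
  set.seed(31)
  for (rep in 1:3) {
    sets <- stats::setNames(
      lapply(1:6, function(i) random_profile_set(20, sample(3:8, 1))),
      sprintf("g%d", 1:6))
    genomes <- mat_from_sets(sets, universe = pf(1:20))
    sample_sets <- list(random_profile_set(20, 10))
    samples <- mat_from_sets(list(s1 = sample_sets[[1]]), universe = pf(1:20))
    cand <- enumerate_candidates(names(sets), 2)  # 15 pairs
    ranked <- rank_candidates(cand, genomes, samples)
    oracle <- oracle_best_combo(sets, sample_sets, 2)
    expect_identical(strsplit(ranked$members[1], "+", fixed = TRUE)[[1]],
                     oracle$members)
    expect_equal(ranked$group_score[1], oracle$score, tolerance = 1e-9)
  }
})
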