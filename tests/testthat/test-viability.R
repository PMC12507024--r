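test_that("classify_effect applies the 10% relative-change rule", {
  expect_identical(classify_effect(100, 120), "+")   # +20%
  expect_identical(classify_effect(100, 105), "0")   # +5%
  expect_identical(classify_effect(100, 80), "-")    # -20%
  expect_identical(classify_effect(100, 110), "0")   # exactly +10% not > 10%
  expect_message(e <- classify_effect(0, 5), "zero growth")
  expect_identical(e, "+")
  expect_message(e0 <- classify_effect(0, 0), "zero growth")
  expect_identical(e0, "0")
})

test_that("interaction_label maps all 9 ordered effect pairs symmetrically", {
  expected <- list(
    c("+", "+", "mutualism"), c("+", "0", "commensalism"),
    c("+", "-", "parasitism"), c("0", "0", "neutralism"),
    c("0", "-", "amensalism"), c("-", "-", "competition"))
  for (e in expected) {
    expect_identical(interaction_label(e[1], e[2]), e[3])
    expect_identical(interaction_label(e[2], e[1]), e[3])
  }
  expect_error(interaction_label("x", "+"), "effects")
})

test_that("classify_pair classifies from both strains' growth changes", {
  eff <- matrix(c("0", "+", "-", "0"), 2, 2, byrow = TRUE,
                dimnames = list(c("a", "b"), c("a", "b")))
  g <- growth_from_effects(eff)
  p1 <- classify_pair(g, "a", "b")
  expect_identical(p1$effect_on_i, "+")
  expect_identical(p1$effect_on_j, "-")
  expect_identical(p1$label, "parasitism")
  p2 <- classify_pair(g, "b", "a")
  expect_identical(p2$label, "parasitism")
  expect_error(classify_pair(g, "a", "a"), "differ")
  expect_error(classify_pair(g, "a", "zz"), "missing")
})

test_that("assess_syncom applies the three viability rules", {
  ids <- c("a", "b", "c")
  all_plus <- matrix("+", 3, 3, dimnames = list(ids, ids))
  diag(all_plus) <- "0"
  r <- assess_syncom(growth_from_effects(all_plus,
                                         community = stats::setNames(rep(1, 3), ids)))
  expect_true(r$viable)
  expect_equal(r$pct_nonnegative_pairs, 100)

  # pairs: (a,b) mutualism, (a,c) amensalism, (b,c) competition -> 1/3 non-neg
  eff <- matrix("0", 3, 3, dimnames = list(ids, ids))
  eff["a", "b"] <- "+"; eff["b", "a"] <- "+"
  eff["a", "c"] <- "-"                      # c harms a
  eff["b", "c"] <- "-"; eff["c", "b"] <- "-"
  r2 <- assess_syncom(growth_from_effects(eff))
  expect_equal(r2$pct_nonnegative_pairs, 100 / 3, tolerance = 1e-9)
  expect_false(r2$rule_results[["nonnegative_pairs"]])
  expect_false(r2$viable)

  # all neutral: rule 1 passes at 100%, rule 2 fails for every strain
  neutral <- matrix("0", 3, 3, dimnames = list(ids, ids))
  r3 <- assess_syncom(growth_from_effects(neutral))
  expect_equal(r3$pct_nonnegative_pairs, 100)
  expect_identical(sort(r3$strains_lacking_positive), ids)
  expect_false(r3$viable)

  # rule 3: a strain not growing in the community
  comm <- stats::setNames(c(1, 0, 1), ids)
  r4 <- assess_syncom(growth_from_effects(all_plus, community = comm))
  expect_identical(r4$strains_not_growing_in_community, "b")
  expect_false(r4$viable)
  expect_error(assess_syncom(growth_from_effects(all_plus[1, 1, drop = FALSE])),
               ">= 2")
})

test_that("exactly 50% non-negative pairs is not viable (strict rule)", {
  ids <- c("a", "b", "c", "d")
  eff <- matrix("0", 4, 4, dimnames = list(ids, ids))
  eff["a", "b"] <- "+"; eff["b", "a"] <- "+"     # mutualism
  eff["c", "d"] <- "+"; eff["d", "c"] <- "+"     # mutualism
  eff["a", "c"] <- "-"; eff["b", "d"] <- "-"; eff["a", "d"] <- "-"
  # pairs: ab +, cd +, ac -, ad -, bd -, bc neutral -> 3/6 non-negative
  r <- assess_syncom(growth_from_effects(eff))
  expect_equal(r$pct_nonnegative_pairs, 50)
  expect_false(r$rule_results[["nonnegative_pairs"]])
})

test_that("upgrading one effect never flips a viable SynCom to inviable", {
  set.seed(17)
  ids <- sprintf("s%d", 1:4)
  for (rep in 1:20) {
    eff <- matrix(sample(c("+", "0", "-"), 16, replace = TRUE), 4, 4,
                  dimnames = list(ids, ids))
    diag(eff) <- "0"
    before <- assess_syncom(growth_from_effects(eff))
    ij <- which(eff != "+" & row(eff) != col(eff), arr.ind = TRUE)
    if (nrow(ij) == 0) next
    pick <- ij[sample(nrow(ij), 1), ]
    eff[pick[1], pick[2]] <- if (eff[pick[1], pick[2]] == "-") "0" else "+"
    after <- assess_syncom(growth_from_effects(eff))
    if (before$viable) expect_true(after$viable)
  }
})

test_that("threshold extremes degenerate as documented", {
  eff <- matrix(c("0", "+", "-", "0"), 2, 2, byrow = TRUE,
                dimnames = list(c("a", "b"), c("a", "b")))
  g <- growth_from_effects(eff)
  im_wide <- interaction_matrix(g, threshold = 1e6)
  expect_true(all(im_wide$label == "neutralism"))
  im_zero <- interaction_matrix(g, threshold = 0)
  expect_false(any(im_zero$effect_on_i == "0" & g$paired["a", "b"] != g$alone[["a"]]))
})

test_that("growth table CSV round-trip is lossless", {
  gf <- generate_growth_fixture(sprintf("s%d", 1:4), seed = 2)
  dir <- withr::local_tempdir()
  write_growth_table(gf$growth, dir)
  g2 <- read_growth_table(dir)
  expect_equal(g2$alone, gf$growth$alone)
  expect_equal(g2$paired, gf$growth$paired)
  expect_equal(g2$community, gf$growth$community)
})

test_that("screen_ranked walks the ranked list to the first viable candidate", {
  ids <- function(k) sprintf("m%d_%d", k, 1:3)
  viable_growth <- function(members) {
    eff <- matrix("+", 3, 3, dimnames = list(members, members))
    growth_from_effects(eff, community = stats::setNames(rep(1, 3), members))
  }
  inviable_growth <- function(members) {
    eff <- matrix("-", 3, 3, dimnames = list(members, members))
    diag(eff) <- "0"
    growth_from_effects(eff)
  }
  cands <- list(ids(1), ids(2), ids(3), ids(4))
  sim <- function(members) {
    if (members[1] %in% c("m1_1", "m2_1")) inviable_growth(members)
    else viable_growth(members)
  }
  res <- screen_ranked(cands, sim)
  expect_true(res$viable_found)
  expect_identical(res$winner_index, 3L)
  expect_length(res$reports, 3)

  res_first <- screen_ranked(cands, viable_growth)
  expect_identical(res_first$winner_index, 1L)
  expect_length(res_first$reports, 1)

  res_none <- screen_ranked(cands, inviable_growth)
  expect_false(res_none$viable_found)
  expect_length(res_none$reports, 4)

  # simulator failure skips the candidate as inviable
  sim_fail <- function(members) {
    if (members[1] == "m1_1") stop("boom") else viable_growth(members)
  }
  expect_message(res_skip <- screen_ranked(cands, sim_fail), "boom")
  expect_identical(res_skip$winner_index, 2L)
})

test_that("toy_simulate is deterministic and classification-faithful", {
  ids <- c("a", "b")
  params <- list(baseline = stats::setNames(c(1, 2), ids),
                 effects = matrix(0, 2, 2, dimnames = list(ids, ids)))
  g <- toy_simulate(ids, params, seed = 4)
  expect_equal(g$paired["a", "b"], 1)
  expect_identical(classify_pair(g, "a", "b")$label, "neutralism")

  params$effects["a", "b"] <- 0.3
  params$effects["b", "a"] <- 0.3
  expect_identical(classify_pair(toy_simulate(ids, params, 4), "a", "b")$label,
                   "mutualism")
  params$noise_amp <- 0.02
  g1 <- toy_simulate(ids, params, seed = 7)
  g2 <- toy_simulate(ids, params, seed = 7)
  expect_identical(g1, g2)
})
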