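# Independent oracles used to cross-check the implementation. These stay
# deliberately naive (explicit set arithmetic, full enumeration) and never
# call the code paths they verify.

# accession shorthand: pf(3) == "PF00003"
pf <- function(i) sprintf("PF%05d", i)

# Fisher two-sided p by exhaustive enumeration of all tables with the
# observed margins, probabilities from log-binomial coefficients.
oracle_fisher <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  probs <- exp(logp)
  p_obs <- exp(lchoose(m, a) + lchoose(n, c) - lchoose(m + n, k))
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Naive scorer: matches + weights, by explicit set operations.
oracle_score <- function(genome_pfams, sample_pfams, weights = NULL) {
  matches <- intersect(genome_pfams, sample_pfams)
  w <- if (is.null(weights)) numeric(length(matches)) else {
    vapply(matches, function(p) {
      v <- unclass(weights)[p]
      if (is.na(v)) 0 else as.numeric(v)
    }, 0)
  }
  length(matches) + sum(w)
}

# Brute-force best genome for one greedy iteration (lexicographic ties).
oracle_best_genome <- function(genome_sets, remaining_pfams, weights = NULL) {
  scores <- vapply(genome_sets, oracle_score, 0, sample_pfams = remaining_pfams,
                   weights = weights)
  best <- max(scores)
  if (best <= 0) return(NULL)
  list(id = sort(names(scores)[scores >= best - 1e-12])[1], score = best)
}

# Brute-force best k-subset by mean group score over samples.
oracle_best_combo <- function(genome_sets, sample_sets, k, weights = NULL) {
  ids <- sort(names(genome_sets))
  combos <- utils::combn(ids, k, simplify = FALSE)
  scores <- vapply(combos, function(members) {
    u <- sort(unique(unlist(genome_sets[members])))
    mean(vapply(sample_sets, function(s) oracle_score(u, s, weights), 0))
  }, 0)
  keys <- vapply(combos, paste, "", collapse = "+")
  ord <- order(-scores, keys)
  list(members = combos[[ord[1]]], score = scores[ord[1]])
}

random_profile_set <- function(universe_n, size) {
  pf(sort(sample.int(universe_n, size)))
}

# Build a profile_matrix from a named list of accession vectors.
mat_from_sets <- function(sets, universe = NULL) {
  build_profile_matrix(
    lapply(names(sets), function(id) pfam_profile(id, sets[[id]])),
    universe = universe)
}

# Minimal taxonomy table for given ids; species labels supplied per id
# ("" = unassigned).
toy_taxonomy <- function(ids, species = NULL) {
  if (is.null(species)) species <- sprintf("s__Species %03d", seq_along(ids))
  data.frame(
    genome_id = ids,
    classification = sprintf("d__Bacteria;p__P;c__C;o__O;f__F;g__G;%s",
                             species),
    domain = "Bacteria", phylum = "P", class = "C", order = "O",
    family = "F", genus = "G",
    species = sub("^s__", "", species),
    stringsAsFactors = FALSE)
}

# Growth table with explicit effect matrix and unit baselines; effect
# magnitudes are +/-20% (signed) and +5% (neutral) so classification at the
# default threshold is unambiguous.
growth_from_effects <- function(effects, baseline = NULL, community = NULL) {
  ids <- rownames(effects)
  if (is.null(baseline)) baseline <- stats::setNames(rep(1, length(ids)), ids)
  paired <- matrix(NA_real_, length(ids), length(ids),
                   dimnames = list(ids, ids))
  val <- c("+" = 0.20, "0" = 0.00, "-" = -0.20)
  for (i in ids) for (j in ids) {
    if (i != j) paired[i, j] <- baseline[[i]] * (1 + val[[effects[i, j]]])
  }
  if (is.null(community)) community <- baseline
  growth_table(baseline, paired, community)
}
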