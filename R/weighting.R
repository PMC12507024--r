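#' Core functions of a metagenome group
#'
#' A Pfam is core to a group when its prevalence across the group's samples
#' is strictly greater than the threshold (default > 50%).
#'
#' @param group A [profile_matrix()] of the group's metagenomes (>= 1 row).
#' @param prevalence_threshold Fraction in [0, 1); strict inequality.
#' @return Character vector of core Pfam accessions (sorted).
#' @export
core_functions <- function(group, prevalence_threshold = 0.5) {
  if (!inherits(group, "profile_matrix") || nrow(group) == 0L) {
    stop("group must be a nonempty profile_matrix", call. = FALSE)
  }
  prev <- colMeans(group)
  sort(colnames(group)[prev > prevalence_threshold])
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Conditional exact test for the table `[[a, b], [c, d]]`: the two-sided
#' p-value sums, over the hypergeometric support fixed by the margins, the
#' probabilities of all tables no more likely than the observed one. This
#' matches exhaustive enumeration (and `stats::fisher.test`) to within 1e-9.
#'
#' @param a,b,c,d Non-negative integer cell counts; row 1 is (present in A,
#'   absent in A), row 2 is (present in B, absent in B). At least one count
#'   must be positive.
#' @return Two-sided p-value in (0, 1].
#' @examples
#' fisher_exact_2x2(5, 0, 0, 5)  # 2/252
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("all-zero 2x2 table", call. = FALSE)
  m <- a + b            # row 1 total
  n <- c + d            # row 2 total
  k <- a + c            # column 1 total
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  # relative tolerance guards against ties lost to floating point
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Differentially prevalent functions between two metagenome groups
#'
#' For every Pfam in the union universe a 2x2 presence/absence-by-group
#' table is tested with [fisher_exact_2x2()]. Pfams with p below `alpha`
#' are assigned to the group with the higher prevalence. No multiple-testing
#' correction is applied by default (raw p < .05); `p_adjust = "BH"` enables
#' Benjamini-Hochberg FDR.
#'
#' @param groupA,groupB Nonempty [profile_matrix()] objects.
#' @param alpha Significance threshold on the (possibly adjusted) p-value.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return List with `enriched_in_A`, `enriched_in_B` (character vectors)
#'   and `table`, a data.frame with one row per Pfam: counts, group sizes,
#'   prevalences and p-value.
#' @export
discriminatory_functions <- function(groupA, groupB, alpha = 0.05,
                                     p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (nrow(groupA) == 0L || nrow(groupB) == 0L) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  universe <- sort(union(colnames(groupA), colnames(groupB)))
  nA <- nrow(groupA)
  nB <- nrow(groupB)
  cntA <- cntB <- stats::setNames(integer(length(universe)), universe)
  cntA[colnames(groupA)] <- colSums(groupA)
  cntB[colnames(groupB)] <- colSums(groupB)
  p <- vapply(seq_along(universe), function(i) {
    fisher_exact_2x2(cntA[i], nA - cntA[i], cntB[i], nB - cntB[i])
  }, 0)
  p_eff <- if (p_adjust == "BH") stats::p.adjust(p, "BH") else p
  tab <- data.frame(
    pfam = universe,
    count_present_groupA = as.integer(cntA),
    n_groupA = nA,
    count_present_groupB = as.integer(cntB),
    n_groupB = nB,
    prevalence_A = as.numeric(cntA) / nA,
    prevalence_B = as.numeric(cntB) / nB,
    p_value = p,
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (p_adjust == "BH") tab$p_adjusted <- p_eff
  sig <- p_eff < alpha
  tied <- sig & tab$prevalence_A == tab$prevalence_B
  if (any(tied)) {
    message(sum(tied), " significant Pfam(s) with tied prevalence assigned to neither group")
  }
  list(
    enriched_in_A = universe[sig & tab$prevalence_A > tab$prevalence_B],
    enriched_in_B = universe[sig & tab$prevalence_B > tab$prevalence_A],
    table = tab
  )
}

#' Additive per-Pfam weight vector
#'
#' Core functions carry `w_core` (default 0.0005), discriminatory functions
#' `w_disc` (default 0.0012); a Pfam in both sets carries the sum. All other
#' Pfams weigh 0.
#'
#' @param core,disc Character vectors of Pfam accessions.
#' @param w_core,w_disc Non-negative weights.
#' @return A `weight_vector`: named numeric vector over `union(core, disc)`
#'   with attributes `w_core` and `w_disc`. Look up weights with
#'   [weight_of()].
#' @export
build_weight_vector <- function(core = character(), disc = character(),
                                w_core = 0.0005, w_disc = 0.0012) {
  if (w_core < 0 || w_disc < 0) {
    stop("weights must be non-negative", call. = FALSE)
  }
  pfams <- sort(union(core, disc))
  w <- stats::setNames(
    w_core * (pfams %in% core) + w_disc * (pfams %in% disc), pfams)
  structure(w, w_core = w_core, w_disc = w_disc, class = "weight_vector")
}

#' Arbitrary per-Pfam weights as a weight_vector
#'
#' @param weights Named non-negative numeric vector (names are accessions).
#' @return A `weight_vector`.
#' @export
weight_vector <- function(weights = numeric()) {
  if (length(weights) && (is.null(names(weights)) || any(!nzchar(names(weights))))) {
    stop("weights must be named by Pfam accession", call. = FALSE)
  }
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  structure(weights[order(names(weights))], class = "weight_vector")
}

#' Look up weights for a set of accessions (absent accession = 0)
#'
#' @param wv A `weight_vector` (or `NULL` for all-zero weights).
#' @param pfams Character vector of accessions.
#' @return Numeric vector of weights, same length as `pfams`.
#' @export
weight_of <- function(wv, pfams) {
  if (is.null(wv) || length(wv) == 0L) return(numeric(length(pfams)))
  w <- unclass(wv)[pfams]
  w[is.na(w)] <- 0
  unname(w)
}

#' Genome-collection rarity weights
#'
#' The "genomic function" strategy up-weights Pfams rarely encoded across a
#' strain collection: weight(p) = w * (1 - prevalence of p among genomes).
#' The exact rarity rule is not standardized; this linear form is a
#' documented placeholder and is excluded from pipeline defaults.
#'
#' @param genomes A [profile_matrix()] of the strain collection.
#' @param w Non-negative scale.
#' @return A `weight_vector` over the genome universe.
#' @export
genomic_rarity_weights <- function(genomes, w) {
  if (w < 0) stop("weights must be non-negative", call. = FALSE)
  prev <- colMeans(genomes)
  weight_vector(stats::setNames(w * (1 - prev), colnames(genomes)))
}

#' Evenly spaced weight grid excluding the zero baseline
#'
#' The scan over `(0, stop]` in steps `s` has `stop/s` points; the weight-0
#' baseline is computed separately (at weight 0 every strategy reduces to
#' the unweighted selection). The coarse grid `(0, 1]` step 0.0025 has 400
#' points; the fine grid `(0, 0.01]` step 0.0001 has 100.
#'
#' @param stop Upper end (inclusive).
#' @param step Increment.
#' @return Numeric vector `seq(step, stop, by = step)`.
#' @export
weight_grid <- function(stop = 0.01, step = 0.0001) {
  if (step <= 0 || stop < step) stop("need 0 < step <= stop", call. = FALSE)
  seq_len(round(stop / step)) * step
}

#' Scan a weight grid for one weighting strategy
#'
#' For each grid weight, a per-sample SynCom is selected with only that
#' strategy weighted, and its combined Pfam profile is compared to the
#' sample with [match_stats()]. One summary row per weight, in grid order;
#' at weight 0 all metrics equal the unweighted baseline exactly.
#'
#' @param samples [profile_matrix()] of the target metagenomes.
#' @param genomes [profile_matrix()] of the strain collection.
#' @param strategy `"core"`, `"disc"` or `"genomic"`.
#' @param grid Numeric vector of non-negative weights (see [weight_grid()]).
#' @param samples2 Second group matrix, required for `strategy = "disc"`.
#' @param depth Per-sample selection depth (strains per sample SynCom).
#' @param alpha Fisher threshold for the discriminatory sets.
#' @param selector Selection function `(sample_profile, genomes, weights,
#'   depth) -> pfam_profile` of the selected SynCom union. Defaults to
#'   greedy [iterative_select()]; replaceable by a stub for design
#'   bookkeeping checks.
#' @return data.frame with columns `strategy`, `weight`, `mean_jaccard`,
#'   `mean_pct_matches`, `mean_pct_mismatches`; attribute `n_evaluations`
#'   holds `length(grid) * nrow(samples)`.
#' @export
weight_scan <- function(samples, genomes, strategy = c("core", "disc", "genomic"),
                        grid = weight_grid(), samples2 = NULL, depth = 20L,
                        alpha = 0.05, selector = NULL) {
  strategy <- match.arg(strategy)
  if (any(grid < 0)) stop("grid weights must be >= 0", call. = FALSE)
  if (strategy == "disc" && is.null(samples2)) {
    stop("strategy 'disc' requires samples2", call. = FALSE)
  }
  if (is.null(selector)) {
    selector <- function(sample_profile, genomes, weights, depth) {
      trace <- iterative_select(sample_profile, genomes, weights, depth = depth)
      syncom_union_profile(trace$picks$genome_id, genomes)
    }
  }
  core <- if (strategy == "core") core_functions(samples) else character()
  disc <- if (strategy == "disc") {
    discriminatory_functions(samples, samples2, alpha = alpha)$enriched_in_A
  } else character()
  sample_profiles <- lapply(rownames(samples),
                            function(id) profile_from_matrix(samples, id))
  n_eval <- 0L
  rows <- lapply(grid, function(w) {
    wv <- switch(strategy,
      core = build_weight_vector(core = core, w_core = w, w_disc = 0),
      disc = build_weight_vector(disc = disc, w_core = 0, w_disc = w),
      genomic = genomic_rarity_weights(genomes, w))
    stats_list <- lapply(sample_profiles, function(sp) {
      n_eval <<- n_eval + 1L
      match_stats(selector(sp, genomes, wv, depth), sp)
    })
    data.frame(
      strategy = strategy, weight = w,
      mean_jaccard = mean(vapply(stats_list, `[[`, 0, "jaccard_distance")),
      mean_pct_matches = mean(vapply(stats_list, `[[`, 0, "pct_matches")),
      mean_pct_mismatches = mean(vapply(stats_list, `[[`, 0, "pct_mismatches")),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_evaluations") <- n_eval
  out
}
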