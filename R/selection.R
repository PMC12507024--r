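#' Score a genome against the remaining sample profile
#'
#' Each Pfam present in both the genome and the (remaining) sample scores 1
#' plus its weight; Pfams in the genome but absent from the sample
#' (mismatches) score 0.
#'
#' @param genome,remaining_sample [pfam_profile()] objects (or accession
#'   vectors).
#' @param weights A `weight_vector` or `NULL` (unweighted).
#' @return Numeric score >= 0.
#' @examples
#' g <- pfam_profile("g", c("PF00001", "PF00002", "PF00005"))
#' s <- pfam_profile("s", c("PF00001", "PF00002", "PF00003", "PF00004"))
#' w <- build_weight_vector(disc = "PF00002", w_disc = 0.0012)
#' score_genome(g, s, w)  # 2.0012
#' @export
score_genome <- function(genome, remaining_sample, weights = NULL) {
  genome <- as_profile(genome, "genome")
  remaining_sample <- as_profile(remaining_sample, "sample")
  matches <- genome$pfams[genome$pfams %in% remaining_sample$pfams]
  length(matches) + sum(weight_of(weights, matches))
}

#' Sample-specific iterative greedy selection (step 1)
#'
#' Greedy weighted set cover with masking: all unselected genomes are scored
#' with [score_genome()] against the remaining sample profile, the highest
#' scorer is picked (ties broken by lexicographically smallest genome id),
#' its Pfams are removed from consideration, and the loop repeats until
#' `depth` strains are picked or every remaining score is 0 (early stop,
#' reported via a message).
#'
#' @param sample A [pfam_profile()] for one metagenome.
#' @param genomes A nonempty [profile_matrix()] of the strain collection.
#' @param weights A `weight_vector` or `NULL`.
#' @param depth Maximum strains to select (default 20).
#' @return A `selection_trace`: list with `sample_id`, `depth`, and `picks`,
#'   a data.frame with columns `genome_id`, `score`, `new_pfams_covered`.
#' @export
iterative_select <- function(sample, genomes, weights = NULL, depth = 20L) {
  if (depth < 1L) stop("depth must be >= 1", call. = FALSE)
  if (!inherits(genomes, "profile_matrix") || nrow(genomes) == 0L) {
    stop("genomes must be a nonempty profile_matrix", call. = FALSE)
  }
  sample <- as_profile(sample, "sample")
  ids <- rownames(genomes)
  # restrict to the sample's Pfams present in the genome universe;
  # per-column value = 1 + weight so one matrix product scores all genomes
  cols <- intersect(colnames(genomes), sample$pfams)
  G <- unclass(genomes)[, cols, drop = FALSE]
  colval <- 1 + weight_of(weights, cols)
  remaining <- rep(TRUE, length(cols))        # sample Pfams not yet covered
  unpicked <- rep(TRUE, length(ids))
  picks <- list()
  for (iter in seq_len(depth)) {
    if (!any(unpicked)) break
    scores <- as.numeric(G[unpicked, remaining, drop = FALSE] %*%
                           colval[remaining])
    best <- max(scores, 0)
    if (best <= 0) {
      if (length(picks) < depth) {
        message("early stop for ", sample$entity_id, ": all remaining scores 0 after ",
                length(picks), " pick(s)")
      }
      break
    }
    cand <- ids[unpicked][scores >= best - 1e-12]
    pick <- sort(cand)[1]
    covered_now <- remaining & G[pick, ] == 1L
    picks[[iter]] <- data.frame(genome_id = pick, score = best,
                                new_pfams_covered = sum(covered_now),
                                stringsAsFactors = FALSE)
    remaining <- remaining & !covered_now
    unpicked[ids == pick] <- FALSE
  }
  picks_df <- if (length(picks)) do.call(rbind, picks) else
    data.frame(genome_id = character(), score = numeric(),
               new_pfams_covered = integer(), stringsAsFactors = FALSE)
  structure(list(sample_id = sample$entity_id, depth = as.integer(depth),
                 picks = picks_df),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("<selection_trace> ", x$sample_id, ": ", nrow(x$picks), " pick(s)\n",
      sep = "")
  invisible(x)
}

#' Shortlist strains by selection prevalence (step 2)
#'
#' A genome is kept iff it appears in at least `prevalence_threshold` of the
#' per-sample traces (inclusive >=; default 33.3% of samples).
#'
#' @param traces List of `selection_trace` objects (>= 1).
#' @param prevalence_threshold Fraction in (0, 1].
#' @return Sorted character vector of shortlisted genome ids.
#' @export
shortlist <- function(traces, prevalence_threshold = 1 / 3) {
  stopifnot(length(traces) >= 1L,
            all(vapply(traces, inherits, TRUE, "selection_trace")))
  picked <- unlist(lapply(traces, function(t) unique(t$picks$genome_id)))
  counts <- table(picked)
  # tiny epsilon keeps the inclusive boundary (2/6 >= 1/3) under FP division
  keep <- names(counts)[as.numeric(counts) / length(traces) >=
                          prevalence_threshold - 1e-12]
  sort(keep)
}

#' Enumerate candidate member sets (step 2, combinations)
#'
#' Generates all `choose(n, syn_size)` subsets of the shortlisted genomes in
#' deterministic lexicographic order over the sorted ids. Enumeration is
#' bounded by `max_combinations` (default 1e7) to keep memory finite.
#'
#' @param shortlisted Character vector of genome ids.
#' @param syn_size Members per SynCom (default 10).
#' @param max_combinations Hard cap on the number of combinations.
#' @return Character matrix, one candidate per column (`syn_size` rows),
#'   members sorted within each column.
#' @export
enumerate_candidates <- function(shortlisted, syn_size = 10L,
                                 max_combinations = 1e7) {
  shortlisted <- sort(unique(shortlisted))
  n <- length(shortlisted)
  if (n < syn_size) {
    stop(sprintf(paste0("only %d strain(s) shortlisted but syn_size is %d; ",
                        "lower the prevalence threshold so sufficient strains ",
                        "are shortlisted"), n, syn_size), call. = FALSE)
  }
  n_combo <- choose(n, syn_size)
  if (n_combo > max_combinations) {
    stop(sprintf("choose(%d, %d) = %.4g exceeds max_combinations = %.4g; raise the prevalence threshold or the cap",
                 n, syn_size, n_combo, max_combinations), call. = FALSE)
  }
  idx <- utils::combn(n, syn_size)
  matrix(shortlisted[idx], nrow = syn_size)
}

#' Drop candidates sharing a taxon label (step 2, taxonomic filter)
#'
#' A candidate passes iff no two members share a nonempty label at the given
#' rank; unassigned (empty) labels never collide.
#'
#' @param candidates Character matrix as from [enumerate_candidates()].
#' @param taxonomy data.frame from [read_gtdbtk_summary()] covering every
#'   member (a missing record is an error).
#' @param level Rank at which to filter (default `"species"`).
#' @return The filtered candidate matrix (possibly 0 columns).
#' @export
taxonomic_filter <- function(candidates, taxonomy, level = "species") {
  if (ncol(candidates) == 0L) return(candidates)
  labels <- taxon_labels(taxonomy, level, unique(as.vector(candidates)))
  lab_mat <- matrix(labels[as.vector(candidates)], nrow = nrow(candidates))
  ok <- apply(lab_mat, 2, function(l) {
    l <- l[nzchar(l)]
    !anyDuplicated(l)
  })
  candidates[, ok, drop = FALSE]
}

#' Combined Pfam profile of a member set
#'
#' @param members Character vector of genome ids.
#' @param genomes A [profile_matrix()] containing them.
#' @param entity_id Id for the returned union profile.
#' @return A [pfam_profile()]: the union of the member profiles.
#' @export
syncom_union_profile <- function(members, genomes, entity_id = "syncom") {
  missing <- setdiff(members, rownames(genomes))
  if (length(missing)) {
    stop("genome(s) not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  present <- colSums(unclass(genomes)[members, , drop = FALSE]) > 0
  pfam_profile(entity_id, colnames(genomes)[present])
}

#' Functional redundancy of a member set
#'
#' The percentage of the community's union Pfams encoded by exactly one
#' member, plus the full redundancy histogram (k members -> number of union
#' Pfams encoded by exactly k members).
#'
#' @param member_profiles List of [pfam_profile()] objects (>= 1).
#' @return List with `pct_unique` and `redundancy_histogram` (named integer
#'   vector, names = k).
#' @export
functional_redundancy <- function(member_profiles) {
  stopifnot(length(member_profiles) >= 1L)
  counts <- table(unlist(lapply(member_profiles, `[[`, "pfams")))
  hist <- table(factor(as.integer(counts),
                       levels = seq_len(length(member_profiles))))
  list(
    pct_unique = if (length(counts) == 0L) 100 else
      100 * sum(counts == 1L) / length(counts),
    redundancy_histogram = stats::setNames(as.integer(hist), names(hist))
  )
}

#' Group-score a candidate member set (step 3)
#'
#' The member profiles are combined into one binary union vector and scored
#' with [score_genome()] against each full (unmasked) sample profile; the
#' group score is the arithmetic mean over samples.
#'
#' @param members Character vector of genome ids.
#' @param genomes,samples [profile_matrix()] objects.
#' @param weights A `weight_vector` or `NULL`.
#' @return A `syncom_candidate`: list with `members` (sorted),
#'   `combined_profile`, `group_score`, `functional_redundancy_pct`,
#'   `n_nonredundant_pfams` and a `viable` slot filled by the viability
#'   screen (`NA` until then).
#' @export
group_score <- function(members, genomes, samples, weights = NULL) {
  if (nrow(samples) == 0L) stop("no samples to score against", call. = FALSE)
  members <- sort(members)
  combined <- syncom_union_profile(members, genomes,
                                   paste(members, collapse = "+"))
  per_sample <- vapply(rownames(samples), function(id) {
    score_genome(combined, profile_from_matrix(samples, id), weights)
  }, 0)
  redun <- functional_redundancy(
    lapply(members, function(m) profile_from_matrix(genomes, m)))
  structure(list(
    members = members,
    combined_profile = combined,
    group_score = mean(per_sample),
    per_sample_scores = per_sample,
    functional_redundancy_pct = redun$pct_unique,
    n_nonredundant_pfams = unname(redun$redundancy_histogram["1"]),
    viable = NA
  ), class = "syncom_candidate")
}

#' @export
print.syncom_candidate <- function(x, ...) {
  cat("<syncom_candidate> ", length(x$members), " members, group score ",
      format(x$group_score), "\n", sep = "")
  invisible(x)
}

#' Score and rank all candidates by group score (step 3)
#'
#' Vectorized scoring of every candidate column against every sample, in
#' blocks to bound memory. Candidates are ordered by descending group score,
#' ties broken by the lexicographic member-id tuple.
#'
#' @param candidates Character matrix, one candidate per column.
#' @param genomes,samples [profile_matrix()] objects sharing the genome
#'   universe.
#' @param weights A `weight_vector` or `NULL`.
#' @param top_k Keep only the best `top_k` candidates (default 10000) to
#'   bound the materialized list.
#' @param block_size Candidates scored per block.
#' @return data.frame ranked best-first with columns `rank`, `members`
#'   (ids joined by `"+"`), `group_score`, `functional_redundancy_pct`,
#'   `n_nonredundant_pfams`.
#' @export
rank_candidates <- function(candidates, genomes, samples, weights = NULL,
                            top_k = 10000L, block_size = 2000L) {
  if (ncol(candidates) == 0L) {
    stop("no candidates to rank (all filtered out?)", call. = FALSE)
  }
  if (nrow(samples) == 0L) stop("no samples to score against", call. = FALSE)
  G <- unclass(genomes)
  # W[p, s] = sample_sp * (1 + weight_p): candidate-block %*% W gives scores
  shared <- intersect(colnames(G), colnames(samples))
  W <- t(unclass(samples)[, shared, drop = FALSE]) *
    (1 + weight_of(weights, shared))
  scores <- numeric(ncol(candidates))
  for (start in seq(1L, ncol(candidates), by = block_size)) {
    cols <- start:min(start + block_size - 1L, ncol(candidates))
    block <- candidates[, cols, drop = FALSE]
    C <- matrix(0, nrow = length(cols), ncol = length(shared))
    for (r in seq_len(nrow(block))) {
      C <- C + G[block[r, ], shared, drop = FALSE]
    }
    C <- (C > 0) + 0
    scores[cols] <- rowMeans(C %*% W)
  }
  member_key <- apply(candidates, 2, function(m) paste(sort(m), collapse = "+"))
  ord <- order(-scores, member_key)
  ord <- ord[seq_len(min(top_k, length(ord)))]
  out <- data.frame(
    rank = seq_along(ord),
    members = member_key[ord],
    group_score = scores[ord],
    stringsAsFactors = FALSE
  )
  redun <- lapply(ord, function(j) {
    functional_redundancy(lapply(candidates[, j],
                                 function(m) profile_from_matrix(genomes, m)))
  })
  out$functional_redundancy_pct <- vapply(redun, `[[`, 0, "pct_unique")
  out$n_nonredundant_pfams <- vapply(redun, function(r)
    as.integer(r$redundancy_histogram["1"]), 0L)
  out
}
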