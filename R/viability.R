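#' Growth outcomes of a strain set alone, paired, and in community
#'
#' The contract between growth simulators and the viability screen: final
#' growth (biomass/abundance after the simulation horizon) of every strain
#' alone, in each ordered pair, and in the full community.
#'
#' @param alone Named non-negative numeric: growth of each strain alone.
#' @param paired Numeric matrix, `paired[i, j]` = growth of strain i when
#'   co-cultured with strain j; diagonal ignored. Dimnames = strains.
#' @param community Named non-negative numeric: growth of each strain in the
#'   full-community run.
#' @return A `growth_table` object.
#' @export
growth_table <- function(alone, paired, community) {
  strains <- names(alone)
  if (is.null(strains) || anyDuplicated(strains)) {
    stop("alone must be named by unique strain ids", call. = FALSE)
  }
  if (!is.matrix(paired) || !identical(rownames(paired), strains) ||
      !identical(colnames(paired), strains)) {
    stop("paired must be a strains x strains matrix with matching dimnames",
         call. = FALSE)
  }
  if (!identical(sort(names(community)), sort(strains))) {
    stop("community growth must cover every strain", call. = FALSE)
  }
  off_diag <- paired[row(paired) != col(paired)]
  if (anyNA(off_diag) || any(off_diag < 0) || any(alone < 0) ||
      any(community < 0)) {
    stop("growth values must be defined and non-negative", call. = FALSE)
  }
  structure(list(strains = strains, alone = alone, paired = paired,
                 community = community[strains]),
            class = "growth_table")
}

#' Write / read a growth table as three CSV files
#'
#' The directory contract used to plug in external simulators:
#' `alone.csv` (strain, growth), `pairs.csv` (strain, partner, growth, one
#' row per ordered pair), `community.csv` (strain, growth).
#'
#' @param growth A [growth_table()].
#' @param dir Directory (created if needed).
#' @return `write_growth_table` returns `dir` invisibly;
#'   `read_growth_table` returns a [growth_table()].
#' @export
write_growth_table <- function(growth, dir) {
  stopifnot(inherits(growth, "growth_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(strain = growth$strains,
                              growth = unname(growth$alone)),
                   file.path(dir, "alone.csv"), row.names = FALSE)
  idx <- which(row(growth$paired) != col(growth$paired))
  utils::write.csv(data.frame(
    strain = growth$strains[row(growth$paired)[idx]],
    partner = growth$strains[col(growth$paired)[idx]],
    growth = growth$paired[idx]),
    file.path(dir, "pairs.csv"), row.names = FALSE)
  utils::write.csv(data.frame(strain = growth$strains,
                              growth = unname(growth$community)),
                   file.path(dir, "community.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_growth_table
#' @export
read_growth_table <- function(dir) {
  alone_df <- utils::read.csv(file.path(dir, "alone.csv"),
                              stringsAsFactors = FALSE)
  pairs_df <- utils::read.csv(file.path(dir, "pairs.csv"),
                              stringsAsFactors = FALSE)
  comm_df <- utils::read.csv(file.path(dir, "community.csv"),
                             stringsAsFactors = FALSE)
  strains <- alone_df$strain
  paired <- matrix(NA_real_, length(strains), length(strains),
                   dimnames = list(strains, strains))
  ij <- cbind(match(pairs_df$strain, strains), match(pairs_df$partner, strains))
  if (anyNA(ij)) stop("pairs.csv names a strain absent from alone.csv",
                      call. = FALSE)
  paired[ij] <- pairs_df$growth
  growth_table(stats::setNames(alone_df$growth, strains), paired,
               stats::setNames(comm_df$growth, comm_df$strain))
}

#' Classify the effect of co-culture on one strain
#'
#' Relative growth change r = (paired - alone) / alone: `'+'` if r > +threshold,
#' `'-'` if r < -threshold, else `'0'` (within the neutral band, default
#' +/- 10%). A strain with zero growth alone is a degenerate case: `'+'` if
#' it grows at all when paired, else `'0'`.
#'
#' @param alone,paired Non-negative growth values.
#' @param threshold Neutral band half-width as a fraction (default 0.10).
#' @return One of `"+"`, `"0"`, `"-"`.
#' @export
classify_effect <- function(alone, paired, threshold = 0.10) {
  if (alone == 0) {
    message("zero growth alone: effect classified from paired growth only")
    return(if (paired > 0) "+" else "0")
  }
  r <- (paired - alone) / alone
  if (r > threshold) "+" else if (r < -threshold) "-" else "0"
}

#' Interaction label from an unordered pair of effects
#'
#' (+,+) mutualism; (+,0) commensalism; (+,-) parasitism; (-,0) amensalism;
#' (0,0) neutralism; (-,-) competition.
#'
#' @param e1,e2 Effects (`"+"`, `"0"`, `"-"`), order-free.
#' @return Label string.
#' @export
interaction_label <- function(e1, e2) {
  # character sort order is locale-dependent; rank effects explicitly
  rank <- c("+" = 1L, "0" = 2L, "-" = 3L)
  if (anyNA(rank[c(e1, e2)])) {
    stop("effects must be one of '+', '0', '-'", call. = FALSE)
  }
  pair <- c(e1, e2)[order(rank[c(e1, e2)])]
  key <- paste(pair, collapse = "")
  switch(key,
         "++" = "mutualism",
         "+0" = "commensalism",
         "+-" = "parasitism",
         "0-" = "amensalism",
         "00" = "neutralism",
         "--" = "competition",
         stop("invalid effect pair: ", key, call. = FALSE))
}

#' Classify one unordered pair of strains
#'
#' @param growth A [growth_table()].
#' @param i,j Distinct strain ids.
#' @param threshold Neutral band (see [classify_effect()]).
#' @return List with `strain_i`, `strain_j`, `effect_on_i`, `effect_on_j`,
#'   `label`.
#' @export
classify_pair <- function(growth, i, j, threshold = 0.10) {
  if (identical(i, j)) stop("i and j must differ", call. = FALSE)
  if (!all(c(i, j) %in% growth$strains)) {
    stop("strain(s) missing from growth table", call. = FALSE)
  }
  pi <- growth$paired[i, j]
  pj <- growth$paired[j, i]
  if (is.na(pi) || is.na(pj)) {
    stop("missing paired growth entry for (", i, ", ", j, ")", call. = FALSE)
  }
  ei <- classify_effect(growth$alone[[i]], pi, threshold)
  ej <- classify_effect(growth$alone[[j]], pj, threshold)
  list(strain_i = i, strain_j = j, effect_on_i = ei, effect_on_j = ej,
       label = interaction_label(ei, ej))
}

#' Classify every unordered pair of a growth table
#'
#' @inheritParams classify_pair
#' @return data.frame with one row per unordered pair: `strain_i`,
#'   `strain_j`, `effect_on_i`, `effect_on_j`, `label`.
#' @export
interaction_matrix <- function(growth, threshold = 0.10) {
  n <- length(growth$strains)
  pairs <- utils::combn(growth$strains, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    as.data.frame(classify_pair(growth, pairs[1, k], pairs[2, k], threshold),
                  stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Viability screen for one SynCom (step 4 rules)
#'
#' Three rules: (1) strictly more than `min_nonneg_frac` (default 50%) of
#' the unordered pairs must be non-negative, i.e. contain no `'-'` effect
#' (mutualism, commensalism or neutralism); (2) every strain must receive at
#' least one `'+'` effect; (3) every strain must grow in the full-community
#' run (growth > `community_growth_floor`). The per-effect count
#' (`pct_nonnegative_effects`) is also reported for comparison with the
#' per-pair reading of rule 1.
#'
#' @param growth A [growth_table()] with >= 2 strains.
#' @param threshold Neutral band for effect classification.
#' @param min_nonneg_frac Rule-1 fraction; strict `>`.
#' @param community_growth_floor Rule-3 growth floor; strict `>`.
#' @return A `viability_report`: list with `pct_nonnegative_pairs`,
#'   `pct_nonnegative_effects`, `strains_lacking_positive`,
#'   `strains_not_growing_in_community`, `rule_results` and `viable`.
#' @export
assess_syncom <- function(growth, threshold = 0.10, min_nonneg_frac = 0.5,
                          community_growth_floor = 0) {
  if (length(growth$strains) < 2L) {
    stop("viability needs >= 2 strains", call. = FALSE)
  }
  im <- interaction_matrix(growth, threshold)
  nonneg_pair <- im$effect_on_i != "-" & im$effect_on_j != "-"
  effects <- c(im$effect_on_i, im$effect_on_j)
  got_plus <- unique(c(im$strain_i[im$effect_on_i == "+"],
                       im$strain_j[im$effect_on_j == "+"]))
  lacking <- setdiff(growth$strains, got_plus)
  not_growing <- growth$strains[growth$community <= community_growth_floor]
  rules <- c(
    nonnegative_pairs = mean(nonneg_pair) > min_nonneg_frac,
    all_strains_positive = length(lacking) == 0L,
    all_grow_in_community = length(not_growing) == 0L
  )
  structure(list(
    pct_nonnegative_pairs = 100 * mean(nonneg_pair),
    pct_nonnegative_effects = 100 * mean(effects != "-"),
    interaction_counts = table(factor(im$label, levels = c(
      "mutualism", "commensalism", "parasitism", "amensalism",
      "neutralism", "competition"))),
    strains_lacking_positive = lacking,
    strains_not_growing_in_community = not_growing,
    rule_results = rules,
    viable = all(rules)
  ), class = "viability_report")
}

#' @export
print.viability_report <- function(x, ...) {
  cat("<viability_report> viable:", x$viable,
      sprintf("(%.1f%% pairs non-negative; %d strain(s) lacking '+'; %d not growing)\n",
              x$pct_nonnegative_pairs, length(x$strains_lacking_positive),
              length(x$strains_not_growing_in_community)))
  invisible(x)
}

#' Walk the ranked candidate list until a viable SynCom is found (step 4)
#'
#' Simulates and assesses candidates in rank order; returns the first viable
#' one together with every report produced. A simulator failure marks the
#' candidate inviable (logged) and the walk continues.
#'
#' @param candidates Either a ranked data.frame from [rank_candidates()] or
#'   a list of member-id character vectors, best first.
#' @param simulator Function `(members) -> growth_table`.
#' @param threshold,min_nonneg_frac,community_growth_floor Passed to
#'   [assess_syncom()].
#' @param max_candidates Stop after this many simulations (default all).
#' @return List with `viable_found` (logical), `winner_index` (`NA` if
#'   none), `winner_members`, and `reports` (one per candidate walked).
#' @export
screen_ranked <- function(candidates, simulator, threshold = 0.10,
                          min_nonneg_frac = 0.5, community_growth_floor = 0,
                          max_candidates = Inf) {
  member_sets <- if (is.data.frame(candidates)) {
    strsplit(candidates$members, "+", fixed = TRUE)
  } else candidates
  if (length(member_sets) == 0L) stop("no candidates to screen", call. = FALSE)
  reports <- list()
  for (k in seq_along(member_sets)) {
    if (k > max_candidates) break
    rep_k <- tryCatch({
      g <- simulator(member_sets[[k]])
      assess_syncom(g, threshold, min_nonneg_frac, community_growth_floor)
    }, error = function(e) {
      message("simulator failed for candidate ", k, ": ", conditionMessage(e),
              " (treated as inviable)")
      structure(list(pct_nonnegative_pairs = NA_real_,
                     pct_nonnegative_effects = NA_real_,
                     interaction_counts = NULL,
                     strains_lacking_positive = member_sets[[k]],
                     strains_not_growing_in_community = character(),
                     rule_results = c(simulator_ok = FALSE),
                     viable = FALSE), class = "viability_report")
    })
    reports[[k]] <- rep_k
    if (isTRUE(rep_k$viable)) {
      return(list(viable_found = TRUE, winner_index = k,
                  winner_members = sort(member_sets[[k]]), reports = reports))
    }
  }
  list(viable_found = FALSE, winner_index = NA_integer_,
       winner_members = character(), reports = reports)
}

#' Toy growth simulator
#'
#' Deterministic stand-in for a metabolic-model simulation stage. Growth
#' alone is the per-strain baseline; paired growth of i with j is
#' `baseline_i * (1 + e[i, j] + noise)` where `e[i, j]` is the signed effect
#' of partner j on i; community growth uses the mean effect over partners.
#' Noise is uniform on `+/- noise_amp` (default 0) and reproducible per
#' seed.
#'
#' @param members Character vector of strain ids.
#' @param params List with `baseline` (named numeric) and `effects` (signed
#'   matrix, `effects[i, j]` = effect of j on i; diagonal ignored), each
#'   covering every member; optional `noise_amp` (default 0).
#' @param seed Integer seed for the noise stream.
#' @return A [growth_table()].
#' @export
toy_simulate <- function(members, params, seed = 1L) {
  members <- sort(members)
  baseline <- params$baseline[members]
  if (anyNA(baseline)) stop("baseline missing for some member", call. = FALSE)
  e <- params$effects[members, members, drop = FALSE]
  noise_amp <- if (is.null(params$noise_amp)) 0 else params$noise_amp
  n <- length(members)
  rng <- local({
    set.seed(seed)
    function(k) if (noise_amp == 0) numeric(k) else
      stats::runif(k, -noise_amp, noise_amp)
  })
  paired <- matrix(NA_real_, n, n, dimnames = list(members, members))
  noise_pair <- matrix(rng(n * n), n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) {
      paired[i, j] <- max(0, baseline[i] * (1 + e[i, j] + noise_pair[i, j]))
    }
  }
  mean_e <- vapply(seq_len(n), function(i) mean(e[i, -i]), 0)
  community <- pmax(0, baseline * (1 + mean_e + rng(n)))
  growth_table(stats::setNames(baseline, members), paired,
               stats::setNames(community, members))
}
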