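#' Pipeline run configuration
#'
#' Bundles every tunable of the four-step workflow with its default:
#' per-sample selection depth 20, SynCom size 10, shortlist prevalence
#' 33.3%, core weight 0.0005, discriminatory weight 0.0012, Fisher alpha
#' 0.05, interaction threshold 10%, rule-1 fraction 50%, species-level
#' taxonomic filtering.
#'
#' @param samples Path to the group-A sample profile-matrix TSV (or a
#'   [profile_matrix()]).
#' @param genomes Path to the genome profile-matrix TSV (or a matrix).
#' @param taxonomy Path to a GTDB-Tk summary TSV (or a parsed data.frame);
#'   `NULL` disables the taxonomic filter.
#' @param samples2 Optional second group (enables discriminatory weighting).
#' @param out_dir Output directory for artifacts.
#' @param depth,syn_size,prevalence,w_core,w_disc,alpha Numeric knobs (see
#'   description).
#' @param tax_level Rank for the taxonomic filter.
#' @param interaction_threshold,min_nonneg_frac,community_growth_floor
#'   Viability knobs.
#' @param max_combinations,top_k Enumeration/ranking bounds.
#' @param max_screen Candidates to simulate at most during step 4.
#' @param seed Integer seed (drives the toy simulator).
#' @return A `run_config` list.
#' @export
syncom_config <- function(samples, genomes, taxonomy = NULL, samples2 = NULL,
                          out_dir = NULL, depth = 20L, syn_size = 10L,
                          prevalence = 1 / 3, w_core = 0.0005,
                          w_disc = 0.0012, alpha = 0.05,
                          tax_level = "species",
                          interaction_threshold = 0.10,
                          min_nonneg_frac = 0.5,
                          community_growth_floor = 0,
                          max_combinations = 1e7, top_k = 10000L,
                          max_screen = 100L, seed = 1L) {
  cfg <- list(samples = samples, genomes = genomes, taxonomy = taxonomy,
              samples2 = samples2, out_dir = out_dir, depth = depth,
              syn_size = syn_size, prevalence = prevalence, w_core = w_core,
              w_disc = w_disc, alpha = alpha, tax_level = tax_level,
              interaction_threshold = interaction_threshold,
              min_nonneg_frac = min_nonneg_frac,
              community_growth_floor = community_growth_floor,
              max_combinations = max_combinations, top_k = top_k,
              max_screen = max_screen, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

run_config_keys <- function() names(formals(syncom_config))

#' Write / read a run configuration (JSON)
#'
#' Path-valued fields only; the round trip is lossless and unknown keys in a
#' file are rejected.
#'
#' @param config A `run_config`.
#' @param path JSON file path.
#' @return `read_syncom_config` returns a `run_config`.
#' @export
write_syncom_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_syncom_config
#' @export
read_syncom_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), run_config_keys())
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(syncom_config, raw)
}

load_matrix_arg <- function(x, what) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "profile_matrix")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("input error: ", what, " file not found: ", x,
                              call. = FALSE)
    return(read_profile_matrix(x))
  }
  stop("input error: ", what, " must be a path or profile_matrix",
       call. = FALSE)
}

load_taxonomy_arg <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) {
    if (!"genome_id" %in% names(x) && "user_genome" %in% names(x)) {
      ranks <- t(vapply(x$classification, parse_gtdb_classification,
                        character(7), USE.NAMES = FALSE))
      colnames(ranks) <- names(parse_gtdb_classification(""))
      x <- cbind(data.frame(genome_id = x$user_genome,
                            classification = x$classification,
                            stringsAsFactors = FALSE),
                 as.data.frame(ranks, stringsAsFactors = FALSE))
    }
    return(x)
  }
  read_gtdbtk_summary(x)
}

#' Run the full four-step SynCom design pipeline
#'
#' Step 1: per-sample iterative greedy selection. Step 2: prevalence
#' shortlist, combination enumeration, taxonomic filter. Step 3: group
#' scoring and ranking. Step 4: viability screen down the ranked list with
#' the supplied simulator (default: the planted-mix toy simulator seeded
#' from `config$seed`). Artifacts (per-sample traces, shortlist, ranked
#' candidates, winner, JSON summary) are written to `config$out_dir` when
#' set.
#'
#' @param config A [syncom_config()].
#' @param simulator Optional function `(members) -> growth_table`; `NULL`
#'   uses the toy simulator.
#' @return List with `status` (`"ok"`, `"no_shortlist"`,
#'   `"no_viable_candidate"`), `exit_code` (0, 2, 3), `traces`,
#'   `shortlisted`, `ranked`, `screen`, `winner_members` and `summary`.
#' @export
run_pipeline <- function(config, simulator = NULL) {
  stopifnot(inherits(config, "run_config"))
  genomes <- load_matrix_arg(config$genomes, "genomes")
  samples <- load_matrix_arg(config$samples, "samples")
  samples2 <- load_matrix_arg(config$samples2, "samples2")
  taxonomy <- load_taxonomy_arg(config$taxonomy)

  core <- core_functions(samples)
  disc <- if (!is.null(samples2)) {
    discriminatory_functions(samples, samples2, alpha = config$alpha)$enriched_in_A
  } else character()
  weights <- build_weight_vector(core, disc, config$w_core, config$w_disc)
  log_step <- function(...) message("[syncom] ", sprintf(...))
  log_step("weights: %d core, %d discriminatory Pfam(s)", length(core),
           length(disc))

  traces <- lapply(rownames(samples), function(id) {
    suppressMessages(iterative_select(profile_from_matrix(samples, id),
                                      genomes, weights, depth = config$depth))
  })
  log_step("step 1: %d per-sample trace(s), depth %d", length(traces),
           config$depth)

  shortlisted <- shortlist(traces, config$prevalence)
  log_step("step 2: %d strain(s) shortlisted at prevalence >= %.3f",
           length(shortlisted), config$prevalence)
  out <- list(traces = traces, shortlisted = shortlisted,
              weights = weights)
  if (length(shortlisted) < config$syn_size) {
    out$status <- "no_shortlist"
    out$exit_code <- 2L
    out$summary <- pipeline_summary(config, out)
    write_artifacts(config, out)
    return(out)
  }

  candidates <- enumerate_candidates(shortlisted, config$syn_size,
                                     config$max_combinations)
  n_enumerated <- ncol(candidates)
  if (!is.null(taxonomy)) {
    candidates <- taxonomic_filter(candidates, taxonomy, config$tax_level)
  }
  log_step("step 2: %d combination(s) enumerated, %d after %s-level filter",
           n_enumerated, ncol(candidates), config$tax_level)
  if (ncol(candidates) == 0L) {
    out$status <- "no_shortlist"
    out$exit_code <- 2L
    out$n_enumerated <- n_enumerated
    out$summary <- pipeline_summary(config, out)
    write_artifacts(config, out)
    return(out)
  }

  ranked <- rank_candidates(candidates, genomes, samples, weights,
                            top_k = config$top_k)
  log_step("step 3: %d candidate(s) ranked; best group score %.2f",
           nrow(ranked), ranked$group_score[1])

  if (is.null(simulator)) {
    mix <- fixture_spec()$interaction_mix
    simulator <- function(members) {
      generate_growth_fixture(members, mix,
                              seed = config$seed + 3000L)$growth
    }
  }
  screen <- screen_ranked(ranked, simulator,
                          threshold = config$interaction_threshold,
                          min_nonneg_frac = config$min_nonneg_frac,
                          community_growth_floor = config$community_growth_floor,
                          max_candidates = config$max_screen)
  log_step("step 4: %d candidate(s) screened; viable: %s",
           length(screen$reports), screen$viable_found)

  out$ranked <- ranked
  out$n_enumerated <- n_enumerated
  out$screen <- screen
  out$winner_members <- screen$winner_members
  if (screen$viable_found) {
    out$status <- "ok"
    out$exit_code <- 0L
  } else {
    out$status <- "no_viable_candidate"
    out$exit_code <- 3L
  }
  out$summary <- pipeline_summary(config, out)
  write_artifacts(config, out)
  out
}

pipeline_summary <- function(config, out) {
  list(
    tool = "SynComSelect",
    version = as.character(utils::packageVersion("SynComSelect")),
    status = out$status,
    config = unclass(config)[!vapply(unclass(config), is.null, TRUE)],
    n_samples = length(out$traces),
    n_shortlisted = length(out$shortlisted),
    n_enumerated = if (is.null(out$n_enumerated)) 0L else out$n_enumerated,
    n_ranked = if (is.null(out$ranked)) 0L else nrow(out$ranked),
    n_screened = if (is.null(out$screen)) 0L else length(out$screen$reports),
    winner_members = out$winner_members,
    winner_group_score = if (!is.null(out$screen) && out$screen$viable_found) {
      out$ranked$group_score[out$screen$winner_index]
    } else NULL,
    # wall-clock metadata quarantined in one field so determinism checks can
    # drop it
    generated_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}

write_artifacts <- function(config, out) {
  dir <- config$out_dir
  if (is.null(dir)) return(invisible(NULL))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  traces_df <- do.call(rbind, lapply(out$traces, function(t) {
    if (nrow(t$picks) == 0L) return(NULL)
    cbind(sample_id = t$sample_id, t$picks, pick_order = seq_len(nrow(t$picks)))
  }))
  if (!is.null(traces_df)) {
    utils::write.csv(traces_df, file.path(dir, "traces.csv"),
                     row.names = FALSE)
  }
  writeLines(out$shortlisted, file.path(dir, "shortlist.tsv"))
  if (!is.null(out$ranked)) {
    utils::write.csv(out$ranked, file.path(dir, "ranked_candidates.csv"),
                     row.names = FALSE)
  }
  if (!is.null(out$screen) && out$screen$viable_found) {
    jsonlite::write_json(list(
      members = out$winner_members,
      rank = out$screen$winner_index,
      group_score = out$ranked$group_score[out$screen$winner_index],
      pct_nonnegative_pairs =
        out$screen$reports[[out$screen$winner_index]]$pct_nonnegative_pairs
    ), file.path(dir, "winner.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(out$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}
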