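#' Specification of a synthetic fixture
#'
#' Describes the world the generators emulate: a strain collection with a
#' shared functional core plus accessory functions, metagenomes that are
#' noisy unions of a planted "truth" community, optional two-group structure
#' with differentially prevalent functions, taxonomy labels with deliberate
#' same-species duplicates, and a pairwise interaction mix for growth data.
#' Defaults match the stated benchmark world: 60 samples, 40 genomes, a
#' 2000-Pfam universe, a 10-member truth community and 5% sample noise.
#'
#' @param seed Integer master seed; every generator is a pure function of
#'   (spec, seed).
#' @param n_genomes Strains in the collection.
#' @param n_samples_per_group Metagenomes per group.
#' @param n_groups 1 or 2.
#' @param universe_size Pfams in the universe.
#' @param core_frac Fraction of the universe shared by all genomes.
#' @param accessory_frac Fraction of the universe sampled (without
#'   replacement) as each genome's accessory set.
#' @param planted_truth_members Genomes (the first k ids) whose union
#'   defines every sample.
#' @param planted_disc_pfams Pfams planted at prevalence 0.9 in group A and
#'   0.1 in group B (two-group specs only).
#' @param noise_frac Fraction of the universe added to each sample as noise.
#' @param n_species_duplicates Genomes (among the non-truth strains) that
#'   deliberately share one species label, to exercise the taxonomic filter.
#' @param interaction_mix Named fractions over the six interaction labels;
#'   must sum to 1.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_genomes = 40L, n_samples_per_group = 60L,
                         n_groups = 1L, universe_size = 2000L,
                         core_frac = 0.10, accessory_frac = 0.15,
                         planted_truth_members = 10L, planted_disc_pfams = 20L,
                         noise_frac = 0.05, n_species_duplicates = 2L,
                         interaction_mix = c(mutualism = 0.25,
                                             commensalism = 0.30,
                                             neutralism = 0.25,
                                             amensalism = 0.10,
                                             parasitism = 0.05,
                                             competition = 0.05)) {
  fr <- c(core_frac, accessory_frac, noise_frac)
  if (any(fr < 0 | fr > 1)) stop("fractions must be in [0, 1]", call. = FALSE)
  if (!n_groups %in% 1:2) stop("n_groups must be 1 or 2", call. = FALSE)
  if (abs(sum(interaction_mix) - 1) > 1e-9) {
    stop("interaction_mix must sum to 1", call. = FALSE)
  }
  if (planted_truth_members > n_genomes) {
    stop("more truth members than genomes", call. = FALSE)
  }
  spec <- list(seed = as.integer(seed), n_genomes = as.integer(n_genomes),
               n_samples_per_group = as.integer(n_samples_per_group),
               n_groups = as.integer(n_groups),
               universe_size = as.integer(universe_size),
               core_frac = core_frac, accessory_frac = accessory_frac,
               planted_truth_members = as.integer(planted_truth_members),
               planted_disc_pfams = as.integer(planted_disc_pfams),
               noise_frac = noise_frac,
               n_species_duplicates = as.integer(n_species_duplicates),
               interaction_mix = interaction_mix)
  class(spec) <- "fixture_spec"
  spec
}

fixture_universe <- function(spec) {
  if (spec$universe_size > 99999L) stop("universe too large for PF#####",
                                        call. = FALSE)
  sprintf("PF%05d", seq_len(spec$universe_size))
}

#' Generate a synthetic strain collection with taxonomy
#'
#' Every genome carries the shared core (the first `core_frac` of the
#' universe) plus a random accessory subset. Taxonomy assigns one genus and
#' species per genome; `n_species_duplicates` non-truth genomes share one
#' species label. Deterministic per `spec$seed`.
#'
#' @param spec A [fixture_spec()].
#' @return List with `profiles` (a [profile_matrix()]), `taxonomy` (GTDB-Tk
#'   style data.frame with `user_genome`, `classification`) and
#'   `truth_members` (the planted community ids).
#' @export
generate_genomes <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  universe <- fixture_universe(spec)
  n_core <- round(spec$core_frac * spec$universe_size)
  n_acc <- round(spec$accessory_frac * spec$universe_size)
  if (n_core + n_acc > spec$universe_size) {
    stop("universe too small for requested core/accessory fractions",
         call. = FALSE)
  }
  core <- universe[seq_len(n_core)]
  pool <- universe[-seq_len(n_core)]
  set.seed(spec$seed)
  ids <- sprintf("G%03d", seq_len(spec$n_genomes))
  profiles <- lapply(seq_len(spec$n_genomes), function(i) {
    pfam_profile(ids[i], c(core, sample(pool, n_acc)))
  })
  mat <- build_profile_matrix(profiles, universe = universe)
  genus <- sprintf("g__Genus%03d", seq_len(spec$n_genomes))
  species <- sprintf("s__Genus%03d sp%03d", seq_len(spec$n_genomes),
                     seq_len(spec$n_genomes))
  if (spec$n_species_duplicates >= 2L) {
    # duplicates sit among the last (non-truth) genomes so the planted
    # community itself is never removed by the species filter
    dup <- seq(spec$n_genomes - spec$n_species_duplicates + 1L, spec$n_genomes)
    species[dup] <- species[dup[1]]
    genus[dup] <- genus[dup[1]]
  }
  taxonomy <- data.frame(
    user_genome = ids,
    classification = sprintf(
      "d__Bacteria;p__Phylum01;c__Class01;o__Order01;f__Family%03d;%s;%s",
      seq_len(spec$n_genomes), genus, species),
    stringsAsFactors = FALSE)
  list(profiles = mat, taxonomy = taxonomy,
       truth_members = ids[seq_len(spec$planted_truth_members)])
}

#' Generate synthetic metagenome profile matrices
#'
#' Each sample is the union of the truth members' profiles plus
#' `noise_frac * universe_size` random universe Pfams. With two groups,
#' `planted_disc_pfams` Pfams drawn from outside the truth union are
#' injected at prevalence 0.9 in group A and 0.1 in group B (exact counts).
#' Deterministic per `spec$seed` (offset from the genome stream so genome
#' and sample noise are independent).
#'
#' @param genomes Output of [generate_genomes()] (or a [profile_matrix()]
#'   plus `truth_members` given explicitly).
#' @param spec A [fixture_spec()].
#' @param truth_members Optional override of the planted community.
#' @return List with `groups` (list of 1 or 2 [profile_matrix()] objects),
#'   `truth_union` (accession vector) and `disc_pfams` (planted accessions,
#'   empty for one group).
#' @export
generate_metagenomes <- function(genomes, spec, truth_members = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  mat <- if (is.list(genomes) && !is.null(genomes$profiles)) genomes$profiles
         else genomes
  if (is.null(truth_members)) {
    truth_members <- if (is.list(genomes) && !is.null(genomes$truth_members)) {
      genomes$truth_members
    } else rownames(mat)[seq_len(spec$planted_truth_members)]
  }
  universe <- colnames(mat)
  truth_union <- syncom_union_profile(truth_members, mat, "truth")$pfams
  n_noise <- round(spec$noise_frac * length(universe))
  set.seed(spec$seed + 1000L)
  disc <- character()
  if (spec$n_groups == 2L && spec$planted_disc_pfams > 0L) {
    outside <- setdiff(universe, truth_union)
    if (length(outside) < spec$planted_disc_pfams) {
      stop("universe too small to plant discriminatory Pfams", call. = FALSE)
    }
    disc <- sort(sample(outside, spec$planted_disc_pfams))
  }
  n <- spec$n_samples_per_group
  noise_pool <- setdiff(universe, disc)  # keep planted prevalences exact
  make_group <- function(gname, disc_prev) {
    carriers <- lapply(disc, function(p) sample(n, round(disc_prev * n)))
    profs <- lapply(seq_len(n), function(s) {
      pf <- union(truth_union, sample(noise_pool, n_noise))
      pf <- union(pf, disc[vapply(carriers, function(cs) s %in% cs, TRUE)])
      pfam_profile(sprintf("%s_S%03d", gname, s), pf)
    })
    build_profile_matrix(profs, universe = universe)
  }
  groups <- if (spec$n_groups == 2L) {
    list(A = make_group("A", 0.9), B = make_group("B", 0.1))
  } else {
    list(A = make_group("A", 0))
  }
  list(groups = groups, truth_union = truth_union, disc_pfams = disc)
}

#' Write HMMER-style tblout files that round-trip through the parser
#'
#' One syntactically valid per-sequence (`tblout`) file per entity, one hit
#' line per Pfam (with a versioned accession), such that
#' [parse_hmmer_tblout()] recovers each profile exactly.
#'
#' @param profiles A [profile_matrix()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
generate_hmmer_files <- function(profiles, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(rownames(profiles), function(id) {
    pf <- profile_from_matrix(profiles, id)$pfams
    path <- file.path(out_dir, paste0(id, ".tblout"))
    header <- c(
      "#                                                               --- full sequence ---- --- best 1 domain ---- --- domain number estimation ----",
      "# target name        accession  query name           accession    E-value  score  bias   E-value  score  bias   exp reg clu  ov env dom rep inc description of target")
    body <- if (length(pf)) sprintf(
      "Fam_%s            %s.1   prot_%05d            -            1.2e-30  105.4   0.1   1.5e-30  104.9   0.1   1.1   1   0   0   1   1   1   1 synthetic domain",
      pf, pf, seq_along(pf)) else character()
    writeLines(c(header, body, "#"), path)
    path
  }, "")
  invisible(paths)
}

#' Generate a growth table with a planted interaction mix
#'
#' Each unordered pair is assigned a label drawn from `interaction_mix`
#' (deterministic per seed), then alone/paired/community growth values are
#' constructed so that classification at the default 10% threshold recovers
#' exactly the planted labels: signed effects are +/-20%, neutral effects
#' +5%.
#'
#' @param members Character vector of strain ids (>= 2).
#' @param interaction_mix Named fractions over the six labels, summing to 1.
#' @param seed Integer seed.
#' @return List with `growth` (a [growth_table()]) and `planted_labels`
#'   (data.frame: strain_i, strain_j, label).
#' @export
generate_growth_fixture <- function(members,
                                    interaction_mix = fixture_spec()$interaction_mix,
                                    seed = 1L) {
  stopifnot(length(members) >= 2L)
  if (abs(sum(interaction_mix) - 1) > 1e-9) {
    stop("interaction_mix must sum to 1", call. = FALSE)
  }
  members <- sort(members)
  n <- length(members)
  pairs <- utils::combn(members, 2)
  n_pairs <- ncol(pairs)
  labels <- names(interaction_mix)
  # largest-remainder apportionment keeps planted fractions as close to the
  # requested mix as integer pair counts allow
  quota <- interaction_mix * n_pairs
  counts <- floor(quota)
  short <- n_pairs - sum(counts)
  if (short > 0) {
    extra <- order(quota - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  set.seed(seed)
  assigned <- sample(rep(labels, times = counts))
  effect_of <- c("+" = 0.20, "0" = 0.05, "-" = -0.20)
  label_effects <- list(mutualism = c("+", "+"), commensalism = c("+", "0"),
                        parasitism = c("+", "-"), amensalism = c("-", "0"),
                        neutralism = c("0", "0"), competition = c("-", "-"))
  baseline <- stats::setNames(stats::runif(n, 0.5, 1.5), members)
  e <- matrix(0, n, n, dimnames = list(members, members))
  for (k in seq_len(n_pairs)) {
    eff <- label_effects[[assigned[k]]]
    if (stats::runif(1) < 0.5) eff <- rev(eff)   # who gets which side
    e[pairs[1, k], pairs[2, k]] <- effect_of[[eff[1]]]
    e[pairs[2, k], pairs[1, k]] <- effect_of[[eff[2]]]
  }
  paired <- matrix(NA_real_, n, n, dimnames = list(members, members))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) paired[i, j] <- baseline[i] * (1 + e[i, j])
  }
  community <- pmax(baseline * (1 + vapply(seq_len(n), function(i)
    mean(e[i, -i]), 0)), 0.01)
  list(
    growth = growth_table(baseline, paired, community),
    planted_labels = data.frame(strain_i = pairs[1, ], strain_j = pairs[2, ],
                                label = assigned, stringsAsFactors = FALSE)
  )
}

#' Write a complete fixture bundle to disk
#'
#' Emits everything the pipeline consumes: genome and per-group sample
#' profile matrices (TSV), a GTDB-Tk style taxonomy TSV, a directory of
#' tblout files, and growth CSVs for the truth community.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory.
#' @return Invisibly, a list of the written paths.
#' @export
write_fixture_bundle <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_genomes(spec)
  met <- generate_metagenomes(gen, spec)
  paths <- list(genomes = file.path(out_dir, "genomes.tsv"),
                taxonomy = file.path(out_dir, "taxonomy.tsv"))
  write_profile_matrix(gen$profiles, paths$genomes)
  utils::write.table(gen$taxonomy, paths$taxonomy, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (g in names(met$groups)) {
    p <- file.path(out_dir, sprintf("samples_%s.tsv", g))
    write_profile_matrix(met$groups[[g]], p)
    paths[[paste0("samples_", g)]] <- p
  }
  paths$tblout_dir <- file.path(out_dir, "tblout")
  generate_hmmer_files(gen$profiles, paths$tblout_dir)
  gf <- generate_growth_fixture(gen$truth_members, spec$interaction_mix,
                                seed = spec$seed + 2000L)
  paths$growth_dir <- file.path(out_dir, "growth")
  write_growth_table(gf$growth, paths$growth_dir)
  invisible(paths)
}
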