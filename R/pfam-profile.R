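#' Binary Pfam profile of a single entity
#'
#' A `pfam_profile` is the presence set of Pfam accessions encoded by one
#' entity: an isolate genome, a metagenome assembly, or the union profile of
#' a synthetic community (SynCom). Accessions are version-stripped
#' (`"PF00001.21"` becomes `"PF00001"`), deduplicated and kept sorted, so two
#' profiles compare as sets.
#'
#' @param entity_id Single non-empty string identifying the entity.
#' @param pfams Character vector of Pfam accessions. Version suffixes
#'   (`".N"`) are stripped; duplicates collapse. May be empty.
#' @return An object of class `pfam_profile`: a list with elements
#'   `entity_id` (string) and `pfams` (sorted character vector).
#' @examples
#' p <- pfam_profile("genomeA", c("PF00005.27", "PF00005.27", "PF07690.16"))
#' p$pfams  # "PF00005" "PF07690"
#' @export
pfam_profile <- function(entity_id, pfams = character()) {
  if (!is.character(entity_id) || length(entity_id) != 1L || is.na(entity_id) ||
      !nzchar(entity_id)) {
    stop("entity_id must be a single non-empty string", call. = FALSE)
  }
  pfams <- strip_pfam_version(as.character(pfams))
  bad <- pfams[!grepl("^PF[0-9]{5}$", pfams)]
  if (length(bad) > 0L) {
    stop("invalid Pfam accession(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  structure(list(entity_id = entity_id, pfams = sort(unique(pfams))),
            class = "pfam_profile")
}

#' @export
print.pfam_profile <- function(x, ...) {
  cat("<pfam_profile> ", x$entity_id, ": ", length(x$pfams), " Pfams\n",
      sep = "")
  invisible(x)
}

#' @export
length.pfam_profile <- function(x) length(x$pfams)

# "PF00001.21" -> "PF00001"; leaves non-versioned strings untouched
strip_pfam_version <- function(x) sub("\\.[0-9]+$", "", x)

is_pfam_profile <- function(x) inherits(x, "pfam_profile")

as_profile <- function(x, entity_id = "profile") {
  if (is_pfam_profile(x)) x else pfam_profile(entity_id, x)
}

#' Compare a candidate profile against a sample profile
#'
#' Computes the match/mismatch bookkeeping used throughout SynCom
#' benchmarking. With candidate set A and sample set B:
#' matches = |A intersect B|, mismatches = |A \ B|,
#' pct_matches = 100 * matches / |B| (coverage of the target ecosystem),
#' pct_mismatches = 100 * mismatches / |A| (extraneous functions introduced;
#' 0 for an empty candidate), and Jaccard distance 1 - |A∩B| / |A∪B|.
#'
#' @param candidate,sample `pfam_profile` objects (or character vectors of
#'   accessions). The sample must be nonempty.
#' @return A list of class `match_stats` with fields `n_matches`,
#'   `n_mismatches`, `pct_matches`, `pct_mismatches`, `jaccard_distance`.
#' @examples
#' a <- pfam_profile("syncom", c("PF00001", "PF00002", "PF00005"))
#' b <- pfam_profile("sample", c("PF00001", "PF00002", "PF00003", "PF00004"))
#' match_stats(a, b)$jaccard_distance  # 1 - 2/5 = 0.6
#' @export
match_stats <- function(candidate, sample) {
  candidate <- as_profile(candidate, "candidate")
  sample <- as_profile(sample, "sample")
  if (length(sample$pfams) == 0L) {
    stop("sample profile is empty: percentage of matches is undefined",
         call. = FALSE)
  }
  a <- candidate$pfams
  b <- sample$pfams
  n_int <- sum(a %in% b)
  n_union <- length(a) + length(b) - n_int
  structure(list(
    n_matches = n_int,
    n_mismatches = length(a) - n_int,
    pct_matches = 100 * n_int / length(b),
    pct_mismatches = if (length(a) == 0L) 0 else 100 * (length(a) - n_int) / length(a),
    jaccard_distance = 1 - n_int / n_union
  ), class = "match_stats")
}
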