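#' Parse HMMER tabular output into a Pfam profile
#'
#' Reads an `hmmscan`/`hmmsearch` per-sequence (`tblout`) or per-domain
#' (`domtblout`) table and returns the distinct Pfam accessions among the hit
#' records. The target accession column is used (for `hmmscan` the target is
#' the Pfam model; model names are not stable identifiers). Trailing version
#' suffixes are stripped, and hits to the same Pfam from multiple proteins
#' collapse to one entry. No score filtering is applied by default: the
#' Pfam gathering threshold is assumed to have been applied upstream
#' (`--cut_ga`); `score_floor` optionally drops hits below a full-sequence
#' bit score.
#'
#' @param path Path to the tabular file (or a connection).
#' @param dialect `"tblout"` (18 fixed columns + description) or
#'   `"domtblout"` (22 fixed columns + description).
#' @param entity_id Entity id for the returned profile; defaults to the file
#'   name without extension.
#' @param score_floor Optional numeric; hits with full-sequence score below
#'   it are dropped. Default `NULL` (off).
#' @return A [pfam_profile()].
#' @export
parse_hmmer_tblout <- function(path, dialect = c("tblout", "domtblout"),
                               entity_id = NULL, score_floor = NULL) {
  dialect <- match.arg(dialect)
  min_fields <- if (dialect == "tblout") 18L else 22L
  score_col <- if (dialect == "tblout") 6L else 8L
  if (is.null(entity_id)) {
    entity_id <- if (is.character(path)) {
      sub("\\.[^.]*$", "", basename(path))
    } else "profile"
  }
  lines <- readLines(path, warn = FALSE)
  hits <- character()
  skipped <- 0L
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(trimws(line)) || startsWith(trimws(line), "#")) next
    fields <- strsplit(trimws(line), "[ \t]+")[[1]]
    if (length(fields) < min_fields) {
      stop(sprintf("malformed %s line %d: %d field(s), expected >= %d",
                   dialect, ln, length(fields), min_fields), call. = FALSE)
    }
    if (!is.null(score_floor) &&
        suppressWarnings(as.numeric(fields[score_col])) < score_floor) next
    acc <- strip_pfam_version(fields[2])
    if (!grepl("^PF[0-9]{5}$", acc)) {
      skipped <- skipped + 1L
      next
    }
    hits <- c(hits, acc)
  }
  if (skipped > 0L) {
    warning(skipped, " hit record(s) without a PF##### target accession skipped",
            call. = FALSE)
  }
  pfam_profile(entity_id, hits)
}

#' Vectorize a directory of HMMER annotation files
#'
#' Parses every regular file in `input_dir` with [parse_hmmer_tblout()]
#' (entity id = file name stem) and assembles the binary profile matrix.
#'
#' @param input_dir Directory containing one annotation file per entity.
#' @param dialect Passed to [parse_hmmer_tblout()].
#' @param universe Optional explicit Pfam universe.
#' @return A [profile_matrix()].
#' @export
vectorize_hmmer_dir <- function(input_dir, dialect = "tblout",
                                universe = NULL) {
  files <- sort(list.files(input_dir, full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no files in ", input_dir, call. = FALSE)
  profiles <- lapply(files, parse_hmmer_tblout, dialect = dialect)
  build_profile_matrix(profiles, universe = universe)
}
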