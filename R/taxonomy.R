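#' Parse a GTDB-style classification string
#'
#' Splits `"d__...;p__...;c__...;o__...;f__...;g__...;s__..."` on `';'` and
#' rank prefixes into a named character vector over the seven ranks. Missing
#' or empty ranks yield `""` (unassigned).
#'
#' @param classification Single classification string.
#' @return Named character vector with names `domain`, `phylum`, `class`,
#'   `order`, `family`, `genus`, `species`.
#' @export
parse_gtdb_classification <- function(classification) {
  ranks <- c(d = "domain", p = "phylum", c = "class", o = "order",
             f = "family", g = "genus", s = "species")
  out <- stats::setNames(rep("", length(ranks)), unname(ranks))
  if (is.na(classification) || !nzchar(classification)) return(out)
  parts <- trimws(strsplit(classification, ";", fixed = TRUE)[[1]])
  for (part in parts) {
    m <- regmatches(part, regexec("^([dpcofgs])__(.*)$", part))[[1]]
    if (length(m) == 3L) out[ranks[[m[2]]]] <- trimws(m[3])
  }
  out
}

#' Read a GTDB-Tk classification summary table
#'
#' Accepts the GTDB-Tk summary TSV (columns `user_genome` and
#' `classification`; extra columns ignored) and parses each classification
#' string into per-rank labels.
#'
#' @param path Path to the summary TSV.
#' @return data.frame with columns `genome_id`, `classification`, and one
#'   column per rank (`domain` ... `species`; empty string = unassigned).
#' @export
read_gtdbtk_summary <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", check.names = FALSE,
                          colClasses = "character")
  need <- c("user_genome", "classification")
  if (!all(need %in% names(df))) {
    stop("GTDB-Tk summary must have columns 'user_genome' and 'classification'",
         call. = FALSE)
  }
  ranks <- t(vapply(df$classification, parse_gtdb_classification,
                    character(7), USE.NAMES = FALSE))
  colnames(ranks) <- names(parse_gtdb_classification(""))
  cbind(data.frame(genome_id = df$user_genome,
                   classification = df$classification,
                   stringsAsFactors = FALSE),
        as.data.frame(ranks, stringsAsFactors = FALSE))
}

#' Per-genome labels at one taxonomic rank
#'
#' @param taxonomy data.frame as returned by [read_gtdbtk_summary()].
#' @param level Rank name (`"domain"` ... `"species"`).
#' @param genome_ids Genomes to look up; an absent record is an error.
#' @return Named character vector of labels ("" = unassigned).
#' @export
taxon_labels <- function(taxonomy, level = "species", genome_ids = NULL) {
  level <- match.arg(level, c("domain", "phylum", "class", "order",
                              "family", "genus", "species"))
  if (is.null(genome_ids)) genome_ids <- taxonomy$genome_id
  idx <- match(genome_ids, taxonomy$genome_id)
  if (anyNA(idx)) {
    stop("no taxonomy record for genome(s): ",
         paste(genome_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  stats::setNames(taxonomy[[level]][idx], genome_ids)
}
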