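#' Entities-by-Pfam binary profile matrix
#'
#' A `profile_matrix` is an integer 0/1 matrix with one row per entity
#' (genome or metagenome) and one column per Pfam accession. The column
#' universe is sorted and duplicate-free; cell (i, j) is 1 iff Pfam j is
#' present in entity i's profile.
#'
#' @param values Integer/logical matrix with rownames (entity ids) and
#'   colnames (Pfam accessions), values in {0, 1}.
#' @return A `profile_matrix` object.
#' @export
profile_matrix <- function(values) {
  if (!is.matrix(values)) stop("values must be a matrix", call. = FALSE)
  if (is.null(rownames(values)) && nrow(values) > 0L) {
    stop("values must have entity ids as rownames", call. = FALSE)
  }
  if (is.null(colnames(values)) && ncol(values) > 0L) {
    stop("values must have Pfam accessions as colnames", call. = FALSE)
  }
  storage.mode(values) <- "integer"
  if (length(values) && !all(values %in% c(0L, 1L))) {
    stop("profile matrix cells must be 0 or 1", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate entity_id: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate Pfam accession in universe", call. = FALSE)
  }
  structure(values, class = c("profile_matrix", "matrix", "array"))
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("<profile_matrix> ", nrow(x), " entities x ", ncol(x), " Pfams\n",
      sep = "")
  invisible(x)
}

#' Build a profile matrix from a list of Pfam profiles
#'
#' The Pfam universe defaults to the sorted union of all input profiles.
#' When an explicit universe is given, Pfams present in a profile but absent
#' from the universe are dropped (a message reports the count).
#'
#' @param profiles List of [pfam_profile()] objects with unique entity ids.
#' @param universe Optional character vector of accessions; duplicate-free.
#' @return A [profile_matrix()] with rows in input order and sorted columns.
#' @examples
#' m <- build_profile_matrix(list(
#'   pfam_profile("g1", c("PF00001", "PF00002")),
#'   pfam_profile("g2", c("PF00002", "PF00003"))))
#' dim(m)  # 2 x 3
#' @export
build_profile_matrix <- function(profiles, universe = NULL) {
  stopifnot(is.list(profiles), all(vapply(profiles, is_pfam_profile, TRUE)))
  ids <- vapply(profiles, function(p) p$entity_id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate entity_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (is.null(universe)) {
    universe <- sort(unique(unlist(lapply(profiles, `[[`, "pfams"))))
  } else {
    if (anyDuplicated(universe)) {
      stop("explicit universe contains duplicates", call. = FALSE)
    }
    universe <- sort(strip_pfam_version(as.character(universe)))
    n_drop <- sum(vapply(profiles,
                         function(p) sum(!(p$pfams %in% universe)), 0L))
    if (n_drop > 0L) {
      message(n_drop, " Pfam assignment(s) outside the explicit universe dropped")
    }
  }
  m <- matrix(0L, nrow = length(profiles), ncol = length(universe),
              dimnames = list(ids, universe))
  for (i in seq_along(profiles)) {
    m[i, universe %in% profiles[[i]]$pfams] <- 1L
  }
  profile_matrix(m)
}

#' Extract one entity's profile from a matrix
#'
#' @param matrix A [profile_matrix()].
#' @param entity_id Row label to extract.
#' @return A [pfam_profile()].
#' @export
profile_from_matrix <- function(matrix, entity_id) {
  if (!entity_id %in% rownames(matrix)) {
    stop("entity not in matrix: ", entity_id, call. = FALSE)
  }
  row <- matrix[entity_id, ]
  pfam_profile(entity_id, colnames(matrix)[row == 1L])
}

#' Write / read a profile matrix as TSV
#'
#' The dialect is: first column `entity_id`, remaining columns Pfam
#' accessions, cells 0/1, tab-separated, no quoting. The round trip is
#' lossless including row and column label order.
#'
#' @param matrix A [profile_matrix()].
#' @param path File path.
#' @return `write_profile_matrix` returns `path` invisibly;
#'   `read_profile_matrix` returns a [profile_matrix()].
#' @export
write_profile_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "profile_matrix"))
  df <- data.frame(entity_id = rownames(matrix),
                   unclass(matrix)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_profile_matrix
#' @export
read_profile_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "", fileEncoding = "UTF-8")
  if (names(df)[1] != "entity_id") {
    stop("first column of a profile matrix TSV must be 'entity_id'",
         call. = FALSE)
  }
  ids <- df$entity_id
  pfams <- names(df)[-1]
  m <- matrix(0L, nrow = length(ids), ncol = length(pfams),
              dimnames = list(ids, pfams))
  if (length(ids)) {
    for (j in seq_along(pfams)) {
      v <- df[[j + 1L]]
      ok <- v %in% c("0", "1")
      if (!all(ok)) {
        i <- which(!ok)[1]
        stop(sprintf("non-binary cell '%s' at entity '%s', Pfam '%s'",
                     v[i], ids[i], pfams[j]), call. = FALSE)
      }
      m[, j] <- as.integer(v)
    }
  }
  profile_matrix(m)
}
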