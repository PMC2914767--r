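#' Construct a set of half-sib cross families
#'
#' A `cross_set` is the central data container of segkit: one row per sire
#' (half-sib family) with the count of recessive-phenotype ("Huacaya")
#' offspring `n_huacaya` and total offspring `n_total`, plus the sampling
#' scheme under which the families entered the dataset.
#'
#' Under `ascertainment = "complete"` families were recorded regardless of
#' their offspring phenotypes, and the plain binomial likelihood applies.
#' Under `ascertainment = "truncate"` only families with at least one
#' recessive offspring were retained (every `n_huacaya` must be >= 1), and
#' likelihoods condition on that event.
#'
#' @param families data.frame with columns `sire_id`, `sire_phen`,
#'   `dam_phen`, `n_huacaya`, `n_total`. Phenotype tokens are
#'   case-insensitive and canonicalized to `"Suri"` / `"Huacaya"`.
#' @param ascertainment `"complete"` or `"truncate"`.
#' @param label optional character tag carried along for printing.
#' @return An object of class `cross_set` (a data.frame subclass) with
#'   attributes `ascertainment` and `label`.
#' @examples
#' cs <- cross_set(data.frame(
#'   sire_id = c("A", "B"), sire_phen = "Suri", dam_phen = "Huacaya",
#'   n_huacaya = c(2, 1), n_total = c(9, 7)), ascertainment = "truncate")
#' n_families(cs)
#' @export
cross_set <- function(families,
                      ascertainment = c("complete", "truncate"),
                      label = "") {
  ascertainment <- match.arg(ascertainment)
  required <- c("sire_id", "sire_phen", "dam_phen", "n_huacaya", "n_total")
  missing_cols <- setdiff(required, names(families))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  families <- as.data.frame(families)[required]
  families$sire_id <- as.character(families$sire_id)
  families$sire_phen <- canonical_phenotype(families$sire_phen)
  families$dam_phen <- canonical_phenotype(families$dam_phen)
  families$n_huacaya <- as.integer(families$n_huacaya)
  families$n_total <- as.integer(families$n_total)
  rownames(families) <- NULL
  out <- structure(families,
                   ascertainment = ascertainment,
                   label = label,
                   class = c("cross_set", "data.frame"))
  validate_cross_set(out)
  out
}

canonical_phenotype <- function(x) {
  x <- tolower(trimws(as.character(x)))
  ok <- x %in% c("suri", "huacaya")
  if (!all(ok)) {
    stop("unknown phenotype token(s): ",
         paste(unique(x[!ok]), collapse = ", "))
  }
  ifelse(x == "suri", "Suri", "Huacaya")
}

validate_cross_set <- function(set) {
  fam <- as.data.frame(set)
  if (nrow(fam) > 0L) {
    if (anyNA(fam$n_huacaya) || anyNA(fam$n_total)) {
      stop("offspring counts contain NA")
    }
    if (any(fam$n_total < 1L)) stop("every family needs n_total >= 1")
    if (any(fam$n_huacaya < 0L) || any(fam$n_huacaya > fam$n_total)) {
      stop("need 0 <= n_huacaya <= n_total in every family")
    }
    if (anyDuplicated(fam$sire_id)) {
      stop("duplicate sire_id: ",
           paste(unique(fam$sire_id[duplicated(fam$sire_id)]), collapse = ", "))
    }
    if (identical(attr(set, "ascertainment"), "truncate") &&
        any(fam$n_huacaya == 0L)) {
      stop("truncate-selection sets cannot contain families with n_huacaya = 0")
    }
  }
  invisible(set)
}

#' @export
print.cross_set <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("cross_set: %d half-sib famil%s (%s selection)%s\n",
              nrow(x), if (nrow(x) == 1L) "y" else "ies",
              attr(x, "ascertainment"),
              if (nzchar(lab)) paste0(" - ", lab) else ""))
  if (nrow(x) > 0L) {
    cat(sprintf("  total: %d recessive / %d offspring\n",
                sum(x$n_huacaya), sum(x$n_total)))
    print.data.frame(as.data.frame(x), ...)
  }
  invisible(x)
}

#' Number of families in a cross set
#' @param set a `cross_set`.
#' @return Integer count of half-sib families (rows).
#' @export
n_families <- function(set) nrow(set)

#' Read a half-sib cross table from TSV
#'
#' The dialect is tab-separated UTF-8 with a mandatory header
#' `sire_id sire_phen dam_phen n_huacaya n_total`; lines starting with `#`
#' are ignored. Row order is preserved. Malformed rows (non-integer counts,
#' `n_huacaya > n_total`, unknown phenotype tokens, duplicate sire ids) are
#' rejected with the offending data row number.
#'
#' @param path file path.
#' @param ascertainment sampling scheme to stamp on the returned set.
#' @return A [cross_set()].
#' @seealso [write_cross_table()]
#' @export
read_cross_table <- function(path, ascertainment = c("complete", "truncate")) {
  ascertainment <- match.arg(ascertainment)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", quote = "",
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = TRUE)
  required <- c("sire_id", "sire_phen", "dam_phen", "n_huacaya", "n_total")
  if (!identical(names(raw)[seq_along(required)], required)) {
    stop("bad header in ", path, "; expected columns: ",
         paste(required, collapse = ", "))
  }
  parse_count <- function(col, what) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) | v != floor(v) | v < 0)
    if (length(bad) > 0L) {
      stop(sprintf("row %d: %s is not a non-negative integer (%s)",
                   bad[1L], what, raw[[col]][bad[1L]]))
    }
    as.integer(v)
  }
  if (nrow(raw) == 0L) {
    return(cross_set(data.frame(sire_id = character(), sire_phen = character(),
                                dam_phen = character(),
                                n_huacaya = integer(), n_total = integer()),
                     ascertainment = ascertainment,
                     label = basename(path)))
  }
  r <- parse_count("n_huacaya", "n_huacaya")
  s <- parse_count("n_total", "n_total")
  bad <- which(r > s)
  if (length(bad) > 0L) {
    stop(sprintf("row %d: n_huacaya (%d) exceeds n_total (%d)",
                 bad[1L], r[bad[1L]], s[bad[1L]]))
  }
  for (col in c("sire_phen", "dam_phen")) {
    tok <- tolower(trimws(raw[[col]]))
    bad <- which(!tok %in% c("suri", "huacaya"))
    if (length(bad) > 0L) {
      stop(sprintf("row %d: unknown phenotype token '%s'",
                   bad[1L], raw[[col]][bad[1L]]))
    }
  }
  bad <- which(duplicated(raw$sire_id))
  if (length(bad) > 0L) {
    stop(sprintf("row %d: duplicate sire_id '%s'",
                 bad[1L], raw$sire_id[bad[1L]]))
  }
  if (ascertainment == "truncate" && any(r == 0L)) {
    stop(sprintf("row %d: n_huacaya = 0 not allowed under truncate selection",
                 which(r == 0L)[1L]))
  }
  cross_set(data.frame(sire_id = raw$sire_id, sire_phen = raw$sire_phen,
                       dam_phen = raw$dam_phen, n_huacaya = r, n_total = s,
                       stringsAsFactors = FALSE),
            ascertainment = ascertainment, label = basename(path))
}

#' Write a cross set to TSV
#'
#' Writes the canonical tab-separated dialect read by [read_cross_table()];
#' a write/read round trip reproduces an identical set (up to the file-name
#' label).
#'
#' @param set a `cross_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cross_table <- function(set, path) {
  validate_cross_set(set)
  utils::write.table(as.data.frame(set), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Filter families by size and segregation status
#'
#' Used to restrict a series to informative sibships, e.g. "at least 10
#' offspring per sire", or to the segregating sires only (those with at
#' least one recessive offspring, the probands of truncate selection).
#'
#' @param set a `cross_set`.
#' @param min_s keep families with `n_total >= min_s`.
#' @param segregating_only if `TRUE`, keep only families with
#'   `n_huacaya >= 1`.
#' @return The filtered `cross_set` (ascertainment and label unchanged).
#' @examples
#' t2 <- load_fixture("table2")
#' n_families(filter_families(t2, min_s = 10))          # 22
#' n_families(filter_families(t2, segregating_only = TRUE))  # 23
#' @export
filter_families <- function(set, min_s = 0, segregating_only = FALSE) {
  stopifnot(min_s >= 0)
  keep <- set$n_total >= min_s
  if (segregating_only) keep <- keep & set$n_huacaya >= 1L
  out <- set[keep, , drop = FALSE]
  attributes(out)$ascertainment <- attr(set, "ascertainment")
  attributes(out)$label <- attr(set, "label")
  class(out) <- class(set)
  rownames(out) <- NULL
  out
}

#' Single-offspring design counts
#'
#' In the reciprocal cross the recessive parent is the sire and each dam is
#' mated once, so every dam contributes exactly one offspring and her
#' carrier status is observed at most once. The data then reduce to a single
#' pair of counts: `n_huacaya` recessive offspring among `n_total` matings.
#'
#' @param n_huacaya recessive-offspring count.
#' @param n_total number of single-offspring matings.
#' @return An object of class `single_offspring_set`.
#' @seealso [fit_single_offspring()], [as_single_offspring()]
#' @export
single_offspring_set <- function(n_huacaya, n_total) {
  n_huacaya <- as.integer(n_huacaya)
  n_total <- as.integer(n_total)
  stopifnot(length(n_huacaya) == 1L, length(n_total) == 1L,
            n_huacaya >= 0L, n_total >= n_huacaya)
  structure(list(n_huacaya = n_huacaya, n_total = n_total),
            class = "single_offspring_set")
}

#' Collapse a cross set to single-offspring counts
#'
#' Pools all offspring of a set into one `(n_huacaya, n_total)` pair; only
#' meaningful for designs where each dam contributed one offspring.
#'
#' @param set a `cross_set`.
#' @return A [single_offspring_set()].
#' @export
as_single_offspring <- function(set) {
  single_offspring_set(sum(set$n_huacaya), sum(set$n_total))
}

#' @export
print.single_offspring_set <- function(x, ...) {
  cat(sprintf("single-offspring design: %d recessive among %d matings (%.3f)\n",
              x$n_huacaya, x$n_total,
              if (x$n_total > 0) x$n_huacaya / x$n_total else NA_real_))
  invisible(x)
}
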