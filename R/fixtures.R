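#' Load a bundled cross-series fixture
#'
#' Three alpaca datasets ship with the package as plain TSV files:
#'
#' * `"table1A"` - nine Suri sires test-crossed to Huacaya dams
#'   (26 Huacaya / 94 offspring).
#' * `"table1B"` - eight Huacaya sires crossed to Suri dams
#'   (16 Huacaya / 55 offspring); since the recessive parent here is the
#'   sire, each dam contributes a single offspring and the set is usually
#'   analysed via [as_single_offspring()].
#' * `"table2"` - the Suri x Suri half-sib series, stored as a frequency
#'   grid and expanded to 57 per-sire records (57 Huacaya / 587 offspring).
#'   The grid gives no sire names, so deterministic ids
#'   `SxS_<n_total>_<n_huacaya>_<k>` are synthesized; rows are ordered by
#'   `n_total`, then `n_huacaya`, then `k`, so the expansion is reproducible.
#'
#' All three sets are returned with `ascertainment = "complete"`: they
#' record every family, segregating or not. Restrict to probands with
#' [filter_families()] and re-stamp with [ascertain()] when a truncated
#' analysis is wanted.
#'
#' @param name one of `"table1A"`, `"table1B"`, `"table2"`.
#' @return A [cross_set()].
#' @examples
#' t1a <- load_fixture("table1A")
#' sum(t1a$n_huacaya)  # 26
#' @export
load_fixture <- function(name = c("table1A", "table1B", "table2")) {
  name <- match.arg(name)
  if (name %in% c("table1A", "table1B")) {
    path <- system.file("extdata", paste0(name, ".tsv"), package = "segkit",
                        mustWork = TRUE)
    set <- read_cross_table(path, ascertainment = "complete")
    attr(set, "label") <- name
    return(set)
  }
  path <- system.file("extdata", "table2_counts.tsv", package = "segkit",
                      mustWork = TRUE)
  grid <- utils::read.table(path, header = TRUE, sep = "\t",
                            comment.char = "#")
  grid <- grid[order(grid$n_total, grid$n_huacaya), , drop = FALSE]
  r <- rep(grid$n_huacaya, grid$n_males)
  s <- rep(grid$n_total, grid$n_males)
  k <- stats::ave(r, paste(s, r), FUN = seq_along)
  cross_set(data.frame(sire_id = sprintf("SxS_%d_%d_%d", s, r, k),
                       sire_phen = "Suri", dam_phen = "Suri",
                       n_huacaya = r, n_total = s,
                       stringsAsFactors = FALSE),
            ascertainment = "complete", label = "table2")
}
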