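#' G-square heterogeneity test of segregation ratios
#'
#' Tests whether the proportion of recessive offspring is homogeneous
#' across the families of a set, via the log-likelihood-ratio (G) statistic
#' on the k x 2 contingency table of (recessive, dominant) counts per sire:
#' `G = 2 * sum O * ln(O / E)`, expected counts from the row and column
#' marginals, zero cells contributing zero. Degrees of freedom are `k - 1`
#' and the p-value is the chi-square upper tail.
#'
#' @param set a [cross_set()] with at least two families.
#' @return An object of class `htest` with the G statistic, df and p-value.
#' @examples
#' g_test(load_fixture("table1A"))  # G ~ 28.1 on 8 df
#' @export
g_test <- function(set) {
  stopifnot(inherits(set, "cross_set"))
  if (nrow(set) < 2L) stop("g_test needs at least two families")
  if (any(set$n_total < 1L)) stop("families with no offspring")
  O <- cbind(recessive = set$n_huacaya,
             dominant = set$n_total - set$n_huacaya)
  if (any(colSums(O) == 0)) stop("a phenotype column is all zero")
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  terms <- ifelse(O > 0, O * log(O / E), 0)
  G <- 2 * sum(terms)
  df <- nrow(O) - 1L
  structure(list(statistic = c(G = G),
                 parameter = c(df = df),
                 p.value = stats::pchisq(G, df = df, lower.tail = FALSE),
                 method = "G-square test of segregation-ratio heterogeneity",
                 data.name = attr(set, "label"),
                 observed = O, expected = E),
            class = "htest")
}

#' Monte Carlo permutation test of segregation-ratio homogeneity
#'
#' Under the null hypothesis, the observed recessive offspring are
#' distributed among the sibships binomially with a common ratio. The test
#' fixes the pooled observed ratio `p = sum(r) / sum(s)` and scores each
#' dataset by `sum over sibships of log Binomial(r_i; s_i, p)` (the plain
#' binomial by default; `statistic = "truncate"` uses the truncated kernel).
#' Each replicate redistributes the `sum(r)` recessive offspring uniformly
#' at random over the `sum(s)` offspring slots (respecting sibship sizes -
#' a multivariate hypergeometric draw), and the p-value is the fraction of
#' replicates whose statistic is strictly lower than the observed one (ties
#' count as not lower).
#'
#' By default only segregating sibships (`r >= 1`) enter the test, matching
#' the usual truncate-selection series; set `include_nonsegregating = TRUE`
#' to permute over every family.
#'
#' @param set a non-empty [cross_set()].
#' @param n_replicates number of Monte Carlo replicates.
#' @param seed optional integer; when supplied the RNG state is set locally
#'   (and restored), making the result bit-reproducible.
#' @param include_nonsegregating permute over all families, not only the
#'   segregating ones.
#' @param statistic binomial kernel for the score, `"complete"` (default)
#'   or `"truncate"`.
#' @return A `perm_test` object: `p_value`, `n_lower`, `n_replicates`,
#'   `observed` statistic, pooled `p_hat`, `seed`, `degenerate` flag.
#' @examples
#' t2seg <- filter_families(load_fixture("table2"), segregating_only = TRUE)
#' permutation_test(t2seg, n_replicates = 1000, seed = 1)
#' @export
permutation_test <- function(set, n_replicates = 10000, seed = NULL,
                             include_nonsegregating = FALSE,
                             statistic = c("complete", "truncate")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(set, "cross_set"), n_replicates >= 1)
  if (!include_nonsegregating) {
    set <- filter_families(set, segregating_only = TRUE)
  }
  if (nrow(set) == 0L) stop("no sibships to permute over")
  r <- set$n_huacaya
  s <- set$n_total
  r_tot <- sum(r)
  if (r_tot == 0L || nrow(set) == 1L) {
    # no recessives, or a single sibship (every permutation reproduces the
    # observed counts): homogeneity cannot be rejected
    return(structure(list(p_value = 1, n_lower = 0L,
                          n_replicates = as.integer(n_replicates),
                          observed = NA_real_, p_hat = r_tot / sum(s),
                          seed = seed,
                          statistic = statistic, degenerate = TRUE),
                     class = "perm_test"))
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  p_hat <- r_tot / sum(s)
  score <- if (statistic == "complete") {
    function(cnt) sum(stats::dbinom(cnt, s, p_hat, log = TRUE))
  } else {
    function(cnt) {
      if (any(cnt == 0L)) return(-Inf)
      sum(family_prob(cnt, s, p_hat, "truncate", log = TRUE))
    }
  }
  observed <- score(r)
  slots <- rep.int(seq_along(s), s)
  k <- length(s)
  n_lower <- 0L
  for (b in seq_len(n_replicates)) {
    cnt <- tabulate(sample(slots, r_tot), nbins = k)
    if (score(cnt) < observed) n_lower <- n_lower + 1L
  }
  structure(list(p_value = n_lower / n_replicates, n_lower = n_lower,
                 n_replicates = as.integer(n_replicates),
                 observed = observed, p_hat = p_hat, seed = seed,
                 statistic = statistic, degenerate = FALSE),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Monte Carlo permutation test of segregation-ratio homogeneity\n")
  if (isTRUE(x$degenerate)) {
    cat("  degenerate: no recessive offspring; p = 1\n")
    return(invisible(x))
  }
  cat(sprintf("  pooled ratio p = %.4f, observed statistic = %.4f (%s kernel)\n",
              x$p_hat, x$observed, x$statistic))
  cat(sprintf("  p-value = %.4g (%d of %d replicates below observed)\n",
              x$p_value, x$n_lower, x$n_replicates))
  invisible(x)
}
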