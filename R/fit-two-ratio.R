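#' Two-ratio hard-max mixture fit
#'
#' Fits the heterogeneity model in which each sire segregates at one of two
#' ratios, `R1` or `R2`, and each family is assigned to whichever ratio
#' gives it the higher likelihood. The objective is
#' `L(R1, R2) = sum over families of max(l_i(R1), l_i(R2))`, where `l_i` is
#' the family log-likelihood (plain or truncated binomial according to the
#' set's ascertainment mode). This is a hard assignment, not an EM-style
#' soft mixture: the per-family component is part of the fit.
#'
#' The objective is piecewise-smooth in the implied assignment, so a coarse
#' two-dimensional grid (step `grid_step`) locates the basin, after which
#' assignment/refit iterations (classification EM) polish the optimum: at
#' the current `(R1, R2)` each family is assigned to its better component
#' (ties to component 1, the lower ratio), then each component's ratio is
#' re-estimated on its families alone. Results are canonicalized so that
#' `R1 <= R2`.
#'
#' Families with `r = 0` are excluded when the set's ascertainment mode is
#' `"truncate"` (they cannot appear under that sampling scheme).
#'
#' @param set a non-empty [cross_set()].
#' @param grid_step coarse grid step for the global search (<= 0.01).
#' @return A `two_ratio_fit`: `R1`, `R2` (with `R1 <= R2`), `loglik`,
#'   `assignment` (named integer vector, 1 or 2 per sire), `n_families`,
#'   `degenerate` flag for single-family sets.
#' @examples
#' t1a <- ascertain(filter_families(load_fixture("table1A"),
#'                                  segregating_only = TRUE))
#' fit_two_ratio(t1a)  # R1 ~ 0.08, R2 ~ 0.51, logL ~ -11.76
#' @export
fit_two_ratio <- function(set, grid_step = 0.005) {
  stopifnot(inherits(set, "cross_set"), grid_step > 0, grid_step <= 0.01)
  mode <- attr(set, "ascertainment")
  if (mode == "truncate" && any(set$n_huacaya == 0L)) {
    set <- filter_families(set, segregating_only = TRUE)
  }
  if (nrow(set) == 0L) stop("cannot fit an empty cross_set")
  r <- set$n_huacaya
  s <- set$n_total
  eps <- 1e-9
  lfam <- function(p) family_prob(r, s, rep_len(p, length(r)), mode, log = TRUE)
  fit_component <- function(idx) {
    if (mode == "complete" && sum(r[idx]) == 0L) return(0)
    stats::optimize(function(p) sum(lfam(p)[idx]),
                    lower = eps, upper = 1 - eps,
                    maximum = TRUE, tol = 1e-10)$maximum
  }
  if (nrow(set) == 1L) {
    R <- fit_component(1L)
    ll <- sum(lfam(R))
    return(structure(list(R1 = R, R2 = R, loglik = ll,
                          assignment = stats::setNames(1L, set$sire_id),
                          n_families = 1L, degenerate = TRUE),
                     class = "two_ratio_fit"))
  }
  # global coarse grid over R1 <= R2
  grid <- seq(grid_step, 1 - grid_step, by = grid_step)
  lmat <- vapply(grid, lfam, numeric(length(r)))   # families x grid
  best <- -Inf
  best_ij <- c(1L, 1L)
  for (i in seq_along(grid)) {
    obj <- colSums(pmax(lmat[, i:length(grid), drop = FALSE], lmat[, i]))
    j <- which.max(obj)
    if (obj[j] > best) {
      best <- obj[j]
      best_ij <- c(i, i + j - 1L)
    }
  }
  R12 <- grid[best_ij]
  # classification-EM polish: assign, refit each component, repeat
  for (iter in 1:100) {
    l1 <- lfam(R12[1L])
    l2 <- lfam(R12[2L])
    a <- ifelse(l1 >= l2, 1L, 2L)
    new_R12 <- R12
    if (any(a == 1L)) new_R12[1L] <- fit_component(which(a == 1L))
    if (any(a == 2L)) new_R12[2L] <- fit_component(which(a == 2L))
    new_R12 <- sort(new_R12)
    if (max(abs(new_R12 - R12)) < 1e-12) break
    R12 <- new_R12
  }
  # an empty component carries no information; collapse it onto the other
  # so that homogeneous data return R1 = R2 = the single-ratio MLE
  a <- ifelse(lfam(R12[1L]) >= lfam(R12[2L]), 1L, 2L)
  if (!any(a == 1L)) R12[1L] <- R12[2L]
  if (!any(a == 2L)) R12[2L] <- R12[1L]
  l1 <- lfam(R12[1L])
  l2 <- lfam(R12[2L])
  assignment <- stats::setNames(ifelse(l1 >= l2, 1L, 2L), set$sire_id)
  structure(list(R1 = R12[1L], R2 = R12[2L],
                 loglik = sum(pmax(l1, l2)),
                 assignment = assignment,
                 n_families = nrow(set), degenerate = FALSE),
            class = "two_ratio_fit")
}

#' @export
print.two_ratio_fit <- function(x, ...) {
  cat(sprintf("two-ratio fit over %d families%s\n", x$n_families,
              if (isTRUE(x$degenerate)) " (degenerate: single family)" else ""))
  cat(sprintf("  R1 = %.4f (%d families), R2 = %.4f (%d families)\n",
              x$R1, sum(x$assignment == 1L), x$R2, sum(x$assignment == 2L)))
  cat(sprintf("  log-likelihood = %.4f\n", x$loglik))
  invisible(x)
}

#' Likelihood-ratio test: two ratios vs one
#'
#' The single-ratio model is nested in the two-ratio model (set `R1 = R2`),
#' so minus twice the log-likelihood difference is referred to a chi-square
#' distribution with one degree of freedom (one extra estimated parameter).
#'
#' @param fit1 the single-ratio `seg_fit` (from [fit_single_R()]).
#' @param fit2 the `two_ratio_fit` on the same set.
#' @return A list with `statistic`, `df` and `p_value`.
#' @export
lrt_two_vs_one <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "seg_fit"), inherits(fit2, "two_ratio_fit"))
  stat <- 2 * (fit2$loglik - fit1$loglik)
  if (stat < -1e-6) {
    stop("two-ratio log-likelihood below single-ratio: fits are inconsistent")
  }
  stat <- max(stat, 0)
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}
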