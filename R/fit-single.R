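# Profile-likelihood machinery shared by the single-ratio, conditional and
# recombination fits. The 95% limits are the two parameter values where the
# log-likelihood falls 5.0238/2 below its maximum; 5.0238 is used verbatim
# as the chi-square value with tail probability 0.025, for compatibility
# with the confidence limits quoted for these data.
PROFILE_DROP <- 5.0238 / 2

# Finds the two roots of ll(x) = ll(xhat) - PROFILE_DROP on [lower, upper].
# When the log-likelihood is still above the threshold at an interval end,
# that end is reported and flagged as a boundary.
profile_ci <- function(ll, xhat, lmax, lower, upper, tol = 1e-9) {
  thr <- lmax - PROFILE_DROP
  at <- function(x) {
    v <- suppressWarnings(ll(x))
    if (!is.finite(v)) -Inf else v
  }
  lo_boundary <- at(lower) > thr
  ci_low <- if (lo_boundary) lower else {
    stats::uniroot(function(x) at(x) - thr, lower = lower, upper = xhat,
                   tol = tol)$root
  }
  hi_boundary <- at(upper) > thr
  ci_high <- if (hi_boundary) upper else {
    stats::uniroot(function(x) at(x) - thr, lower = xhat, upper = upper,
                   tol = tol)$root
  }
  list(ci = c(ci_low, ci_high), boundary = c(lo_boundary, hi_boundary))
}

new_seg_fit <- function(estimate, loglik, ci, boundary, n_families,
                        model_tag, extra = list()) {
  structure(c(list(estimate = estimate, loglik = loglik,
                   ci_low = ci[1L], ci_high = ci[2L],
                   boundary = boundary, n_families = n_families,
                   model_tag = model_tag), extra),
            class = "seg_fit")
}

#' @export
print.seg_fit <- function(x, ...) {
  cat(sprintf("%s fit over %d famil%s\n", x$model_tag, x$n_families,
              if (x$n_families == 1L) "y" else "ies"))
  cat(sprintf("  estimate = %.4f, 95%% profile CI [%.4f, %.4f]%s\n",
              x$estimate, x$ci_low, x$ci_high,
              if (any(x$boundary)) " (boundary)" else ""))
  cat(sprintf("  log-likelihood = %.4f\n", x$loglik))
  invisible(x)
}

#' Maximum-likelihood estimate of a single segregation ratio
#'
#' Maximizes the total log-likelihood of `set` over the segregation ratio
#' `R` in `[0, 1]`, with the ascertainment mode (plain or truncated
#' binomial) taken from the set. With `composition = "HR"` or `"HHR"` the
#' carrier frequency must be supplied via `H_fixed` and the per-offspring
#' probability becomes `H * R` or `H^2 * R`; the profile and its confidence
#' limits are in terms of `R`.
#'
#' The 95% limits are the two values of `R` where the log-likelihood has
#' dropped 5.0238/2 below the maximum (see [fit_recombination()] for the
#' same rule on the recombination fraction); when no root exists inside
#' `[0, 1]` the bound is clamped and flagged in `$boundary`.
#'
#' @param set a non-empty [cross_set()].
#' @param composition how `R` composes into the per-offspring probability;
#'   see [seg_params()].
#' @param H_fixed carrier frequency, required for `"HR"` / `"HHR"`.
#' @return A `seg_fit` with `estimate`, `loglik`, `ci_low`, `ci_high`,
#'   `boundary`, `n_families`, `model_tag`.
#' @examples
#' t1a <- filter_families(load_fixture("table1A"), segregating_only = TRUE)
#' fit_single_R(ascertain(t1a))  # R ~ 0.290, CI ~ (0.184, 0.409)
#' @export
fit_single_R <- function(set, composition = c("R_only", "HR", "HHR"),
                         H_fixed = NULL) {
  composition <- match.arg(composition)
  stopifnot(inherits(set, "cross_set"))
  if (nrow(set) == 0L) stop("cannot fit an empty cross_set")
  if (composition == "R_only") {
    H_fixed <- 1
  } else if (is.null(H_fixed)) {
    stop("composition '", composition, "' needs H_fixed")
  }
  stopifnot(H_fixed > 0, H_fixed <= 1)
  mode <- attr(set, "ascertainment")
  ll <- function(R) set_loglik(set, seg_params(R, H_fixed, composition))
  eps <- 1e-9
  tag <- sprintf("single-R (%s, %s%s)", mode, composition,
                 if (composition == "R_only") "" else
                   sprintf(", H = %.3g", H_fixed))
  if (mode == "complete" && sum(set$n_huacaya) == 0L) {
    # no recessives ever observed: the MLE sits on the boundary R = 0
    lmax <- ll(0)
    pc <- profile_ci(ll, eps, lmax, lower = 0, upper = 1 - eps)
    return(new_seg_fit(0, lmax, pc$ci, pc$boundary, nrow(set), tag,
                       list(composition = composition, H_fixed = H_fixed,
                            ascertainment = mode)))
  }
  opt <- stats::optimize(ll, lower = eps, upper = 1 - eps, maximum = TRUE,
                         tol = 1e-9)
  est <- opt$maximum
  lmax <- opt$objective
  # optimize() cannot land exactly on a boundary; check both ends when legal
  if (mode == "complete") {
    for (b in c(0, 1)) {
      lb <- ll(b)
      if (is.finite(lb) && lb > lmax) {
        est <- b
        lmax <- lb
      }
    }
  }
  pc <- profile_ci(ll, est, lmax,
                   lower = if (mode == "truncate") 1e-12 else 0,
                   upper = 1 - 1e-12)
  new_seg_fit(est, lmax, pc$ci, pc$boundary, nrow(set), tag,
              list(composition = composition, H_fixed = H_fixed,
                   ascertainment = mode))
}

#' Conditional fit for the single-offspring design
#'
#' When each dam contributes exactly one offspring, the likelihood of
#' `n_huacaya` recessives among `n_total` matings is binomial with
#' `p = H * R`, and `H` and `R` are not jointly identifiable: any pair with
#' the same product fits equally well. One parameter is therefore fixed and
#' the other estimated; the MLE of the free parameter is the closed form
#' `(n_huacaya / n_total) / fixed_value`, clamped to `[0, 1]`.
#'
#' @param data a [single_offspring_set()].
#' @param fix which parameter is held fixed, `"R"` or `"H"`.
#' @param fixed_value its value, in `(0, 1]`.
#' @return A `seg_fit` for the free parameter (profile CI included).
#' @examples
#' so <- single_offspring_set(16, 55)
#' fit_single_offspring(so, fix = "R", fixed_value = 0.5)$estimate   # 0.582
#' fit_single_offspring(so, fix = "H", fixed_value = 0.88)$estimate  # 0.331
#' @export
fit_single_offspring <- function(data, fix = c("R", "H"), fixed_value) {
  fix <- match.arg(fix)
  stopifnot(inherits(data, "single_offspring_set"),
            fixed_value > 0, fixed_value <= 1)
  if (data$n_total == 0L) stop("n_total = 0: nothing to fit")
  est <- min(1, (data$n_huacaya / data$n_total) / fixed_value)
  ll <- function(x) {
    stats::dbinom(data$n_huacaya, data$n_total,
                  min(1, x * fixed_value), log = TRUE)
  }
  pc <- profile_ci(ll, max(est, 1e-12), ll(est), lower = 0, upper = 1)
  free <- setdiff(c("R", "H"), fix)
  new_seg_fit(est, ll(est), pc$ci, pc$boundary, 1L,
              sprintf("single-offspring (%s free, %s = %.3g)",
                      free, fix, fixed_value),
              list(fix = fix, fixed_value = fixed_value, free = free))
}
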