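#' Segregation-model parameters
#'
#' Bundles the segregation ratio `R` with the carrier (segregating-animal)
#' frequency `H` and declares how they compose into the per-offspring
#' recessive probability `p`:
#'
#' * `"R_only"`: `p = R` - both parents' carrier status is known, as in a
#'   test-cross of a proven segregating sire.
#' * `"HR"`: `p = H * R` - one mate of unknown status per offspring
#'   (e.g. a proven sire mated to random dams, each dam carrying with
#'   probability `H`).
#' * `"HHR"`: `p = H^2 * R` - both mates of unknown status.
#'
#' @param R segregation ratio in `[0, 1]`.
#' @param H carrier frequency in `[0, 1]`; defaults to 1.
#' @param composition `"R_only"`, `"HR"` or `"HHR"`.
#' @return An object of class `seg_params`.
#' @examples
#' effective_p(seg_params(R = 0.5, H = 0.582, composition = "HR"))  # 0.291
#' @export
seg_params <- function(R, H = 1, composition = c("R_only", "HR", "HHR")) {
  composition <- match.arg(composition)
  stopifnot(length(R) == 1L, is.finite(R), R >= 0, R <= 1,
            length(H) == 1L, is.finite(H), H >= 0, H <= 1)
  structure(list(R = R, H = H, composition = composition),
            class = "seg_params")
}

#' @export
print.seg_params <- function(x, ...) {
  cat(sprintf("seg_params: R = %.4g, H = %.4g, composition = %s (p = %.4g)\n",
              x$R, x$H, x$composition, effective_p(x)))
  invisible(x)
}

#' Per-offspring recessive probability implied by the parameters
#'
#' @param params a [seg_params()] object.
#' @return `R`, `H*R` or `H^2*R` according to the composition.
#' @export
effective_p <- function(params) {
  stopifnot(inherits(params, "seg_params"))
  switch(params$composition,
         R_only = params$R,
         HR = params$H * params$R,
         HHR = params$H^2 * params$R)
}

#' Probability of a half-sib family's offspring counts
#'
#' Probability of observing `r` recessive offspring among `s`, given the
#' per-offspring recessive probability `p`. Under `"complete"` selection
#' this is the plain binomial pmf; under `"truncate"` selection the family
#' is known to contain at least one recessive offspring (the proband), and
#' the binomial term is divided by `1 - (1 - p)^s`.
#'
#' Boundary conventions: under complete selection `p = 0` gives probability
#' 1 for `r = 0` (and 0 otherwise), `p = 1` gives probability 1 for
#' `r = s`. Under truncate selection `r = 0` and `p = 0` are structural
#' domain errors (the conditioning event is impossible).
#'
#' @param r recessive-offspring counts (vectorized).
#' @param s total-offspring counts.
#' @param p per-offspring recessive probability.
#' @param ascertainment `"complete"` or `"truncate"`.
#' @param log if `TRUE`, return log-probabilities.
#' @return Probabilities (or log-probabilities) in `[0, 1]`.
#' @examples
#' family_prob(1, 1, 0.3, "truncate")   # 1: the proband is certain
#' family_prob(0, 7, 0.5, "complete")   # (1/2)^7
#' @export
family_prob <- function(r, s, p, ascertainment = c("complete", "truncate"),
                        log = FALSE) {
  ascertainment <- match.arg(ascertainment)
  n <- max(length(r), length(s), length(p))
  r <- rep_len(as.numeric(r), n)
  s <- rep_len(as.numeric(s), n)
  p <- rep_len(as.numeric(p), n)
  if (any(!is.finite(r)) || any(!is.finite(s)) || any(!is.finite(p))) {
    stop("non-finite arguments")
  }
  if (any(r != floor(r)) || any(s != floor(s))) stop("r and s must be integers")
  if (any(r < 0) || any(s < 1) || any(r > s)) stop("need 0 <= r <= s, s >= 1")
  if (any(p < 0) || any(p > 1)) stop("p must lie in [0, 1]")
  if (ascertainment == "truncate") {
    if (any(r == 0)) {
      stop("truncate selection conditions on r >= 1; got a family with r = 0")
    }
    if (any(p == 0)) {
      stop("truncate selection with p = 0: conditioning event has probability 0")
    }
  }
  lp <- stats::dbinom(r, s, p, log = TRUE)
  if (ascertainment == "truncate") {
    # log(1 - (1-p)^s), stable for small p via log1p/expm1
    lp <- lp - log(-expm1(s * log1p(-p)))
  }
  if (log) lp else exp(lp)
}

#' Total log-likelihood of a cross set
#'
#' `sum over families of log family_prob(r_i, s_i, p)`, where `p` is the
#' effective per-offspring probability of `params` and the ascertainment
#' mode is taken from the set. `-Inf` is a legal value (some family has
#' probability zero at these parameters); structural domain errors are
#' reported with the offending sire id.
#'
#' @param set a [cross_set()].
#' @param params a [seg_params()] object.
#' @return The total log-likelihood (0 for an empty set).
#' @export
set_loglik <- function(set, params) {
  stopifnot(inherits(set, "cross_set"))
  if (nrow(set) == 0L) return(0)
  p <- effective_p(params)
  mode <- attr(set, "ascertainment")
  if (mode == "truncate") {
    if (any(set$n_huacaya == 0L)) {
      stop("family ", set$sire_id[set$n_huacaya == 0L][1L],
           ": r = 0 invalid under truncate selection")
    }
    if (p == 0) {
      stop("family ", set$sire_id[1L],
           ": effective p = 0 invalid under truncate selection")
    }
  }
  sum(family_prob(set$n_huacaya, set$n_total, p, mode, log = TRUE))
}
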