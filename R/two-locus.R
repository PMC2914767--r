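#' Test-cross recessive-offspring ratio of a double-heterozygous diplotype
#'
#' Under the two-linked-locus model the recessive phenotype requires
#' homozygosity for the recessive allele at both loci, so a test-cross
#' offspring is recessive exactly when the double-heterozygous parent
#' transmits the doubly-recessive (`ab`) haplotype. For a cis (`AB//ab`)
#' parent that haplotype is parental; for a trans (`Ab//aB`) parent it can
#' only arise by recombination.
#'
#' Two conventions are offered. The default returns the ratios in the form
#' used throughout the bundled analyses: `R1 = 1/2 - h` for cis and
#' `R2 = h/2` for trans. With `exact = TRUE` the cis value is the exact
#' gamete-enumeration probability `(1 - h)/2` (trans is `h/2` under both
#' conventions); the two cis forms differ by `h/2`, which matters once `h`
#' is appreciable. See the methods vignette for why both are kept.
#'
#' @param phase `"cis"` or `"trans"` (vectorized).
#' @param h recombination fraction in `[0, 0.5]`.
#' @param exact use the exact gamete probability for cis.
#' @return The probability that a test-cross offspring is recessive.
#' @examples
#' gamete_recessive_prob("cis", 0)       # 0.5: complete linkage
#' gamete_recessive_prob("trans", 0)     # 0: no recombination, no ab gamete
#' gamete_recessive_prob("cis", 0.099)   # 0.401
#' @export
gamete_recessive_prob <- function(phase, h, exact = FALSE) {
  if (any(h < 0) || any(h > 0.5)) stop("h must lie in [0, 0.5]")
  n <- max(length(phase), length(h))
  phase <- rep_len(as.character(phase), n)
  h <- rep_len(h, n)
  if (!all(phase %in% c("cis", "trans"))) {
    stop("phase must be 'cis' or 'trans'")
  }
  cis_val <- if (exact) (1 - h) / 2 else 0.5 - h
  ifelse(phase == "cis", cis_val, h / 2)
}

#' Maximum-likelihood recombination fraction from grouped test-cross families
#'
#' Given a partition of the segregating sires into a cis group (expected
#' recessive ratio `1/2 - h`) and a trans group (expected ratio `h/2`),
#' maximizes the summed family log-likelihood over `h` in `[0, 0.5]`, with
#' the binomial kernel chosen by `ascertainment` (truncated by default,
#' matching how segregating test-cross sires are collected). The 95% limits
#' follow the same 5.0238/2 profile-drop rule as [fit_single_R()].
#'
#' When `grouping` is omitted it is derived from [fit_two_ratio()]: the
#' low-ratio component becomes the trans group, the high-ratio component
#' the cis group. If one group is empty the fit degenerates to a
#' single-group fit and is flagged.
#'
#' @param set a [cross_set()]; under truncate ascertainment every family
#'   must have at least one recessive offspring.
#' @param grouping named character vector mapping every `sire_id` to
#'   `"cis"` or `"trans"`; `NULL` to derive it from the two-ratio fit.
#' @param ascertainment binomial kernel; defaults to the set's mode.
#' @param exact_gametes use the exact cis gamete probability `(1 - h)/2`
#'   instead of `1/2 - h` (see [gamete_recessive_prob()]).
#' @return A `recomb_fit`: `h`, `loglik`, `ci_low`, `ci_high`, `boundary`,
#'   `grouping`, `single_group` flag.
#' @examples
#' t1a <- ascertain(filter_families(load_fixture("table1A"),
#'                                  segregating_only = TRUE))
#' fit_recombination(t1a)
#' @export
fit_recombination <- function(set, grouping = NULL,
                              ascertainment = NULL,
                              exact_gametes = FALSE) {
  stopifnot(inherits(set, "cross_set"))
  if (nrow(set) == 0L) stop("cannot fit an empty cross_set")
  mode <- if (is.null(ascertainment)) attr(set, "ascertainment") else
    match.arg(ascertainment, c("complete", "truncate"))
  if (mode == "truncate" && any(set$n_huacaya == 0L)) {
    stop("truncate-selection fit requires every family to have r >= 1")
  }
  if (is.null(grouping)) {
    tr <- fit_two_ratio(set)
    grouping <- ifelse(tr$assignment == 1L, "trans", "cis")
    names(grouping) <- names(tr$assignment)
  }
  if (!all(set$sire_id %in% names(grouping))) {
    stop("grouping does not cover sire(s): ",
         paste(setdiff(set$sire_id, names(grouping)), collapse = ", "))
  }
  grp <- grouping[set$sire_id]
  if (!all(grp %in% c("cis", "trans"))) {
    stop("grouping values must be 'cis' or 'trans'")
  }
  single_group <- length(unique(grp)) == 1L
  if (single_group) {
    warning("all families in one group; h is estimated from that group alone")
  }
  r <- set$n_huacaya
  s <- set$n_total
  ll <- function(h) {
    p <- gamete_recessive_prob(grp, h, exact = exact_gametes)
    if (mode == "truncate" && any(p <= 0)) return(-Inf)
    sum(family_prob(r, s, p, mode, log = TRUE))
  }
  eps <- 1e-9
  opt <- stats::optimize(ll, lower = eps, upper = 0.5 - eps, maximum = TRUE,
                         tol = 1e-9)
  hhat <- opt$maximum
  lmax <- opt$objective
  if (mode == "complete") {
    for (b in c(0, 0.5)) {
      lb <- ll(b)
      if (is.finite(lb) && lb > lmax) {
        hhat <- b
        lmax <- lb
      }
    }
  }
  pc <- profile_ci(ll, max(hhat, 1e-12), lmax, lower = 0, upper = 0.5)
  structure(list(h = hhat, loglik = lmax,
                 ci_low = pc$ci[1L], ci_high = pc$ci[2L],
                 boundary = pc$boundary,
                 grouping = stats::setNames(grp, set$sire_id),
                 ascertainment = mode, exact_gametes = exact_gametes,
                 single_group = single_group, n_families = nrow(set)),
            class = "recomb_fit")
}

#' @export
print.recomb_fit <- function(x, ...) {
  cat(sprintf("recombination-fraction fit over %d families (%s kernel%s)\n",
              x$n_families, x$ascertainment,
              if (x$exact_gametes) ", exact gametes" else ""))
  cat(sprintf("  h = %.4f, 95%% profile CI [%.4f, %.4f]%s\n",
              x$h, x$ci_low, x$ci_high,
              if (any(x$boundary)) " (boundary)" else ""))
  cat(sprintf("  groups: %d trans, %d cis; log-likelihood = %.4f\n",
              sum(x$grouping == "trans"), sum(x$grouping == "cis"), x$loglik))
  invisible(x)
}

# Doubly-recessive (ab) gamete probability for each fully-specified
# two-locus genotype of a dominant-phenotype parent. Phase matters only for
# the double heterozygote.
SURI_GENOTYPES <- c("AABB", "AABb", "AAbb", "AaBB",
                    "AaBb_cis", "AaBb_trans", "Aabb", "aaBB", "aaBb")

ab_gamete_prob <- function(genotype, h) {
  switch(genotype,
         AABB = 0, AABb = 0, AAbb = 0, AaBB = 0,
         AaBb_cis = (1 - h) / 2,
         AaBb_trans = h / 2,
         Aabb = 1 / 2, aaBB = 0, aaBb = 1 / 2,
         stop("unknown genotype: ", genotype))
}

#' Expected recessive-offspring fraction in intercrosses, by parental pair
#'
#' For every ordered pair of dominant-phenotype two-locus genotypes,
#' returns the probability that an offspring is doubly homozygous recessive
#' (`aabb`): the product of each parent's `ab`-gamete probability, obtained
#' by gamete enumeration (`(1-h)/2` for cis double heterozygotes, `h/2` for
#' trans, Mendelian values for the unambiguous genotypes).
#'
#' @param h recombination fraction in `[0, 0.5]`.
#' @return A symmetric 9 x 9 matrix with dimnames the parental genotypes
#'   (`AaBb_cis` / `AaBb_trans` denote the phase-known double
#'   heterozygotes).
#' @examples
#' expected_suri_suri_ratios(0)["AaBb_cis", "AaBb_cis"]    # 0.25
#' expected_suri_suri_ratios(0.1)["AaBb_cis", "AaBb_trans"] # 0.0225
#' @export
expected_suri_suri_ratios <- function(h) {
  stopifnot(length(h) == 1L, h >= 0, h <= 0.5)
  g <- vapply(SURI_GENOTYPES, ab_gamete_prob, numeric(1L), h = h)
  outer(g, g)
}

#' Decline of carrier frequency under recessive culling
#'
#' Starting from an all-heterozygote founding stock of a single-locus
#' recessive trait, intercrossing at random and culling every recessive
#' offspring before reproduction leaves a fraction of heterozygous
#' (segregating) animals among the phenotypically dominant survivors that
#' declines with each generation k as `2 / (k + 2)`:
#' 2/3, 1/2, 2/5, 1/3, 2/7, 1/4, 2/9, ...
#'
#' This is the yardstick against which an observed carrier proportion in a
#' long-culled herd can be judged: under one-locus inheritance a herd
#' culled for a handful of generations should retain far fewer carriers
#' than, say, three-quarters.
#'
#' @param generations number of culling generations (>= 1).
#' @return Numeric vector of the first `generations` carrier fractions.
#' @examples
#' heterozygote_decline(7)  # 2/3, 1/2, 2/5, 1/3, 2/7, 1/4, 2/9
#' @export
heterozygote_decline <- function(generations) {
  stopifnot(length(generations) == 1L, generations >= 1,
            generations == floor(generations))
  k <- seq_len(generations)
  2 / (k + 2)
}
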