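#' Configuration for simulated half-sib cross datasets
#'
#' Describes a generative model for per-sire offspring counts:
#'
#' * `model = "one_locus"`: a segregating sire transmits the recessive
#'   phenotype with ratio `R`.
#' * `model = "two_locus"`: a segregating sire is a double heterozygote,
#'   cis with probability `cis_fraction`, and transmits at the phase ratio
#'   given by [gamete_recessive_prob()] at recombination fraction `h`.
#'
#' Designs: `"testcross"` mates each sire to recessive-phenotype dams, so
#' the per-offspring recessive probability is the sire's transmission
#' ratio; `"intercross"` mates to dominant-phenotype dams of unknown
#' status, each offspring's dam drawn independently as segregating with
#' probability `H` (one offspring per dam - the half-sib design), so the
#' marginal recessive probability composes as `H*R` given a segregating
#' sire; `"single_offspring"` forces every family size to 1.
#'
#' Family sizes come from `sizes`: a single integer (fixed size), an
#' integer vector (sampled with replacement), or `"table1A"` / `"table2"`
#' (resampled from the bundled series' sizes).
#'
#' @param model `"one_locus"` or `"two_locus"`.
#' @param n_sires number of half-sib families.
#' @param H probability that a sire (and, in intercrosses, each dam) is
#'   segregating.
#' @param R one-locus segregation ratio (required for `"one_locus"`).
#' @param h recombination fraction (required for `"two_locus"`).
#' @param cis_fraction probability that a segregating two-locus sire is cis.
#' @param sizes family-size law (see above).
#' @param design `"testcross"`, `"intercross"` or `"single_offspring"`.
#' @param exact_gametes passed to [gamete_recessive_prob()] for two-locus
#'   test-crosses.
#' @param seed optional integer seed; with it, [simulate_crosses()] is
#'   deterministic.
#' @return A `sim_config` list.
#' @export
sim_config <- function(model = c("one_locus", "two_locus"),
                       n_sires,
                       H = 1,
                       R = NULL,
                       h = NULL,
                       cis_fraction = 0.5,
                       sizes = 10,
                       design = c("testcross", "intercross",
                                  "single_offspring"),
                       exact_gametes = FALSE,
                       seed = NULL) {
  model <- match.arg(model)
  design <- match.arg(design)
  stopifnot(n_sires >= 1, H >= 0, H <= 1,
            cis_fraction >= 0, cis_fraction <= 1)
  if (model == "one_locus") {
    if (is.null(R)) stop("one_locus model needs R")
    stopifnot(R >= 0, R <= 1)
    if (!is.null(h)) stop("h is a two_locus parameter")
  } else {
    if (is.null(h)) stop("two_locus model needs h")
    stopifnot(h >= 0, h <= 0.5)
    if (!is.null(R)) stop("R is a one_locus parameter")
  }
  structure(list(model = model, n_sires = as.integer(n_sires), H = H,
                 R = R, h = h, cis_fraction = cis_fraction, sizes = sizes,
                 design = design, exact_gametes = exact_gametes, seed = seed),
            class = "sim_config")
}

resolve_sizes <- function(sizes, n) {
  if (is.character(sizes)) {
    pool <- load_fixture(match.arg(sizes, c("table1A", "table2")))$n_total
    return(sample(pool, n, replace = TRUE))
  }
  sizes <- as.integer(sizes)
  stopifnot(all(sizes >= 1))
  if (length(sizes) == 1L) rep.int(sizes, n) else
    sample(sizes, n, replace = TRUE)
}

#' Simulate a half-sib cross dataset
#'
#' Draws each sire's latent status (segregating with probability `H`; if
#' two-locus and segregating, cis with probability `cis_fraction`), a
#' family size from the size law, and offspring phenotypes as Bernoulli
#' draws at the model-implied per-offspring recessive probability. The
#' result is a complete-selection [cross_set()]; the latent truth is
#' attached as `attr(, "truth")` (a data.frame with `sire_id`,
#' `segregating`, `phase`, `p`) so calibration studies can condition on it.
#'
#' @param config a [sim_config()].
#' @return A `cross_set` with a `truth` attribute.
#' @examples
#' cfg <- sim_config("one_locus", n_sires = 20, R = 0.3, sizes = 10, seed = 1)
#' sim <- simulate_crosses(cfg)
#' attr(sim, "truth")[1:3, ]
#' @export
simulate_crosses <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(config$seed)
  }
  n <- config$n_sires
  seg <- stats::runif(n) < config$H
  phase <- rep(NA_character_, n)
  if (config$model == "two_locus") {
    phase[seg] <- ifelse(stats::runif(sum(seg)) < config$cis_fraction,
                         "cis", "trans")
  }
  s <- if (config$design == "single_offspring") rep.int(1L, n) else
    resolve_sizes(config$sizes, n)
  # sire's transmission ratio (prob. an offspring inherits the recessive
  # genotype from the sire side), zero for non-segregating sires
  trans_ratio <- numeric(n)
  if (config$model == "one_locus") {
    trans_ratio[seg] <- config$R
  } else {
    trans_ratio[seg] <- gamete_recessive_prob(phase[seg], config$h,
                                              exact = config$exact_gametes)
  }
  r <- integer(n)
  p_eff <- numeric(n)
  for (i in seq_len(n)) {
    if (config$design == "testcross") {
      p_eff[i] <- trans_ratio[i]
      r[i] <- stats::rbinom(1L, s[i], p_eff[i])
    } else {
      # intercross / single_offspring: each offspring has its own dam,
      # segregating with probability H and transmitting like the sire model
      if (config$model == "one_locus") {
        # recessive offspring requires both mates segregating; given that,
        # the cross segregates at ratio R (composition p = H.H.R marginally)
        dam_seg <- stats::runif(s[i]) < config$H
        p_off <- ifelse(dam_seg & seg[i], config$R, 0)
      } else {
        dam_seg <- stats::runif(s[i]) < config$H
        dam_phase <- ifelse(stats::runif(s[i]) < config$cis_fraction,
                            "cis", "trans")
        dam_g <- ifelse(dam_seg,
                        gamete_recessive_prob(dam_phase, config$h,
                                              exact = TRUE), 0)
        sire_g <- if (seg[i]) {
          gamete_recessive_prob(phase[i], config$h, exact = TRUE)
        } else 0
        p_off <- sire_g * dam_g
      }
      r[i] <- sum(stats::runif(s[i]) < p_off)
      p_eff[i] <- mean(p_off)
    }
  }
  out <- cross_set(data.frame(sire_id = sprintf("sim_%03d", seq_len(n)),
                              sire_phen = "Suri",
                              dam_phen = if (config$design == "testcross")
                                "Huacaya" else "Suri",
                              n_huacaya = r, n_total = s,
                              stringsAsFactors = FALSE),
                   ascertainment = "complete", label = "simulated")
  attr(out, "truth") <- data.frame(sire_id = out$sire_id,
                                   segregating = seg, phase = phase,
                                   p = p_eff, stringsAsFactors = FALSE)
  out
}

#' Apply truncate-selection ascertainment to a simulated set
#'
#' Drops every family with no recessive offspring and relabels the set as
#' truncate-selected, mimicking how segregating families enter a real
#' truncate-selection series.
#'
#' @param set a complete-selection [cross_set()].
#' @param mode only `"truncate"` is defined.
#' @return The ascertained `cross_set` (truth attribute subset alongside).
#' @export
ascertain <- function(set, mode = "truncate") {
  mode <- match.arg(mode, "truncate")
  stopifnot(inherits(set, "cross_set"))
  if (identical(attr(set, "ascertainment"), "truncate")) {
    return(set)
  }
  keep <- set$n_huacaya >= 1L
  if (!any(keep)) stop("no family has a recessive offspring; nothing survives")
  truth <- attr(set, "truth")
  out <- set[keep, , drop = FALSE]
  attributes(out)$label <- attr(set, "label")
  attributes(out)$ascertainment <- "truncate"
  class(out) <- class(set)
  rownames(out) <- NULL
  if (!is.null(truth)) {
    attr(out, "truth") <- truth[keep, , drop = FALSE]
  }
  validate_cross_set(out)
  out
}
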