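# Builders used across the suite.

make_set <- function(r, s, ascertainment = "complete",
                     ids = sprintf("F%02d", seq_along(r)),
                     sire_phen = "Suri", dam_phen = "Huacaya") {
  cross_set(data.frame(sire_id = ids,
                       sire_phen = rep_len(sire_phen, length(ids)),
                       dam_phen = rep_len(dam_phen, length(ids)),
                       n_huacaya = r, n_total = s,
                       stringsAsFactors = FALSE),
            ascertainment = ascertainment)
}

# Random small family sets (all segregating so both kernels apply).
random_seg_set <- function(n_fam, max_s = 8, ascertainment = "truncate") {
  s <- sample(2:max_s, n_fam, replace = TRUE)
  r <- vapply(s, function(si) sample(1:si, 1L), integer(1L))
  make_set(r, s, ascertainment = ascertainment)
}

# Absolute-tolerance comparison (expect_equal's tolerance is relative).
expect_near <- function(object, expected, tol) {
  testthat::expect_lt(max(abs(object - expected)), tol)
}

# Independent slow oracle: exhaustive grid search for the single-ratio MLE.
grid_mle <- function(set, step = 1e-5) {
  grid <- seq(step, 1 - step, by = step)
  ll <- vapply(grid, function(p) {
    sum(family_prob(set$n_huacaya, set$n_total, p,
                    attr(set, "ascertainment"), log = TRUE))
  }, numeric(1L))
  grid[which.max(ll)]
}
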