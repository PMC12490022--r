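# shared fixtures and independent oracles

# independent brute-force OLS slope/intercept by direct summation
ols_brute <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxy <- sum(x * y); sxx <- sum(x * x)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  list(slope = slope, intercept = intercept)
}

# a single-species (pH-independent) compound record
simple_record <- function(id, k, k_oh = 5e9) {
  reactivity_record(id, species_k_o3 = k, k_oh = k_oh)
}

# minimal pair_regression for QC-gate tests
make_reg <- function(slope = 1, intercept = 0, r_squared = 0.99,
                     n_points = 30L, k_competitor = 1000) {
  structure(list(
    target_id = "t", competitor_id = "c", slope = slope,
    intercept = intercept, slope_se = 0.01, r_squared = r_squared,
    n_points = n_points, k_competitor = k_competitor,
    k_estimate = slope * k_competitor, k_se = 0.01 * k_competitor),
    class = "pair_regression")
}

# independent abatement implementation for the finite-difference oracle:
# -100*expm1 keeps full precision near saturation, where subtracting two
# values close to 100 would lose the signal
abatement_oracle <- function(k_o3, k_oh, o3e, ohe) {
  -100 * expm1(-(k_o3 * o3e + k_oh * ohe))
}

# central finite-difference partials (step 1e-6 relative) of the oracle,
# differenced on the unit survival scale (before the x100) to keep the
# floating-point noise floor at ~2e-16; NA where even that resolution
# cannot resolve the difference (the partial is then numerically nil and
# the caller asserts so via the elasticity bound)
fd_partials <- function(k_o3, k_oh, o3e, ohe, h_rel = 1e-6) {
  x0 <- c(k_o3 = k_o3, k_oh = k_oh, o3_exposure = o3e, oh_exposure = ohe)
  xfun <- function(x) x[["k_o3"]] * x[["o3_exposure"]] +
    x[["k_oh"]] * x[["oh_exposure"]]
  out <- numeric(4); names(out) <- names(x0)
  for (nm in names(x0)) {
    h <- x0[[nm]] * h_rel
    xp <- x0; xp[nm] <- xp[nm] + h
    xm <- x0; xm[nm] <- xm[nm] - h
    d <- expm1(-xfun(xm)) - expm1(-xfun(xp)) # = (A(p+h) - A(p-h)) / 100
    out[nm] <- if (abs(d) > 1e-9) 100 * d / (2 * h) else NA_real_
  }
  out
}

# two-compound noiseless experiment used across kinetics tests
noiseless_experiment <- function(k_target = 500, k_comp = 1000,
                                 seed = 1) {
  mix <- mixture_spec(data.frame(compound_id = "tgt", k_true = k_target))
  comp <- list(simple_record("cmp", k_comp))
  generate_competition_experiment(mix, comp, noise_cv = 0, seed = seed)
}
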