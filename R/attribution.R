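#' @title Attribution results
#' @description Every attribution estimator returns a one-row tibble of class
#' `attribution_result` with columns `method`, `estimate`, `horizon` (years,
#' `0` meaning the age-independent `t -> 0` limit), `n` (subjects), `n_cases`
#' (observed cases, when known) and `n_attributed`
#' (`round(estimate * n_cases)`, signed). Bootstrap variants add `conf_low`,
#' `conf_high`, `conf_level`. The estimate can never exceed 1; negative values
#' indicate a protective exposure and are flagged when their magnitude is
#' large enough (> 0.5) to be outside the interpretable regime.
#' @param estimate,method,horizon,n,n_cases,ace Fields as described.
#' @keywords internal
new_attribution_result <- function(estimate, method, horizon = 0, n = NA_integer_,
                                   n_cases = NA_integer_, ace = NA_real_) {
  if (!is.finite(estimate) || estimate > 1 + 1e-12) {
    abort("attribution fraction must be finite and at most 1")
  }
  if (estimate < -0.5) {
    warn(paste0("large negative attribution fraction (", signif(estimate, 3),
                "): outside the interpretable protective regime"))
  }
  out <- tibble(
    method = method, estimate = estimate, horizon = horizon,
    n = as.integer(n), n_cases = as.integer(n_cases),
    n_attributed = if (is.na(n_cases)) NA_integer_ else
      attributed_cases(estimate, n_cases),
    ace = ace
  )
  class(out) <- c("attribution_result", class(out))
  out
}

#' @export
print.attribution_result <- function(x, ...) {
  cat("<attribution_result> method:", x$method, "\n")
  NextMethod()
}

#' @rdname new_attribution_result
#' @param x An `attribution_result`.
#' @param ... Unused.
#' @export
#' @method tidy attribution_result
tidy.attribution_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "attribution_result")
  out
}

#' @rdname new_attribution_result
#' @export
#' @method glance attribution_result
glance.attribution_result <- function(x, ...) tidy(x)

check_lp <- function(lp) {
  e <- eta_total(lp)
  if (length(e) < 1) abort("empty linear-predictor decomposition")
  if (any(!is.finite(e))) abort("linear predictors must be finite")
  invisible(e)
}

#' Backdoor-adjusted population attribution fraction
#'
#' The fraction of disease incidence attributed to the exposures `X`, comparing
#' the observed population with one where every subject is set to the exposure
#' baseline while confounders and other risk factors keep their observed,
#' correlated values:
#' \deqn{A_f = 1 - \frac{\sum_i e^{\eta_{w_i}+\eta_{z_i}}}{\sum_i
#'   e^{\eta_{x_i}+\eta_{w_i}+\eta_{z_i}}}.}
#' This is the sample form of the backdoor-adjusted excess fraction under
#' proportional hazards in the rare-disease limit; it equals the `t -> 0` limit
#' of [af_age()] and is independent of age. The numerator of the underlying
#' excess-risk contrast is the average causal effect of `X`; the result records
#' it (per unit baseline cumulative hazard) in the `ace` column.
#'
#' @param lp An `lp_decomposition` (columns `eta_x`, `eta_w`, `eta_z`), e.g.
#'   from [linear_predictors()].
#' @param n_cases Optional observed case count, used to report attributed
#'   cases.
#' @return An `attribution_result`.
#' @examples
#' lp <- tibble::tibble(eta_x = c(0, log(2), 0, log(2)),
#'                      eta_w = 0, eta_z = c(0, 0, log(3), log(3)))
#' af_backdoor(lp)$estimate # 1/3
#' @export
af_backdoor <- function(lp, n_cases = NA_integer_) {
  check_lp(lp)
  num <- sum(exp(lp$eta_w + lp$eta_z))
  den <- sum(exp(eta_total(lp)))
  new_attribution_result(1 - num / den, "backdoor", horizon = 0, n = nrow(lp),
                         n_cases = n_cases, ace = (den - num) / nrow(lp))
}

#' Confounder weights of the backdoor attribution fraction
#'
#' The backdoor fraction can be written
#' \eqn{A_f = 1 - 1 / \sum_i w_i e^{\eta_{x_i}}} with weights
#' \deqn{w_i = \frac{e^{\eta_{w_i}+\eta_{z_i}}}{\sum_j
#'   e^{\eta_{w_j}+\eta_{z_j}}},}
#' showing that each subject's exposure relative risk is weighted by the
#' relative risk from confounders and other risk factors. With no confounders
#' or other risk factors all weights are `1/n`. The weights sum to 1.
#'
#' @inheritParams af_backdoor
#' @return Numeric weight vector summing to 1.
#' @export
af_weights <- function(lp) {
  check_lp(lp)
  e <- exp(lp$eta_w + lp$eta_z)
  e / sum(e)
}

#' WHO-style attributable fraction
#'
#' The comparison fraction \eqn{A_W = 1 - 1 / \mathrm{mean}(e^{\eta_x})},
#' which ignores correlation between the exposures and the confounders/other
#' risk factors by construction. It bounds the backdoor fraction from below
#' (above) when \eqn{e^{\eta_x}} is positively (negatively) correlated with
#' \eqn{e^{\eta_w + \eta_z}}, with equality at zero sample covariance.
#'
#' @inheritParams af_backdoor
#' @return An `attribution_result`.
#' @export
af_who <- function(lp, n_cases = NA_integer_) {
  check_lp(lp)
  new_attribution_result(1 - 1 / mean(exp(lp$eta_x)), "who", horizon = 0,
                         n = nrow(lp), n_cases = n_cases)
}

#' Age-dependent attribution fraction from estimated survival curves
#'
#' Evaluates the attribution fraction at a finite horizon `t` using the exact
#' Weibull proportional-hazards incidence
#' \eqn{F(t) = 1 - \exp(-H_0(t) e^{\eta})} rather than the rare-disease
#' approximation:
#' \deqn{A_f(t) = 1 - \frac{\sum_i F(t, x_0, w_i, z_i)}{\sum_i
#'   F(t, x_i, w_i, z_i)}.}
#' As `t -> 0` this converges to [af_backdoor()]; for positive exposure
#' effects it decreases slowly with age.
#'
#' @inheritParams af_backdoor
#' @param bh A [weibull_hazard()] baseline.
#' @param t Horizon age in years (> 0).
#' @return An `attribution_result` with `horizon = t`.
#' @export
af_age <- function(lp, bh, t, n_cases = NA_integer_) {
  check_lp(lp)
  if (length(t) != 1 || t <= 0) abort("t must be a single positive age")
  H0 <- cumulative_hazard(bh, t)
  F1 <- 1 - exp(-H0 * exp(eta_total(lp)))
  F0 <- 1 - exp(-H0 * exp(lp$eta_w + lp$eta_z))
  new_attribution_result(1 - sum(F0) / sum(F1), "backdoor_age_t", horizon = t,
                         n = nrow(lp), n_cases = n_cases)
}

#' Pairwise attribution fraction between two exposure settings
#'
#' Comparing interventions `do(X = x1)` against `do(X = x2)`, the confounder
#' sums cancel and the fraction reduces to the conventional relative-risk
#' form \eqn{1 - e^{\eta_{x_1} - \eta_{x_2}}}. Negative values mean `x1` is
#' the riskier setting.
#'
#' @param eta_x1,eta_x2 Log relative risks of the two settings vs baseline.
#' @return Numeric fraction.
#' @export
af_pairwise <- function(eta_x1, eta_x2) {
  if (any(!is.finite(c(eta_x1, eta_x2)))) abort("inputs must be finite")
  1 - exp(eta_x1 - eta_x2)
}

#' Attribution fraction for the effect of treatment on the treated
#'
#' Among the actually exposed, the counterfactual contrast of exposure versus
#' baseline (with confounders held at their exposed-population distribution)
#' reduces under proportional hazards to \eqn{A_{ETT} = (R - 1)/R} where
#' \eqn{R = e^{\eta_{x_1}}} is the exposure relative risk — the simplest
#' attribution fraction in the literature, and invariant to confounder
#' structure.
#'
#' @param R Relative risk (> 0).
#' @return Numeric fraction ((R-1)/R; negative for protective `R < 1`).
#' @export
af_ett <- function(R) {
  if (any(!is.finite(R) | R <= 0)) abort("R must be positive")
  (R - 1) / R
}

#' Attributed case count
#'
#' \eqn{N_{A_f} = \mathrm{round}(A_f \times N_{obs})}: the signed number of
#' observed cases attributed to (or, when negative, prevented by) the
#' exposure.
#'
#' @param af Attribution fraction(s).
#' @param n_obs Observed case count(s), nonnegative.
#' @return Integer count(s), signed.
#' @examples
#' attributed_cases(0.9836, 3113) # 3062
#' @export
attributed_cases <- function(af, n_obs) {
  if (any(n_obs < 0)) abort("n_obs must be nonnegative")
  as.integer(round(af * n_obs))
}

#' Transform a fraction to the (P0 - P)/P0 scale
#'
#' For protective exposures one may prefer the fraction of the *intervened*
#' incidence, \eqn{(P_0 - P)/P_0}. In terms of \eqn{A_f = (P - P_0)/P} the
#' exact value is \eqn{-A_f/(1 - A_f)}; to first order it is
#' \eqn{-A_f(1 + A_f)}, so the two scales agree in magnitude when `af` is
#' small.
#'
#' @param af Attribution fraction (< 1).
#' @return Tibble with columns `exact` and `first_order`.
#' @export
af_flip <- function(af) {
  if (any(af >= 1)) abort("af must be < 1 (the intervened incidence vanishes)")
  tibble(exact = -af / (1 - af), first_order = -af * (1 + af))
}

#' Rare binary exposure approximation A_f ~ p(R - 1)
#'
#' For a binary exposure with prevalence `p` and relative risk `R`,
#' uncorrelated with the other risk factors and confounders, the attribution
#' fraction is exactly \eqn{1 - 1/(1 + p(R-1))}, and approximately
#' \eqn{p(R-1)} provided \eqn{p(R-1) \ll 1}. Halving the exposed proportion
#' halves the approximate fraction exactly.
#'
#' @param p Exposed proportion in `[0, 1]`.
#' @param R Relative risk (> 0).
#' @return Tibble with columns `approx` and `exact`.
#' @export
af_binary_approx <- function(p, R) {
  if (any(p < 0 | p > 1)) abort("p must lie in [0, 1]")
  if (any(R <= 0)) abort("R must be positive")
  tibble(approx = p * (R - 1), exact = 1 - 1 / (1 + p * (R - 1)))
}

#' Nonparametric bootstrap for the backdoor attribution fraction
#'
#' Subject-level resampling of the full pipeline (Cox fit, then
#' [af_backdoor()]), giving a seeded percentile interval. Replicates whose Cox
#' fit fails or does not converge are dropped with a warning; more than 10%
#' dropped is an error.
#'
#' @param cohort,roles As in [fit_ph()].
#' @param B Number of bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return An `attribution_result` with `conf_low`, `conf_high`, `conf_level`
#'   and attribute `replicates` (the replicate estimates).
#' @export
bootstrap_af <- function(cohort, roles, B = 200, seed = 1, level = 0.95) {
  if (B < 100) abort("B must be at least 100")
  fit <- fit_ph(cohort, roles)
  point <- af_backdoor(linear_predictors(fit), n_cases = fit$n_events)
  set.seed(seed)
  idx <- matrix(sample.int(nrow(cohort), nrow(cohort) * B, replace = TRUE),
                ncol = B)
  reps <- vapply(seq_len(B), function(b) {
    res <- tryCatch({
      f <- fit_ph(cohort[idx[, b], , drop = FALSE], roles)
      if (!f$converged) NA_real_ else af_backdoor(linear_predictors(f))$estimate
    }, error = function(e) NA_real_)
    res
  }, numeric(1))
  dropped <- sum(is.na(reps))
  if (dropped > 0) {
    warn(paste0(dropped, " of ", B, " bootstrap replicates failed to converge",
                " and were dropped"))
  }
  if (dropped > 0.1 * B) abort("more than 10% of bootstrap replicates failed")
  qs <- quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                 na.rm = TRUE, names = FALSE, type = 7)
  out <- point
  out$conf_low <- qs[1]
  out$conf_high <- qs[2]
  out$conf_level <- level
  attr(out, "replicates") <- reps
  out
}
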