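#' Discrete causal model with explicit outcome probabilities
#'
#' A fully enumerable causal model for ground-truth computation: categorical
#' confounders `Z` with marginal probabilities, exposures `X` and other risk
#' factors `W` with conditional probabilities given `Z`, and an explicit
#' outcome probability \eqn{P(Y=1 \mid x, w, z)} supplied as a function of a
#' one-row data frame of covariate levels. Used to validate the attribution
#' estimators by exhaustive summation; never used by them.
#'
#' @param confounders Named list: confounder -> named probability vector.
#' @param exposures,other_risks Named lists: covariate -> named probability
#'   vector or `function(z)` returning one (as in [generative_model()]).
#' @param p_y `function(row)` returning \eqn{P(Y=1)} for a one-row data frame
#'   of covariate levels.
#' @return Object of class `discrete_causal_model`.
#' @export
discrete_causal_model <- function(confounders, exposures, other_risks = list(),
                                  p_y) {
  stopifnot(is.function(p_y))
  gm <- generative_model(confounders = confounders, exposures = exposures,
                         other_risks = other_risks)
  structure(list(confounders = confounders, exposures = exposures,
                 other_risks = other_risks, levels = gm$levels,
                 baseline = gm$baseline, p_y = p_y),
            class = "discrete_causal_model")
}

# Exhaustive joint distribution over all covariate patterns:
# P(x, w, z) = prod_z P(z) * prod_{xw} P(xw | z).
enumerate_strata <- function(model) {
  zcovs <- names(model$confounders)
  xwcovs <- c(names(model$exposures), names(model$other_risks))
  grid <- expand.grid(model$levels[c(zcovs, xwcovs)],
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  prob <- rep(1, nrow(grid))
  for (cv in zcovs) {
    prob <- prob * unname(model$confounders[[cv]][grid[[cv]]])
  }
  xw <- c(model$exposures, model$other_risks)
  for (cv in names(xw)) {
    spec <- xw[[cv]]
    if (!is.function(spec)) {
      prob <- prob * unname(spec[grid[[cv]]])
    } else {
      for (i in seq_len(nrow(grid))) {
        p <- spec(grid[i, zcovs, drop = FALSE])
        prob <- replace(prob, i, prob[i] * unname(p[[grid[[cv]][i]]]))
      }
    }
  }
  out <- as_tibble(grid)
  out$prob <- prob
  out
}

# The oracle's own survival evaluation (independent of the ph_fit module):
# incidence by age t under a Weibull-baseline proportional-hazards model.
oracle_incidence <- function(shape, scale, t, eta) {
  1 - exp(-((t / scale)^shape) * exp(eta))
}

oracle_eta <- function(lhr, data, covariates = names(lhr)) {
  out <- rep(0, nrow(data))
  for (cv in covariates) {
    out <- out + unname(lhr[[cv]][as.character(data[[cv]])])
  }
  out
}

#' Interventional outcome probability by exhaustive adjustment
#'
#' Evaluates the backdoor adjustment formula exactly on a
#' [discrete_causal_model()]:
#' \deqn{P(Y=1 \mid do(X=x)) = \sum_{w,z} P(Y=1 \mid x, w, z)\, P(w, z),}
#' which differs from the observational conditional
#' \eqn{P(Y=1 \mid X=x) = \sum_{w,z} P(Y=1 \mid x,w,z) P(w,z \mid x)} whenever
#' `X` is confounded.
#'
#' @param model A [discrete_causal_model()].
#' @param setting Named character vector fixing each exposure covariate to a
#'   level.
#' @return The interventional probability (scalar).
#' @export
do_probability <- function(model, setting) {
  stopifnot(inherits(model, "discrete_causal_model"))
  check_setting_levels(model, setting, names(model$exposures), all_x = TRUE)
  strata <- enumerate_strata(model)
  wz <- c(names(model$confounders), names(model$other_risks))
  marg <- strata %>%
    group_by(dplyr::across(dplyr::all_of(wz))) %>%
    summarise(prob = sum(.data$prob), .groups = "drop")
  p <- 0
  for (i in seq_len(nrow(marg))) {
    row <- marg[i, wz, drop = FALSE]
    for (cv in names(setting)) row[[cv]] <- setting[[cv]]
    p <- p + model$p_y(row) * marg$prob[i]
  }
  p
}

#' @rdname do_probability
#' @description `conditional_probability()` gives the ordinary observational
#'   conditional for comparison.
#' @export
conditional_probability <- function(model, setting) {
  stopifnot(inherits(model, "discrete_causal_model"))
  check_setting_levels(model, setting, names(model$exposures), all_x = TRUE)
  strata <- enumerate_strata(model)
  keep <- rep(TRUE, nrow(strata))
  for (cv in names(setting)) keep <- keep & strata[[cv]] == setting[[cv]]
  strata <- strata[keep, , drop = FALSE]
  px <- sum(strata$prob)
  if (px == 0) abort("conditioning event has probability zero")
  p <- 0
  for (i in seq_len(nrow(strata))) {
    p <- p + model$p_y(strata[i, setdiff(names(strata), "prob"),
                              drop = FALSE]) * strata$prob[i]
  }
  p / px
}

check_setting_levels <- function(model, setting, xcovs, all_x = FALSE) {
  if (length(setting) == 0) abort("setting must fix at least one exposure")
  bad <- setdiff(names(setting), xcovs)
  if (length(bad) > 0) {
    abort(paste0("not exposure covariate(s): ", paste(bad, collapse = ", ")))
  }
  if (all_x && !setequal(names(setting), xcovs)) {
    abort("setting must fix every exposure covariate")
  }
  for (cv in names(setting)) {
    if (!setting[[cv]] %in% model$levels[[cv]]) {
      abort(paste0("'", setting[[cv]], "' is not a declared level of '",
                   cv, "'"))
    }
  }
}

#' Interventional incidence rate under proportional hazards, exactly and in the
#' rare-disease limit
#'
#' For a [generative_model()] (whose strata carry Weibull proportional-hazards
#' survival curves), evaluates \eqn{P(Y=1, T<t \mid do(X=x))} two ways: the
#' exact stratified sum \eqn{\sum_{w,z} F(t, x, w, z) P(w,z)}, and the
#' rare-disease closed form \eqn{e^{\eta_x} H_0(t) A_{WZ}} with
#' \eqn{A_{WZ} = \sum_{w,z} e^{\eta_w + \eta_z} P(w,z)}. The two agree when
#' the cumulative hazard is small.
#'
#' @param model A [generative_model()].
#' @param t Horizon age (>= 0).
#' @param setting Named character vector fixing exposure covariates.
#' @param bh Baseline hazard (defaults to the model's).
#' @return Tibble with columns `exact` and `rare_limit`.
#' @export
do_rate_ph <- function(model, t, setting, bh = model$baseline_hazard) {
  stopifnot(inherits(model, "generative_model"))
  if (t < 0) abort("t must be nonnegative")
  check_setting_levels(model, setting, names(model$exposures))
  strata <- enumerate_strata(model)
  wz <- c(names(model$confounders), names(model$other_risks))
  marg <- strata %>%
    group_by(dplyr::across(dplyr::all_of(wz))) %>%
    summarise(prob = sum(.data$prob), .groups = "drop")
  eta_wz <- oracle_eta(model$log_hr, marg, wz)
  eta_x <- sum(vapply(names(setting), function(cv) {
    unname(model$log_hr[[cv]][[setting[[cv]]]])
  }, numeric(1)))
  exact <- sum(marg$prob *
                 oracle_incidence(bh$shape, bh$scale, t, eta_x + eta_wz))
  H0 <- (t / bh$scale)^bh$shape
  rare <- exp(eta_x) * H0 * sum(marg$prob * exp(eta_wz))
  tibble(exact = exact, rare_limit = rare)
}

#' Exact attribution fraction on a known generative model
#'
#' Evaluates the backdoor excess fraction by exhaustive summation over the
#' model's discrete joint distribution, using the exact Weibull incidence
#' \eqn{F(t) = 1 - e^{-H_0(t) e^{\eta}}} at a finite horizon, or its
#' age-independent `t -> 0` limit (`t = 0`), where the fraction depends only
#' on the relative risks:
#' \deqn{A_f(0) = 1 - \frac{E[e^{\eta_w+\eta_z}]}{E[e^{\eta_x+\eta_w+\eta_z}]}.}
#'
#' @inheritParams do_rate_ph
#' @param t Horizon age; `0` requests the analytic limit.
#' @return The true attribution fraction (scalar).
#' @export
af_exact <- function(model, t = 0, bh = model$baseline_hazard) {
  stopifnot(inherits(model, "generative_model"))
  if (t < 0) abort("t must be nonnegative")
  strata <- enumerate_strata(model)
  xcovs <- names(model$exposures)
  wz <- c(names(model$confounders), names(model$other_risks))
  eta_wz <- oracle_eta(model$log_hr, strata, wz)
  eta_full <- eta_wz + oracle_eta(model$log_hr, strata, xcovs)
  if (t == 0) {
    return(1 - sum(strata$prob * exp(eta_wz)) /
             sum(strata$prob * exp(eta_full)))
  }
  F1 <- oracle_incidence(bh$shape, bh$scale, t, eta_full)
  F0 <- oracle_incidence(bh$shape, bh$scale, t, eta_wz)
  1 - sum(strata$prob * F0) / sum(strata$prob * F1)
}

#' Monte-Carlo attribution fraction from paired interventional simulation
#'
#' Simulates an observational cohort and its `do(X = x0)` copy with shared
#' random draws (same seed, subjects followed from birth), and estimates
#' \eqn{A_f(t) = (P - P_0)/P} from the event proportions by age `t`. The
#' standard error is propagated from the paired binomial counts by the delta
#' method.
#'
#' @param model A [generative_model()].
#' @param n Simulated subjects (>= 10^4 recommended).
#' @param seed Integer seed.
#' @param t Horizon age (defaults to the model's censoring age).
#' @param setting Baseline exposure setting (defaults to every exposure at its
#'   declared baseline level).
#' @return Tibble with `estimate`, `se`, `p_obs`, `p_do`, `n`.
#' @export
af_counterfactual_mc <- function(model, n, seed, t = model$censor_age,
                                 setting = NULL) {
  stopifnot(inherits(model, "generative_model"))
  if (is.null(setting)) {
    xcovs <- names(model$exposures)
    setting <- setNames(model$baseline[xcovs], xcovs)
  }
  obs <- simulate_cohort(model, n, seed, left_truncation = FALSE)
  int <- simulate_do(model, n, seed, setting, left_truncation = FALSE)
  y <- as.numeric(obs$event == 1 & obs$exit_age <= t)
  y0 <- as.numeric(int$event == 1 & int$exit_age <= t)
  P <- mean(y)
  if (P == 0) abort("no events by the requested horizon")
  D <- mean(y - y0)
  se <- ratio_se(y - y0, y)
  tibble(estimate = D / P, se = se, p_obs = P, p_do = mean(y0), n = n)
}

# delta-method standard error of mean(num)/mean(den) from paired observations
ratio_se <- function(num, den) {
  n <- length(num)
  mn <- mean(num); md <- mean(den)
  v <- var(num) / md^2 - 2 * stats::cov(num, den) * mn / md^3 +
    var(den) * mn^2 / md^4
  sqrt(pmax(v, 0) / n)
}

#' Monte-Carlo effect of treatment on the treated
#'
#' Uses sharp counterfactual pairs ([simulate_counterfactual_pair()]) to
#' estimate the ETT attribution fraction
#' \deqn{\frac{P(Y_{x_1}=1 \mid X=x_1) - P(Y_{x_0}=1 \mid X=x_1)}
#'   {P(Y_{x_1}=1 \mid X=x_1)},}
#' which under proportional hazards should match the closed form
#' \eqn{(R-1)/R} with \eqn{R = e^{\eta_{x_1}}}, whatever the confounding
#' strength.
#'
#' @inheritParams af_counterfactual_mc
#' @param covariate,x1,x0 Exposure covariate and its exposed/unexposed levels.
#' @return Tibble with `estimate`, `se`, `p_x1`, `p_x0`, `n_exposed`.
#' @export
ett_mc <- function(model, n, seed, covariate, x1, x0, t = model$censor_age) {
  pairs <- simulate_counterfactual_pair(model, n, seed, covariate, x1, x0,
                                        horizon = t)
  if (nrow(pairs) == 0) abort("no exposed subjects in the simulation")
  p1 <- mean(pairs$y_x1)
  if (p1 == 0) abort("no events among the exposed by the requested horizon")
  est <- (p1 - mean(pairs$y_x0)) / p1
  tibble(estimate = est,
         se = ratio_se(pairs$y_x1 - pairs$y_x0, pairs$y_x1),
         p_x1 = p1, p_x0 = mean(pairs$y_x0), n_exposed = nrow(pairs))
}
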