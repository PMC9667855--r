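#' Declare a generative model for a confounded survival cohort
#'
#' Describes the data-generating process used by [simulate_cohort()] and
#' friends: categorical confounders `Z` drawn from marginal distributions,
#' exposures `X` and other risk factors `W` drawn conditionally on `Z` (this is
#' what makes the cohort confounded), and a latent event age drawn from a
#' Weibull-baseline proportional-hazards model
#' \eqn{h(t) = h_0(t)\,e^{\eta_x+\eta_w+\eta_z}}. Study entry age is uniform and
#' follow-up is administratively censored, mimicking a mid-life volunteer
#' cohort.
#'
#' @param confounders Named list: confounder name -> named probability vector
#'   over its levels.
#' @param exposures,other_risks Named lists: covariate name -> either a named
#'   probability vector (drawn independently of `Z`) or a
#'   `function(z)` taking a one-row data frame of confounder levels and
#'   returning a named probability vector (drawn conditionally on `Z`).
#' @param log_hr Named list: covariate name -> named numeric vector of log
#'   hazard ratios per level. Missing levels default to 0; the baseline level
#'   must carry log hazard ratio 0.
#' @param baseline_hazard A [weibull_hazard()] giving the cumulative baseline
#'   hazard \eqn{H_0(t) = (t/b)^a}.
#' @param baselines Named character vector of baseline levels (defaults to each
#'   covariate's first level).
#' @param entry_age Length-2 numeric, uniform study-entry age range in years.
#' @param censor_age Administrative censoring age in years.
#' @param sexes Optional named probability vector (e.g. `c(F = 0.5, M = 0.5)`);
#'   when given, subjects carry a `sex` label (it does not alter the hazard).
#' @param outcomes Optional named list for multi-outcome simulation
#'   ([simulate_landscape()]): outcome code -> list with elements `chapter`
#'   (character), `baseline_hazard` (defaults to the model's), and `log_hr`
#'   (defaults to the model's).
#' @return An object of class `generative_model`.
#' @examples
#' gm <- generative_model(
#'   confounders = list(ses = c(low = 0.5, high = 0.5)),
#'   exposures = list(smoking = function(z) {
#'     if (z$ses == "low") c(never = 0.5, current = 0.5)
#'     else c(never = 0.8, current = 0.2)
#'   }),
#'   log_hr = list(smoking = c(current = log(2)), ses = c(low = log(1.5))),
#'   baseline_hazard = weibull_hazard(5, 150)
#' )
#' simulate_cohort(gm, n = 5, seed = 1)
#' @export
generative_model <- function(confounders, exposures, other_risks = list(),
                             log_hr = list(),
                             baseline_hazard = weibull_hazard(5, 150),
                             baselines = character(),
                             entry_age = c(40, 70), censor_age = 80,
                             sexes = NULL, outcomes = NULL) {
  check_probs <- function(p, what) {
    if (!is.numeric(p) || is.null(names(p)) || any(p < 0)) {
      abort(paste0(what, " must be a named nonnegative probability vector"))
    }
    if (abs(sum(p) - 1) > 1e-12) {
      abort(paste0(what, " probabilities must sum to 1 (within 1e-12)"))
    }
    if (length(p) == 0) abort(paste0(what, ": empty level set"))
  }
  for (cv in names(confounders)) check_probs(confounders[[cv]], cv)
  if (!is.null(sexes)) check_probs(sexes, "sexes")
  stopifnot(inherits(baseline_hazard, "weibull_hazard"))
  if (length(entry_age) != 2 || entry_age[1] >= entry_age[2]) {
    abort("entry_age must be an increasing length-2 range")
  }

  z_levels <- lapply(confounders, names)
  # level sets of conditional covariates: probe functions at the first Z pattern
  probe_z <- as.data.frame(lapply(z_levels, `[`, 1), stringsAsFactors = FALSE)
  cond_levels <- function(spec, cv) {
    p <- if (is.function(spec)) spec(probe_z) else spec
    check_probs(p, cv)
    names(p)
  }
  xw <- c(exposures, other_risks)
  xw_levels <- lapply(names(xw), function(cv) cond_levels(xw[[cv]], cv))
  names(xw_levels) <- names(xw)
  levels <- c(xw_levels, z_levels)

  baseline <- vapply(names(levels), function(cv) {
    b <- if (cv %in% names(baselines)) baselines[[cv]] else levels[[cv]][1]
    if (!b %in% levels[[cv]]) {
      abort(paste0("baseline '", b, "' not a level of '", cv, "'"))
    }
    b
  }, character(1))

  normalise_lhr <- function(lhr, levels, baseline) {
    for (cv in names(lhr)) {
      if (!cv %in% names(levels)) {
        abort(paste0("log_hr given for undeclared covariate '", cv, "'"))
      }
      bad <- setdiff(names(lhr[[cv]]), levels[[cv]])
      if (length(bad) > 0) {
        abort(paste0("log_hr for undeclared level(s) of '", cv, "': ",
                     paste(bad, collapse = ", ")))
      }
    }
    out <- lapply(names(levels), function(cv) {
      full <- setNames(rep(0, length(levels[[cv]])), levels[[cv]])
      got <- lhr[[cv]]
      full[names(got)] <- got
      if (full[[baseline[[cv]]]] != 0) {
        abort(paste0("baseline level of '", cv, "' must have log hazard ratio 0"))
      }
      full
    })
    setNames(out, names(levels))
  }
  log_hr <- normalise_lhr(log_hr, levels, baseline)

  if (!is.null(outcomes)) {
    if (is.null(names(outcomes)) || any(names(outcomes) == "")) {
      abort("outcomes must be a named list (names are outcome codes)")
    }
    outcomes <- lapply(outcomes, function(oc) {
      oc$chapter <- oc$chapter %||% "I"
      oc$baseline_hazard <- oc$baseline_hazard %||% baseline_hazard
      stopifnot(inherits(oc$baseline_hazard, "weibull_hazard"))
      oc$log_hr <- normalise_lhr(oc$log_hr %||% list(), levels, baseline)
      oc
    })
  }

  structure(list(
    confounders = confounders, exposures = exposures,
    other_risks = other_risks, log_hr = log_hr, levels = levels,
    baseline = baseline, baseline_hazard = baseline_hazard,
    entry_age = entry_age, censor_age = censor_age, sexes = sexes,
    outcomes = outcomes
  ), class = "generative_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.generative_model <- function(x, ...) {
  cat("<generative_model>\n")
  cat("  confounders:", paste(names(x$confounders), collapse = ", "), "\n")
  cat("  exposures:  ", paste(names(x$exposures), collapse = ", "), "\n")
  if (length(x$other_risks) > 0) {
    cat("  other risks:", paste(names(x$other_risks), collapse = ", "), "\n")
  }
  cat("  baseline hazard: Weibull shape", x$baseline_hazard$shape,
      "scale", x$baseline_hazard$scale, "\n")
  cat("  entry", x$entry_age[1], "-", x$entry_age[2],
      "y, censored at", x$censor_age, "y\n")
  if (!is.null(x$outcomes)) {
    cat("  outcomes:", paste(names(x$outcomes), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Covariate roles induced by a generative model
#'
#' Builds the [covariate_roles()] matching a [generative_model()], so that
#' simulated cohorts can be analysed with the model's own covariate structure.
#'
#' @param model A [generative_model()].
#' @return A [covariate_roles()] object.
#' @export
roles_of <- function(model) {
  stopifnot(inherits(model, "generative_model"))
  pick <- function(covs) {
    out <- model$levels[covs]
    lapply(out, as.character)
  }
  covariate_roles(
    exposures = pick(names(model$exposures)),
    other_risks = pick(names(model$other_risks)),
    confounders = pick(names(model$confounders)),
    baselines = model$baseline
  )
}

#' Invert the Weibull proportional-hazards survival function
#'
#' Given a uniform draw `u`, returns the event age `T` satisfying
#' \eqn{S(T) = \exp(-(T/b)^a e^{\eta})= u}, i.e.
#' \eqn{T = b\,(-\ln u \; e^{-\eta})^{1/a}}.
#'
#' @param bh A [weibull_hazard()] (or a [generative_model()], whose baseline
#'   hazard is used).
#' @param eta Total log relative risk (finite; recycled against `u`).
#' @param u Uniform(0, 1) draw(s), strictly inside the unit interval.
#' @return Event age(s) in years.
#' @examples
#' sample_event_time(weibull_hazard(1, 1), eta = 0, u = exp(-2)) # exponential: 2
#' @export
sample_event_time <- function(bh, eta, u) {
  if (inherits(bh, "generative_model")) bh <- bh$baseline_hazard
  stopifnot(inherits(bh, "weibull_hazard"))
  if (any(u <= 0 | u >= 1)) abort("u must lie strictly in (0, 1)")
  if (any(!is.finite(eta))) abort("eta must be finite")
  bh$scale * (-log(u) * exp(-eta))^(1 / bh$shape)
}

# total log relative risk for rows of `data` under a log-hazard-ratio list
eta_from_lhr <- function(lhr, data, covariates = names(lhr)) {
  if (length(covariates) == 0 || nrow(data) == 0) return(rep(0, nrow(data)))
  parts <- vapply(covariates, function(cv) {
    unname(lhr[[cv]][as.character(data[[cv]])])
  }, numeric(nrow(data)))
  if (nrow(data) == 1) sum(parts) else rowSums(parts)
}

# draw confounders, then exposures/other risks conditionally on the Z pattern;
# draw order (declared order, grouped by sorted Z pattern) is fixed so paired
# seeds stay aligned between observational and interventional runs
draw_covariates <- function(model, n) {
  df <- tibble(.rows = n)
  for (cv in names(model$confounders)) {
    p <- model$confounders[[cv]]
    df[[cv]] <- sample(names(p), n, replace = TRUE, prob = p)
  }
  if (!is.null(model$sexes)) {
    df$sex <- sample(names(model$sexes), n, replace = TRUE, prob = model$sexes)
  }
  zcovs <- names(model$confounders)
  xw <- c(model$exposures, model$other_risks)
  for (cv in names(xw)) {
    spec <- xw[[cv]]
    if (!is.function(spec)) {
      df[[cv]] <- sample(names(spec), n, replace = TRUE, prob = spec)
    } else {
      df[[cv]] <- rep(NA_character_, n)
      pat <- if (length(zcovs) > 0) {
        do.call(paste, c(df[zcovs], sep = "\r"))
      } else {
        rep("", n)
      }
      for (pt in sort(unique(pat))) {
        idx <- which(pat == pt)
        p <- spec(df[idx[1], zcovs, drop = FALSE])
        df[[cv]][idx] <- sample(names(p), length(idx), replace = TRUE, prob = p)
      }
    }
  }
  df
}

sim_batch <- function(model, n, setting = NULL) {
  df <- draw_covariates(model, n)
  if (!is.null(setting)) for (cv in names(setting)) df[[cv]] <- setting[[cv]]
  df$entry_age <- runif(n, model$entry_age[1], model$entry_age[2])
  u <- runif(n)
  eta <- eta_from_lhr(model$log_hr, df)
  df$.latent_age <- sample_event_time(model$baseline_hazard, eta, u)
  df
}

finalise_cohort <- function(df, model, left_truncation) {
  if (!left_truncation) df$entry_age <- 0
  df$event <- as.integer(df$.latent_age <= model$censor_age)
  df$exit_age <- pmin(df$.latent_age, model$censor_age)
  df$.latent_age <- NULL
  df$subject_id <- seq_len(nrow(df))
  df[, c("subject_id", intersect("sex", names(df)), "entry_age", "exit_age",
         "event",
         setdiff(names(df), c("subject_id", "sex", "entry_age", "exit_age",
                              "event")))]
}

validate_setting <- function(model, setting) {
  if (length(setting) == 0) abort("setting must fix at least one exposure")
  bad <- setdiff(names(setting), names(model$exposures))
  if (length(bad) > 0) {
    abort(paste0("do-interventions are defined only on exposures (X); not X: ",
                 paste(bad, collapse = ", ")))
  }
  for (cv in names(setting)) {
    if (!setting[[cv]] %in% model$levels[[cv]]) {
      abort(paste0("'", setting[[cv]], "' is not a level of '", cv, "'"))
    }
  }
}

#' Simulate an observational, left-truncated survival cohort
#'
#' Draws confounders, exposures conditional on confounders, a uniform study
#' entry age, and a latent Weibull proportional-hazards event age. Subjects
#' whose latent event precedes study entry are discarded and redrawn
#' (left truncation by rejection: such subjects would never be observed), and
#' follow-up is administratively censored at `model$censor_age`. Fully
#' reproducible for a given `(model, n, seed)`.
#'
#' @param model A [generative_model()].
#' @param n Number of subjects to return.
#' @param seed Integer seed for the single RNG stream used by the call.
#' @param left_truncation If `FALSE`, subjects are followed from birth
#'   (`entry_age = 0`) and no rejection occurs; this variant exists for
#'   ground-truth causal computations, not for emulating an observational
#'   study.
#' @return A tibble with columns `subject_id`, optional `sex`, `entry_age`,
#'   `exit_age`, `event` and one column per covariate.
#' @export
simulate_cohort <- function(model, n, seed, left_truncation = TRUE) {
  stopifnot(inherits(model, "generative_model"), n >= 1)
  set.seed(seed)
  if (!left_truncation) {
    return(finalise_cohort(sim_batch(model, n), model, FALSE))
  }
  kept <- list()
  got <- 0
  while (got < n) {
    df <- sim_batch(model, n - got)
    df <- df[df$.latent_age >= df$entry_age, , drop = FALSE]
    if (nrow(df) > 0) {
      kept[[length(kept) + 1]] <- df
      got <- got + nrow(df)
    }
  }
  finalise_cohort(bind_rows(kept), model, TRUE)
}

#' Simulate an interventional cohort under do(X = x)
#'
#' Identical generative process to [simulate_cohort()] except that the named
#' exposures are forced to fixed levels *after* the confounders (and every
#' other covariate) are drawn: the confounder marginal is untouched, which is
#' exactly the interventional distribution \eqn{P(\cdot \mid do(X=x))}.
#' Interventions are defined only on exposure (`X`) covariates. With the same
#' seed, every random draw is shared with the corresponding
#' [simulate_cohort()] call, so paired comparisons are low-variance.
#'
#' @inheritParams simulate_cohort
#' @param setting Named character vector, exposure covariate -> forced level.
#' @return A cohort tibble as in [simulate_cohort()].
#' @export
simulate_do <- function(model, n, seed, setting, left_truncation = TRUE) {
  stopifnot(inherits(model, "generative_model"), n >= 1)
  validate_setting(model, setting)
  set.seed(seed)
  if (!left_truncation) {
    return(finalise_cohort(sim_batch(model, n, setting), model, FALSE))
  }
  kept <- list()
  got <- 0
  while (got < n) {
    df <- sim_batch(model, n - got, setting)
    df <- df[df$.latent_age >= df$entry_age, , drop = FALSE]
    if (nrow(df) > 0) {
      kept[[length(kept) + 1]] <- df
      got <- got + nrow(df)
    }
  }
  finalise_cohort(bind_rows(kept), model, TRUE)
}

#' Simulate sharp counterfactual outcome pairs among the exposed
#'
#' For one exposure covariate, draws each subject's confounders, covariates and
#' a single uniform `u`, then computes the event age twice — once with the
#' exposure set to `x1` and once set to `x0` — sharing `u` and all other
#' covariates (monotone coupling). Only subjects whose *factual* exposure equals
#' `x1` are returned, which is the population over which the effect of
#' treatment on the treated is defined.
#'
#' @inheritParams simulate_cohort
#' @param covariate Name of the exposure covariate being intervened on.
#' @param x1,x0 Its "exposed" and "unexposed" levels (distinct).
#' @param horizon Age by which the binary outcomes `y_x1`, `y_x0` are assessed
#'   (default the model's censoring age); subjects are followed from birth.
#' @return Tibble of exposed subjects with covariates, latent ages `t_x1`,
#'   `t_x0` and outcomes `y_x1`, `y_x0` (0/1 by `horizon`).
#' @export
simulate_counterfactual_pair <- function(model, n, seed, covariate, x1, x0,
                                         horizon = model$censor_age) {
  stopifnot(inherits(model, "generative_model"), n >= 1)
  validate_setting(model, setNames(c(x1, x0), c(covariate, covariate))[1])
  if (!x0 %in% model$levels[[covariate]]) {
    abort(paste0("'", x0, "' is not a level of '", covariate, "'"))
  }
  if (identical(x1, x0)) abort("x1 and x0 must differ")
  set.seed(seed)
  df <- draw_covariates(model, n)
  u <- runif(n)
  other <- setdiff(names(model$log_hr), covariate)
  eta_common <- eta_from_lhr(model$log_hr, df, other)
  lhr <- model$log_hr[[covariate]]
  t1 <- sample_event_time(model$baseline_hazard, eta_common + lhr[[x1]], u)
  t0 <- sample_event_time(model$baseline_hazard, eta_common + lhr[[x0]], u)
  df$t_x1 <- t1
  df$t_x0 <- t0
  df$y_x1 <- as.integer(t1 <= horizon)
  df$y_x0 <- as.integer(t0 <= horizon)
  as_tibble(df[df[[covariate]] == x1, , drop = FALSE])
}

#' Simulate a multi-outcome cohort with a long diagnosis table
#'
#' Multi-outcome variant of [simulate_cohort()]: each outcome declared in
#' `model$outcomes` gets an independent latent Weibull event age given the
#' shared covariates (diseases are analysed separately, so no competing-risk
#' dependence is modelled). Diagnoses occurring by the censoring age are
#' returned in a long events table, *including* those before study entry —
#' exclusion of prevalent cases is an analysis step
#' ([derive_first_incidence()]), not a sampling step.
#'
#' @inheritParams simulate_cohort
#' @return A list with `subjects` (subject_id, optional sex, entry_age,
#'   covariates) and `events` (subject_id, code, chapter, diagnosis_age).
#' @export
simulate_landscape <- function(model, n, seed) {
  stopifnot(inherits(model, "generative_model"), n >= 1)
  if (is.null(model$outcomes)) abort("model declares no outcomes")
  set.seed(seed)
  subjects <- draw_covariates(model, n)
  subjects$entry_age <- runif(n, model$entry_age[1], model$entry_age[2])
  subjects$subject_id <- seq_len(n)
  front <- c("subject_id", intersect("sex", names(subjects)), "entry_age")
  subjects <- subjects[, c(front, setdiff(names(subjects), front))]
  events <- purrr::imap(model$outcomes, function(oc, code) {
    u <- runif(n)
    eta <- eta_from_lhr(oc$log_hr, subjects)
    t_ev <- sample_event_time(oc$baseline_hazard, eta, u)
    keep <- t_ev <= model$censor_age
    tibble(subject_id = subjects$subject_id[keep], code = code,
           chapter = oc$chapter, diagnosis_age = t_ev[keep])
  })
  events <- bind_rows(events) %>% arrange(.data$subject_id, .data$diagnosis_age)
  list(subjects = as_tibble(subjects), events = events)
}
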