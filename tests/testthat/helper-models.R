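# Shared fixtures, built in code.

# Four-subject micro-populations used throughout: exposure relative risks
# (1, 2, 1, 2) against confounder relative risks (1, 1, 3, 3), either
# uncorrelated (case A) or positively correlated (case B).
micro_lp <- function(correlated = FALSE) {
  eta_x <- if (correlated) c(0, 0, log(2), log(2)) else c(0, log(2), 0, log(2))
  tibble::tibble(eta_x = eta_x, eta_w = 0, eta_z = c(0, 0, log(3), log(3)))
}

# A confounded smoking cohort: low socio-economic tertile smokes more and
# (through the deprivation gradient) has higher hazard.
smoking_model <- function(current_lhr = log(2),
                          baseline_hazard = weibull_hazard(5, 150),
                          sexes = NULL) {
  generative_model(
    confounders = list(ses = c(T3 = 0.4, T2 = 0.35, T1 = 0.25)),
    exposures = list(smoking = function(z) {
      switch(z$ses,
             T3 = c(never = 0.50, previous = 0.25, current = 0.25),
             T2 = c(never = 0.65, previous = 0.20, current = 0.15),
             T1 = c(never = 0.80, previous = 0.12, current = 0.08))
    }),
    other_risks = list(alcohol = c(rarely = 0.3, sometimes = 0.4,
                                   regularly = 0.3)),
    log_hr = list(smoking = c(previous = log(1.3), current = current_lhr),
                  ses = c(T2 = log(1.2), T3 = log(1.5)),
                  alcohol = c(sometimes = log(1.1), regularly = log(1.2))),
    baseline_hazard = baseline_hazard,
    baselines = c(ses = "T1"),
    sexes = sexes
  )
}

# Small fully-discrete model (binary everything) for exhaustive-enumeration
# cross-checks.
binary_model <- function(x_lhr = log(2), z_lhr = log(1.6),
                         p_x_given_z = c(z0 = 0.2, z1 = 0.5),
                         baseline_hazard = weibull_hazard(5, 150)) {
  generative_model(
    confounders = list(z = c(z0 = 0.6, z1 = 0.4)),
    exposures = list(x = function(zrow) {
      p <- p_x_given_z[[zrow$z]]
      c(x0 = 1 - p, x1 = p)
    }),
    log_hr = list(x = c(x1 = x_lhr), z = c(z1 = z_lhr)),
    baseline_hazard = baseline_hazard
  )
}

# Per-subject true linear predictors for a simulated cohort, from the
# generating model's own log hazard ratios (no fitting involved).
true_lp <- function(model, cohort) {
  part <- function(covs) {
    if (length(covs) == 0) return(rep(0, nrow(cohort)))
    rowSums(vapply(covs, function(cv) {
      unname(model$log_hr[[cv]][as.character(cohort[[cv]])])
    }, numeric(nrow(cohort))))
  }
  tibble::tibble(eta_x = part(names(model$exposures)),
                 eta_w = part(names(model$other_risks)),
                 eta_z = part(names(model$confounders)))
}

# Delta-method standard error of the sample backdoor fraction
# 1 - mean(b)/mean(a) with a = exp(eta_x+eta_w+eta_z), b = exp(eta_w+eta_z).
af_backdoor_se <- function(lp) {
  a <- exp(lp$eta_x + lp$eta_w + lp$eta_z)
  b <- exp(lp$eta_w + lp$eta_z)
  n <- length(a)
  ma <- mean(a); mb <- mean(b)
  v <- stats::var(b) / ma^2 - 2 * stats::cov(a, b) * mb / ma^3 +
    stats::var(a) * mb^2 / ma^4
  sqrt(max(v, 0) / n)
}

# A 20-disease synthetic landscape: smoking and BMI tertile confounded by a
# deprivation tertile; a spread of true joint effects including nulls and one
# protective association, across five chapters.
landscape_effects <- function() {
  codes <- sprintf("D%02d", 1:20)
  chapters <- rep(c("I", "II", "VI", "X", "XII"), each = 4)
  smoking_lhr <- c(1.1, 0.9, 0.7, 0.0,
                   0.6, 0.5, 0.0, 0.0,
                   0.45, 0.4, 0.0, 0.0,
                   0.35, 0.0, 0.0, 0.0,
                   0.3, -0.5, 0.0, 0.0)
  bmi_lhr <- c(0.5, 0.4, 0.0, 0.6,
               0.35, 0.0, 0.45, 0.0,
               0.0, 0.3, 0.35, 0.0,
               0.3, 0.0, 0.0, 0.0,
               0.0, -0.3, 0.3, 0.0)
  tibble::tibble(code = codes, chapter = chapters,
                 smoking_lhr = smoking_lhr, bmi_lhr = bmi_lhr)
}

# outcomes whose joint smoking/BMI effect is truly nonzero
landscape_affected <- function() {
  eff <- landscape_effects()
  eff$code[eff$smoking_lhr != 0 | eff$bmi_lhr != 0]
}

landscape_model <- function(scale = 175, sexes = NULL) {
  eff <- landscape_effects()
  outcomes <- lapply(seq_len(nrow(eff)), function(i) {
    list(chapter = eff$chapter[i],
         baseline_hazard = weibull_hazard(5, scale),
         log_hr = list(
           smoking = c(previous = eff$smoking_lhr[i] / 2,
                       current = eff$smoking_lhr[i]),
           bmi = c(T1 = 0, T3 = eff$bmi_lhr[i]),
           ses = c(T2 = 0.15, T3 = 0.35)))
  })
  names(outcomes) <- eff$code
  generative_model(
    confounders = list(ses = c(T1 = 1 / 3, T2 = 1 / 3, T3 = 1 / 3)),
    exposures = list(
      smoking = function(z) switch(z$ses,
        T1 = c(never = 0.75, previous = 0.15, current = 0.10),
        T2 = c(never = 0.62, previous = 0.22, current = 0.16),
        T3 = c(never = 0.50, previous = 0.25, current = 0.25)),
      bmi = function(z) switch(z$ses,
        T1 = c(T2 = 0.40, T1 = 0.35, T3 = 0.25),
        T2 = c(T2 = 0.36, T1 = 0.30, T3 = 0.34),
        T3 = c(T2 = 0.32, T1 = 0.25, T3 = 0.43))),
    log_hr = list(),
    baselines = c(smoking = "never", bmi = "T2", ses = "T1"),
    sexes = sexes,
    outcomes = outcomes
  )
}

# True age-independent joint attribution fraction for one landscape outcome,
# by exhaustive enumeration on a single-outcome copy of the model.
landscape_true_af <- function(model, code) {
  oc <- model$outcomes[[code]]
  single <- generative_model(
    confounders = model$confounders,
    exposures = model$exposures,
    log_hr = oc$log_hr,
    baseline_hazard = oc$baseline_hazard,
    baselines = model$baseline[c("smoking", "bmi", "ses")]
  )
  af_exact(single)
}

landscape_roles <- function() {
  covariate_roles(
    exposures = list(smoking = c("never", "previous", "current"),
                     bmi = c("T1", "T2", "T3")),
    confounders = list(ses = c("T1", "T2", "T3")),
    baselines = c(smoking = "never", bmi = "T2", ses = "T1")
  )
}
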