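#' Configuration for a multi-disease attribution survey
#'
#' Bundles the analysis rules of the landscape survey: the minimum case count
#' for a disease to be analysed (140 cases keeps at least 10 cases per
#' adjusted parameter, with headroom for a two-parameter parametric baseline),
#' the FDR level of the Benjamini-Hochberg selection, the administrative study
#' end age, the named exposure contrasts whose Wald tests drive inclusion, and
#' the exclusion/censoring code sets.
#'
#' @param min_cases Minimum cases per disease and sex stratum (default 140).
#' @param fdr_level FDR level for the Benjamini-Hochberg selection.
#' @param study_end_age Administrative censoring age in years.
#' @param tests Named list of contrasts tested per disease; each element is
#'   `c(covariate = , level = )`, the non-baseline level whose Wald test
#'   against baseline drives inclusion (defaults: current-vs-never smoking and
#'   top-vs-middle BMI tertile).
#' @param exclude_prior Character vector of regular expressions; subjects with
#'   any pre-entry diagnosis whose code matches (and does not match
#'   `exclude_prior_exception`) are excluded from every analysis — e.g. prior
#'   cancer other than non-melanoma skin cancer.
#' @param exclude_prior_exception Regular expressions exempting codes from
#'   `exclude_prior` (e.g. `"^C44"`).
#' @param censor_codes Regular expressions; the first post-entry diagnosis
#'   matching (and not matching `censor_exception`) right-censors follow-up at
#'   its age.
#' @param censor_exception Regular expressions exempting codes from
#'   `censor_codes`.
#' @return Object of class `survey_config`.
#' @export
survey_config <- function(min_cases = 140, fdr_level = 0.05,
                          study_end_age = 80,
                          tests = list(
                            smoking = c(covariate = "smoking",
                                        level = "current"),
                            bmi = c(covariate = "bmi", level = "T3")
                          ),
                          exclude_prior = character(),
                          exclude_prior_exception = character(),
                          censor_codes = exclude_prior,
                          censor_exception = exclude_prior_exception) {
  if (min_cases < 1) abort("min_cases must be at least 1")
  if (fdr_level <= 0 || fdr_level >= 1) abort("fdr_level must lie in (0, 1)")
  if (length(tests) == 0 || is.null(names(tests))) {
    abort("tests must be a named list of c(covariate=, level=) contrasts")
  }
  structure(list(min_cases = min_cases, fdr_level = fdr_level,
                 study_end_age = study_end_age, tests = tests,
                 exclude_prior = exclude_prior,
                 exclude_prior_exception = exclude_prior_exception,
                 censor_codes = censor_codes,
                 censor_exception = censor_exception),
            class = "survey_config")
}

matches_any <- function(codes, patterns, exceptions = character()) {
  if (length(patterns) == 0) return(rep(FALSE, length(codes)))
  hit <- Reduce(`|`, lapply(patterns, function(p) grepl(p, codes)))
  if (length(exceptions) > 0) {
    exc <- Reduce(`|`, lapply(exceptions, function(p) grepl(p, codes)))
    hit <- hit & !exc
  }
  hit
}

#' Derive the first-incidence survival outcome for one disease code
#'
#' Implements the survey's outcome definition for a single code: only the
#' first diagnosis in the code's chapter counts for each subject (minimising
#' confounding by prior disease within the chapter); subjects whose first
#' chapter diagnosis precedes study entry are excluded, as are subjects with
#' any pre-entry diagnosis in the configured exclusion set. Follow-up is
#' right-censored at death (if a `death_age` column is present), at the first
#' post-entry diagnosis in the configured censoring set, or at the study end
#' age — whichever comes first, with censoring taking precedence over a
#' same-age event. A first-in-chapter diagnosis of a *different* code censors
#' at its age.
#'
#' @param subjects Tibble with `subject_id`, `entry_age`, optional `death_age`.
#' @param events Long tibble with `subject_id`, `code`, `diagnosis_age` and
#'   (unless `chapter_map` covers all codes) `chapter`.
#' @param code The target disease code.
#' @param config A [survey_config()].
#' @param chapter_map Optional tibble `code`, `chapter`; used to resolve the
#'   target chapter and any event codes lacking a chapter label.
#' @return Tibble with `subject_id`, `entry_age`, `exit_age`, `event` for the
#'   retained subjects.
#' @export
derive_first_incidence <- function(subjects, events, code, config,
                                   chapter_map = NULL) {
  stopifnot(inherits(config, "survey_config"))
  if (!is.null(chapter_map) && !"chapter" %in% names(events)) {
    events <- left_join(events, chapter_map, by = "code")
  }
  if (!"chapter" %in% names(events)) {
    abort("events need a 'chapter' column or a chapter_map")
  }
  target_chapter <- if (!is.null(chapter_map) && code %in% chapter_map$code) {
    chapter_map$chapter[match(code, chapter_map$code)]
  } else {
    unique(events$chapter[events$code == code])
  }
  if (length(target_chapter) != 1 || is.na(target_chapter)) {
    abort(paste0("cannot resolve a unique chapter for code '", code, "'"))
  }
  ev <- semi_join(events, subjects, by = "subject_id")

  entry <- setNames(subjects$entry_age, subjects$subject_id)
  pre_entry <- ev$diagnosis_age < entry[as.character(ev$subject_id)]

  # global pre-entry exclusions (e.g. prior cancer other than C44)
  excl_ids <- unique(ev$subject_id[
    pre_entry & matches_any(ev$code, config$exclude_prior,
                            config$exclude_prior_exception)])

  # first diagnosis in the target chapter per subject (ties: smallest code)
  first <- ev %>%
    filter(.data$chapter == target_chapter) %>%
    arrange(.data$subject_id, .data$diagnosis_age, .data$code) %>%
    distinct(.data$subject_id, .keep_all = TRUE)
  prevalent_ids <- first$subject_id[
    first$diagnosis_age < entry[as.character(first$subject_id)]]

  out <- subjects %>%
    filter(!.data$subject_id %in% c(excl_ids, prevalent_ids)) %>%
    left_join(first %>% select("subject_id", first_code = "code",
                               first_age = "diagnosis_age"),
              by = "subject_id")

  # first post-entry censoring diagnosis (death-like competing causes)
  cens <- ev %>%
    filter(!pre_entry,
           matches_any(.data$code, config$censor_codes,
                       config$censor_exception),
           .data$chapter != target_chapter) %>%
    arrange(.data$subject_id, .data$diagnosis_age) %>%
    distinct(.data$subject_id, .keep_all = TRUE) %>%
    select("subject_id", censor_dx_age = "diagnosis_age")
  out <- left_join(out, cens, by = "subject_id")

  death <- if ("death_age" %in% names(out)) out$death_age else NA_real_
  cap <- pmin(ifelse(is.na(death), Inf, death),
              ifelse(is.na(out$censor_dx_age), Inf, out$censor_dx_age),
              config$study_end_age)
  is_event <- !is.na(out$first_age) & out$first_code == code &
    out$first_age < cap
  exit <- ifelse(is_event, out$first_age,
                 pmin(cap, ifelse(is.na(out$first_age), Inf, out$first_age)))
  res <- tibble(subject_id = out$subject_id, entry_age = out$entry_age,
                exit_age = exit, event = as.integer(is_event))
  res[res$exit_age > res$entry_age, , drop = FALSE]
}

#' Keep diseases with enough cases to fit the adjusted model
#'
#' @param records Tibble with a case-count column `n_cases`.
#' @param threshold Minimum case count (>= 1); records with
#'   `n_cases >= threshold` are kept.
#' @return The retained records.
#' @export
min_case_filter <- function(records, threshold = 140) {
  if (threshold < 1) abort("threshold must be at least 1")
  filter(records, .data$n_cases >= threshold)
}

#' Benjamini-Hochberg selection across many disease tests
#'
#' Step-up FDR control at the given level; q-values are the standard monotone
#' BH adjusted p-values (via [stats::p.adjust()]), and a test is selected when
#' its q-value does not exceed the level. `NA` p-values yield `NA` q-values
#' and are never selected.
#'
#' @param p Numeric p-values in `[0, 1]` (may contain `NA`).
#' @param level FDR level in (0, 1).
#' @return Tibble with columns `p`, `q`, `selected`.
#' @export
fdr_select <- function(p, level = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  q <- p.adjust(p, method = "BH")
  tibble(p = p, q = q, selected = !is.na(q) & q <= level)
}

#' Combine single-exposure inclusion masks for the joint analysis
#'
#' A disease enters the joint smoking-and-BMI analysis when it is selected in
#' either single-exposure analysis (elementwise OR).
#'
#' @param smoking_mask,bmi_mask Logical vectors of equal length.
#' @return Logical vector.
#' @export
joint_inclusion <- function(smoking_mask, bmi_mask) {
  if (length(smoking_mask) != length(bmi_mask)) {
    abort("masks must have equal length")
  }
  smoking_mask | bmi_mask
}

af_tier_levels <- c("af>=0.5", "0.35<=af<0.5", "0.2<=af<0.35",
                    "-0.2<af<0.2", "af<=-0.2")

#' Rank surveyed diseases and assign attribution tiers
#'
#' Adds: `rank_af` (descending attribution fraction), `rank_n_attributed`
#' (descending absolute attributed cases), and `tier`, the banding used to
#' colour the survey tables — pathogenic-scale `A_f >= 0.5`, then
#' `[0.35, 0.5)`, `[0.2, 0.35)`, the uninformative band `(-0.2, 0.2)`, and the
#' strongly protective band `A_f <= -0.2`. Ties break deterministically by
#' code string.
#'
#' @param records Tibble with columns `af`, `n_attributed`, `code`.
#' @return `records` with `tier`, `rank_af`, `rank_n_attributed` added, sorted
#'   by `rank_af`.
#' @export
rank_and_tier <- function(records) {
  records %>%
    mutate(
      tier = factor(dplyr::case_when(
        .data$af >= 0.5 ~ "af>=0.5",
        .data$af >= 0.35 ~ "0.35<=af<0.5",
        .data$af >= 0.2 ~ "0.2<=af<0.35",
        .data$af > -0.2 ~ "-0.2<af<0.2",
        TRUE ~ "af<=-0.2"
      ), levels = af_tier_levels),
      rank_af = rank_desc(.data$af, .data$code),
      rank_n_attributed = rank_desc(abs(.data$n_attributed), .data$code)
    ) %>%
    arrange(.data$rank_af)
}

rank_desc <- function(x, tie) {
  ord <- order(-x, tie)
  out <- integer(length(x))
  out[ord] <- seq_along(x)
  out
}

#' Summarise attribution fractions by disease chapter
#'
#' Chapters are retained only when at least `min_above` member diseases have
#' `af > above`; the reported median is taken over all the chapter's surveyed
#' diseases, with the member count exposed for bar-width scaling.
#'
#' @param records Tibble with columns `chapter`, `af`.
#' @param min_above Minimum number of member diseases above the threshold
#'   (default 5).
#' @param above Attribution-fraction threshold (default 0.2).
#' @return Tibble with `chapter`, `median_af`, `n_diseases`, `n_above`, sorted
#'   by descending median.
#' @export
chapter_summary <- function(records, min_above = 5, above = 0.2) {
  records %>%
    group_by(.data$chapter) %>%
    summarise(median_af = median(.data$af), n_diseases = n(),
              n_above = sum(.data$af > above), .groups = "drop") %>%
    filter(.data$n_above >= min_above) %>%
    arrange(dplyr::desc(.data$median_af))
}

remap_roles <- function(map, roles) {
  map$role <- roles$roles$role[match(map$covariate, roles$roles$covariate)]
  map
}

#' Run the multi-disease attribution survey
#'
#' End-to-end emulation of the study design: for every disease code (and each
#' sex separately, when a `sex` column is present), derive the first-incidence
#' outcome with exclusions and censoring, drop diseases below the minimum case
#' count, fit one multiply-adjusted left-truncated Cox model, and compute the
#' attribution fraction for each single-exposure contrast and for the joint
#' contrast (all tested exposures in `X` simultaneously, everything else in
#' `W`). Inclusion is decided by Benjamini-Hochberg FDR on the named Wald
#' contrasts, pooled across codes and sexes; a disease enters the joint
#' results when selected for either exposure. Included records are ranked,
#' tiered and summarised by chapter. Deterministic given its inputs.
#'
#' @param subjects Subject tibble: `subject_id`, optional `sex`, `entry_age`,
#'   optional `death_age`, covariate columns.
#' @param events Long diagnosis tibble: `subject_id`, `code`, `chapter`,
#'   `diagnosis_age`.
#' @param roles A [covariate_roles()] whose exposures are the jointly tested
#'   covariates (e.g. smoking and BMI) and whose `W`/`Z` sets hold the other
#'   adjustments.
#' @param config A [survey_config()].
#' @param chapter_map Optional tibble `code`, `chapter`; defaults to the
#'   distinct pairs in `events`.
#' @param codes Codes to analyse (default: all codes in `chapter_map`).
#' @return Object of class `disease_survey`: list with `records` (one row per
#'   code and sex), `included` (ranked/tiered subset), `chapters`, `config`.
#' @export
run_survey <- function(subjects, events, roles, config = survey_config(),
                       chapter_map = NULL, codes = NULL) {
  stopifnot(inherits(config, "survey_config"))
  if (is.null(chapter_map)) {
    chapter_map <- distinct(events, .data$code, .data$chapter)
  }
  if (is.null(codes)) codes <- sort(unique(chapter_map$code))
  sexes <- if ("sex" %in% names(subjects)) {
    sort(unique(subjects$sex))
  } else {
    "all"
  }
  test_names <- names(config$tests)
  joint_covs <- unname(vapply(config$tests, `[[`, character(1), "covariate"))
  roles_joint <- set_exposures(roles, joint_covs)

  rows <- list()
  for (code in codes) {
    for (sx in sexes) {
      sub <- if (identical(sx, "all")) subjects else
        filter(subjects, .data$sex == sx)
      oc <- withCallingHandlers(
        derive_first_incidence(sub, events, code, config, chapter_map),
        error = function(e) {
          abort(paste0("code ", code, " (", sx, "): ", conditionMessage(e)))
        })
      row <- tibble(code = code,
                    chapter = chapter_map$chapter[
                      match(code, chapter_map$code)],
                    sex = sx, n = nrow(oc), n_cases = sum(oc$event))
      if (row$n_cases >= config$min_cases) {
        cohort <- left_join(oc, sub, by = c("subject_id", "entry_age"))
        fit <- withCallingHandlers(
          fit_ph(cohort, roles_joint),
          error = function(e) {
            abort(paste0("code ", code, " (", sx, "): ",
                         conditionMessage(e)))
          })
        row$fitted <- fit$converged
        if (fit$converged) {
          est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
          for (nm in test_names) {
            tst <- config$tests[[nm]]
            lp_k <- decompose_linear_predictor(
              fit$design, est,
              remap_roles(fit$map, set_exposures(roles, tst[["covariate"]])))
            row[[paste0("af_", nm)]] <-
              af_backdoor(lp_k, n_cases = row$n_cases)$estimate
            hit <- fit$coefficients$covariate == tst[["covariate"]] &
              fit$coefficients$level == tst[["level"]]
            row[[paste0("p_", nm)]] <-
              if (any(hit)) fit$coefficients$p_value[hit] else NA_real_
          }
          lp_joint <- decompose_linear_predictor(
            fit$design, est, remap_roles(fit$map, roles_joint))
          joint <- af_backdoor(lp_joint, n_cases = row$n_cases)
          row$af <- joint$estimate
          row$n_attributed <- joint$n_attributed
        }
      } else {
        row$fitted <- FALSE
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  records <- bind_rows(rows)
  for (nm in test_names) {
    pcol <- paste0("p_", nm)
    if (!pcol %in% names(records)) records[[pcol]] <- NA_real_
    sel <- fdr_select(records[[pcol]], config$fdr_level)
    records[[paste0("q_", nm)]] <- sel$q
    records[[paste0("selected_", nm)]] <- sel$selected
  }
  masks <- lapply(test_names,
                  function(nm) records[[paste0("selected_", nm)]])
  records$included <- Reduce(joint_inclusion, masks)
  included <- records %>%
    filter(.data$included, .data$fitted) %>%
    rank_and_tier()
  chapters <- chapter_summary(included)
  structure(list(records = records, included = included, chapters = chapters,
                 config = config),
            class = "disease_survey")
}

#' @export
print.disease_survey <- function(x, ...) {
  cat("<disease_survey>", nrow(x$records), "code-sex records;",
      nrow(x$included), "included after FDR selection\n")
  if (nrow(x$included) > 0) {
    print(count(x$included, .data$tier, .drop = FALSE))
  }
  invisible(x)
}

#' @rdname run_survey
#' @param x A `disease_survey`.
#' @param ... Unused.
#' @export
#' @method tidy disease_survey
tidy.disease_survey <- function(x, ...) x$records

#' @rdname run_survey
#' @export
#' @method glance disease_survey
glance.disease_survey <- function(x, ...) {
  tibble(n_records = nrow(x$records),
         n_fitted = sum(x$records$fitted),
         n_included = nrow(x$included),
         n_top_tier = sum(x$included$tier == "af>=0.5"),
         mean_af = mean(x$included$af),
         median_af = median(x$included$af))
}

#' Re-run the survey under stricter exclusions and summarise the differences
#'
#' Runs [run_survey()] under the main and the sensitivity configurations
#' (typically broader pre-entry disease exclusions), pairs the per-disease
#' joint attribution fractions, and reports their differences with mean,
#' median and standard deviation.
#'
#' @inheritParams run_survey
#' @param config_main,config_sensitivity The two [survey_config()]s.
#' @return List with `main`, `sensitivity` (both `disease_survey`), `paired`
#'   (per code-sex differences `af_sensitivity - af_main`) and `summary`
#'   (tibble: `mean_diff`, `median_diff`, `sd_diff`, `n`).
#' @export
sensitivity_rerun <- function(subjects, events, roles, config_main,
                              config_sensitivity, chapter_map = NULL,
                              codes = NULL) {
  main <- run_survey(subjects, events, roles, config_main, chapter_map, codes)
  sens <- run_survey(subjects, events, roles, config_sensitivity, chapter_map,
                     codes)
  a <- main$records %>%
    filter(.data$fitted) %>%
    select("code", "sex", af_main = "af")
  b <- sens$records %>%
    filter(.data$fitted) %>%
    select("code", "sex", af_sensitivity = "af")
  paired <- dplyr::inner_join(a, b, by = c("code", "sex")) %>%
    mutate(diff = .data$af_sensitivity - .data$af_main)
  summary <- tibble(mean_diff = mean(paired$diff),
                    median_diff = median(paired$diff),
                    sd_diff = sd(paired$diff), n = nrow(paired))
  list(main = main, sensitivity = sens, paired = paired, summary = summary)
}

#' Write survey outputs to a directory
#'
#' Writes `records.csv` (one row per code and sex), `chapters.csv` and a
#' plain-text `tiers.txt` mirroring the ranked tier tables.
#'
#' @param survey A `disease_survey`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_survey <- function(survey, dir) {
  stopifnot(inherits(survey, "disease_survey"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(survey$records, file.path(dir, "records.csv"))
  readr::write_csv(survey$chapters, file.path(dir, "chapters.csv"))
  writeLines(tier_report(survey), file.path(dir, "tiers.txt"))
  invisible(dir)
}

#' @rdname write_survey
#' @description `tier_report()` renders the included records as fixed-width
#'   text grouped by tier.
#' @export
tier_report <- function(survey) {
  inc <- survey$included
  lines <- character()
  for (tr in levels(inc$tier)) {
    rows <- inc[inc$tier == tr, , drop = FALSE]
    if (nrow(rows) == 0) next
    lines <- c(lines, paste0("== tier ", tr, " =="))
    lines <- c(lines, sprintf(
      "%-10s %-4s N=%-6d N_Af=%-6d A_f=%+.3f rank=%d",
      rows$code, rows$sex, rows$n_cases, rows$n_attributed, rows$af,
      rows$rank_af))
  }
  if (length(lines) == 0) lines <- "(no diseases included)"
  lines
}
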