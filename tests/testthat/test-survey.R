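cfg0 <- survey_config(min_cases = 1, study_end_age = 80)

test_that("first-incidence outcomes use the earliest in-chapter diagnosis", {
  subjects <- tibble::tibble(subject_id = 1:5, entry_age = c(50, 50, 50, 50, 50))
  events <- tibble::tibble(
    subject_id = c(1, 1, 2, 3, 4, 5),
    code = c("J44", "J44", "J44", "J18", "J44", "J44"),
    chapter = "X",
    diagnosis_age = c(55, 60, 45, 52, 70, 85))
  oc <- derive_first_incidence(subjects, events, "J44", cfg0)
  # subject 1: earliest of 55/60
  expect_equal(oc$exit_age[oc$subject_id == 1], 55)
  expect_equal(oc$event[oc$subject_id == 1], 1L)
  # subject 2: chapter onset before entry -> excluded entirely
  expect_false(2 %in% oc$subject_id)
  # subject 3: first in chapter is a different code -> censored at its age
  expect_equal(oc$exit_age[oc$subject_id == 3], 52)
  expect_equal(oc$event[oc$subject_id == 3], 0L)
  # subject 5: diagnosis after study end -> censored at 80
  expect_equal(oc$exit_age[oc$subject_id == 5], 80)
  expect_equal(oc$event[oc$subject_id == 5], 0L)
})

test_that("prior-diagnosis exclusions and censoring causes are applied", {
  cfg <- survey_config(min_cases = 1, study_end_age = 80,
                       exclude_prior = "^C",
                       exclude_prior_exception = "^C44")
  subjects <- tibble::tibble(subject_id = 1:4, entry_age = 50,
                             death_age = c(NA, NA, 60, NA))
  events <- tibble::tibble(
    subject_id = c(1, 1, 2, 2, 3, 4, 4),
    code = c("C34", "J44", "C44", "J44", "J44", "C34", "J44"),
    chapter = c("II", "X", "II", "X", "X", "II", "X"),
    diagnosis_age = c(45, 60, 45, 60, 65, 55, 65))
  oc <- derive_first_incidence(subjects, events, "J44", cfg)
  # prior cancer (not non-melanoma skin) excludes subject 1
  expect_false(1 %in% oc$subject_id)
  # C44 exception keeps subject 2
  expect_equal(oc$event[oc$subject_id == 2], 1L)
  # death before the in-chapter diagnosis censors subject 3 at death
  expect_equal(oc$exit_age[oc$subject_id == 3], 60)
  expect_equal(oc$event[oc$subject_id == 3], 0L)
  # post-entry cancer censors subject 4 before its chapter-X diagnosis
  expect_equal(oc$exit_age[oc$subject_id == 4], 55)
  expect_equal(oc$event[oc$subject_id == 4], 0L)
  expect_error(derive_first_incidence(subjects, events, "Z99", cfg0),
               "chapter")
})

test_that("the minimum-case rule keeps 140 and drops 139", {
  records <- tibble::tibble(code = c("a", "b", "c"),
                            n_cases = c(139L, 140L, 5L))
  expect_equal(min_case_filter(records, 140)$code, "b")
  expect_equal(nrow(min_case_filter(records, 1)), 3)
  expect_error(min_case_filter(records, 0), "at least 1")
})

test_that("BH selection matches the hand-executed step-up rule", {
  sel <- fdr_select(c(0.001, 0.01, 0.02, 0.04, 0.2), level = 0.05)
  expect_equal(sel$selected, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(sel$q, c(0.005, 0.025, 1 / 30, 0.05, 0.2), tolerance = 1e-12)
  expect_true(all(sel$q >= sel$p))
  expect_false(any(fdr_select(rep(1, 6))$selected))
  # a single test reduces to p <= level
  expect_true(fdr_select(0.04)$selected)
  expect_false(fdr_select(0.06)$selected)
  expect_error(fdr_select(c(0.5, 1.2)), "\\[0, 1\\]")
  # selection is monotone in the level
  p <- c(0.004, 0.011, 0.02, 0.3, 0.6)
  loose <- fdr_select(p, 0.05)$selected
  tight <- fdr_select(p, 0.01)$selected
  expect_true(all(!tight | loose))
})

test_that("joint inclusion is the elementwise union", {
  expect_equal(joint_inclusion(c(TRUE, FALSE), c(FALSE, FALSE)),
               c(TRUE, FALSE))
  expect_equal(joint_inclusion(logical(0), logical(0)), logical(0))
  expect_error(joint_inclusion(c(TRUE), c(TRUE, FALSE)), "equal length")
  # sizes compose like the survey counts: two overlapping selections
  set.seed(8)
  a <- sample(c(TRUE, FALSE), 300, TRUE, prob = c(0.43, 0.57))
  b <- sample(c(TRUE, FALSE), 300, TRUE, prob = c(0.51, 0.49))
  expect_equal(sum(joint_inclusion(a, b)), sum(a | b))
})

test_that("tiers and ranks are assigned deterministically", {
  records <- tibble::tibble(
    code = c("E66", "J44", "R04", "K25", "D03", "N81", "M13"),
    chapter = "X",
    af = c(0.55, 0.5, 0.35, 0.2, -0.29, -0.19, 0.35),
    n_attributed = c(306L, 230L, 162L, 70L, -79L, -819L, 70L))
  rt <- rank_and_tier(records)
  expect_equal(as.character(rt$tier[rt$code == "E66"]), "af>=0.5")
  expect_equal(as.character(rt$tier[rt$code == "J44"]), "af>=0.5")
  expect_equal(as.character(rt$tier[rt$code == "K25"]), "0.2<=af<0.35")
  expect_equal(as.character(rt$tier[rt$code == "D03"]), "af<=-0.2")
  expect_equal(as.character(rt$tier[rt$code == "N81"]), "-0.2<af<0.2")
  # every record falls in exactly one tier
  expect_false(any(is.na(rt$tier)))
  # ties in af break by code string
  expect_lt(rt$rank_af[rt$code == "M13"], rt$rank_af[rt$code == "R04"])
  # |N_Af| ranking puts the large protective count first
  expect_equal(rt$code[rt$rank_n_attributed == 1], "N81")
})

test_that("chapter summaries apply the five-disease threshold rule", {
  records <- tibble::tibble(
    chapter = c(rep("X", 6), rep("II", 4), rep("VI", 3)),
    af = c(0.3, 0.25, 0.5, 0.22, 0.21, 0.1,
           0.3, 0.3, 0.3, 0.3,
           0.1, 0.05, 0.02))
  cs <- chapter_summary(records)
  # II has only 4 diseases above 0.2, VI none: both excluded
  expect_equal(cs$chapter, "X")
  expect_equal(cs$median_af, median(c(0.3, 0.25, 0.5, 0.22, 0.21, 0.1)))
  expect_equal(cs$n_diseases, 6L)
  expect_equal(nrow(chapter_summary(dplyr::mutate(records, af = 0))), 0L)
  expect_equal(chapter_summary(tibble::tibble(chapter = "X",
                                              af = c(0.3, 0.2, 0.5)),
                               min_above = 1)$median_af, 0.3)
})

# a compact landscape for end-to-end checks: first outcome truly affected by
# smoking, the rest null
mini_model <- function(sexes = NULL) {
  gm <- landscape_model(sexes = sexes)
  gm$outcomes <- gm$outcomes[c("D01", "D04", "D07", "D16", "D20")]
  for (cd in c("D04", "D07", "D16", "D20")) {
    gm$outcomes[[cd]]$log_hr$smoking[] <- 0
    gm$outcomes[[cd]]$log_hr$bmi[] <- 0
  }
  gm
}

test_that("the survey selects the truly affected outcome and is deterministic", {
  gm <- mini_model()
  sim <- simulate_landscape(gm, 25000, seed = 71)
  cfg <- survey_config(min_cases = 100)
  s1 <- run_survey(sim$subjects, sim$events, landscape_roles(), cfg)
  s2 <- run_survey(sim$subjects, sim$events, landscape_roles(), cfg)
  expect_identical(s1$records, s2$records)
  rec <- s1$records
  expect_true(rec$included[rec$code == "D01"])
  expect_gt(rec$af[rec$code == "D01"], 0.15)
  # q-values never fall below p-values
  expect_true(all(rec$q_smoking >= rec$p_smoking - 1e-15, na.rm = TRUE))
  expect_s3_class(glance(s1), "tbl_df")
  expect_s3_class(autoplot(s1), "ggplot")
  expect_s3_class(plot_af_ranking(s1), "ggplot")
})

test_that("sex-specific cohorts are fitted separately", {
  gm <- mini_model(sexes = c(F = 0.5, M = 0.5))
  sim <- simulate_landscape(gm, 20000, seed = 73)
  s <- run_survey(sim$subjects, sim$events, landscape_roles(),
                  survey_config(min_cases = 50))
  expect_setequal(unique(s$records$sex), c("F", "M"))
  expect_equal(nrow(s$records), 2 * length(gm$outcomes))
  # per-sex estimates come from disjoint subjects, so they differ
  afs <- dplyr::filter(s$records, code == "D01")
  expect_false(isTRUE(all.equal(afs$af[1], afs$af[2])))
})

test_that("survey outputs round-trip to disk", {
  gm <- mini_model()
  sim <- simulate_landscape(gm, 15000, seed = 79)
  s <- run_survey(sim$subjects, sim$events, landscape_roles(),
                  survey_config(min_cases = 50))
  dir <- withr::local_tempdir()
  write_survey(s, dir)
  expect_true(file.exists(file.path(dir, "records.csv")))
  back <- readr::read_csv(file.path(dir, "records.csv"),
                          show_col_types = FALSE)
  expect_equal(nrow(back), nrow(s$records))
  expect_true(any(grepl("tier", readLines(file.path(dir, "tiers.txt")))))
})

test_that("identical sensitivity configs produce zero differences", {
  gm <- mini_model()
  sim <- simulate_landscape(gm, 15000, seed = 83)
  cfg <- survey_config(min_cases = 50)
  out <- sensitivity_rerun(sim$subjects, sim$events, landscape_roles(),
                           cfg, cfg)
  expect_true(all(out$paired$diff == 0))
  expect_equal(out$summary$mean_diff, 0)
  expect_equal(out$summary$sd_diff, 0)
  expect_setequal(names(out$summary),
                  c("mean_diff", "median_diff", "sd_diff", "n"))
})

test_that("stricter exclusions shift estimates in a reverse-causation scenario", {
  gm <- mini_model()
  sim <- simulate_landscape(gm, 20000, seed = 89)
  # construct reverse causation: a pre-entry cardiovascular diagnosis given
  # preferentially to never-smokers who go on to have the target event, which
  # biases the smoking contrast until those subjects are excluded
  cases <- sim$events$subject_id[sim$events$code == "D01"]
  sm <- sim$subjects$smoking[match(cases, sim$subjects$subject_id)]
  tagged <- cases[sm == "never"]
  tagged <- tagged[seq_len(floor(length(tagged) * 0.5))]
  prior <- tibble::tibble(
    subject_id = tagged, code = "I21", chapter = "IX",
    diagnosis_age = sim$subjects$entry_age[
      match(tagged, sim$subjects$subject_id)] - 1)
  events2 <- dplyr::bind_rows(sim$events, prior)
  cfg_main <- survey_config(min_cases = 50)
  cfg_sens <- survey_config(min_cases = 50, exclude_prior = "^I21",
                            censor_codes = character())
  out <- sensitivity_rerun(sim$subjects, events2, landscape_roles(),
                           cfg_main, cfg_sens, codes = c("D01", "D04"))
  d01 <- out$paired$diff[out$paired$code == "D01"]
  # removing never-smoker cases raises the smoking-attributable fraction
  expect_gt(abs(d01), 0.02)
  expect_equal(nrow(out$summary), 1)
})
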