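#' Declare covariate roles for a causal proportional-hazards analysis
#'
#' Splits the modelled covariates into three disjoint roles: the exposures of
#' interest `X` (e.g. smoking, BMI tertile), other modelled risk factors `W`
#' (e.g. alcohol, height tertile), and confounders `Z` that satisfy the backdoor
#' criterion (e.g. education, socio-economic status). Every covariate is
#' categorical with a declared, ordered level set and a declared baseline level;
#' the baseline need not be the first level (BMI conventionally uses the middle
#' tertile).
#'
#' @param exposures,other_risks,confounders Named lists mapping covariate name
#'   to its ordered character vector of levels. `other_risks` and `confounders`
#'   may be empty lists.
#' @param baselines Named character vector mapping covariate name to its
#'   baseline level. Covariates omitted here default to their first declared
#'   level.
#' @return An object of class `covariate_roles`: a list with elements `roles`
#'   (tibble with columns `covariate`, `role`), `levels` (named list) and
#'   `baseline` (named character vector).
#' @examples
#' roles <- covariate_roles(
#'   exposures = list(smoking = c("never", "previous", "current")),
#'   confounders = list(education = c("degree", "post16", "to16")),
#'   baselines = c(smoking = "never", education = "degree")
#' )
#' roles
#' @export
covariate_roles <- function(exposures, other_risks = list(),
                            confounders = list(), baselines = character()) {
  groups <- list(x = exposures, w = other_risks, z = confounders)
  for (g in names(groups)) {
    lv <- groups[[g]]
    if (length(lv) > 0 && (is.null(names(lv)) || any(names(lv) == ""))) {
      abort(paste0("all covariates in '", g, "' must be named"))
    }
  }
  covs <- unlist(lapply(groups, names), use.names = FALSE)
  if (length(covs) == 0) abort("at least one covariate must be declared")
  if (anyDuplicated(covs)) {
    abort(paste0("covariate roles must be disjoint; duplicated: ",
                 paste(unique(covs[duplicated(covs)]), collapse = ", ")))
  }
  levels <- c(exposures, other_risks, confounders)
  for (cv in names(levels)) {
    lv <- levels[[cv]]
    if (!is.character(lv) || length(lv) < 2 || anyDuplicated(lv)) {
      abort(paste0("covariate '", cv, "' needs >= 2 distinct character levels"))
    }
  }
  baseline <- vapply(names(levels), function(cv) {
    b <- if (cv %in% names(baselines)) baselines[[cv]] else levels[[cv]][1]
    if (!b %in% levels[[cv]]) {
      abort(paste0("baseline '", b, "' is not a declared level of '", cv, "'"))
    }
    b
  }, character(1))
  extra <- setdiff(names(baselines), names(levels))
  if (length(extra) > 0) {
    abort(paste0("baselines given for undeclared covariates: ",
                 paste(extra, collapse = ", ")))
  }
  roles <- tibble(
    covariate = covs,
    role = rep(c("x", "w", "z"),
               times = vapply(groups, length, integer(1)))
  )
  structure(list(roles = roles, levels = levels, baseline = baseline),
            class = "covariate_roles")
}

#' @export
print.covariate_roles <- function(x, ...) {
  cat("<covariate_roles>\n")
  for (r in c("x", "w", "z")) {
    covs <- x$roles$covariate[x$roles$role == r]
    lab <- c(x = "exposures (X)", w = "other risks (W)", z = "confounders (Z)")[r]
    cat(" ", lab, ":",
        if (length(covs) == 0) "(none)" else paste(covs, collapse = ", "), "\n")
  }
  for (cv in names(x$levels)) {
    cat("   ", cv, ": ", paste(x$levels[[cv]], collapse = "/"),
        " [baseline ", x$baseline[[cv]], "]\n", sep = "")
  }
  invisible(x)
}

#' Reassign which covariates play the exposure role
#'
#' Returns a copy of `roles` in which only `exposures` are treated as `X`; all
#' other former exposures are moved to the other-risk set `W`. Used by the
#' survey pipeline to compute smoking-only, BMI-only and joint contrasts from a
#' single fitted model.
#'
#' @param roles A [covariate_roles()] object.
#' @param exposures Character vector of covariate names to treat as exposures.
#' @return A `covariate_roles` object with the new partition.
#' @export
set_exposures <- function(roles, exposures) {
  stopifnot(inherits(roles, "covariate_roles"))
  missing <- setdiff(exposures, roles$roles$covariate)
  if (length(missing) > 0) {
    abort(paste0("not declared covariates: ", paste(missing, collapse = ", ")))
  }
  if (any(roles$roles$role[roles$roles$covariate %in% exposures] == "z")) {
    abort("confounders cannot be promoted to exposures")
  }
  new_roles <- roles
  new_roles$roles <- roles$roles %>%
    mutate(role = dplyr::case_when(
      .data$covariate %in% exposures ~ "x",
      .data$role == "z" ~ "z",
      TRUE ~ "w"
    )) %>%
    arrange(match(.data$role, c("x", "w", "z")))
  new_roles
}

#' Build the indicator design matrix for declared categorical covariates
#'
#' Produces one indicator column per non-baseline level of each declared
#' covariate, so a subject at baseline for every covariate maps to an all-zero
#' row. Columns are named `covariate.level` and annotated with their role.
#'
#' @param data Data frame holding one column per declared covariate (character
#'   or factor levels).
#' @param roles A [covariate_roles()] object.
#' @return A list with `design` (numeric matrix, n x p) and `map` (tibble with
#'   columns `column`, `covariate`, `level`, `role`).
#' @examples
#' roles <- covariate_roles(
#'   exposures = list(smoking = c("never", "previous", "current"))
#' )
#' build_design(data.frame(smoking = c("never", "current")), roles)$design
#' @export
build_design <- function(data, roles) {
  stopifnot(inherits(roles, "covariate_roles"))
  covs <- roles$roles$covariate
  missing <- setdiff(covs, names(data))
  if (length(missing) > 0) {
    abort(paste0("covariates missing from data: ",
                 paste(missing, collapse = ", ")))
  }
  cols <- list()
  map <- list()
  for (cv in covs) {
    obs <- as.character(data[[cv]])
    bad <- setdiff(unique(obs[!is.na(obs)]), roles$levels[[cv]])
    if (length(bad) > 0) {
      abort(paste0("undeclared level(s) for covariate '", cv, "': ",
                   paste(bad, collapse = ", ")))
    }
    role <- roles$roles$role[roles$roles$covariate == cv]
    for (lv in setdiff(roles$levels[[cv]], roles$baseline[[cv]])) {
      nm <- paste(cv, lv, sep = ".")
      cols[[nm]] <- as.numeric(obs == lv)
      map[[nm]] <- tibble(column = nm, covariate = cv, level = lv, role = role)
    }
  }
  design <- do.call(cbind, cols)
  rownames(design) <- NULL
  list(design = design, map = bind_rows(map))
}

#' Split a fitted linear predictor into exposure, other-risk and confounder parts
#'
#' Given per-column log hazard ratios and the design's column-to-role map,
#' computes per-subject components `eta_x`, `eta_w`, `eta_z` whose sum equals
#' the full linear predictor exactly. A subject at baseline for every covariate
#' has all three components equal to zero.
#'
#' @param design Numeric indicator matrix from [build_design()].
#' @param coefficients Numeric vector of log hazard ratios, aligned with (and
#'   checked against) the design columns; a named vector is matched by name.
#' @param map Column-role map from [build_design()].
#' @return A tibble of class `lp_decomposition` with columns `eta_x`, `eta_w`,
#'   `eta_z`, one row per design row.
#' @export
decompose_linear_predictor <- function(design, coefficients, map) {
  if (length(coefficients) != ncol(design)) {
    abort("length(coefficients) must equal ncol(design)")
  }
  if (!is.null(names(coefficients))) {
    if (!setequal(names(coefficients), colnames(design))) {
      abort("coefficient names do not match design columns")
    }
    coefficients <- coefficients[colnames(design)]
  }
  if (any(!is.finite(coefficients))) abort("coefficients must be finite")
  out <- lapply(c(x = "x", w = "w", z = "z"), function(r) {
    keep <- map$column[map$role == r]
    if (length(keep) == 0) return(rep(0, nrow(design)))
    idx <- match(keep, colnames(design))
    as.numeric(design[, idx, drop = FALSE] %*% coefficients[idx])
  })
  new_lp(tibble(eta_x = out$x, eta_w = out$w, eta_z = out$z))
}

new_lp <- function(df) {
  class(df) <- c("lp_decomposition", class(df))
  df
}

#' Assign empirical tertiles, optionally within groups
#'
#' Cuts a numeric vector at its 1/3 and 2/3 empirical quantiles
#' (linear-interpolation "type 7" definition), within each level of `group`
#' when given (e.g. sex-specific tertiles of height or BMI). Values tied with a
#' cut point are assigned to the lower tertile.
#'
#' @param x Numeric vector.
#' @param group Optional grouping vector of the same length; quantiles are
#'   computed within each group, never pooled.
#' @return Factor with levels `T1`, `T2`, `T3` (`NA` where `x` is `NA`).
#' @examples
#' assign_tertiles(1:9)
#' @export
assign_tertiles <- function(x, group = NULL) {
  if (is.null(group)) group <- rep(1L, length(x))
  if (length(group) != length(x)) abort("group must match length of x")
  out <- factor(rep(NA_character_, length(x)), levels = c("T1", "T2", "T3"))
  for (g in unique(group[!is.na(group)])) {
    idx <- which(group == g & !is.na(x))
    if (length(idx) < 3) {
      abort(paste0("need >= 3 non-missing values per group (group ", g, ")"))
    }
    q <- quantile(x[idx], c(1, 2) / 3, type = 7, names = FALSE)
    if (q[1] == q[2]) {
      abort(paste0("tertile cut points coincide in group ", g,
                   "; tertiles undefined"))
    }
    out[idx] <- cut(x[idx], breaks = c(-Inf, q[1], q[2], Inf),
                    labels = c("T1", "T2", "T3"), right = TRUE)
  }
  out
}

#' Read covariate roles from an INI-style configuration file
#'
#' The file has sections `[exposures]`, `[other_risk]`, `[confounders]`, each
#' containing per-covariate lines of the form
#' `smoking.levels = never, previous, current` and
#' `smoking.baseline = never` (baseline optional, defaulting to the first
#' level).
#'
#' @param path Path to the configuration file.
#' @return A [covariate_roles()] object.
#' @export
read_covariate_roles <- function(path) {
  ini <- read_ini(path)
  sec <- c(exposures = "exposures", other_risks = "other_risk",
           confounders = "confounders")
  pulled <- lapply(sec, function(s) {
    kv <- ini[[s]]
    if (is.null(kv)) return(list())
    keys <- names(kv)
    covs <- unique(sub("\\.(levels|baseline)$", "", keys))
    out <- list()
    for (cv in covs) {
      lv <- kv[[paste0(cv, ".levels")]]
      if (is.null(lv)) abort(paste0("missing '", cv, ".levels' in [", s, "]"))
      out[[cv]] <- trimws(strsplit(lv, ",")[[1]])
    }
    out
  })
  baselines <- character()
  for (s in sec) {
    kv <- ini[[s]]
    bk <- grep("\\.baseline$", names(kv), value = TRUE)
    for (k in bk) baselines[[sub("\\.baseline$", "", k)]] <- trimws(kv[[k]])
  }
  covariate_roles(exposures = pulled$exposures,
                  other_risks = pulled$other_risks,
                  confounders = pulled$confounders,
                  baselines = baselines)
}

# Minimal INI reader: [section] headers, key = value lines, '#'/';' comments.
read_ini <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("[#;].*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(out[[section]])) out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(section)) abort("key outside of any [section]")
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      out[[section]][[key]] <- val
    } else {
      abort(paste0("cannot parse line: ", ln))
    }
  }
  out
}
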