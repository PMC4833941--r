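# Mediation-by-attenuation ledger: how much of the intervention effect on
# IPV does each candidate mediator explain?
#
# The base model is a modified Poisson regression of the outcome on arm,
# site-pair fixed effects, age group, marital status and the EA-level
# baseline outcome prevalence, with EA-clustered robust SEs. Each mediator is
# then added singly; the percent attenuation is computed on the excess
# risk-ratio scale,
#
#   A = 100 * (RR_mediator - RR_base) / (1 - RR_base),
#
# positive values meaning the effect moved toward the null. The log-RR scale
# is deliberately NOT used: it does not reproduce the percent-change
# arithmetic of published attenuation tables (see the package tests).

#' Assemble the mediation analysis frame for one reporter
#'
#' Respondents of the reporter's sex, partnered in the past year, with a
#' non-missing outcome; decadal age groups and the baseline EA-level outcome
#' prevalence are attached.
#'
#' @param followup,baseline roster data frames of the two waves.
#' @param reporter `"women"` or `"men"`.
#' @param outcome 0/1 outcome column (default the latent `ipv`; pass a
#'   derived indicator column for pipeline runs).
#' @return analysis data frame with `baseline_ipv_ea` attached.
#' @export
mediation_frame <- function(followup, baseline, reporter = c("women", "men"),
                            outcome = "ipv") {
  reporter <- match.arg(reporter)
  sx <- if (reporter == "women") "female" else "male"
  d <- followup[followup$sex == sx & followup$partnered_past_year == 1L &
                  !is.na(followup[[outcome]]), , drop = FALSE]
  d <- add_age_group(d)
  base_prev <- baseline_ea_prevalence(
    baseline[baseline$sex == sx, , drop = FALSE], outcome = outcome)
  names(base_prev)[2] <- "baseline_ipv_ea"
  d <- merge(d, base_prev, by = "ea_id", all.x = TRUE)
  if (outcome != "ipv") d$ipv <- d[[outcome]]
  d
}

base_formula <- function() {
  ipv ~ arm + pair_id + age_group + marital_status + baseline_ipv_ea
}

#' Intervention risk ratio from the base mediation model
#'
#' Modified Poisson regression of the outcome on arm, site-pair, age group,
#' marital status and baseline EA-level outcome prevalence, with EA-clustered
#' robust SEs.
#'
#' @param data a [mediation_frame()].
#' @param cluster clustering column for the robust variance (default
#'   `"ea_id"`).
#' @return an `effect_estimate` for the arm term, with the fit attached as
#'   attribute `fit`.
#' @export
base_model_rr <- function(data, cluster = "ea_id") {
  fit <- fit_glm(base_formula(), data, link = "log", cluster = cluster)
  est <- risk_ratio_from_model(fit, "arm")
  attr(est, "fit") <- fit
  est
}

#' Intervention risk ratio after adding one mediator
#'
#' @param data a [mediation_frame()]; community-level mediators must already
#'   be attached as a per-respondent exposure column (see
#'   [attach_community_exposure()]).
#' @param mediator mediator column name.
#' @param cluster clustering column.
#' @return an `effect_estimate` for the arm term.
#' @export
mediator_adjusted_rr <- function(data, mediator, cluster = "ea_id") {
  v <- data[[mediator]]
  if (is.null(v)) stop("no mediator column '", mediator, "'")
  if (length(unique(v[!is.na(v)])) < 2L)
    stop("mediator '", mediator, "' is constant in the analysis frame")
  f <- stats::update(base_formula(), paste(". ~ . +", mediator))
  fit <- fit_glm(f, data, link = "log", cluster = cluster)
  est <- risk_ratio_from_model(fit, "arm")
  attr(est, "fit") <- fit
  est
}

#' Percent attenuation of an intervention effect by a mediator
#'
#' `100 * (RR_mediator - RR_base) / (1 - RR_base)` on the excess risk-ratio
#' scale; positive values mean the effect moved toward the null after
#' adjustment, negative values mean it strengthened. Undefined (NA with a
#' message) when the base RR equals 1.
#'
#' @param base,adjusted risk ratios (numbers or `effect_estimate` rows).
#' @return unrounded percent; use [round_half_away()] for display.
#' @export
percent_attenuation <- function(base, adjusted) {
  b <- if (is.data.frame(base)) base$estimate else base
  a <- if (is.data.frame(adjusted)) adjusted$estimate else adjusted
  out <- ifelse(abs(1 - b) < 1e-12, NA_real_, 100 * (a - b) / (1 - b))
  if (anyNA(out)) message("attenuation undefined where the base RR is 1")
  out
}

#' Mediation ledger across a list of mediators
#'
#' Fits the base model once per reporter frame, then one mediator-adjusted
#' model per mediator, and tabulates adjusted RRs with percent attenuation.
#' Rows are ordered by ecological level (community, relationship,
#' individual). Per-mediator failures are recorded in the row and the run
#' continues. The analysis n of each model is recorded; it differs from the
#' base n only when a mediator has missing values.
#'
#' @param data a [mediation_frame()].
#' @param mediators data frame with columns `name`, `column`, `level`
#'   (community / relationship / individual).
#' @param cluster clustering column.
#' @return data frame: one row per mediator with base and adjusted RR, CI,
#'   percent attenuation (unrounded and display-rounded), n, and error
#'   messages where a fit failed.
#' @export
mediation_table <- function(data, mediators, cluster = "ea_id") {
  stopifnot(all(c("name", "column", "level") %in% names(mediators)))
  if (anyDuplicated(mediators$name))
    stop("duplicate mediator names: ",
         paste(unique(mediators$name[duplicated(mediators$name)]),
               collapse = ", "))
  base <- base_model_rr(data, cluster = cluster)
  lvl_order <- c(community = 1L, relationship = 2L, individual = 3L)
  mediators <- mediators[order(lvl_order[mediators$level]), , drop = FALSE]
  rows <- lapply(seq_len(nrow(mediators)), function(i) {
    m <- mediators[i, ]
    est <- tryCatch(mediator_adjusted_rr(data, m$column, cluster = cluster),
                    error = function(e) e)
    if (inherits(est, "error")) {
      return(data.frame(mediator = m$name, level = m$level,
                        base_rr = base$estimate, adjusted_rr = NA_real_,
                        lower = NA_real_, upper = NA_real_,
                        attenuation_pct = NA_real_,
                        attenuation_display = NA_real_,
                        n = NA_integer_, error = conditionMessage(est),
                        stringsAsFactors = FALSE))
    }
    att <- percent_attenuation(base, est)
    data.frame(mediator = m$name, level = m$level,
               base_rr = base$estimate, adjusted_rr = est$estimate,
               lower = est$lower, upper = est$upper,
               attenuation_pct = att,
               attenuation_display = round_half_away(att),
               n = est$n, error = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mediator = character(), level = character(),
               base_rr = numeric(), adjusted_rr = numeric(),
               lower = numeric(), upper = numeric(),
               attenuation_pct = numeric(), attenuation_display = numeric(),
               n = integer(), error = character(), stringsAsFactors = FALSE)
  attr(out, "base") <- base
  out
}

#' Mediator-outcome association risk ratio
#'
#' Individual-level modified Poisson regression of the outcome on the
#' mediator, adjusted for site-pair, intervention arm, age group, marital
#' status, education and childhood abuse, with EA-clustered robust SEs.
#' Community-level mediators should be entered as EA prevalence per 10
#' percentage points (see [attach_community_exposure()]), so the RR reads
#' "per 10% change in community prevalence of the mediator".
#'
#' @param data a [mediation_frame()].
#' @param mediator mediator column name.
#' @param cluster clustering column.
#' @return an `effect_estimate` for the mediator term.
#' @export
risk_factor_association <- function(data, mediator, cluster = "ea_id") {
  f <- stats::as.formula(paste(
    "ipv ~", mediator,
    "+ arm + pair_id + age_group + marital_status + education + childhood_abuse"))
  fit <- fit_glm(f, data, link = "log", cluster = cluster)
  term <- grep(paste0("^", mediator), names(fit$coefficients), value = TRUE)[1]
  est <- risk_ratio_from_model(fit, term)
  attr(est, "fit") <- fit
  est
}

#' Cluster-bootstrap CI for a percent attenuation (extension)
#'
#' The published attenuation percentages carry no CIs; this optional
#' extension resamples EAs with replacement within each community and
#' recomputes the attenuation. Clearly an add-on beyond the published
#' analysis.
#'
#' @param data a [mediation_frame()].
#' @param mediator mediator column name.
#' @param n_boot bootstrap replicates.
#' @param level confidence level.
#' @param seed RNG seed.
#' @return list with the point attenuation and percentile CI.
#' @export
attenuation_boot_ci <- function(data, mediator, n_boot = 200L, level = 0.95,
                                seed = 1L) {
  point <- percent_attenuation(base_model_rr(data),
                               mediator_adjusted_rr(data, mediator))
  set.seed(seed)
  eas <- split(unique(data$ea_id), sub("_E.*", "", unique(data$ea_id)))
  draws <- vapply(seq_len(n_boot), function(b) {
    samp <- unlist(lapply(eas, function(e) sample(e, length(e), replace = TRUE)))
    dd <- do.call(rbind, lapply(seq_along(samp), function(i) {
      d <- data[data$ea_id == samp[i], , drop = FALSE]
      d$ea_id <- paste0(samp[i], "_b", i)
      d
    }))
    tryCatch(percent_attenuation(base_model_rr(dd),
                                 mediator_adjusted_rr(dd, mediator)),
             error = function(e) NA_real_)
  }, numeric(1))
  qs <- stats::quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE)
  list(attenuation = point, lower = qs[[1]], upper = qs[[2]],
       n_failed = sum(is.na(draws)))
}
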