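# End-to-end orchestration: simulate (or load) -> indicators -> EA
# aggregation -> intervention effects -> mediator associations -> mediation
# ledger, with a machine-readable manifest. Deterministic for a fixed config.

#' Validate a respondent roster
#'
#' Structural violations (arm varying within a community, an EA spanning
#' communities, a community spanning pairs, duplicate respondent ids,
#' missing required columns) are hard errors naming the offender. Value
#' violations (age outside 18--49, sex not female/male, flags not 0/1) are
#' collected as warnings and the offending rows are flagged for exclusion.
#'
#' @param data roster data frame (e.g. from [read_roster_csv()]).
#' @return list with `violations` (data frame: rule, id, n_rows, severity)
#'   and `data` (rows with value violations removed).
#' @export
validate_roster <- function(data) {
  required <- c("respondent_id", "pair_id", "community_id", "ea_id", "arm",
                "sex", "age", "marital_status", "education",
                "partnered_past_year")
  miss <- setdiff(required, names(data))
  if (length(miss))
    stop("roster lacks required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(data$respondent_id))
    stop("duplicate respondent id(s): ",
         paste(utils::head(unique(
           data$respondent_id[duplicated(data$respondent_id)]), 3),
           collapse = ", "))
  arm_per_comm <- tapply(data$arm, data$community_id,
                         function(a) length(unique(a)))
  if (any(arm_per_comm > 1L))
    stop("arm varies within community: ",
         paste(names(arm_per_comm)[arm_per_comm > 1L], collapse = ", "))
  comm_per_ea <- tapply(data$community_id, data$ea_id,
                        function(x) length(unique(x)))
  if (any(comm_per_ea > 1L))
    stop("EA spans multiple communities: ",
         paste(names(comm_per_ea)[comm_per_ea > 1L], collapse = ", "))
  pair_per_comm <- tapply(data$pair_id, data$community_id,
                          function(x) length(unique(x)))
  if (any(pair_per_comm > 1L))
    stop("community spans multiple pairs: ",
         paste(names(pair_per_comm)[pair_per_comm > 1L], collapse = ", "))

  viol <- list()
  bad_age <- is.na(data$age) | data$age < 18 | data$age > 49
  if (any(bad_age))
    viol$age <- data.frame(rule = "age outside 18-49", n_rows = sum(bad_age),
                           severity = "warning")
  bad_sex <- !data$sex %in% c("female", "male")
  if (any(bad_sex))
    viol$sex <- data.frame(rule = "sex not female/male",
                           n_rows = sum(bad_sex), severity = "warning")
  sex_per_ea <- tapply(data$sex, data$ea_id, function(x) length(unique(x)))
  if (any(sex_per_ea > 1L))
    viol$ea_sex <- data.frame(rule = "EA not single-sex",
                              n_rows = sum(data$ea_id %in%
                                             names(sex_per_ea)[sex_per_ea > 1L]),
                              severity = "warning")
  drop <- bad_age | bad_sex
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(rule = character(), n_rows = integer(), severity = character())
  rownames(violations) <- NULL
  if (nrow(violations))
    warning(sum(drop), " row(s) excluded by roster validation")
  list(violations = violations, data = data[!drop, , drop = FALSE])
}

state_to_binary <- function(state) {
  ifelse(state == "true", 1L, ifelse(state == "false", 0L, NA_integer_))
}

#' Run the full pathways analysis pipeline
#'
#' Simulates a trial (or takes one), derives all indicators, aggregates EA
#' prevalences, estimates intervention effects on the IPV outcomes
#' (pair-matched cluster-level ITT) and on every mediator (cluster-level ITT
#' for binary mediators, adjusted EA-level mean differences for community
#' norms), fits the mediator-outcome association models, and produces the
#' mediation-by-attenuation ledger. Writes the five report tables plus a
#' manifest to `out_dir` when given; re-running with the same config is
#' bit-identical.
#'
#' @param config a [sim_config()] (the simulated-input source) or a list
#'   with elements `baseline` and `followup` (rosters already loaded).
#' @param indicator_config path to the indicator YAML (default the shipped
#'   config).
#' @param out_dir optional output directory for CSV/JSON reports.
#' @return (invisibly when writing) list with elements `itt`, `mediator_effects`,
#'   `associations`, `mediation`, `ea_summaries`, `manifest`.
#' @export
run_pipeline <- function(config = sim_config(),
                         indicator_config = default_indicator_config(),
                         out_dir = NULL) {
  if (!file.exists(indicator_config))
    stop("indicator config not found: ", indicator_config)
  specs <- parse_indicator_specs(indicator_config)

  if (inherits(config, "sim_config")) {
    trial <- generate_trial(config)
    seed <- config$seed
  } else if (is.list(config) && all(c("baseline", "followup") %in% names(config))) {
    trial <- config
    seed <- NA_integer_
  } else stop("config must be a sim_config or a list(baseline=, followup=)")

  base_v <- validate_roster(trial$baseline)
  fol_v <- validate_roster(trial$followup)
  baseline <- base_v$data
  followup <- fol_v$data

  im_base <- build_indicator_matrix(specs, baseline)
  im_fol <- build_indicator_matrix(specs, followup)
  ea_base <- suppressMessages(ea_prevalence(im_base))
  ea_fol <- suppressMessages(ea_prevalence(im_fol))

  # derived outcome columns on both waves
  for (oc in c("ipv_experience", "ipv_perpetration")) {
    baseline[[oc]] <- state_to_binary(
      im_base$values[[oc]][match(baseline$respondent_id,
                                 im_base$values$respondent_id)])
    followup[[oc]] <- state_to_binary(
      im_fol$values[[oc]][match(followup$respondent_id,
                                im_fol$values$respondent_id)])
  }

  outcome_of <- c(women = "ipv_experience", men = "ipv_perpetration")
  med_specs <- specs[vapply(specs, function(s) s$level != "outcome",
                            logical(1))]

  # ---- outcome ITT (report shaped like the trial's effect table) ----------
  itt <- do.call(rbind, lapply(c("women", "men"), function(rep_) {
    oc <- outcome_of[[rep_]]
    d <- mediation_frame(followup, baseline, rep_, outcome = oc)
    est <- itt_effect(d, outcome = "ipv",
                      covariates = c("age_group", "marital_status",
                                     "baseline_ipv_ea"))
    data.frame(outcome = oc, reporter = rep_, arr = est$estimate,
               lower = est$lower, upper = est$upper, n = est$n,
               adjustment = attr(est, "adjustment"),
               stringsAsFactors = FALSE)
  }))

  # ---- intervention effect on each mediator -------------------------------
  mediator_effects <- do.call(rbind, lapply(med_specs, function(s) {
    do.call(rbind, lapply(c("women", "men"), function(rep_) {
      if (s$reporter != "both" && s$reporter != rep_) return(NULL)
      sx <- if (rep_ == "women") "female" else "male"
      if (s$level == "community") {
        sf <- ea_fol[ea_fol$indicator == s$name & ea_fol$sex == sx, ]
        sb <- ea_base[ea_base$indicator == s$name & ea_base$sex == sx, ]
        md <- tryCatch(adjusted_mean_difference(sf, sb), error = function(e) e)
        if (inherits(md, "error"))
          return(data.frame(mediator = s$name, level = s$level,
                            reporter = rep_, measure = "mean_difference",
                            estimate = NA_real_, lower = NA_real_,
                            upper = NA_real_, n = NA_integer_,
                            error = conditionMessage(md),
                            stringsAsFactors = FALSE))
        return(data.frame(mediator = s$name, level = s$level, reporter = rep_,
                          measure = "mean_difference", estimate = md$estimate,
                          lower = md$lower, upper = md$upper, n = md$n_ea,
                          error = NA_character_, stringsAsFactors = FALSE))
      }
      d <- followup[followup$sex == sx, , drop = FALSE]
      d$y <- state_to_binary(
        im_fol$values[[s$name]][match(d$respondent_id,
                                      im_fol$values$respondent_id)])
      d <- add_age_group(d[!is.na(d$y), , drop = FALSE])
      est <- tryCatch(
        itt_effect(d, outcome = "y",
                   covariates = c("age_group", "marital_status")),
        error = function(e) e)
      if (inherits(est, "error"))
        return(data.frame(mediator = s$name, level = s$level, reporter = rep_,
                          measure = "risk_ratio", estimate = NA_real_,
                          lower = NA_real_, upper = NA_real_, n = NA_integer_,
                          error = conditionMessage(est),
                          stringsAsFactors = FALSE))
      data.frame(mediator = s$name, level = s$level, reporter = rep_,
                 measure = "risk_ratio", estimate = est$estimate,
                 lower = est$lower, upper = est$upper, n = est$n,
                 error = NA_character_, stringsAsFactors = FALSE)
    }))
  }))
  rownames(mediator_effects) <- NULL

  # ---- association and mediation ledgers ----------------------------------
  frames <- lapply(c(women = "women", men = "men"), function(rep_)
    mediation_frame(followup, baseline, rep_, outcome = outcome_of[[rep_]]))
  attach_mediators <- function(d) {
    sx <- unique(d$sex)
    for (s in med_specs) {
      col <- paste0("med_", s$name)
      if (s$level == "community") {
        sf <- ea_fol[ea_fol$sex == sx, ]
        d[[col]] <- attach_community_exposure(d, sf, s$name, scale = 10)
      } else {
        d[[col]] <- state_to_binary(
          im_fol$values[[s$name]][match(d$respondent_id,
                                        im_fol$values$respondent_id)])
      }
    }
    d
  }
  frames <- lapply(frames, attach_mediators)

  med_tab <- data.frame(
    name = vapply(med_specs, `[[`, "", "name"),
    column = paste0("med_", vapply(med_specs, `[[`, "", "name")),
    level = vapply(med_specs, `[[`, "", "level"),
    reporter = vapply(med_specs, `[[`, "", "reporter"),
    stringsAsFactors = FALSE)

  associations <- do.call(rbind, lapply(c("women", "men"), function(rep_) {
    d <- frames[[rep_]]
    mt <- med_tab[med_tab$reporter %in% c("both", rep_), ]
    do.call(rbind, lapply(seq_len(nrow(mt)), function(i) {
      est <- tryCatch(risk_factor_association(d, mt$column[i]),
                      error = function(e) e)
      if (inherits(est, "error"))
        return(data.frame(mediator = mt$name[i], level = mt$level[i],
                          reporter = rep_, arr = NA_real_, lower = NA_real_,
                          upper = NA_real_, n = NA_integer_,
                          error = conditionMessage(est),
                          stringsAsFactors = FALSE))
      data.frame(mediator = mt$name[i], level = mt$level[i], reporter = rep_,
                 arr = est$estimate, lower = est$lower, upper = est$upper,
                 n = est$n, error = NA_character_, stringsAsFactors = FALSE)
    }))
  }))
  rownames(associations) <- NULL

  mediation <- do.call(rbind, lapply(c("women", "men"), function(rep_) {
    mt <- med_tab[med_tab$reporter %in% c("both", rep_), ]
    out <- mediation_table(frames[[rep_]], mt)
    out$reporter <- rep_
    out
  }))
  rownames(mediation) <- NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("crtpathways")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    n_baseline = nrow(baseline), n_followup = nrow(followup),
    n_indicators = length(specs),
    clamp_rate = as.list(attr(trial, "clamp_rate") %||% NA),
    validation_warnings = nrow(base_v$violations) + nrow(fol_v$violations),
    tables = c("itt", "mediator_effects", "associations", "mediation",
               "ea_summaries")
  )

  result <- list(itt = itt, mediator_effects = mediator_effects,
                 associations = associations, mediation = mediation,
                 ea_summaries = ea_fol, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(itt, file.path(out_dir, "itt_effects.csv"),
                     row.names = FALSE)
    utils::write.csv(mediator_effects,
                     file.path(out_dir, "mediator_effects.csv"),
                     row.names = FALSE)
    utils::write.csv(associations, file.path(out_dir, "associations.csv"),
                     row.names = FALSE)
    utils::write.csv(mediation, file.path(out_dir, "mediation_ledger.csv"),
                     row.names = FALSE)
    utils::write.csv(ea_fol, file.path(out_dir, "ea_summaries.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(result))
  }
  result
}
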