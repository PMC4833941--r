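# Synthetic pair-matched CRT survey generator.
#
# Structure: communities nested in matched pairs, single-sex enumeration
# areas (EAs) nested in communities, respondents nested in EAs. Each
# (wave, community, EA) owns its own pseudo-random substream derived from the
# config seed, so changing one EA's draws never shifts another's.

MARITAL_LEVELS <- c("married", "regular_partner", "single")
MARITAL_PROBS <- c(0.55, 0.30, 0.15)
EDUCATION_LEVELS <- c("primary", "secondary", "higher")
EDUCATION_PROBS <- c(0.45, 0.40, 0.15)
AGE_CENTRE <- 33.5 # mean of uniform ages 18..49

.calib_cache <- new.env(parent = emptyenv())

calib_key <- function(cfg) {
  paste(cfg$arm_log_rr, cfg$mediated_fraction, cfg$norm_shift,
        cfg$norm_intercept, cfg$sigma_pair, cfg$sigma_community, cfg$sigma_ea,
        cfg$baseline_prevalence, cfg$attitude_log_rr, cfg$abuse_prob,
        cfg$ea_size_mean, cfg$ea_size_sd,
        paste(cfg$ea_size_range, collapse = ","),
        paste(unlist(cfg$covariate_effects), collapse = ","),
        sep = "|")
}

# Discretised truncated-normal EA sizes on [min, max].
draw_ea_sizes <- function(n, cfg) {
  lo <- cfg$ea_size_range[1] - 0.499
  hi <- cfg$ea_size_range[2] + 0.499
  u <- stats::runif(n, stats::pnorm(lo, cfg$ea_size_mean, cfg$ea_size_sd),
                    stats::pnorm(hi, cfg$ea_size_mean, cfg$ea_size_sd))
  x <- round(stats::qnorm(u, cfg$ea_size_mean, cfg$ea_size_sd))
  pmin(pmax(x, cfg$ea_size_range[1]), cfg$ea_size_range[2])
}

# Individual-level log relative risk from covariates (excluding arm, norm and
# attitude terms).
covariate_log_rr <- function(cfg, age, marital, education, abuse) {
  ce <- cfg$covariate_effects
  mar <- c(married = 0, ce$marital)[marital]
  edu <- c(primary = 0, ce$education)[education]
  ce$age_per_decade * (age - AGE_CENTRE) / 10 + mar + edu +
    ce$childhood_abuse * abuse
}

# Monte-Carlo population used to calibrate the norm-pathway coefficient and
# the intercept correction. One virtual respondent per virtual EA; the
# respondent's own attitude is one of the EA's Bernoulli draws so that the
# realized EA prevalence includes self.
calib_population <- function(cfg, m_per_arm = 200000L) {
  set.seed(760013L)
  arm <- rep(c(0L, 1L), each = m_per_arm)
  eta <- cfg$norm_intercept + cfg$norm_shift * arm +
    stats::rnorm(2L * m_per_arm, 0, sqrt(cfg$sigma_pair^2 + cfg$sigma_community^2)) +
    stats::rnorm(2L * m_per_arm, 0, cfg$sigma_ea)
  p_att <- stats::plogis(eta)
  n_ea <- draw_ea_sizes(2L * m_per_arm, cfg)
  a_self <- stats::rbinom(2L * m_per_arm, 1L, p_att)
  x_ea <- (a_self + stats::rbinom(2L * m_per_arm, n_ea - 1L, p_att)) / n_ea
  age <- sample(18:49, 2L * m_per_arm, replace = TRUE)
  marital <- sample(MARITAL_LEVELS, 2L * m_per_arm, TRUE, MARITAL_PROBS)
  education <- sample(EDUCATION_LEVELS, 2L * m_per_arm, TRUE, EDUCATION_PROBS)
  abuse <- stats::rbinom(2L * m_per_arm, 1L, cfg$abuse_prob)
  list(arm = arm, x_ea = x_ea, a_self = a_self,
       cov_lrr = covariate_log_rr(cfg, age, marital, education, abuse))
}

# Marginal arm risk ratio implied by a candidate norm coefficient theta,
# evaluated on a fixed MC population (common random numbers).
mc_marginal_rr <- function(theta, pop, cfg, ref_norm) {
  lam <- cfg$mediated_fraction
  g <- pop$cov_lrr + theta * (pop$x_ea - ref_norm) +
    cfg$attitude_log_rr * pop$a_self
  # intercept correction: control-arm marginal risk equals baseline_prevalence
  c0 <- log(mean(exp(g[pop$arm == 0L])))
  risk <- cfg$baseline_prevalence *
    exp(g - c0 + (1 - lam) * cfg$arm_log_rr * pop$arm)
  risk <- pmin(pmax(risk, 1e-9), 1 - 1e-9)
  list(rr = mean(risk[pop$arm == 1L]) / mean(risk[pop$arm == 0L]), c0 = c0)
}

# Calibrate the norm-pathway coefficient theta by root-finding against the MC
# estimate of the marginal arm risk ratio, so that the total effect equals
# exp(arm_log_rr) at every mediated fraction.
calibrate_norm_model <- function(cfg) {
  key <- calib_key(cfg)
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
  pop <- calib_population(cfg)
  ref_norm <- mean(pop$x_ea[pop$arm == 0L])
  lam <- cfg$mediated_fraction
  if (lam == 0 || abs(cfg$arm_log_rr) < 1e-12) {
    theta <- 0
  } else {
    f <- function(th) log(mc_marginal_rr(th, pop, cfg, ref_norm)$rr) - cfg$arm_log_rr
    dx <- mean(pop$x_ea[pop$arm == 1L]) - ref_norm
    scale <- abs(lam * cfg$arm_log_rr) / max(abs(dx), 1e-6)
    theta <- stats::uniroot(f, lower = -4 * scale, upper = 4 * scale,
                            extendInt = "yes", tol = 1e-6)$root
  }
  final <- mc_marginal_rr(theta, pop, cfg, ref_norm)
  out <- list(theta = theta, ref_norm = ref_norm, c0 = final$c0,
              mc_marginal_rr = final$rr)
  .calib_cache[[key]] <- out
  out
}

#' Population marginal risk ratio implied by a simulation configuration
#'
#' Estimates the marginal intervention risk ratio of the data-generating
#' process by a large Monte-Carlo draw of virtual respondents, independent of
#' the draw used internally to calibrate the norm pathway. Used as the
#' recovery target for estimator validation; by the calibration contract the
#' value is `exp(arm_log_rr)` (within Monte-Carlo error) at every mediated
#' fraction.
#'
#' @param config a [sim_config()].
#' @param n_respondents minimum number of virtual respondents (default 1e6).
#' @return a single risk ratio.
#' @export
true_marginal_rr <- function(config, n_respondents = 1e6) {
  validate_sim_config(config)
  cal <- calibrate_norm_model(config)
  m <- ceiling(n_respondents / (2 * config$ea_size_mean))
  set.seed(sub_seed(config$seed, 99L))
  arm_ea <- rep(c(0L, 1L), each = m)
  eta <- config$norm_intercept + config$norm_shift * arm_ea +
    stats::rnorm(2L * m, 0, sqrt(config$sigma_pair^2 + config$sigma_community^2)) +
    stats::rnorm(2L * m, 0, config$sigma_ea)
  p_att <- stats::plogis(eta)
  n_ea <- draw_ea_sizes(2L * m, config)
  # expand to respondents
  idx <- rep.int(seq_len(2L * m), n_ea)
  n_tot <- length(idx)
  attitude <- stats::rbinom(n_tot, 1L, p_att[idx])
  x_ea <- tapply(attitude, idx, mean)[as.character(seq_len(2L * m))]
  age <- sample(18:49, n_tot, replace = TRUE)
  marital <- sample(MARITAL_LEVELS, n_tot, TRUE, MARITAL_PROBS)
  education <- sample(EDUCATION_LEVELS, n_tot, TRUE, EDUCATION_PROBS)
  abuse <- stats::rbinom(n_tot, 1L, config$abuse_prob)
  lam <- config$mediated_fraction
  g <- covariate_log_rr(config, age, marital, education, abuse) +
    cal$theta * (as.numeric(x_ea)[idx] - cal$ref_norm) +
    config$attitude_log_rr * attitude - cal$c0 +
    (1 - lam) * config$arm_log_rr * arm_ea[idx]
  risk <- pmin(pmax(config$baseline_prevalence * exp(g), 1e-9), 1 - 1e-9)
  arm_r <- arm_ea[idx]
  mean(risk[arm_r == 1L]) / mean(risk[arm_r == 0L])
}

#' Generate baseline and follow-up waves of a synthetic pair-matched CRT
#'
#' Draws two cross-sectional survey waves from the data-generating process in
#' [sim_config()]. Communities come in matched pairs with one community per
#' arm; each community holds single-sex EAs (first half female, second half
#' male); respondents carry design identifiers, covariates, eligibility
#' flags, latent ground-truth columns and (optionally) item-level responses
#' from which every composite indicator can be rebuilt.
#'
#' The baseline wave is drawn with all arm coefficients forced to zero, so no
#' generated variable differs systematically between arms at baseline.
#' Community- and pair-level random effects are shared between waves, making
#' baseline EA prevalences informative covariates for follow-up analysis.
#'
#' Ground-truth columns: `accepts_violence` (latent attitude), its realized
#' EA prevalence `norm_accept_ea` (proportion), and `ipv` (latent outcome;
#' `NA` for respondents not partnered in the past year, who are ineligible
#' for the outcome).
#'
#' @param config a [sim_config()].
#' @param items generate item-level survey responses (default `TRUE`); set
#'   `FALSE` for simulation loops that only need the latent columns. Latent
#'   draws are identical either way.
#' @return an object of class `crt_trial`: a list with elements `baseline`
#'   and `followup` (data frames), plus attributes `config`, `calibration`
#'   and `clamp_rate` (shares of respondents whose modelled risk was clamped
#'   into (0,1), by wave).
#' @export
generate_trial <- function(config, items = TRUE) {
  validate_sim_config(config)
  cal <- calibrate_norm_model(config)
  n_comm <- 2L * config$n_pairs

  # arm assignment within pair, and persistent pair/community effects
  set.seed(sub_seed(config$seed, 0L))
  first_is_int <- stats::rbinom(config$n_pairs, 1L, 0.5)
  pair_of <- rep(seq_len(config$n_pairs), each = 2L)
  arm_of <- integer(n_comm)
  for (p in seq_len(config$n_pairs)) {
    i <- 2L * p - 1L
    arm_of[i] <- first_is_int[p]
    arm_of[i + 1L] <- 1L - first_is_int[p]
  }
  u_pair <- stats::rnorm(config$n_pairs, 0, config$sigma_pair)
  v_comm <- stats::rnorm(n_comm, 0, config$sigma_community)

  waves <- c(baseline = 1L, followup = 2L)
  out <- list()
  clamp_rates <- c(baseline = 0, followup = 0)
  for (w in names(waves)) {
    widx <- waves[[w]]
    follow <- w == "followup"
    blocks <- vector("list", n_comm * config$eas_per_community)
    clamped <- 0L
    total <- 0L
    bi <- 1L
    for (ci in seq_len(n_comm)) {
      for (ei in seq_len(config$eas_per_community)) {
        set.seed(sub_seed(config$seed, widx, ci, ei))
        sex <- if (ei <= config$eas_per_community / 2) "female" else "male"
        n <- draw_ea_sizes(1L, config)
        arm <- arm_of[ci]
        w_ea <- stats::rnorm(1, 0, config$sigma_ea)
        eta_norm <- config$norm_intercept +
          (if (follow) config$norm_shift * arm else 0) +
          u_pair[pair_of[ci]] + v_comm[ci] + w_ea
        attitude <- stats::rbinom(n, 1L, stats::plogis(eta_norm))
        x_ea <- mean(attitude)

        age <- sample(18:49, n, replace = TRUE)
        marital <- sample(MARITAL_LEVELS, n, TRUE, MARITAL_PROBS)
        education <- sample(EDUCATION_LEVELS, n, TRUE, EDUCATION_PROBS)
        abuse <- stats::rbinom(n, 1L, config$abuse_prob)
        partnered <- stats::rbinom(n, 1L, config$partnered_prob)
        cohabiting <- as.integer(partnered == 1L &
                                   stats::rbinom(n, 1L, config$cohabiting_prob) == 1L)
        witnessed <- stats::rbinom(n, 1L, config$witnessed_prob)
        polygamous <- as.integer(partnered == 1L &
                                   stats::rbinom(n, 1L, config$polygamous_prob) == 1L)

        lam <- config$mediated_fraction
        g <- covariate_log_rr(config, age, marital, education, abuse) +
          cal$theta * (x_ea - cal$ref_norm) +
          config$attitude_log_rr * attitude - cal$c0 +
          (if (follow) (1 - lam) * config$arm_log_rr * arm else 0)
        risk <- config$baseline_prevalence * exp(g)
        clamped <- clamped + sum(risk <= 0 | risk >= 1)
        total <- total + n
        risk <- pmin(pmax(risk, 1e-9), 1 - 1e-9)
        ipv <- ifelse(partnered == 1L, stats::rbinom(n, 1L, risk), NA_integer_)

        df <- data.frame(
          respondent_id = sprintf("%s_C%02d_E%02d_R%03d", w, ci, ei, seq_len(n)),
          pair_id = sprintf("P%d", pair_of[ci]),
          community_id = sprintf("C%02d", ci),
          ea_id = sprintf("C%02d_E%02d", ci, ei),
          arm = arm,
          sex = sex,
          age = age,
          marital_status = marital,
          education = education,
          childhood_abuse = abuse,
          partnered_past_year = partnered,
          cohabiting = cohabiting,
          witnessed_ipv = witnessed,
          polygamous = polygamous,
          accepts_violence = attitude,
          norm_accept_ea = x_ea,
          ipv = ipv,
          stringsAsFactors = FALSE
        )
        if (items) df <- cbind(df, gen_items(n, attitude, ipv, sex, partnered))
        blocks[[bi]] <- df
        bi <- bi + 1L
      }
    }
    roster <- do.call(rbind, blocks)
    rownames(roster) <- NULL
    attr(roster, "wave") <- w
    clamp_rates[[w]] <- clamped / total
    out[[w]] <- roster
  }
  if (max(clamp_rates) > config$clamp_threshold)
    warning(sprintf("risk clamp rate %.2f%% exceeds threshold %.2f%%",
                    100 * max(clamp_rates), 100 * config$clamp_threshold))
  structure(out, class = "crt_trial", config = config, calibration = cal,
            clamp_rate = clamp_rates)
}

#' @export
print.crt_trial <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("Synthetic pair-matched CRT\n")
  for (w in names(x))
    cat(sprintf("  %s: %d respondents, %d EAs, %d communities\n", w,
                nrow(x[[w]]), length(unique(x[[w]]$ea_id)),
                length(unique(x[[w]]$community_id))))
  cat(sprintf("  mediated fraction %.2f, total arm RR %.3f\n",
              cfg$mediated_fraction, exp(cfg$arm_log_rr)))
  invisible(x)
}

# Item-level survey responses, driven by the latent attitude and outcome so
# that the composite indicators in the shipped config recover the latents
# exactly: the 12-scenario acceptability battery has >=1 "yes" iff
# accepts_violence == 1, the act list has >=1 "yes" iff ipv == 1 (women), and
# the anonymous card equals ipv (men).
gen_items <- function(n, attitude, ipv, sex, partnered) {
  sex <- rep(sex, length.out = n)
  yn <- function(p) ifelse(stats::rbinom(n, 1L, p) == 1L, "yes", "no")
  att_p <- function(q, s) stats::plogis(q + s * attitude)

  # multi-item battery with a forced positive when the latent is positive
  battery <- function(k, latent, p_item) {
    m <- matrix("no", n, k)
    pos <- which(latent == 1L)
    if (length(pos)) {
      draws <- matrix(stats::rbinom(length(pos) * k, 1L, p_item),
                      length(pos), k)
      none <- rowSums(draws) == 0L
      if (any(none))
        draws[cbind(which(none), sample.int(k, sum(none), replace = TRUE))] <- 1L
      m[pos, ] <- ifelse(draws == 1L, "yes", "no")
    }
    m
  }

  scen <- battery(12L, attitude, 0.35)
  colnames(scen) <- paste0("att_", c("disobeys", "answers_back", "disrespects",
                                     "suspects", "unfaithful", "gossips",
                                     "neglects", "housework", "refuses_sex",
                                     "accuses", "secrets", "angry"))

  ipv_w <- ifelse(is.na(ipv), 0L, ipv)
  acts <- battery(7L, ifelse(sex == "female", ipv_w, 0L), 0.40)
  colnames(acts) <- paste0("act_", c("slap", "push", "fist", "kick", "choke",
                                     "weapon", "stick"))
  # act items only asked of partnered women
  acts[sex != "female" | partnered == 0L, ] <- NA_character_

  card <- rep(NA_character_, n)
  men_p <- sex == "male" & partnered == 1L
  card[men_p] <- ifelse(ipv_w[men_p] == 1L, "yes", "no")

  resp <- matrix("no", n, 9L)
  for (k in 1:9) resp[, k] <- yn(att_p(stats::qlogis(0.25), -0.3))
  colnames(resp) <- paste0("resp_", c("gathered", "knocked", "separated",
                                      "authority", "advised_woman",
                                      "asked_woman", "told_man",
                                      "referred_man", "helped_man"))

  cat3 <- function(p_many) {
    many <- stats::rbinom(n, 1L, p_many) == 1L
    ifelse(many, "many", ifelse(stats::rbinom(n, 1L, 0.6) == 1L, "few", "none"))
  }
  joint_p <- att_p(stats::qlogis(0.55), -0.5)
  joint_hi <- stats::rbinom(n, 1L, joint_p) == 1L
  joint <- ifelse(joint_hi,
                  ifelse(stats::rbinom(n, 1L, 0.5) == 1L, "all", "most"),
                  ifelse(stats::rbinom(n, 1L, 0.5) == 1L, "sometimes", "never"))
  drunk_hi <- stats::rbinom(n, 1L, att_p(stats::qlogis(0.20), 0.4)) == 1L
  drunk <- ifelse(drunk_hi,
                  sample(c("monthly", "weekly", "most_days"), n, TRUE),
                  sample(c("never", "less_monthly"), n, TRUE))

  fin_part <- yn(att_p(stats::qlogis(0.70), -0.4))
  fin_sole <- yn(att_p(stats::qlogis(0.30), 0.4))
  fin_part[sex != "female"] <- NA_character_
  fin_sole[sex != "male"] <- NA_character_

  told <- yn(rep(0.5, n))
  told[is.na(ipv) | ipv_w == 0L] <- NA_character_

  data.frame(
    scen, acts,
    card_violence = card,
    intervene_ok = yn(att_p(stats::qlogis(0.60), -0.8)),
    witness_helped = yn(att_p(stats::qlogis(0.35), -0.5)),
    resp,
    refuse_sex_ok = yn(att_p(stats::qlogis(0.75), -0.9)),
    condom_ok = yn(att_p(stats::qlogis(0.60), -0.7)),
    respect_joint = yn(att_p(stats::qlogis(0.60), -0.6)),
    man_decides_work = yn(att_p(stats::qlogis(0.45), 0.8)),
    tell_others_ok = yn(att_p(stats::qlogis(0.70), -0.6)),
    discuss_day_self = yn(att_p(stats::qlogis(0.85), -0.4)),
    discuss_day_partner = yn(att_p(stats::qlogis(0.85), -0.4)),
    discuss_worries = yn(att_p(stats::qlogis(0.80), -0.4)),
    sex_asked = yn(att_p(stats::qlogis(0.60), -0.5)),
    sex_told = yn(att_p(stats::qlogis(0.60), -0.5)),
    appreciate_house = cat3(att_p(stats::qlogis(0.60), -0.4)),
    appreciate_house_applicable = yn(rep(0.85, n)),
    appreciate_outside = cat3(att_p(stats::qlogis(0.55), -0.4)),
    appreciate_outside_applicable = yn(rep(0.75, n)),
    joint_decisions = joint,
    man_helps_house = yn(att_p(stats::qlogis(0.60), -0.4)),
    refused_job = yn(att_p(stats::qlogis(0.15), 0.5)),
    fin_participated = fin_part,
    fin_sole_control = fin_sole,
    other_partner = yn(att_p(stats::qlogis(0.10) + 1.2 * (sex == "male"), 0.4)),
    partner_suspicious = yn(att_p(stats::qlogis(0.15), 0.8)),
    separated_past_year = yn(att_p(stats::qlogis(0.03), 0.3)),
    drunk_freq = drunk,
    told_someone = told,
    stringsAsFactors = FALSE
  )
}

#' Write or read a trial roster as CSV
#'
#' The column dictionary is the union of design identifiers, covariates,
#' eligibility flags, ground-truth columns and item responses documented in
#' [generate_trial()].
#'
#' @param roster a roster data frame (one wave).
#' @param path file path.
#' @return `read_roster_csv` returns the roster data frame.
#' @export
write_roster_csv <- function(roster, path) {
  utils::write.csv(roster, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_roster_csv
#' @export
read_roster_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  df
}
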