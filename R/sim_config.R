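#' Configuration for the synthetic pair-matched trial generator
#'
#' Defines the data-generating process for a pair-matched community-randomised
#' trial of a binary outcome (past-year IPV) in which a configurable fraction
#' of the intervention effect flows through community-level normative
#' attitudes. Structural defaults mirror the motivating trial: 8 communities
#' in 4 matched pairs, 12 single-sex enumeration areas (EAs) per community,
#' and a mean of 28 respondents per EA (range 18--35).
#'
#' The outcome model is multiplicative on the risk scale (log link), so the
#' natural effect measure is a risk ratio. The total marginal intervention
#' effect is `exp(arm_log_rr)`; a share `mediated_fraction` of the log
#' risk-ratio is routed through the realized EA-level prevalence of
#' violence-accepting attitudes (the community-norm pathway), with the
#' norm-pathway coefficient calibrated internally so that the total marginal
#' arm risk ratio equals `exp(arm_log_rr)` for every value of
#' `mediated_fraction`.
#'
#' @param n_pairs number of matched community pairs (2 communities each).
#' @param eas_per_community number of enumeration areas per community; half
#'   are sampled as all-female, half as all-male.
#' @param ea_size_mean,ea_size_sd,ea_size_range mean, spread and hard range of
#'   respondents per EA; sizes are drawn from a discretised truncated normal.
#' @param arm_log_rr total intervention effect on the log risk-ratio scale
#'   (default `log(0.45)`).
#' @param mediated_fraction share (lambda, in \[0,1\]) of `arm_log_rr` routed
#'   through the community-norm pathway.
#' @param norm_shift intervention effect (logit scale) on the prevalence of
#'   violence-accepting attitudes; negative values mean the intervention
#'   reduces acceptability.
#' @param norm_intercept logit of the control-arm attitude prevalence.
#' @param sigma_pair,sigma_community,sigma_ea standard deviations of the
#'   pair-, community- and EA-level random effects on the attitude logit.
#' @param baseline_prevalence marginal outcome risk in the control arm among
#'   partnered respondents.
#' @param covariate_effects named list of log risk-ratio effects:
#'   `age_per_decade` (continuous, centred at the expected age), `marital`
#'   (named vector, reference "married"), `education` (named vector,
#'   reference "primary"), `childhood_abuse`.
#' @param attitude_log_rr direct effect of an individual's own
#'   violence-accepting attitude on the log outcome risk (default 0, so the
#'   only norm pathway is ecological).
#' @param partnered_prob,cohabiting_prob,witnessed_prob,polygamous_prob,abuse_prob
#'   prevalences of the eligibility flags and childhood abuse exposure.
#' @param clamp_threshold generate a warning when the share of respondents
#'   whose modelled risk had to be clamped into (0,1) exceeds this.
#' @param seed integer seed; all randomness in [generate_trial()] flows from
#'   it through per-(wave, community, EA) substreams.
#'
#' @return an object of class `sim_config` (a validated list).
#' @seealso [generate_trial()], [true_marginal_rr()]
#' @export
sim_config <- function(n_pairs = 4L,
                       eas_per_community = 12L,
                       ea_size_mean = 28,
                       ea_size_sd = 3.5,
                       ea_size_range = c(18L, 35L),
                       arm_log_rr = log(0.45),
                       mediated_fraction = 0.5,
                       norm_shift = -1.0,
                       norm_intercept = 0,
                       sigma_pair = 0.3,
                       sigma_community = 0.25,
                       sigma_ea = 0.25,
                       baseline_prevalence = 0.30,
                       covariate_effects = list(
                         age_per_decade = -0.10,
                         marital = c(regular_partner = 0.15, single = 0.25),
                         education = c(secondary = -0.10, higher = -0.25),
                         childhood_abuse = log(1.5)
                       ),
                       attitude_log_rr = 0,
                       partnered_prob = 0.85,
                       cohabiting_prob = 0.65,
                       witnessed_prob = 0.50,
                       polygamous_prob = 0.10,
                       abuse_prob = 0.35,
                       clamp_threshold = 0.02,
                       seed = 1L) {
  cfg <- list(
    n_pairs = as.integer(n_pairs),
    eas_per_community = as.integer(eas_per_community),
    ea_size_mean = ea_size_mean,
    ea_size_sd = ea_size_sd,
    ea_size_range = as.integer(ea_size_range),
    arm_log_rr = arm_log_rr,
    mediated_fraction = mediated_fraction,
    norm_shift = norm_shift,
    norm_intercept = norm_intercept,
    sigma_pair = sigma_pair,
    sigma_community = sigma_community,
    sigma_ea = sigma_ea,
    baseline_prevalence = baseline_prevalence,
    covariate_effects = covariate_effects,
    attitude_log_rr = attitude_log_rr,
    partnered_prob = partnered_prob,
    cohabiting_prob = cohabiting_prob,
    witnessed_prob = witnessed_prob,
    polygamous_prob = polygamous_prob,
    abuse_prob = abuse_prob,
    clamp_threshold = clamp_threshold,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_pairs < 1L) stop("n_pairs must be >= 1")
  if (cfg$eas_per_community < 2L)
    stop("eas_per_community must be >= 2 (EAs are single-sex, both sexes needed)")
  lam <- cfg$mediated_fraction
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam < 0 || lam > 1)
    stop("mediated_fraction must be a single value in [0, 1]")
  r <- cfg$ea_size_range
  if (length(r) != 2L || r[1] > r[2])
    stop("ea_size_range must be c(min, max) with min <= max")
  if (cfg$ea_size_mean < r[1] || cfg$ea_size_mean > r[2])
    stop("ea_size_range must bracket ea_size_mean")
  for (s in c("sigma_pair", "sigma_community", "sigma_ea", "ea_size_sd"))
    if (cfg[[s]] < 0) stop(s, " must be >= 0")
  if (cfg$baseline_prevalence <= 0 || cfg$baseline_prevalence >= 1)
    stop("baseline_prevalence must be in (0, 1)")
  for (p in c("partnered_prob", "cohabiting_prob", "witnessed_prob",
              "polygamous_prob", "abuse_prob"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  if (lam > 0 && abs(cfg$arm_log_rr) > 1e-12 && abs(cfg$norm_shift) < 1e-8)
    stop("mediated_fraction > 0 requires a nonzero norm_shift: ",
         "there is no community-norm pathway to route the effect through")
  invisible(cfg)
}

#' Read a simulation configuration from a YAML file
#'
#' Any field of [sim_config()] may be given; unspecified fields keep their
#' defaults. Nested `covariate_effects` entries are merged into the default
#' list.
#'
#' @param path path to a YAML file.
#' @return a `sim_config` object.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown sim_config fields in ", path, ": ",
         paste(unknown, collapse = ", "))
  if (!is.null(vals$covariate_effects)) {
    defaults <- formals(sim_config)$covariate_effects
    defaults <- eval(defaults)
    for (nm in names(vals$covariate_effects)) {
      v <- vals$covariate_effects[[nm]]
      defaults[[nm]] <- if (is.list(v)) unlist(v) else v
    }
    vals$covariate_effects <- defaults
  }
  do.call(sim_config, vals)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Pair-matched CRT simulation config\n")
  cat(sprintf("  %d pairs x 2 communities, %d EAs/community, EA size %g [%d-%d]\n",
              x$n_pairs, x$eas_per_community, x$ea_size_mean,
              x$ea_size_range[1], x$ea_size_range[2]))
  cat(sprintf("  total arm RR %.3f, mediated fraction %.2f, norm shift %.2f (logit)\n",
              exp(x$arm_log_rr), x$mediated_fraction, x$norm_shift))
  cat(sprintf("  control outcome risk %.2f, sigmas (pair/community/EA) %.2f/%.2f/%.2f\n",
              x$baseline_prevalence, x$sigma_pair, x$sigma_community, x$sigma_ea))
  invisible(x)
}
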