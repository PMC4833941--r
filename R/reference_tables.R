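# Reported estimates from the motivating community-mobilisation CRT, used as
# fixed inputs: the attenuation arithmetic can be reconstructed exactly from
# the printed adjusted risk ratios, and the outcome prevalences from the
# printed numerators/denominators. Individual-level raw data are available
# on request only, so these printed values are the reconstruction targets.

#' Reported base/adjusted risk-ratio pairs from the trial's mediation table
#'
#' One row per mediator per reporter: the intervention aRR without the
#' mediator (`base_rr`), with the mediator added (`adjusted_rr`), and the
#' percent change printed in the report (`printed_pct`, integer).
#'
#' @return data frame with mediator, level, reporter, base_rr, adjusted_rr,
#'   printed_pct.
#' @export
trial_attenuation_pairs <- function() {
  w <- function(mediator, level, adj, pct)
    data.frame(mediator = mediator, level = level, reporter = "women",
               base_rr = 0.44, adjusted_rr = adj, printed_pct = pct,
               stringsAsFactors = FALSE)
  m <- function(mediator, level, adj, pct)
    data.frame(mediator = mediator, level = level, reporter = "men",
               base_rr = 0.45, adjusted_rr = adj, printed_pct = pct,
               stringsAsFactors = FALSE)
  out <- rbind(
    w("comm_intervene_ok",      "community",    0.44,  0),
    w("comm_responded",         "community",    0.43, -2),
    w("comm_accept_violence",   "community",    0.83, 70),
    w("comm_refuse_sex_ok",     "community",    0.57, 23),
    w("comm_condom_ok",         "community",    0.62, 32),
    w("comm_respect_joint",     "community",    0.64, 36),
    w("comm_man_decides_work",  "community",    0.70, 46),
    w("discuss_day",            "relationship", 0.51, 13),
    w("discuss_worries",        "relationship", 0.51, 13),
    w("discuss_sex",            "relationship", 0.53, 16),
    w("appreciate_house",       "relationship", 0.46,  4),
    w("appreciate_outside",     "relationship", 0.45,  2),
    w("joint_decisions",        "relationship", 0.52, 14),
    w("man_helps_house",        "relationship", 0.47,  5),
    w("refused_job",            "relationship", 0.48,  7),
    w("finances_joint",         "relationship", 0.47,  5),
    w("partner_suspicious",     "relationship", 0.54, 18),
    w("att_accept_violence",    "individual",   0.53, 16),
    w("att_tell_others",        "individual",   0.46,  4),
    w("att_refuse_sex",         "individual",   0.54, 18),
    w("att_condom",             "individual",   0.51, 13),
    w("att_respect_joint",      "individual",   0.53, 16),
    w("att_man_decides_work",   "individual",   0.51, 13),
    m("comm_intervene_ok",      "community",    0.66, 38),
    m("comm_responded",         "community",    0.52, 13),
    m("comm_accept_violence",   "community",    0.97, 95),
    m("comm_refuse_sex_ok",     "community",    0.41, -7),
    m("comm_condom_ok",         "community",    0.56, 20),
    m("comm_respect_joint",     "community",    0.58, 24),
    m("comm_man_decides_work",  "community",    0.82, 67),
    m("discuss_day",            "relationship", 0.46,  2),
    m("discuss_worries",        "relationship", 0.47,  4),
    m("discuss_sex",            "relationship", 0.49,  7),
    m("appreciate_house",       "relationship", 0.48,  5),
    m("appreciate_outside",     "relationship", 0.48,  5),
    m("joint_decisions",        "relationship", 0.49,  7),
    m("man_helps_house",        "relationship", 0.49,  7),
    m("refused_job",            "relationship", 0.51, 11),
    m("finances_joint",         "relationship", 0.47,  4),
    m("concurrent_partners",    "relationship", 0.49,  7),
    m("partner_suspicious",     "relationship", 0.57, 22),
    m("att_accept_violence",    "individual",   0.68, 42),
    m("att_tell_others",        "individual",   0.57, 22),
    m("att_refuse_sex",         "individual",   0.48,  5),
    m("att_condom",             "individual",   0.47,  4),
    m("att_respect_joint",      "individual",   0.54, 16),
    m("att_man_decides_work",   "individual",   0.58, 24),
    m("drunk_monthly",          "individual",   0.47,  4)
  )
  rownames(out) <- NULL
  out
}

#' Reported IPV outcome counts and adjusted risk ratios from the trial
#'
#' Numerators/denominators (and printed percents) by arm and wave for the
#' two IPV outcomes, plus the trial's adjusted cluster-level ITT risk ratios
#' with their 95% CIs.
#'
#' @return data frame with outcome, wave, arm, events, n, printed_pct.
#' @export
trial_outcome_counts <- function() {
  out <- data.frame(
    outcome = rep(c("ipv_experience", "ipv_perpetration"), each = 4),
    wave = rep(c("baseline", "baseline", "followup", "followup"), 2),
    arm = rep(c("intervention", "control"), 4),
    events = c(75, 57, 46, 93, 95, 101, 123, 256),
    n = c(302, 273, 504, 424, 309, 326, 617, 523),
    printed_pct = c(25, 21, 9, 22, 31, 31, 20, 49),
    stringsAsFactors = FALSE
  )
  attr(out, "reported_arr") <- data.frame(
    outcome = c("ipv_experience", "ipv_perpetration"),
    arr = c(0.48, 0.39), lower = c(0.16, 0.20), upper = c(1.39, 0.73))
  out
}
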