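# Enumeration-area aggregation: EA prevalences of indicators (the
# community-level ecological exposures), arm summaries, and adjusted mean
# differences for community-level outcomes.

#' EA-level prevalence of each indicator
#'
#' Prevalence is `100 * true / (true + false)` among eligible, non-missing
#' respondents in the EA. EAs with a zero denominator for an indicator are
#' omitted from that indicator's summaries with a message.
#'
#' @param im an `indicator_matrix` from [build_indicator_matrix()].
#' @param indicators optional character vector restricting the indicators.
#' @return data frame with columns ea_id, community_id, pair_id, arm, sex,
#'   indicator, n (denominator), n_true, prevalence (percent).
#' @export
ea_prevalence <- function(im, indicators = NULL) {
  stopifnot(inherits(im, "indicator_matrix"))
  vals <- im$values
  inds <- indicators %||% names(im$specs)
  ea_info <- unique(vals[, c("ea_id", "community_id", "pair_id", "arm", "sex")])
  out <- do.call(rbind, lapply(inds, function(ind) {
    st <- vals[[ind]]
    keep <- st %in% c("true", "false")
    if (!any(keep)) return(NULL)
    nt <- tapply(st[keep] == "true", vals$ea_id[keep], sum)
    nn <- tapply(rep(1L, sum(keep)), vals$ea_id[keep], sum)
    df <- data.frame(ea_id = names(nn), indicator = ind,
                     n = as.integer(nn), n_true = as.integer(nt),
                     prevalence = prevalence_pct(as.integer(nt), as.integer(nn)),
                     stringsAsFactors = FALSE)
    df
  }))
  dropped <- nrow(ea_info) * length(inds) - nrow(out)
  if (dropped > 0)
    message(dropped, " EA x indicator cells omitted (zero eligible respondents)")
  out <- merge(ea_info, out, by = "ea_id")
  out[order(out$indicator, out$ea_id), ]
}

#' Per-arm mean and SD of EA prevalences
#'
#' Unweighted across EAs within arm, as in trial reports of "EA-level mean
#' risk % (sd)". With a single EA in an arm the SD is reported as missing.
#'
#' @param summaries output of [ea_prevalence()].
#' @return data frame with indicator, arm, n_ea, mean, sd.
#' @export
arm_summary <- function(summaries) {
  out <- do.call(rbind, lapply(split(summaries,
                                     list(summaries$indicator, summaries$arm),
                                     drop = TRUE), function(d) {
    data.frame(indicator = d$indicator[1], arm = d$arm[1], n_ea = nrow(d),
               mean = mean(d$prevalence),
               sd = if (nrow(d) > 1) stats::sd(d$prevalence) else NA_real_)
  }))
  rownames(out) <- NULL
  out[order(out$indicator, out$arm), ]
}

#' Adjusted mean difference in EA prevalence between arms
#'
#' EA-level linear model of prevalence on arm with community-pair fixed
#' effects, optionally adjusted for the EA's baseline prevalence of the same
#' indicator; the intervention effect estimator for community-level
#' (continuous) outcomes. The CI uses the t distribution on the model's
#' residual df. The adjustment actually applied is recorded in the result
#' since reported analyses do not always state it fully.
#'
#' @param summaries follow-up [ea_prevalence()] rows for a single indicator.
#' @param baseline_summaries optional baseline [ea_prevalence()] rows for the
#'   same indicator; matched to follow-up EAs by `ea_id`.
#' @param level confidence level.
#' @return list with estimate, se, lower, upper, df, n_ea, adjustment.
#' @export
adjusted_mean_difference <- function(summaries, baseline_summaries = NULL,
                                     level = 0.95) {
  ind <- unique(summaries$indicator)
  if (length(ind) != 1L)
    stop("summaries must cover exactly one indicator, got: ",
         paste(ind, collapse = ", "))
  d <- summaries
  if (length(unique(d$arm)) != 2L) stop("both arms required")
  if (any(tapply(d$arm, d$pair_id, function(a) length(unique(a))) < 2L))
    stop("every pair needs EAs in both arms")
  adjustment <- "community-pair fixed effects"
  if (!is.null(baseline_summaries)) {
    base <- baseline_summaries[baseline_summaries$indicator == ind,
                               c("ea_id", "prevalence")]
    names(base)[2] <- "baseline_prevalence"
    d <- merge(d, base, by = "ea_id")
    fit <- stats::lm(prevalence ~ arm + factor(pair_id) + baseline_prevalence,
                     data = d)
    adjustment <- paste(adjustment, "+ baseline EA prevalence")
  } else {
    fit <- stats::lm(prevalence ~ arm + factor(pair_id), data = d)
  }
  est <- stats::coef(fit)["arm"]
  # a perfect fit is legitimate here (flagged below), so silence summary.lm
  se <- sqrt(suppressWarnings(stats::vcov(fit))["arm", "arm"])
  df <- fit$df.residual
  tq <- stats::qt(1 - (1 - level) / 2, df)
  degenerate <- is.finite(se) && se < 1e-10
  list(indicator = ind, estimate = unname(est), se = unname(se),
       lower = unname(est - tq * se), upper = unname(est + tq * se),
       df = df, n_ea = nrow(d), adjustment = adjustment,
       degenerate = degenerate)
}

#' Attach an EA-level mediator prevalence to respondents as model exposure
#'
#' Each respondent receives the prevalence of the mediator in their own EA
#' (including themselves by default; a leave-one-out variant excludes the
#' respondent's own response), divided by `scale` so that the fitted risk
#' ratio is per `scale` percentage points (default 10, matching "per 10%
#' change in community prevalence").
#'
#' @param data respondent-level data frame with `ea_id`.
#' @param summaries [ea_prevalence()] rows for the mediator.
#' @param indicator mediator indicator name.
#' @param scale percentage points per exposure unit (default 10).
#' @param leave_one_out exclude the respondent's own response; requires
#'   `im` so the respondent's own state is known.
#' @param im the `indicator_matrix` (only needed for leave-one-out).
#' @return numeric exposure vector aligned with `data` rows; `NA` for
#'   respondents whose EA has no summary.
#' @export
attach_community_exposure <- function(data, summaries, indicator, scale = 10,
                                      leave_one_out = FALSE, im = NULL) {
  s <- summaries[summaries$indicator == indicator, ]
  if (!nrow(s)) stop("no EA summaries for indicator '", indicator, "'")
  idx <- match(data$ea_id, s$ea_id)
  prev <- s$prevalence[idx]
  if (leave_one_out) {
    if (is.null(im)) stop("leave_one_out requires the indicator matrix")
    own <- im$values[[indicator]][match(data$respondent_id,
                                        im$values$respondent_id)]
    n <- s$n[idx]
    nt <- s$n_true[idx]
    in_denom <- own %in% c("true", "false")
    loo <- ifelse(in_denom & n > 1,
                  100 * (nt - (own == "true")) / (n - 1),
                  prev)
    prev <- loo
  }
  prev / scale
}
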