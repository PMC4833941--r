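# Pair-matched cluster-level intention-to-treat risk-ratio estimator.
#
# Expected events per cluster come from an individual-level logistic model of
# the outcome on covariates only -- fitted pooled over both arms WITHOUT the
# arm term, so the per-cluster observed/expected ratio residuals carry the
# whole intervention contrast. Pair-level log ratios of intervention to
# control residuals are combined with size weights and a t-based CI on
# (pairs - 1) degrees of freedom, the standard cluster-summary device for
# pair-matched CRTs.

#' Observed and expected events per cluster
#'
#' @param fit a `crt_glm` logistic fit of the outcome on covariates (no arm
#'   term), from [fit_glm()].
#' @param data the data frame the model was fitted on (rows dropped by
#'   complete-case filtering are handled via the fit's row record).
#' @param site,pair,arm column names of the cluster (randomisation unit),
#'   pair and arm identifiers.
#' @return data frame with cluster, pair, arm, observed, expected, n;
#'   clusters whose members were all filtered out are absent.
#' @export
expected_events <- function(fit, data, site = "community_id",
                            pair = "pair_id", arm = "arm") {
  rows <- fit$rows_used
  cl <- as.character(data[[site]][rows])
  o <- tapply(fit$y, cl, sum)
  e <- tapply(fit$mu, cl, sum)
  n <- tapply(rep(1L, length(cl)), cl, sum)
  info <- unique(data.frame(cluster = as.character(data[[site]][rows]),
                            pair = as.character(data[[pair]][rows]),
                            arm = data[[arm]][rows],
                            stringsAsFactors = FALSE))
  out <- data.frame(cluster = names(o), observed = as.numeric(o),
                    expected = as.numeric(e), n = as.integer(n),
                    stringsAsFactors = FALSE)
  out <- merge(info, out, by = "cluster")
  out[order(out$pair, -out$arm), ]
}

#' Per-cluster ratio residuals O_j / E_j
#'
#' @param oe data frame from [expected_events()] (columns observed,
#'   expected).
#' @return the input with `ratio` added and a `zero_observed` flag; a zero
#'   expected count with nonzero observed is an error.
#' @export
ratio_residuals <- function(oe) {
  if (any(oe$expected <= 0))
    stop("non-positive expected events for cluster(s): ",
         paste(oe$cluster[oe$expected <= 0], collapse = ", "))
  oe$ratio <- oe$observed / oe$expected
  oe$zero_observed <- oe$observed == 0
  oe
}

#' Pair-matched combination of cluster ratio residuals into a risk ratio
#'
#' For each pair p the log ratio `l_p = log(R_int) - log(R_ctrl)` is formed;
#' the point estimate is the exponential of the size-weighted mean of the
#' `l_p` and the CI comes from the t distribution with (pairs - 1) df on the
#' weighted log ratios. Clusters with zero observed events get a 0.5
#' continuity correction added to both observed and expected counts (flagged
#' in the output). With a single pair only the point estimate is returned.
#'
#' @param residuals data frame from [ratio_residuals()].
#' @param weights `"pair"` (pair total sample size, default) or
#'   `"harmonic"` (harmonic mean of the two cluster sizes).
#' @param level confidence level.
#' @return an `effect_estimate` data frame row (term "arm") with the pair
#'   table attached as attribute `pairs`.
#' @export
paired_cluster_rr <- function(residuals, weights = c("pair", "harmonic"),
                              level = 0.95) {
  weights <- match.arg(weights)
  d <- residuals
  cc <- d$observed == 0
  if (any(cc)) {
    d$observed[cc] <- d$observed[cc] + 0.5
    d$expected[cc] <- d$expected[cc] + 0.5
    d$ratio[cc] <- d$observed[cc] / d$expected[cc]
  }
  pairs <- split(d, d$pair)
  tab <- do.call(rbind, lapply(pairs, function(p) {
    if (nrow(p) != 2L || length(unique(p$arm)) != 2L)
      stop("pair '", p$pair[1], "' must have exactly one cluster per arm")
    int <- p[p$arm == 1, ]
    ctl <- p[p$arm == 0, ]
    data.frame(pair = p$pair[1],
               log_ratio = log(int$ratio) - log(ctl$ratio),
               weight = switch(weights,
                               pair = int$n + ctl$n,
                               harmonic = 2 / (1 / int$n + 1 / ctl$n)),
               n = int$n + ctl$n,
               continuity = any(p$observed != round(p$observed)),
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  wm <- weighted_mean_ci(tab$log_ratio, tab$weight, level = level)
  out <- data.frame(term = "arm", estimate = exp(wm$mean),
                    lower = if (is.na(wm$se)) NA_real_ else exp(wm$lower),
                    upper = if (is.na(wm$se)) NA_real_ else exp(wm$upper),
                    se_log = wm$se, n = sum(tab$n),
                    n_clusters = nrow(d),
                    degenerate = !is.na(wm$se) && wm$se < 1e-10,
                    stringsAsFactors = FALSE)
  class(out) <- c("effect_estimate", "data.frame")
  attr(out, "pairs") <- tab
  attr(out, "continuity_corrected") <- any(cc)
  out
}

#' Adjusted cluster-level intention-to-treat risk ratio
#'
#' End-to-end composition: an individual-level logistic model of the outcome
#' on the covariates (pooled, no arm term) supplies expected events; clusters
#' are summarised by observed/expected ratio residuals; pair-level log
#' ratios are combined with size weights and a t-based CI.
#'
#' @param data follow-up analysis rows: one per eligible respondent, with a
#'   0/1 outcome column, design identifiers and covariate columns.
#' @param outcome outcome column name.
#' @param covariates character vector of adjustment columns (use
#'   `character(0)` for a crude, intercept-only expected-events model).
#' @param site,pair,arm identifier columns.
#' @param weights passed to [paired_cluster_rr()].
#' @param level confidence level.
#' @return an `effect_estimate` with attributes `residuals` (the cluster
#'   table) and `adjustment` (description of the covariate set).
#' @export
itt_effect <- function(data, outcome, covariates = c("age_group",
                                                     "marital_status",
                                                     "baseline_ipv_ea"),
                       site = "community_id", pair = "pair_id", arm = "arm",
                       weights = "pair", level = 0.95) {
  rhs <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  f <- stats::as.formula(paste(outcome, "~", rhs))
  fit <- fit_glm(f, data, link = "logit")
  oe <- expected_events(fit, data, site = site, pair = pair, arm = arm)
  res <- ratio_residuals(oe)
  est <- paired_cluster_rr(res, weights = weights, level = level)
  attr(est, "residuals") <- res
  attr(est, "adjustment") <-
    if (length(covariates)) paste(covariates, collapse = ", ") else "none (crude)"
  est
}

#' Decadal age groups used as the default age adjustment
#'
#' @param data data frame with an `age` column.
#' @return the data frame with an `age_group` factor (18-29, 30-39, 40-49).
#' @export
add_age_group <- function(data) {
  data$age_group <- cut(data$age, breaks = c(17, 29, 39, 49),
                        labels = c("18-29", "30-39", "40-49"))
  data
}

#' Baseline EA-level prevalence of an outcome, for adjustment
#'
#' Computes the percent prevalence of a 0/1 column per EA from the baseline
#' wave (among partnered respondents for IPV outcomes, since the outcome is
#' defined only for them).
#'
#' @param baseline baseline roster.
#' @param outcome 0/1 column name (NA allowed; rows with NA are excluded).
#' @return data frame ea_id, baseline prevalence (percent) named
#'   `baseline_<outcome>_ea`.
#' @export
baseline_ea_prevalence <- function(baseline, outcome = "ipv") {
  ok <- !is.na(baseline[[outcome]])
  p <- tapply(baseline[[outcome]][ok], baseline$ea_id[ok], mean)
  out <- data.frame(ea_id = names(p), prev = 100 * as.numeric(p),
                    stringsAsFactors = FALSE)
  names(out)[2] <- paste0("baseline_", outcome, "_ea")
  out
}
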