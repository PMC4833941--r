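# EA-level aggregation: prevalences, arm summaries, adjusted mean
# differences, ecological exposure attachment.

specs <- parse_indicator_specs(default_indicator_config())

test_that("prevalence arithmetic matches pooled hand calculations", {
  expect_equal(prevalence_pct(46, 504), 9.126984, tolerance = 1e-6)
  expect_equal(prevalence_pct(10, 10), 100)
  expect_true(is.nan(prevalence_pct(0, 0)))
})

test_that("EA prevalences conserve counts and handle degenerate EAs", {
  tr <- gen_quiet(small_config(seed = 31L), items = TRUE)
  im <- build_indicator_matrix(specs, tr$followup)
  eas <- suppressMessages(ea_prevalence(im))
  # aggregation conserves counts: EA numerators sum to the pooled numerator
  den <- im$denominators
  for (nm in c("ipv_experience", "att_accept_violence", "man_helps_house")) {
    pooled <- sum(den$n_true[den$indicator == nm])
    expect_equal(sum(eas$n_true[eas$indicator == nm]), pooled, info = nm)
  }
  expect_true(all(eas$prevalence >= 0 & eas$prevalence <= 100))
  # an all-true EA reads 100%
  one <- eas[eas$n == eas$n_true & eas$n > 0, ]
  if (nrow(one)) expect_true(all(one$prevalence == 100))
  # zero-eligible EAs are omitted with a note: male EAs carry no
  # ipv_experience cells at all
  expect_message(ea_prevalence(im, "ipv_experience"), "omitted")
  ipv_eas <- suppressMessages(ea_prevalence(im, "ipv_experience"))
  expect_true(all(ipv_eas$sex == "female"))
})

test_that("arm summaries reproduce hand-computed mean and SD", {
  s <- data.frame(ea_id = c("E1", "E2", "E3"), community_id = "C",
                  pair_id = "P1", arm = c(0L, 0L, 1L), sex = "female",
                  indicator = "x", n = 10L, n_true = 5L,
                  prevalence = c(40, 60, 50))
  a <- arm_summary(s)
  expect_equal(a$mean[a$arm == 0], 50)
  expect_equal(a$sd[a$arm == 0], sd(c(40, 60)), tolerance = 1e-6)
  expect_equal(a$sd[a$arm == 0], 14.14214, tolerance = 1e-4)
  # single EA in an arm: SD undefined, reported missing
  expect_true(is.na(a$sd[a$arm == 1]))
  # identical EAs: SD 0
  s$prevalence <- 50
  expect_equal(arm_summary(s)$mean, c(50, 50))
  expect_equal(arm_summary(s)$sd[1], 0)
})

make_ea_summaries <- function(prev, pairs = 2, eas = 3) {
  grid <- expand.grid(pair = seq_len(pairs), arm = c(0L, 1L),
                      ea = seq_len(eas))
  data.frame(ea_id = sprintf("P%dA%dE%d", grid$pair, grid$arm, grid$ea),
             community_id = sprintf("P%dA%d", grid$pair, grid$arm),
             pair_id = sprintf("P%d", grid$pair), arm = grid$arm,
             sex = "female", indicator = "x", n = 20L, n_true = 10L,
             prevalence = prev(grid))
}

test_that("adjusted mean difference: exact and degenerate cases", {
  # identical arms -> difference 0
  s0 <- make_ea_summaries(function(g) 50 + 3 * g$ea)
  md0 <- adjusted_mean_difference(s0)
  expect_equal(md0$estimate, 0, tolerance = 1e-10)
  # intervention exactly +10 over a pair-constant surface -> difference 10
  # with a perfect fit, flagged as degenerate
  s10 <- make_ea_summaries(function(g) 50 + 2 * g$pair + 10 * g$arm)
  md10 <- adjusted_mean_difference(s10)
  expect_equal(md10$estimate, 10, tolerance = 1e-10)
  expect_true(md10$degenerate)
  # +10 with EA-level noise: unbiased but not degenerate
  s10b <- make_ea_summaries(function(g) 50 + 3 * g$ea + 10 * g$arm)
  expect_equal(adjusted_mean_difference(s10b)$estimate, 10, tolerance = 1e-10)
  expect_false(adjusted_mean_difference(s10b)$degenerate)
  # exchangeable pairs, no baseline: equals simple difference of arm means
  set.seed(41)
  s <- make_ea_summaries(function(g) 50 + 8 * g$arm + rnorm(nrow(g), 0, 5))
  md <- adjusted_mean_difference(s)
  simple <- mean(s$prevalence[s$arm == 1]) - mean(s$prevalence[s$arm == 0])
  expect_equal(md$estimate, simple, tolerance = 1e-10)
  expect_match(md$adjustment, "pair")
  # structural failures
  expect_error(adjusted_mean_difference(s[s$arm == 0, ]), "both arms")
  expect_error(
    adjusted_mean_difference(rbind(s0[s0$indicator == "x", ],
                                   transform(s0, indicator = "y"))),
    "one indicator")
})

test_that("mean difference recovers the generator's known norm shift", {
  # oracle: expected arm difference in attitude prevalence implied by the
  # config's logit shift, by direct Monte-Carlo of the norm model
  cfg <- small_config(mediated_fraction = 0)
  set.seed(99)
  re <- rnorm(2e5, 0, sqrt(cfg$sigma_pair^2 + cfg$sigma_community^2)) +
    rnorm(2e5, 0, cfg$sigma_ea)
  oracle <- 100 * mean(plogis(cfg$norm_intercept + cfg$norm_shift + re) -
                         plogis(cfg$norm_intercept + re))
  ests <- vapply(1:100, function(s) {
    tr <- gen_quiet(small_config(seed = 7000L + s, mediated_fraction = 0))
    f <- tr$followup
    prev <- tapply(f$accepts_violence, f$ea_id, mean) * 100
    info <- unique(f[, c("ea_id", "community_id", "pair_id", "arm")])
    s_ea <- data.frame(info, sex = "both", indicator = "norm",
                       n = 1L, n_true = 0L,
                       prevalence = as.numeric(prev[info$ea_id]))
    adjusted_mean_difference(s_ea)$estimate
  }, numeric(1))
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - oracle), 3 * se)
})

test_that("community exposure attachment scales as documented", {
  s <- data.frame(ea_id = c("E1", "E2"), community_id = "C", pair_id = "P1",
                  arm = 0L, sex = "female", indicator = "x",
                  n = c(10L, 20L), n_true = c(3L, 10L),
                  prevalence = c(30, 50))
  d <- data.frame(respondent_id = c("a", "b", "c"),
                  ea_id = c("E1", "E2", "E9"))
  expect_equal(attach_community_exposure(d, s, "x", scale = 10),
               c(3, 5, NA))
  expect_equal(attach_community_exposure(d, s, "x", scale = 1),
               c(30, 50, NA))
  expect_error(attach_community_exposure(d, s, "nope"), "no EA summaries")
})

test_that("leave-one-out exposure removes the respondent's own response", {
  r <- data.frame(
    respondent_id = c("a", "b", "c", "d"),
    pair_id = "P1", community_id = "C01", ea_id = "C01_E01",
    arm = 0L, sex = "female", intervene_ok = c("yes", "yes", "no", "no"),
    stringsAsFactors = FALSE)
  spec <- parse_indicator_specs(write_yaml_config(c(
    "indicators:",
    "  - name: x", "    level: community",
    "    rule: {kind: value_in, items: [intervene_ok], values: ['yes']}")))
  im <- build_indicator_matrix(spec, r)
  s <- suppressMessages(ea_prevalence(im))
  full <- attach_community_exposure(r, s, "x", scale = 1)
  loo <- attach_community_exposure(r, s, "x", scale = 1,
                                   leave_one_out = TRUE, im = im)
  expect_equal(full, rep(50, 4))
  expect_equal(loo, c(100 / 3, 100 / 3, 200 / 3, 200 / 3))
})

test_that("per-10% risk ratio equals the per-1% risk ratio to the 10th power", {
  tr <- gen_quiet(small_config(seed = 32L, mediated_fraction = 1))
  d <- mediation_frame(tr$followup, tr$baseline, "women")
  d <- attach_latent_norm(d, tr$followup)       # per 10 points
  d$med_norm1 <- d$med_norm * 10                # per 1 point
  rr10 <- risk_factor_association(d, "med_norm")
  rr1 <- risk_factor_association(d, "med_norm1")
  expect_equal(rr10$estimate, rr1$estimate^10, tolerance = 1e-6)
})
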