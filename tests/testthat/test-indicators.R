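# Indicator engine: parsing, tri-state evaluation, eligibility denominators,
# missingness policy, serialisation.

# hand-built roster: all items at innocuous defaults, overridable per column
make_roster <- function(n, ...) {
  dict <- item_dictionary()
  df <- data.frame(
    respondent_id = sprintf("R%03d", seq_len(n)),
    pair_id = rep("P1", n), community_id = rep("C01", n),
    ea_id = rep("C01_E01", n), arm = rep(0L, n), sex = rep("female", n),
    age = rep(30L, n),
    marital_status = rep("married", n), education = rep("primary", n),
    childhood_abuse = rep(0L, n), partnered_past_year = rep(1L, n),
    cohabiting = rep(1L, n),
    witnessed_ipv = rep(0L, n), polygamous = rep(0L, n),
    stringsAsFactors = FALSE)
  for (it in names(dict)) {
    df[[it]] <- rep(if ("no" %in% dict[[it]]) "no" else dict[[it]][1], n)
  }
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  df
}

specs <- parse_indicator_specs(default_indicator_config())

test_that("default config covers both outcomes and the full mediator battery", {
  lv <- vapply(specs, `[[`, "", "level")
  expect_equal(sum(lv == "outcome"), 2L)
  expect_gte(sum(lv != "outcome"), 24L)
  # the 12-scenario acceptability battery is encoded
  expect_length(specs$comm_accept_violence$rules$both$items, 12L)
  # the men's anonymous-card measure is reporter-stratified
  expect_equal(specs$ipv_perpetration$reporter, "men")
  expect_equal(specs$ipv_perpetration$rules$both$items, "card_violence")
})

test_that("malformed configs are rejected with the offending spec named", {
  expect_error(parse_indicator_specs(write_yaml_config(c(
    "indicators:",
    "  - name: bad_item", "    level: individual",
    "    rule: {kind: value_in, items: [no_such_item], values: ['yes']}"))),
    "bad_item.*no_such_item")
  expect_error(parse_indicator_specs(write_yaml_config(c(
    "indicators:",
    "  - name: empty_rule", "    level: individual",
    "    rule: {kind: any_of, items: [], values: ['yes']}"))),
    "empty_rule.*>= 1 items")
  expect_error(parse_indicator_specs(write_yaml_config(c(
    "indicators:",
    "  - name: bad_value", "    level: individual",
    "    rule: {kind: value_in, items: [drunk_freq], values: [sometimes]}"))),
    "bad_value.*not admissible")
  expect_error(parse_indicator_specs(write_yaml_config(c(
    "indicators:",
    "  - name: dup", "    level: individual",
    "    rule: {kind: value_in, items: [intervene_ok], values: ['yes']}",
    "  - name: dup", "    level: individual",
    "    rule: {kind: value_in, items: [condom_ok], values: ['yes']}"))),
    "duplicate")
})

test_that("act-list outcome follows the at-least-one rule with eligibility", {
  r <- make_roster(4,
    act_kick = c("yes", "no", "no", "no"),
    partnered_past_year = c(1L, 1L, 0L, 1L),
    sex = c("female", "female", "female", "male"))
  st <- evaluate_indicator(specs$ipv_experience, r)
  expect_equal(st, c("true", "false", "ineligible", "ineligible"))
})

test_that("missingness policy distinguishes missing from false and ineligible", {
  # any_of: missing responses are non-qualifying unless all are missing
  r <- make_roster(3)
  acts <- grep("^act_", names(r), value = TRUE)
  for (a in acts) r[[a]] <- c(NA, NA, NA)
  r$act_slap <- c("yes", "no", NA)
  st <- evaluate_indicator(specs$ipv_experience, r)
  expect_equal(st, c("true", "false", "missing"))
  # all_of: any missing component makes the indicator missing
  r2 <- make_roster(3,
    discuss_day_self = c("yes", NA, "yes"),
    discuss_day_partner = c("yes", "yes", "no"))
  expect_equal(evaluate_indicator(specs$discuss_day, r2),
               c("true", "missing", "false"))
  # single item: missing -> missing
  r3 <- make_roster(2, discuss_worries = c(NA, "yes"))
  expect_equal(evaluate_indicator(specs$discuss_worries, r3),
               c("missing", "true"))
})

test_that("applicability flags yield ineligible, distinct from eligibility", {
  r <- make_roster(3,
    appreciate_house = c("many", "many", "none"),
    appreciate_house_applicable = c("yes", "no", "yes"))
  expect_equal(evaluate_indicator(specs$appreciate_house, r),
               c("true", "ineligible", "false"))
})

test_that("reporter-specific finance rules encode both phrasings", {
  r <- make_roster(4,
    sex = c("female", "female", "male", "male"),
    fin_participated = c("yes", "no", NA, NA),
    fin_sole_control = c(NA, NA, "no", "yes"))
  expect_equal(evaluate_indicator(specs$finances_joint, r),
               c("true", "false", "true", "false"))
})

test_that("composite rule requires the response AND a qualifying action", {
  r <- make_roster(4,
    witnessed_ipv = c(1L, 1L, 1L, 0L),
    witness_helped = c("yes", "yes", "no", "yes"),
    resp_knocked = c("yes", "no", "yes", "yes"))
  expect_equal(evaluate_indicator(specs$comm_responded, r),
               c("true", "false", "false", "ineligible"))
})

test_that("matrix denominators count only eligible, evaluated respondents", {
  r <- make_roster(10, partnered_past_year = c(rep(1L, 4), rep(0L, 6)))
  im <- build_indicator_matrix(specs, r)
  den <- im$denominators
  expect_equal(den$denominator[den$indicator == "ipv_experience" &
                                 den$sex == "female"], 4L)
  # men's perpetration indicator: all-female roster -> every cell ineligible
  expect_true(all(im$values$ipv_perpetration == "ineligible"))
  expect_equal(den$denominator[den$indicator == "ipv_perpetration" &
                                 den$sex == "female"], 0L)
})

test_that("duplicate respondent ids are a hard error; empty rosters work", {
  r <- make_roster(2)
  r$respondent_id <- c("A", "A")
  expect_error(build_indicator_matrix(specs, r), "duplicate respondent")
  im0 <- build_indicator_matrix(specs, make_roster(0))
  expect_equal(nrow(im0$values), 0L)
  expect_equal(sum(im0$denominators$denominator), 0L)
})

test_that("every cell takes exactly one of the four states", {
  tr <- gen_quiet(small_config(seed = 21L), items = TRUE)
  im <- build_indicator_matrix(specs, tr$followup)
  for (nm in names(specs)) {
    expect_true(all(im$values[[nm]] %in%
                      c("true", "false", "ineligible", "missing")), info = nm)
  }
  # denominator identity: true + false
  den <- im$denominators
  expect_equal(den$denominator, den$n_true + den$n_false)
})

test_that("adding a qualifying response never flips an any_of true to false", {
  tr <- gen_quiet(small_config(seed = 22L), items = TRUE)
  r <- tr$followup
  before <- evaluate_indicator(specs$att_accept_violence, r)
  flip <- sample(nrow(r), 200)
  r$att_angry[flip] <- "yes"
  after <- evaluate_indicator(specs$att_accept_violence, r)
  expect_false(any(before == "true" & after == "false"))
  expect_true(all(after[flip][before[flip] %in% c("true", "false")] == "true"))
})

test_that("serialised matrices are idempotent under re-serialisation", {
  tr <- gen_quiet(small_config(seed = 23L), items = TRUE)
  im <- build_indicator_matrix(specs, tr$followup)
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_indicator_matrix(im, p1)
  im2 <- read_indicator_matrix(p1, specs)
  write_indicator_matrix(im2, p2)
  expect_identical(readLines(p1), readLines(p2))
  # prevalences survive the round trip
  d1 <- im$denominators; d2 <- im2$denominators
  expect_equal(d1$prevalence, d2$prevalence)
})
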