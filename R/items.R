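# Item dictionary: every survey item an indicator rule may reference, with
# its admissible response values. Missing responses are NA.

#' Survey item dictionary
#'
#' @return a named list mapping item code to the character vector of
#'   admissible response values.
#' @export
item_dictionary <- function() {
  yn <- c("yes", "no")
  freq3 <- c("none", "few", "many")
  freq4 <- c("never", "sometimes", "most", "all")
  drunk <- c("never", "less_monthly", "monthly", "weekly", "most_days")
  items <- list()
  for (it in paste0("att_", c("disobeys", "answers_back", "disrespects",
                              "suspects", "unfaithful", "gossips", "neglects",
                              "housework", "refuses_sex", "accuses", "secrets",
                              "angry")))
    items[[it]] <- yn
  for (it in paste0("act_", c("slap", "push", "fist", "kick", "choke",
                              "weapon", "stick")))
    items[[it]] <- yn
  items$card_violence <- yn
  items$intervene_ok <- yn
  items$witness_helped <- yn
  for (it in paste0("resp_", c("gathered", "knocked", "separated", "authority",
                               "advised_woman", "asked_woman", "told_man",
                               "referred_man", "helped_man")))
    items[[it]] <- yn
  items$refuse_sex_ok <- yn
  items$condom_ok <- yn
  items$respect_joint <- yn
  items$man_decides_work <- yn
  items$tell_others_ok <- yn
  items$discuss_day_self <- yn
  items$discuss_day_partner <- yn
  items$discuss_worries <- yn
  items$sex_asked <- yn
  items$sex_told <- yn
  items$appreciate_house <- freq3
  items$appreciate_house_applicable <- yn
  items$appreciate_outside <- freq3
  items$appreciate_outside_applicable <- yn
  items$joint_decisions <- freq4
  items$man_helps_house <- yn
  items$refused_job <- yn
  items$fin_participated <- yn
  items$fin_sole_control <- yn
  items$other_partner <- yn
  items$partner_suspicious <- yn
  items$separated_past_year <- yn
  items$drunk_freq <- drunk
  items$told_someone <- yn
  items
}

# Eligibility flags that may appear in an indicator's eligibility list.
# "outcome" is special: it resolves to the reporter's IPV outcome indicator.
ELIGIBILITY_FLAGS <- c("partnered_past_year", "cohabiting", "witnessed_ipv",
                       "non_polygamous", "outcome")
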