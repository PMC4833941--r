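# Default indicator configuration: the IPV outcomes and the candidate
# community-, relationship- and individual-level mediators, as composite
# rules over item-level survey responses.
#
# Community-level entries are respondent-level indicators that the
# aggregation stage turns into EA-level prevalences (the ecological
# exposure); several intentionally share items with their individual-level
# counterparts (a norm is the aggregate of individual attitudes).
indicators:
  # ---- IPV outcomes -------------------------------------------------------
  - name: ipv_experience
    label: "Past-year experience of physical IPV (women)"
    level: outcome
    reporter: women
    eligibility: [partnered_past_year]
    rule:
      kind: any_of
      items: [act_slap, act_push, act_fist, act_kick, act_choke, act_weapon, act_stick]
      values: ["yes"]
  - name: ipv_perpetration
    label: "Past-year perpetration of IPV, anonymous card (men)"
    level: outcome
    reporter: men
    eligibility: [partnered_past_year]
    rule:
      kind: value_in
      items: [card_violence]
      values: ["yes"]

  # ---- Community-level mediators (EA-aggregated) --------------------------
  - name: comm_intervene_ok
    label: "Okay for others to intervene if IPV is occurring"
    level: community
    rule: {kind: value_in, items: [intervene_ok], values: ["yes"]}
  - name: comm_responded
    label: "Witnesses of IPV who responded appropriately"
    level: community
    eligibility: [witnessed_ipv]
    rule:
      kind: composite
      rules:
        - {kind: value_in, items: [witness_helped], values: ["yes"]}
        - kind: any_of
          items: [resp_gathered, resp_knocked, resp_separated, resp_authority,
                  resp_advised_woman, resp_asked_woman, resp_told_man,
                  resp_referred_man, resp_helped_man]
          values: ["yes"]
  - name: comm_accept_violence
    label: "Acceptable for a man to use violence against his partner (norm)"
    level: community
    rule:
      kind: any_of
      items: [att_disobeys, att_answers_back, att_disrespects, att_suspects,
              att_unfaithful, att_gossips, att_neglects, att_housework,
              att_refuses_sex, att_accuses, att_secrets, att_angry]
      values: ["yes"]
  - name: comm_refuse_sex_ok
    label: "Acceptable for a woman to refuse sex (norm)"
    level: community
    rule: {kind: value_in, items: [refuse_sex_ok], values: ["yes"]}
  - name: comm_condom_ok
    label: "Okay for a woman to ask her husband to use a condom (norm)"
    level: community
    rule: {kind: value_in, items: [condom_ok], values: ["yes"]}
  - name: comm_respect_joint
    label: "Community would respect a man deciding jointly with his wife (norm)"
    level: community
    rule: {kind: value_in, items: [respect_joint], values: ["yes"]}
  - name: comm_man_decides_work
    label: "Man's role to decide if his wife can work (norm)"
    level: community
    rule: {kind: value_in, items: [man_decides_work], values: ["yes"]}

  # ---- Relationship-level mediators (partnered in past year) --------------
  - name: discuss_day
    label: "Discuss things that happen in the day"
    level: relationship
    eligibility: [partnered_past_year]
    rule:
      kind: all_of
      items: [discuss_day_self, discuss_day_partner]
      values: ["yes"]
  - name: discuss_worries
    label: "Discuss worries"
    level: relationship
    eligibility: [partnered_past_year]
    rule: {kind: value_in, items: [discuss_worries], values: ["yes"]}
  - name: discuss_sex
    label: "Discuss what you both like during sex"
    level: relationship
    eligibility: [partnered_past_year]
    rule:
      kind: all_of
      items: [sex_asked, sex_told]
      values: ["yes"]
  - name: appreciate_house
    label: "Appreciates work partner does around the house (where applicable)"
    level: relationship
    eligibility: [partnered_past_year]
    applicability: [appreciate_house_applicable]
    rule: {kind: value_in, items: [appreciate_house], values: [many]}
  - name: appreciate_outside
    label: "Appreciates work partner does outside the house (where applicable)"
    level: relationship
    eligibility: [partnered_past_year]
    applicability: [appreciate_outside_applicable]
    rule: {kind: value_in, items: [appreciate_outside], values: [many]}
  - name: joint_decisions
    label: "Joint decision making most or all of the time"
    level: relationship
    eligibility: [partnered_past_year]
    rule: {kind: value_in, items: [joint_decisions], values: [most, all]}
  - name: man_helps_house
    label: "Man helps around the house (cohabiting couples)"
    level: relationship
    eligibility: [partnered_past_year, cohabiting]
    rule: {kind: value_in, items: [man_helps_house], values: ["yes"]}
  - name: refused_job
    label: "Woman refused a job because her husband didn't want her to work"
    level: relationship
    eligibility: [partnered_past_year]
    rule: {kind: value_in, items: [refused_job], values: ["yes"]}
  - name: finances_joint
    label: "Woman participated in deciding how finances are spent (cohabiting)"
    level: relationship
    eligibility: [partnered_past_year, cohabiting]
    rule_by_reporter:
      women: {kind: value_in, items: [fin_participated], values: ["yes"]}
      men: {kind: negation, items: [fin_sole_control], values: ["yes"]}
  - name: concurrent_partners
    label: "Concurrent sexual partners (non-polygamous partnered)"
    level: relationship
    eligibility: [partnered_past_year, non_polygamous]
    rule: {kind: value_in, items: [other_partner], values: ["yes"]}
  - name: partner_suspicious
    label: "Male partner often suspicious that female partner is unfaithful"
    level: relationship
    eligibility: [partnered_past_year]
    rule: {kind: value_in, items: [partner_suspicious], values: ["yes"]}
  - name: separated
    label: "Separated or divorced in the past year"
    level: relationship
    eligibility: [partnered_past_year]
    rule: {kind: value_in, items: [separated_past_year], values: ["yes"]}

  # ---- Individual-level mediators -----------------------------------------
  - name: att_accept_violence
    label: "Acceptable for a man to use violence against his partner (attitude)"
    level: individual
    rule:
      kind: any_of
      items: [att_disobeys, att_answers_back, att_disrespects, att_suspects,
              att_unfaithful, att_gossips, att_neglects, att_housework,
              att_refuses_sex, att_accuses, att_secrets, att_angry]
      values: ["yes"]
  - name: att_tell_others
    label: "Okay for a woman to tell others if experiencing violence"
    level: individual
    rule: {kind: value_in, items: [tell_others_ok], values: ["yes"]}
  - name: att_refuse_sex
    label: "Acceptable for a woman to refuse sex (attitude)"
    level: individual
    rule: {kind: value_in, items: [refuse_sex_ok], values: ["yes"]}
  - name: att_condom
    label: "Okay for a woman to ask her husband to use a condom (attitude)"
    level: individual
    rule: {kind: value_in, items: [condom_ok], values: ["yes"]}
  - name: att_respect_joint
    label: "Others would respect a man deciding jointly with his wife (attitude)"
    level: individual
    rule: {kind: value_in, items: [respect_joint], values: ["yes"]}
  - name: att_man_decides_work
    label: "Man's role to decide if his wife can work (attitude)"
    level: individual
    rule: {kind: value_in, items: [man_decides_work], values: ["yes"]}
  - name: drunk_monthly
    label: "Drunk at least once a month"
    level: individual
    rule: {kind: value_in, items: [drunk_freq], values: [monthly, weekly, most_days]}
  - name: told_someone
    label: "Experiencing/perpetrating IPV and has told someone"
    level: individual
    eligibility: [outcome]
    rule: {kind: value_in, items: [told_someone], values: ["yes"]}
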