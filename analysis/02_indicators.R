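#!/usr/bin/env Rscript
# Stage 2: turn item-level responses into the composite indicators (both IPV
# outcomes and 27 candidate mediators), check the rosters, and aggregate the
# community-level indicators to EA prevalences.

library(crtpathways)

baseline <- validate_roster(read_roster_csv("results/roster_baseline.csv"))$data
followup <- validate_roster(read_roster_csv("results/roster_followup.csv"))$data

specs <- parse_indicator_specs(default_indicator_config())
im_base <- build_indicator_matrix(specs, baseline)
im_fol <- build_indicator_matrix(specs, followup)

write_indicator_matrix(im_base, "results/indicators_baseline.csv")
write_indicator_matrix(im_fol, "results/indicators_followup.csv")
write.csv(im_fol$denominators, "results/indicator_denominators.csv",
          row.names = FALSE)
write.csv(ea_prevalence(im_fol), "results/ea_summaries_followup.csv",
          row.names = FALSE)
write.csv(ea_prevalence(im_base), "results/ea_summaries_baseline.csv",
          row.names = FALSE)

den <- im_fol$denominators
ipv_w <- den[den$indicator == "ipv_experience" & den$sex == "female", ]
ipv_m <- den[den$indicator == "ipv_perpetration" & den$sex == "male", ]
cat("Indicator matrices written to results/\n")
cat(sprintf("  %d indicators evaluated for %d follow-up respondents\n",
            length(specs), nrow(im_fol$values)))
cat(sprintf("  women's IPV prevalence: %d/%d (%.0f%%); men's: %d/%d (%.0f%%)\n",
            ipv_w$n_true, ipv_w$denominator, ipv_w$prevalence,
            ipv_m$n_true, ipv_m$denominator, ipv_m$prevalence))
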