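#!/usr/bin/env Rscript
# Step 2 — mine significant predictive combinations (Protocol 1).
#
# Randomly allocates 32,547 of the 308,205 simulated persons to the
# analysis cohort, binarizes them with the guideline scheme (36 items),
# calibrates the Tarone support threshold, tests every combination of up
# to four items carried by at least 10 people with the one-sided Fisher
# exact test at the Bonferroni level alpha / k_D(sigma*), and drops
# combinations containing a simpler significant one. The validation
# cohort is untouched by any of this.

suppressMessages(library(lamprisk))

seed_split <- 20260930L
cohort <- read_cohort_csv("scratch/cohort.csv")
parts <- split_cohort(cohort, fraction = 32547 / 308205, seed = seed_split)
message("analysis cohort: ", nrow(parts$analysis),
        " persons, ", sum(parts$analysis$outcome), " events")

ds <- labeled_dataset_from_cohort(parts$analysis,
                                  default_binarization_scheme())
t0 <- Sys.time()
rules <- lamp_mine(ds, alpha = 0.05, max_arity = 4, support_floor = 10)
message(sprintf("mining done in %.1f s", as.numeric(Sys.time() - t0,
                                                    units = "secs")))
print(rules)

prov <- list(seed_split = seed_split, alpha = 0.05, max_arity = 4,
             support_floor = 10)
write_rules_json(rules, "results/rules.json", provenance = prov)
flat <- rules$rules
if (nrow(flat) > 0) flat$condition <- NULL
data.table::fwrite(flat, "results/rules.csv")
message("wrote results/rules.json, results/rules.csv")
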