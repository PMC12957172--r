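#!/usr/bin/env Rscript
# Stage 4 — pairwise co-occurrence and SCI cut-off per subgroup.
#
# For each diabetes-type x sex subgroup: exact 2x2 contingency counts for
# every retained condition pair, SCI / phi / t statistics, and the
# data-driven SCI cut-off (q positive pairs; e pairs passing t > 1.96 and
# joint count above the mean; top-e by SCI kept as significant edges).

library(mmnet)

cohort <- readRDS("results/cache/02_cohort.rds")
assoc <- stage_associate(cohort)
saveRDS(assoc, "results/cache/04_assoc.rds")

dir.create("results/pairs", recursive = TRUE, showWarnings = FALSE)
for (sg in names(assoc)) {
  a <- assoc[[sg]]
  write.csv(a$pairs, sprintf("results/pairs/pairs_%s.csv", sg),
            row.names = FALSE)
  jsonlite::write_json(a$cutoff[c("q", "e", "sci_cutoff")],
                       sprintf("results/pairs/cutoff_%s.json", sg),
                       auto_unbox = TRUE, digits = NA)
  message(sprintf("%s: N=%d, q=%d, e=%d, cutoff=%s", sg, a$N,
                  a$cutoff$q, a$cutoff$e, format(a$cutoff$sci_cutoff)))
}
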