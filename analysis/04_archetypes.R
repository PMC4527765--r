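#!/usr/bin/env Rscript
# Classify the structure of each feature's relationship to Cell Speed and
# to CMD: quintile stratification, pairwise Wilcoxon tests (1v3, 3v5, 1v5)
# with Bonferroni correction, and mapping of the significance triple to one
# of seven archetypes. Compares the recovered archetypes to the planted
# ground truth.

suppressPackageStartupMessages(library(cmdyn))

tab <- utils::read.csv(file.path("results", "table_with_cmd.csv"))
truth <- utils::read.csv(file.path("results", "table", "ground_truth.csv"))
features <- truth$feature

for (proc in c("speed", "cmd")) {
  res <- archetype_classify(tab, proc, features)
  message(sprintf("%s: %d/%d features with at least one significant contrast",
                  proc, res$n_related, length(features)))
  print(res$venn)
  utils::write.csv(res$results,
                   file.path("results", sprintf("archetypes_%s.csv", proc)),
                   row.names = FALSE)
  jsonlite::write_json(as.list(res$venn),
                       file.path("results", sprintf("venn_%s.json", proc)),
                       auto_unbox = TRUE)
  planted <- truth$feature[truth$process %in% c(proc, "both")]
  hit <- res$results$feature[res$results$category != "none"]
  message(sprintf("  planted %s-linked features recovered: %d/%d (spurious: %d)",
                  proc, length(intersect(planted, hit)), length(planted),
                  length(setdiff(hit, planted))))
}
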