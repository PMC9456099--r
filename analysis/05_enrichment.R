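#!/usr/bin/env Rscript
# Step 5 — hypergeometric over-representation of each gene category from
# step 2 against the study's annotation table (universe = all annotated
# genes). Ontology-style calls use BH-corrected q < 0.05; pathway-style
# calls use raw p < 0.05 (both conventions are computed here for the CQEG
# set). The planted term should top the CQEG ranking.

library(omegascan)

ann <- annotation_table("results/study/annotations.tsv")
for (cat in c("qeg", "cqeg")) {
  genes <- readLines(file.path("results/branch_scan", paste0(cat, ".txt")))
  if (length(genes) == 0L) { message(toupper(cat), ": empty set"); next }
  res_bh <- enrich(genes, ann, alpha = 0.05, correction = "BH")
  res_raw <- enrich(genes, ann, alpha = 0.05, correction = "none")
  out <- file.path("results", paste0("enrichment_", cat, ".tsv"))
  write.table(res_bh, out, sep = "\t", quote = FALSE, row.names = FALSE)
  message(toupper(cat), " (", length(genes), " genes): top term ",
          res_bh$term[1], "  q = ", signif(res_bh$q[1], 3),
          "  [BH-significant: ", res_bh$significant[1],
          "; raw-p rule: ", res_raw$significant[1], "]")
}
message("tables in results/enrichment_*.tsv")
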