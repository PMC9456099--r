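#!/usr/bin/env Rscript
# Step 1 — build the synthetic ortholog study every later step consumes:
# 50 single-copy genes (300 codons) evolved on the fixed 8-taxon species
# tree with two non-sister highland lineages (C, E). Five genes carry
# foreground acceleration (omega_fg = 5 vs background 0.2), three genes
# carry planted amino-acid replacement events, and an annotation table
# plants one term shared by the accelerated genes. Ground truth is written
# alongside so downstream steps can score themselves.

library(omegascan)

out <- "results/study"
cfg <- default_study_config(seed = 1L)
study <- generate_study(cfg, out)

message("study written to ", out)
message("genes: ", cfg$n_genes, " (", cfg$n_selected, " accelerated, omega_fg = ",
        cfg$omega_fg, ")")
message("planted events:")
print(study$truth_events)
message("planted enrichment term: ", cfg$planted_term)
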