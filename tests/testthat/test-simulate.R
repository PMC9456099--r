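test_that("zero branch lengths copy the root to every taxon", {
  tr <- read_species_tree(text = "((A:0,B:0):0,(C:0,D:0):0);")
  aln <- simulate_codon_alignment(tr, 50, list(type = "null", omega = 1),
                                  seed = 61)
  expect_equal(length(unique(aln$seqs)), 1L)
})

test_that("simulation is byte-deterministic given a seed", {
  tr <- default_study_tree()
  a1 <- simulate_codon_alignment(tr, 100, list(type = "null", omega = 0.5),
                                 seed = 62)
  a2 <- simulate_codon_alignment(tr, 100, list(type = "null", omega = 0.5),
                                 seed = 62)
  expect_identical(a1$seqs, a2$seqs)
})

test_that("long-run codon frequencies approach the stationary distribution", {
  ## two taxa joined by a very long path: sampled codons are draws from pi
  tr <- read_species_tree(text = "(A:25,B:25);")
  pi <- default_codon_pi()
  aln <- simulate_codon_alignment(tr, 5000, list(type = "null", omega = 1),
                                  pi = pi, seed = 63)
  obs <- table(factor(c(split_codons(aln$seqs[["A"]]),
                        split_codons(aln$seqs[["B"]])),
                      levels = names(pi)))
  gof <- suppressWarnings(stats::chisq.test(as.numeric(obs), p = pi))
  expect_gt(gof$p.value, 0.01)
})

test_that("one-step simulated transitions match the transition matrix rows", {
  ## evolve many sites one branch from a fixed parent state and compare the
  ## child distribution with the corresponding P(t) row (simulator and
  ## likelihood engine share this matrix implementation)
  code <- genetic_code()
  pi <- default_codon_pi()
  eig <- rate_matrix_eigen(build_rate_matrix(2, 0.5, pi), pi)
  P <- transition_probabilities(eig, 0.15)
  set.seed(64)
  for (st in c(1L, 30L, 61L)) {
    kids <- omegascan:::evolve_states(rep(st, 30000L), P)
    obs <- tabulate(kids, 61L)
    keep <- P[st, ] > 1e-5
    gof <- suppressWarnings(
      stats::chisq.test(obs[keep], p = P[st, keep] / sum(P[st, keep])))
    expect_gt(gof$p.value, 0.01)
  }
})

test_that("counting-based dN/dS from two-taxon simulations is monotone in omega", {
  ## crude counting estimate: proportion of nonsynonymous vs synonymous
  ## differing codon pairs, normalised by the neutral expectation
  tr <- read_species_tree(text = "(A:0.15,B:0.15);")
  code <- genetic_code()
  ratio <- vapply(c(0.2, 1, 5), function(om) {
    aln <- simulate_codon_alignment(tr, 4000, list(type = "null", omega = om),
                                    seed = 65 + om * 10)
    ca <- split_codons(aln$seqs[["A"]])
    cb <- split_codons(aln$seqs[["B"]])
    diff1 <- mapply(function(x, y) sum(strsplit(x, "")[[1]] !=
                                         strsplit(y, "")[[1]]), ca, cb) == 1L
    aa_a <- translate_codons(ca); aa_b <- translate_codons(cb)
    sum(diff1 & aa_a != aa_b) / sum(diff1 & aa_a == aa_b)
  }, numeric(1))
  expect_true(ratio[1] < ratio[2] && ratio[2] < ratio[3])
})

test_that("planted substitutions round-trip through the screens", {
  set.seed(66)
  tr <- default_study_tree()
  aln <- simulate_codon_alignment(tr, 60, list(type = "null", omega = 0.2),
                                  gene_id = "gX")
  p1 <- plant_substitution(aln, 10L, "convergent", c("C", "E"), "S", "P")
  conv <- find_convergent_substitutions(p1, c("C", "E"))
  expect_true(10L %in% conv$column)
  expect_equal(conv$focal_res[conv$column == 10L], "P")
  p2 <- plant_substitution(aln, 20L, "lineage_specific", "C", "D", "E")
  ls <- find_lineage_specific_substitutions(p2, "C")
  expect_true(20L %in% ls$column)
  expect_error(plant_substitution(aln, 10L, "convergent", "C", "S", "P"),
               "two focal taxa")
  expect_error(plant_substitution(aln, 999L, "lineage_specific", "C", "S", "P"))
})

test_that("study generation writes a complete, reproducible dataset", {
  cfg <- default_study_config(n_genes = 6L, n_selected = 2L, n_codons = 30L,
                              seed = 67L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- generate_study(cfg, d1)
  s2 <- generate_study(cfg, d2)
  expect_equal(nrow(s1$truth_regimes), 6L)
  expect_identical(s1$truth_regimes$gene_id[s1$truth_regimes$regime == "branch"],
                   c("gene_001", "gene_002"))
  ## same seed, same bytes
  for (f in c("annotations.tsv", "tree.nwk", "truth_regimes.tsv",
              file.path("alignments", "gene_003.fasta")))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  ## planted events recorded and the planted term covers the selected genes
  expect_equal(nrow(s1$truth_events), 3L)
  ann <- annotation_table(file.path(d1, "annotations.tsv"))
  expect_true(all(c("gene_001", "gene_002") %in%
                    ann$term_genes[[cfg$planted_term]]))
  expect_setequal(ann$universe, sprintf("gene_%03d", 1:6))
})
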