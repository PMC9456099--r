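test_that("codon alignment validation enforces shape, frame and alphabet", {
  aln <- codon_alignment(c(a = "ATGGGT---", b = "ATGGGCAAA"))
  expect_equal(aln$n_codons, 3L)
  expect_error(codon_alignment(c(a = "ATGGGT", b = "ATGGGCAAA")), "ragged")
  expect_error(codon_alignment(c(a = "ATGG", b = "ATGC")), "frame")
  expect_error(codon_alignment(c(a = "ATGQGT", b = "ATGGGT")), "invalid")
  expect_error(codon_alignment(c(a = "ATGGGT", a = "ATGGGC")), "duplicated")
})

test_that("internal stop codons are rejected with taxon and codon index, terminal stops pass", {
  expect_error(
    codon_alignment(c(a = "ATGTAAGGGCCCAAA", b = "ATGCCCGGGCCCAAA")),
    "taxon 'a' at codon 2")
  expect_silent(codon_alignment(c(a = "ATGCCCTAA", b = "ATGCCCTGA")))
})

test_that("FASTA read/write round-trips alignments byte-stably", {
  set.seed(1)
  code <- genetic_code()
  seqs <- vapply(1:4, function(i)
    paste(sample(code$sense_codons, 300, replace = TRUE), collapse = ""),
    character(1))
  names(seqs) <- paste0("sp", 1:4)
  aln <- codon_alignment(seqs, "g1")
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_codon_alignment(aln, f1)
  back <- read_codon_alignment(f1, gene_id = "g1")
  expect_identical(back$seqs, aln$seqs)
  write_codon_alignment(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("back-translation inverts translation and validates input", {
  expect_identical(
    back_translate(c(x = "M-K"), c(x = "ATGAAA"))$seqs[["x"]], "ATG---AAA")
  expect_identical(
    back_translate(c(x = "MK"), c(x = "ATGAAG"))$seqs[["x"]], "ATGAAG")
  expect_error(back_translate(c(x = "MK"), c(x = "ATGATGAAA")), "mismatch")
  expect_error(back_translate(c(x = "MKW"), c(x = "ATGAAA")), "length mismatch")
  ## round trip on random gap-free proteins
  set.seed(42)
  code <- genetic_code()
  for (rep in 1:5) {
    cods <- sample(setdiff(code$sense_codons, "TGG"), 50, replace = TRUE)
    cds <- paste(cods, collapse = "")
    prot <- paste(translate_codons(cods), collapse = "")
    bt <- back_translate(setNames(prot, "t"), setNames(cds, "t"))
    expect_identical(bt$seqs[["t"]], cds)
    expect_identical(translate_alignment(bt)$seqs[["t"]], prot)
  }
})

test_that("gap-column trimming matches the threshold rule and returns a column map", {
  aln <- codon_alignment(c(a = "ATG---AAA", b = "ATG---AAA",
                           c = "ATG---AAA", d = "ATGCCCAAA"))
  tr <- trim_gap_columns(aln, 0.5)
  expect_equal(attr(tr, "column_map"), c(1L, 3L))
  expect_identical(tr$seqs[["a"]], "ATGAAA")
  expect_identical(trim_gap_columns(aln, 1.0)$seqs, aln$seqs)
  ## brute-force comparison on random gappy alignments
  set.seed(7)
  for (rep in 1:20) {
    r <- random_codon_alignment()
    thr <- sample(c(0, 0.3, 0.5, 0.8, 1), 1)
    cm <- codon_matrix(r)
    keep <- which(vapply(seq_len(ncol(cm)), function(j)
      mean(grepl("-", cm[, j])) <= thr, logical(1)))
    expect_equal(attr(trim_gap_columns(r, thr), "column_map"), keep)
  }
})

test_that("foreground marking by leaf list and by #1 labels is equivalent", {
  tr1 <- read_species_tree(text = "((A#1,B):1,(C,D):1);")
  tr2 <- mark_foreground(read_species_tree(text = "((A,B):1,(C,D):1);"), "A")
  expect_identical(tr1$foreground, tr2$foreground)
  expect_identical(sum(tr1$foreground), 1L)
  ## six plateau-style terminal marks
  tr <- read_species_tree(text = "((((s1,s2),(s3,s4)),((s5,s6),(s7,s8))),(s9,s10));")
  fg <- c("s1", "s3", "s5", "s7", "s9", "s10")
  marked <- mark_foreground(tr, fg)
  tips <- marked$edge[marked$foreground, 2L]
  expect_setequal(marked$tip.label[tips], fg)
  expect_error(mark_foreground(tr, character(0)), "empty")
  expect_error(mark_foreground(tr, "nope"), "not in tree")
})

test_that("pruning preserves path lengths between retained leaves", {
  tr <- mark_foreground(
    read_species_tree(text = "((A:0.1,B:0.2):0.3,(C:0.15,(D:0.4,E:0.1):0.2):0.1);"),
    c("A", "D"))
  pruned <- prune_to_taxa(tr, c("A", "C", "D"))
  d_full <- ape::cophenetic.phylo(tr)
  d_sub <- ape::cophenetic.phylo(pruned)
  expect_equal(d_sub, d_full[rownames(d_sub), colnames(d_sub)],
               tolerance = 1e-12)
  kept_fg <- pruned$tip.label[pruned$edge[pruned$foreground, 2L]]
  expect_setequal(kept_fg, c("A", "D"))
})

test_that("tree write/read round-trips foreground marks", {
  tr <- mark_foreground(
    read_species_tree(text = "((A:0.1,B:0.2):0.3,(C:0.15,D:0.4):0.1);"),
    c("B", "C"))
  f <- withr::local_tempfile(fileext = ".nwk")
  write_species_tree(tr, f)
  back <- read_species_tree(f)
  fg1 <- sort(tr$tip.label[tr$edge[tr$foreground, 2L]])
  fg2 <- sort(back$tip.label[back$edge[back$foreground, 2L]])
  expect_identical(fg1, fg2)
})
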