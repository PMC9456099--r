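test_that("degeneracy classification matches exhaustive enumeration over the code table", {
  gc <- genetic_code()
  ref <- Biostrings::GENETIC_CODE  # independent code table
  for (cd in gc$sense_codons) {
    fam <- paste0(substr(cd, 1, 2), c("A", "C", "G", "T"))
    expected <- sum(ref[fam] == ref[[cd]])
    expect_equal(classify_codon_degeneracy(cd), expected, info = cd)
  }
  expect_equal(classify_codon_degeneracy("GGT"), 4L)
  expect_equal(classify_codon_degeneracy("TTT"), 2L)
  expect_true(is.na(classify_codon_degeneracy("G-T")))
  expect_true(is.na(classify_codon_degeneracy("TAA")))
})

test_that("four-fold site extraction applies the strict cross-taxon rule", {
  aln <- codon_alignment(c(a = "GGTATG", b = "GGCATG", c = "GGAATG"))
  fs <- extract_fourfold_sites(aln)
  expect_equal(fs$columns, 1L)
  expect_identical(unname(fs$sites), c("T", "C", "A"))
  ## first two bases differ in taxon b -> rejected under strict
  aln2 <- codon_alignment(c(a = "GGT", b = "GCT", c = "GGT"))
  expect_length(extract_fourfold_sites(aln2)$columns, 0L)
  ## but accepted per-taxon when both codons are 4D (GGx Gly, GCx Ala)
  expect_equal(extract_fourfold_sites(aln2, strict = FALSE)$columns, 1L)
})

test_that("extraction equals the definitional brute-force scanner on random alignments", {
  set.seed(13)
  for (rep in 1:200) {
    r <- random_codon_alignment(n_taxa = 5L, n_codons = 12L)
    expect_identical(extract_fourfold_sites(r)$columns,
                     oracle_fourfold_columns(r, strict = TRUE))
    expect_identical(extract_fourfold_sites(r, strict = FALSE)$columns,
                     oracle_fourfold_columns(r, strict = FALSE))
  }
})

test_that("supergene concatenation is additive, deterministic and order-invariant", {
  a1 <- codon_alignment(c(x = "GGTGGAGCC", y = "GGCGGAGCA"), "g2")
  a2 <- codon_alignment(c(x = "CCTACT", y = "CCGACC"), "g1")
  s1 <- extract_fourfold_sites(a1)
  s2 <- extract_fourfold_sites(a2)
  sg <- build_supergene(list(s1, s2))
  expect_equal(nchar(sg$seqs[["x"]]),
               length(s1$columns) + length(s2$columns))
  ## ascending gene_id order: g1 first
  expect_identical(sg$boundaries$gene_id, c("g1", "g2"))
  expect_identical(build_supergene(list(s2, s1))$seqs, sg$seqs)
  ## single gene: supergene equals its extracted sites
  expect_identical(unname(build_supergene(list(s1))$seqs[["x"]]),
                   unname(s1$sites[["x"]]))
  ## boundary intervals partition the length
  expect_equal(sg$boundaries$start[1L], 1L)
  expect_equal(sg$boundaries$end[nrow(sg$boundaries)],
               nchar(sg$seqs[[1L]]))
  ## taxa mismatch is an error naming the gene
  s3 <- extract_fourfold_sites(codon_alignment(c(x = "GGT", z = "GGC"), "g3"))
  expect_error(build_supergene(list(s1, s3)), "g3")
})

test_that("extraction is idempotent on alignments built from extracted sites", {
  set.seed(5)
  for (rep in 1:10) {
    r <- random_codon_alignment(n_taxa = 4L, n_codons = 30L, gap_prob = 0,
                                n_prob = 0)
    fs <- extract_fourfold_sites(r)
    if (length(fs$columns) == 0L) next
    ## recode extracted third positions as GG<x> (Gly family, 4D) codons
    rec <- vapply(fs$sites, function(s)
      paste(paste0("GG", strsplit(s, "")[[1L]]), collapse = ""), character(1))
    aln2 <- codon_alignment(rec, "rec")
    expect_equal(length(extract_fourfold_sites(aln2)$columns),
                 length(fs$columns))
  }
})

test_that("supergene writers emit valid FASTA and PHYLIP", {
  a1 <- codon_alignment(c(x = "GGTGGA", y = "GGCGGA"), "g1")
  sg <- build_supergene(list(extract_fourfold_sites(a1)))
  fa <- withr::local_tempfile(fileext = ".fasta")
  ph <- withr::local_tempfile(fileext = ".phy")
  bm <- withr::local_tempfile(fileext = ".tsv")
  write_supergene(sg, fa, "fasta", boundary_path = bm)
  write_supergene(sg, ph, "phylip")
  expect_identical(as.character(Biostrings::readBStringSet(fa)[["x"]]),
                   unname(sg$seqs[["x"]]))
  lines <- readLines(ph)
  expect_match(lines[1L], "^ 2 2$")
  expect_equal(nrow(utils::read.delim(bm)), 1L)
})
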