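## small protein alignment builder
prot_aln <- function(rows, gene = "g") {
  structure(list(gene_id = gene, taxa = names(rows),
                 seqs = rows), class = "protein_alignment")
}

test_that("Grantham matrix matches published values and its generating formula", {
  g <- grantham_matrix()
  expect_true(isSymmetric(g))
  expect_equal(g["S", "P"], 74L)
  expect_equal(g["L", "I"], 5L)
  expect_equal(g["D", "E"], 45L)
  expect_equal(g["R", "K"], 26L)
  expect_equal(g["F", "Y"], 22L)
  expect_equal(g["C", "W"], 215L)
  ## recompute from the physicochemical properties (composition, polarity,
  ## volume); the printed table rounds, and the D-W entry is a known
  ## printed-table discrepancy
  props <- rbind(
    S = c(1.42, 9.2, 32), R = c(0.65, 10.5, 124), L = c(0, 4.9, 111),
    P = c(0.39, 8.0, 32.5), T = c(0.71, 8.6, 61), A = c(0, 8.1, 31),
    V = c(0, 5.9, 84), G = c(0.74, 9.0, 3), I = c(0, 5.2, 111),
    F = c(0, 5.2, 132), Y = c(0.20, 6.2, 136), C = c(2.75, 5.5, 55),
    H = c(0.58, 10.4, 96), Q = c(0.89, 10.5, 85), N = c(1.33, 11.6, 56),
    K = c(0.33, 11.3, 119), D = c(1.38, 13.0, 54), E = c(0.92, 12.3, 83),
    M = c(0, 5.7, 105), W = c(0.13, 5.4, 170))
  aas <- rownames(g)
  for (i in 1:19) for (j in (i + 1):20) {
    d <- props[aas[i], ] - props[aas[j], ]
    form <- 50.723 * sqrt(1.833 * d[1]^2 + 0.1018 * d[2]^2 + 0.000399 * d[3]^2)
    if (aas[i] == "D" && aas[j] == "W") next
    expect_lt(abs(g[aas[i], aas[j]] - form), 1.2)
  }
})

test_that("lineage-specific screen makes the conserved-replacement call and skips shared residues", {
  rows <- c(focal = "MED", paste0("b", 1:29))
  names(rows) <- c("focal", paste0("b", 1:29))
  rows[-1] <- "MDD"
  calls <- find_lineage_specific_substitutions(prot_aln(rows), "focal")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$column, 2L)
  expect_equal(calls$background_res, "D")
  expect_equal(calls$focal_res, "E")
  expect_equal(calls$notation, "D2E")
  expect_equal(calls$grantham, 45L)
  ## focal residue shared by part of the background -> no call
  rows2 <- c(focal = "A", b1 = "A", b2 = "G", b3 = "G")
  expect_equal(nrow(find_lineage_specific_substitutions(prot_aln(rows2), "focal")), 0L)
  expect_error(find_lineage_specific_substitutions(prot_aln(rows2), "zzz"),
               "not in alignment")
})

test_that("reported position uses the reference taxon's ungapped coordinate", {
  rows <- c(focal = "GG-AE", b1 = "GGAAD", b2 = "GGAAD", b3 = "GGAAD")
  calls <- find_lineage_specific_substitutions(prot_aln(rows), "focal")
  ## column 5, but focal has a gap at column 3 -> ungapped position 4
  expect_equal(calls$column, 5L)
  expect_equal(calls$ref_pos, 4L)
  expect_equal(calls$notation, "D4E")
})

test_that("convergent screen requires both focal taxa to share the derived residue", {
  rows <- c(f1 = "MPT", f2 = "MPT", b1 = "MST", b2 = "MST", b3 = "MST")
  calls <- find_convergent_substitutions(prot_aln(rows), c("f1", "f2"))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$background_res, "S")
  expect_equal(calls$focal_res, "P")
  expect_equal(calls$grantham, 74L)  # serine-to-proline
  ## fully conserved column, and discordant focal residues: no call
  rows2 <- c(f1 = "MPT", f2 = "MST", b1 = "MST", b2 = "MST", b3 = "MST")
  expect_equal(nrow(find_convergent_substitutions(prot_aln(rows2), c("f1", "f2"))), 0L)
  expect_error(find_convergent_substitutions(prot_aln(rows2), c("f1", "f1")),
               "distinct")
})

test_that("screens equal the definitional brute-force scanners on random alignments", {
  set.seed(41)
  aas <- rownames(grantham_matrix())
  for (rep in 1:300) {
    n_tax <- sample(5:8, 1)
    n_col <- 12L
    m <- matrix(sample(c(aas, "-"), n_tax * n_col, replace = TRUE,
                       prob = c(rep(0.6 / 20, 20), 0.4)),
                nrow = n_tax)
    ## make many columns near-conserved so calls are possible
    cons <- sample(aas, n_col, replace = TRUE)
    for (j in seq_len(n_col)) {
      keep <- runif(n_tax) < 0.8
      m[keep, j] <- cons[j]
    }
    rownames(m) <- paste0("t", seq_len(n_tax))
    rows <- apply(m, 1L, paste, collapse = "")
    pa <- prot_aln(rows)
    ident <- sample(c(0.8, 1), 1)
    got <- find_lineage_specific_substitutions(pa, "t1",
                                               min_background_identity = ident)
    expect_identical(got$column, oracle_ls_columns(m, "t1", ident))
    gotc <- find_convergent_substitutions(pa, c("t1", "t2"),
                                          min_background_identity = ident)
    expect_identical(gotc$column, oracle_conv_columns(m, c("t1", "t2"), ident))
  }
})

test_that("calls are invariant to background taxon order and screens stay disjoint on planted data", {
  rows <- c(f1 = "MPTAK", f2 = "MPTCK", b1 = "MSTCK", b2 = "MSTCK",
            b3 = "MSTCK", b4 = "MSTCK")
  pa <- prot_aln(rows)
  conv <- find_convergent_substitutions(pa, c("f1", "f2"))
  expect_equal(conv$column, 2L)
  ## the single-focal screen on f1 rejects column 2 (f2 carries P too)
  ls1 <- find_lineage_specific_substitutions(pa, "f1")
  expect_false(2L %in% ls1$column)
  expect_true(4L %in% ls1$column)  # A vs conserved C is f1-specific
  ## reorder background
  pa2 <- prot_aln(rows[c("f1", "f2", "b4", "b2", "b3", "b1")])
  expect_identical(find_convergent_substitutions(pa2, c("f1", "f2"))$column,
                   conv$column)
  expect_identical(
    find_lineage_specific_substitutions(pa2, "f1")$column, ls1$column)
})

test_that("planted events in invariant alignments are recovered perfectly", {
  set.seed(43)
  tr <- default_study_tree()
  n_found <- 0L
  for (rep in 1:25) {
    ## invariant background alignment
    cods <- sample(genetic_code()$sense_codons, 40, replace = TRUE)
    seqs <- setNames(rep(paste(cods, collapse = ""), 8), tr$tip.label)
    aln <- codon_alignment(seqs, "inv")
    expect_equal(nrow(find_lineage_specific_substitutions(aln, "C")), 0L)
    col <- sample(40, 1)
    res <- sample(setdiff(rownames(grantham_matrix()), "W"), 2)
    kind <- sample(c("lineage_specific", "convergent"), 1)
    focal <- if (kind == "convergent") c("C", "E") else "C"
    planted <- plant_substitution(aln, col, kind, focal, res[1], res[2])
    calls <- if (kind == "convergent")
      find_convergent_substitutions(planted, c("C", "E"))
    else find_lineage_specific_substitutions(planted, "C")
    expect_equal(calls$column, col)
    expect_equal(calls$background_res, res[1])
    expect_equal(calls$focal_res, res[2])
    n_found <- n_found + nrow(calls)
  }
  expect_equal(n_found, 25L)  # sensitivity 1.0, no extra calls
})

test_that("severity annotation attaches Grantham distances and NA for nonstandard residues", {
  calls <- data.frame(background_res = c("S", "L", "X"),
                      focal_res = c("P", "I", "A"))
  out <- annotate_severity(calls)
  expect_equal(out$grantham, c(74L, 5L, NA_integer_))
})
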