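#' Degeneracy class of a codon's third position
#'
#' Counts how many of the four third-position nucleotides preserve the
#' encoded amino acid, computed directly from the code table.
#'
#' @param codon a triplet over `{A,C,G,T}` (vectorised).
#' @param code a [genetic_code()].
#' @return integer in `{1,2,3,4}`, or `NA` ("unclassifiable") for gapped,
#'   ambiguous or stop codons.
#' @export
classify_codon_degeneracy <- function(codon, code = genetic_code()) {
  codon <- toupper(codon)
  vapply(codon, function(cd) {
    if (is.na(cd) || grepl("[^ACGT]", cd)) return(NA_integer_)
    aa <- code$aa[cd]
    if (is.na(aa) || aa == "*") return(NA_integer_)
    fam <- paste0(substr(cd, 1L, 2L), c("A", "C", "G", "T"))
    sum(code$aa[fam] == aa)
  }, integer(1), USE.NAMES = FALSE)
}

#' Extract four-fold degenerate third-position sites from an alignment
#'
#' A codon column is accepted iff, for every taxon, the codon is ungapped,
#' unambiguous and four-fold degenerate at its third position, and (under the
#' default strict rule) the first two nucleotides are identical across all
#' taxa, which guarantees the third position is selectively equivalent in
#' every lineage. `strict = FALSE` relaxes the cross-taxon identity
#' requirement and classifies degeneracy per taxon.
#'
#' @param aln a [codon_alignment()].
#' @param code a [genetic_code()].
#' @param strict require cross-taxon identity of codon positions 1-2
#'   (default `TRUE`).
#' @return a `fourfold_sites` object: list with `gene_id`, `taxa`,
#'   `columns` (accepted 1-based codon columns) and `sites` (named character
#'   vector: per-taxon string of extracted third positions).
#' @export
extract_fourfold_sites <- function(aln, code = genetic_code(), strict = TRUE) {
  cm <- codon_matrix(aln)
  deg <- matrix(classify_codon_degeneracy(cm, code), nrow = nrow(cm))
  all4 <- colSums(deg == 4L, na.rm = TRUE) == nrow(cm) &
    colSums(is.na(deg)) == 0L
  if (strict) {
    pre <- matrix(substr(cm, 1L, 2L), nrow = nrow(cm))
    same <- apply(pre, 2L, function(x) length(unique(x)) == 1L)
    keep <- which(all4 & same)
  } else keep <- which(all4)
  third <- matrix(substr(cm, 3L, 3L), nrow = nrow(cm))
  sites <- apply(third[, keep, drop = FALSE], 1L, paste, collapse = "")
  if (length(keep) == 0L) sites <- rep("", nrow(cm))
  names(sites) <- aln$taxa
  structure(list(gene_id = aln$gene_id, taxa = aln$taxa,
                 columns = keep, sites = sites),
            class = "fourfold_sites")
}

#' Concatenate four-fold degenerate sites into a per-species supergene
#'
#' Genes are concatenated in ascending `gene_id` order regardless of input
#' order, so the output is deterministic and order-invariant.
#'
#' @param sets list of `fourfold_sites` objects sharing the same taxa.
#' @param taxa_order optional ordering of taxa for the output.
#' @return a `supergene` object: list with `taxa`, `seqs` (named
#'   concatenated strings), and `boundaries` (data.frame gene_id/start/end,
#'   1-based closed intervals partitioning the supergene).
#' @export
build_supergene <- function(sets, taxa_order = NULL) {
  stopifnot(length(sets) > 0L)
  ids <- vapply(sets, `[[`, character(1), "gene_id")
  if (anyDuplicated(ids)) stop("duplicated gene_id among site sets")
  sets <- sets[order(ids)]
  taxa <- if (is.null(taxa_order)) sets[[1L]]$taxa else taxa_order
  for (s in sets)
    if (!setequal(s$taxa, taxa))
      stop("taxa mismatch in gene ", s$gene_id)
  seqs <- setNames(rep("", length(taxa)), taxa)
  b <- data.frame(gene_id = character(0), start = integer(0), end = integer(0))
  pos <- 0L
  for (s in sets) {
    n <- length(s$columns)
    seqs <- paste0(seqs, s$sites[taxa])
    names(seqs) <- taxa
    if (n > 0L)
      b <- rbind(b, data.frame(gene_id = s$gene_id, start = pos + 1L,
                               end = pos + n))
    pos <- pos + n
  }
  structure(list(taxa = taxa, seqs = seqs, boundaries = b),
            class = "supergene")
}

#' @export
print.supergene <- function(x, ...) {
  cat("supergene: ", length(x$taxa), " taxa, ",
      nchar(x$seqs[[1L]]), " four-fold degenerate sites from ",
      nrow(x$boundaries), " genes\n", sep = "")
  invisible(x)
}

#' Write a supergene (FASTA or sequential PHYLIP) plus its boundary map
#'
#' @param sg a `supergene`.
#' @param path output alignment file.
#' @param format `"fasta"` or `"phylip"`.
#' @param boundary_path optional TSV to receive the gene boundary map.
#' @export
write_supergene <- function(sg, path, format = c("fasta", "phylip"),
                            boundary_path = NULL) {
  format <- match.arg(format)
  if (format == "fasta")
    Biostrings::writeXStringSet(Biostrings::BStringSet(sg$seqs), path, width = 60L)
  else
    write_phylip(sg$seqs, path)
  if (!is.null(boundary_path))
    utils::write.table(sg$boundaries, boundary_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}
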