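#' In-frame codon alignments
#'
#' A `codon_alignment` is the unit of every downstream test: an aligned set of
#' coding sequences over named taxa whose length is divisible by three and
#' whose reading frame starts at column 1. Codon columns are indexed 1-based.
#'
#' @param seqs named character vector of equal-length aligned nucleotide
#'   strings (alphabet `A,C,G,T,N,-`; case-insensitive on input).
#' @param gene_id gene identifier carried through all outputs.
#' @param code a [genetic_code()].
#' @return an object of class `codon_alignment` with fields `gene_id`,
#'   `taxa`, `seqs`, `n_codons`.
#' @export
codon_alignment <- function(seqs, gene_id = "gene", code = genetic_code()) {
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("every sequence must be named by its taxon")
  if (anyDuplicated(names(seqs)))
    stop("duplicated taxon names: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: sequence lengths ", paste(unique(lens), collapse = ", "))
  len <- lens[[1L]]
  if (len %% 3L != 0L)
    stop("alignment length ", len, " is not divisible by 3 (frame error)")
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad))
    stop("invalid characters in taxa: ", paste(names(seqs)[bad], collapse = ", "))
  aln <- structure(list(
    gene_id = gene_id,
    taxa = names(seqs),
    seqs = seqs,
    n_codons = len %/% 3L
  ), class = "codon_alignment")
  .check_internal_stops(aln, code)
  aln
}

.check_internal_stops <- function(aln, code) {
  cm <- codon_matrix(aln)
  if (ncol(cm) == 0L) return(invisible(aln))
  stops <- matrix(cm %in% code$stop_codons, nrow = nrow(cm))
  if (ncol(stops) > 1L) {
    internal <- stops[, -ncol(stops), drop = FALSE]
    if (any(internal)) {
      hit <- which(internal, arr.ind = TRUE)[1L, ]
      stop("internal stop codon in taxon '", aln$taxa[hit[["row"]]],
           "' at codon ", hit[["col"]], " of gene ", aln$gene_id)
    }
  }
  invisible(aln)
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment '", x$gene_id, "': ", length(x$taxa), " taxa, ",
      x$n_codons, " codons\n", sep = "")
  invisible(x)
}

#' Codon matrix of an alignment
#'
#' @param aln a [codon_alignment()].
#' @return character matrix, taxa in rows, codon columns; dimnames set.
#' @export
codon_matrix <- function(aln) {
  m <- matrix("", nrow = length(aln$taxa), ncol = aln$n_codons,
              dimnames = list(aln$taxa, NULL))
  for (i in seq_along(aln$taxa))
    m[i, ] <- split_codons(aln$seqs[[i]])
  m
}

#' Integer state encoding of an alignment
#'
#' Maps each codon to its 1..61 sense-codon state index; any codon containing
#' `N` or `-` (and any stop, permitted only terminally) becomes `NA` and is
#' treated as missing data by the likelihood engine and simulator.
#'
#' @inheritParams codon_matrix
#' @param code a [genetic_code()].
#' @return integer matrix taxa x codons with `NA` for missing.
#' @export
codon_index_matrix <- function(aln, code = genetic_code()) {
  cm <- codon_matrix(aln)
  idx <- code$codon_index[cm]
  matrix(unname(idx), nrow = nrow(cm), dimnames = dimnames(cm))
}

#' Read an aligned FASTA file as a codon alignment
#'
#' @param path FASTA file of equal-length, in-frame nucleotide sequences.
#' @param gene_id gene identifier; default: file name without extension.
#' @param code a [genetic_code()].
#' @return a [codon_alignment()]. Ragged records, a length not divisible by
#'   three, or an internal stop codon are errors.
#' @export
read_codon_alignment <- function(path, gene_id = NULL, code = genetic_code()) {
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("no FASTA records in ", path)
  if (is.null(gene_id))
    gene_id <- sub("\\.(fa|fasta|fna)$", "", basename(path), ignore.case = TRUE)
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(x))  # first token of header
  codon_alignment(seqs, gene_id = gene_id, code = code)
}

#' Write a codon alignment to FASTA
#'
#' Lines are wrapped at a fixed 60 characters so that read/write round-trips
#' are byte-stable.
#'
#' @param aln a [codon_alignment()].
#' @param path output file.
#' @export
write_codon_alignment <- function(aln, path) {
  x <- Biostrings::BStringSet(aln$seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Translate a codon alignment to a protein alignment
#'
#' @param aln a [codon_alignment()].
#' @param code a [genetic_code()].
#' @return a `protein_alignment`: list with `gene_id`, `taxa`, `seqs`
#'   (amino-acid strings; `-` for fully gapped codons, `X` for partially
#'   ambiguous ones). A terminal stop translates to `*` and is kept.
#' @export
translate_alignment <- function(aln, code = genetic_code()) {
  cm <- codon_matrix(aln)
  seqs <- apply(cm, 1L, function(r) paste(translate_codons(r, code), collapse = ""))
  structure(list(gene_id = aln$gene_id, taxa = aln$taxa, seqs = seqs),
            class = "protein_alignment")
}

#' Back-translate a protein alignment against ungapped CDS
#'
#' Each amino-acid column becomes one codon column; a protein gap becomes
#' `---`. The ungapped protein row must translate exactly from its CDS.
#'
#' @param prot a `protein_alignment` (or named character vector of aligned
#'   amino-acid strings).
#' @param cds_by_taxon named character vector: taxon -> ungapped CDS
#'   (a terminal stop codon is permitted and dropped).
#' @param gene_id gene identifier for the result.
#' @param code a [genetic_code()].
#' @return a [codon_alignment()].
#' @export
back_translate <- function(prot, cds_by_taxon, gene_id = "gene",
                           code = genetic_code()) {
  if (inherits(prot, "protein_alignment")) {
    seqs <- prot$seqs
    gene_id <- prot$gene_id
  } else seqs <- prot
  out <- character(length(seqs))
  names(out) <- names(seqs)
  for (tx in names(seqs)) {
    if (is.na(match(tx, names(cds_by_taxon))))
      stop("no CDS provided for taxon '", tx, "'")
    aas <- strsplit(toupper(seqs[[tx]]), "")[[1L]]
    cds <- toupper(cds_by_taxon[[tx]])
    if (nchar(cds) %% 3L != 0L)
      stop("CDS of '", tx, "' has length not divisible by 3")
    cods <- split_codons(cds)
    if (length(cods) > 0L && code$aa[cods[length(cods)]] == "*")
      cods <- cods[-length(cods)]
    n_res <- sum(aas != "-")
    if (n_res != length(cods))
      stop("CDS/protein length mismatch for '", tx, "': ", length(cods),
           " codons vs ", n_res, " residues")
    k <- 0L
    row <- character(length(aas))
    for (j in seq_along(aas)) {
      if (aas[j] == "-") { row[j] <- "---"; next }
      k <- k + 1L
      got <- unname(code$aa[cods[k]])
      if (!identical(got, aas[j]) && aas[j] != "X")
        stop("translation mismatch for '", tx, "' at residue ", j,
             ": codon ", cods[k], " encodes ", got, ", protein has ", aas[j])
      row[j] <- cods[k]
    }
    out[[tx]] <- paste(row, collapse = "")
  }
  codon_alignment(out, gene_id = gene_id, code = code)
}

#' Remove gap-rich codon columns
#'
#' A codon column's gap fraction is the fraction of taxa whose codon contains
#' any `-`. Columns whose gap fraction exceeds `max_gap_fraction` are removed.
#' This is a deliberately simple, fully specified trimming rule (a stand-in
#' for heuristic alignment trimmers), applied at codon granularity so the
#' reading frame is preserved.
#'
#' @param aln a [codon_alignment()].
#' @param max_gap_fraction keep a column iff gap fraction `<=` this value;
#'   default 0.5.
#' @return the trimmed [codon_alignment()] with attribute `column_map`, an
#'   integer vector mapping new codon columns to old 1-based columns.
#' @export
trim_gap_columns <- function(aln, max_gap_fraction = 0.5) {
  stopifnot(max_gap_fraction >= 0, max_gap_fraction <= 1)
  cm <- codon_matrix(aln)
  gapfrac <- colMeans(matrix(grepl("-", cm, fixed = TRUE), nrow = nrow(cm)))
  keep <- which(gapfrac <= max_gap_fraction)
  seqs <- apply(cm[, keep, drop = FALSE], 1L, paste, collapse = "")
  if (length(keep) == 0L) seqs <- setNames(rep("", length(aln$taxa)), aln$taxa)
  out <- codon_alignment(seqs, gene_id = aln$gene_id)
  attr(out, "column_map") <- keep
  out
}

#' Write a protein or codon alignment in sequential PHYLIP format
#'
#' @param seqs named character vector of equal-length sequences.
#' @param path output file.
#' @export
write_phylip <- function(seqs, path) {
  stopifnot(length(unique(nchar(seqs))) == 1L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(" %d %d", length(seqs), nchar(seqs[[1L]])), con)
  writeLines(sprintf("%-12s%s", names(seqs), unname(seqs)), con)
  invisible(path)
}
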