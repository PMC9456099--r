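#' Grantham physicochemical distance matrix
#'
#' The published Grantham (1974) distances between the 20 standard amino
#' acids, used here as a severity annotation for amino-acid replacements.
#' This is explicitly NOT a PROVEAN score: PROVEAN requires a sequence
#' database search and is out of scope; Grantham distance is a
#' database-free physicochemical proxy and is labelled as such in all
#' outputs.
#'
#' @return symmetric 20 x 20 integer matrix, dimnames = one-letter codes.
#' @export
grantham_matrix <- function() {
  if (!is.null(.omegascan_cache$grantham)) return(.omegascan_cache$grantham)
  aas <- c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F",
           "Y", "C", "H", "Q", "N", "K", "D", "E", "M", "W")
  ## upper triangle, row by row, in the order above
  v <- c(
    110, 145,  74,  58,  99, 124,  56, 142, 155, 144, 112,  89,  68,  46, 121,  65,  80, 135, 177,
         102, 103,  71, 112,  96, 125,  97,  97,  77, 180,  29,  43,  86,  26,  96,  54,  91, 101,
               98,  92,  96,  32, 138,   5,  22,  36, 198,  99, 113, 153, 107, 172, 138,  15,  61,
                    38,  27,  68,  42,  95, 114, 110, 169,  77,  76,  91, 103, 108,  93,  87, 147,
                         58,  69,  59,  89, 103,  92, 149,  47,  42,  65,  78,  85,  65,  81, 128,
                              64,  60,  94, 113, 112, 195,  86,  91, 111, 106, 126, 107,  84, 148,
                                  109,  29,  50,  55, 192,  84,  96, 133,  97, 152, 121,  21,  88,
                                       135, 153, 147, 159,  98,  87,  80, 127,  94,  98, 127, 184,
                                             21,  33, 198,  94, 109, 149, 102, 168, 134,  10,  61,
                                                   22, 205, 100, 116, 158, 102, 177, 140,  28,  40,
                                                       194,  83,  99, 143,  85, 160, 122,  36,  37,
                                                            174, 154, 139, 202, 154, 170, 196, 215,
                                                                  24,  68,  32,  81,  40,  87, 115,
                                                                       46,  53,  61,  29, 101, 130,
                                                                             94,  23,  42, 142, 174,
                                                                                  101,  56,  95, 110,
                                                                                        45, 160, 181,
                                                                                            126, 152,
                                                                                                  67)
  m <- matrix(0L, 20L, 20L, dimnames = list(aas, aas))
  m[lower.tri(m)] <- as.integer(v)  # row-major upper triangle
  m <- m + t(m)
  .omegascan_cache$grantham <- m
  m
}

## Residue matrix of a protein alignment (or translated codon alignment).
residue_matrix <- function(aln, code = genetic_code()) {
  if (inherits(aln, "codon_alignment")) aln <- translate_alignment(aln, code)
  n <- nchar(aln$seqs[[1L]])
  stopifnot(all(nchar(aln$seqs) == n))
  m <- matrix("", nrow = length(aln$taxa), ncol = n,
              dimnames = list(aln$taxa, NULL))
  for (i in seq_along(aln$taxa))
    m[i, ] <- strsplit(aln$seqs[[i]], "")[[1L]]
  m
}

## Shared column logic for both screens. Returns NULL or a list describing
## the background consensus.
.background_profile <- function(col, bg_idx, min_background_identity,
                                min_coverage) {
  bg <- col[bg_idx]
  nongap <- bg[bg != "-" & bg != "X" & bg != "*"]
  if (length(nongap) < min_coverage * length(bg)) return(NULL)
  tab <- sort(table(nongap), decreasing = TRUE)
  cons <- names(tab)[1L]
  ident <- tab[[1L]] / length(nongap)
  if (ident < min_background_identity) return(NULL)
  list(consensus = cons, identity = ident, residues = nongap)
}

.ref_positions <- function(refrow) cumsum(refrow != "-")

.calls_frame <- function() {
  data.frame(gene_id = character(0), kind = character(0),
             focal_taxa = character(0), column = integer(0),
             ref_pos = integer(0), background_res = character(0),
             focal_res = character(0), notation = character(0),
             background_identity = numeric(0), grantham = integer(0),
             stringsAsFactors = FALSE)
}

#' Screen for lineage-specific amino-acid replacements
#'
#' A column is called when the focal taxon carries a standard residue `f`,
#' at least `min_background_identity` of the non-gap background residues
#' agree on a single consensus residue `b != f`, and no background taxon
#' carries `f` at all. With the strict default
#' (`min_background_identity = 1`) this is exactly the
#' conserved-replacement rule behind calls such as ERCC6 D965E. Columns
#' where fewer than `min_coverage` of the background taxa have a residue
#' are skipped.
#'
#' @param aln protein alignment (a `protein_alignment`, or a
#'   [codon_alignment()] which is translated first).
#' @param focal name of the focal taxon.
#' @param min_background_identity required background consensus fraction
#'   (default 1 = fully conserved background).
#' @param reference taxon whose ungapped coordinates are reported
#'   (default: the focal taxon, giving D965E-style notation).
#' @param min_coverage minimum fraction of background taxa with a residue.
#' @param code a [genetic_code()].
#' @return data.frame of calls: `gene_id`, `kind`, `focal_taxa`, `column`
#'   (1-based alignment column), `ref_pos` (ungapped reference position),
#'   `background_res`, `focal_res`, `notation` (e.g. `"D965E"`),
#'   `background_identity`, `grantham`.
#' @export
find_lineage_specific_substitutions <- function(aln, focal,
                                                min_background_identity = 1,
                                                reference = focal,
                                                min_coverage = 0.5,
                                                code = genetic_code()) {
  m <- residue_matrix(aln, code)
  gene_id <- if (is.list(aln)) aln$gene_id else "gene"
  if (!focal %in% rownames(m)) stop("focal taxon '", focal, "' not in alignment")
  if (!reference %in% rownames(m)) stop("reference taxon not in alignment")
  bg_idx <- setdiff(rownames(m), focal)
  refpos <- .ref_positions(m[reference, ])
  out <- .calls_frame()
  std <- rownames(grantham_matrix())
  for (j in seq_len(ncol(m))) {
    f <- m[focal, j]
    if (!f %in% std) next
    prof <- .background_profile(m[, j], bg_idx, min_background_identity,
                                min_coverage)
    if (is.null(prof)) next
    b <- prof$consensus
    if (b == f || !b %in% std) next
    if (f %in% prof$residues) next  # no background taxon may carry f
    rp <- if (m[reference, j] == "-") NA_integer_ else refpos[j]
    out <- rbind(out, data.frame(
      gene_id = gene_id, kind = "lineage_specific", focal_taxa = focal,
      column = j, ref_pos = rp, background_res = b, focal_res = f,
      notation = paste0(b, rp, f),
      background_identity = unname(prof$identity),
      grantham = grantham_matrix()[b, f], stringsAsFactors = FALSE))
  }
  out
}

#' Screen for convergent amino-acid replacements in two lineages
#'
#' A column is called when both focal taxa carry the same standard residue
#' `f`, the background (all other taxa) satisfies the conservation rule
#' with consensus `b != f`, and no background taxon carries `f` — i.e.
#' the replacement occurs only in the two focal species (the rule behind
#' the MLIP serine-to-proline call shared by the two highland reptiles).
#'
#' @inheritParams find_lineage_specific_substitutions
#' @param focal_pair character vector of exactly two distinct taxa.
#' @param reference taxon for reported coordinates (default: first of the
#'   pair).
#' @return data.frame of calls as in
#'   [find_lineage_specific_substitutions()], `kind = "convergent"`,
#'   `focal_taxa` a `+`-joined pair.
#' @export
find_convergent_substitutions <- function(aln, focal_pair,
                                          min_background_identity = 1,
                                          reference = focal_pair[1L],
                                          min_coverage = 0.5,
                                          code = genetic_code()) {
  if (length(focal_pair) != 2L || focal_pair[1L] == focal_pair[2L])
    stop("focal_pair must be two distinct taxa")
  m <- residue_matrix(aln, code)
  gene_id <- if (is.list(aln)) aln$gene_id else "gene"
  miss <- setdiff(focal_pair, rownames(m))
  if (length(miss) > 0L)
    stop("focal taxa not in alignment: ", paste(miss, collapse = ", "))
  bg_idx <- setdiff(rownames(m), focal_pair)
  refpos <- .ref_positions(m[reference, ])
  out <- .calls_frame()
  std <- rownames(grantham_matrix())
  for (j in seq_len(ncol(m))) {
    f1 <- m[focal_pair[1L], j]; f2 <- m[focal_pair[2L], j]
    if (f1 != f2 || !f1 %in% std) next
    prof <- .background_profile(m[, j], bg_idx, min_background_identity,
                                min_coverage)
    if (is.null(prof)) next
    b <- prof$consensus
    if (b == f1 || !b %in% std) next
    if (f1 %in% prof$residues) next
    rp <- if (m[reference, j] == "-") NA_integer_ else refpos[j]
    out <- rbind(out, data.frame(
      gene_id = gene_id, kind = "convergent",
      focal_taxa = paste(focal_pair, collapse = "+"),
      column = j, ref_pos = rp, background_res = b, focal_res = f1,
      notation = paste0(b, rp, f1),
      background_identity = unname(prof$identity),
      grantham = grantham_matrix()[b, f1], stringsAsFactors = FALSE))
  }
  out
}

#' Attach Grantham severity to substitution calls
#'
#' Calls from the screens already carry the distance; this helper
#' (re)annotates an arbitrary call table, leaving `NA` for nonstandard
#' residues. The value is a physicochemical distance, not a PROVEAN score.
#'
#' @param calls data.frame with `background_res` and `focal_res` columns.
#' @return the data.frame with its `grantham` column (re)computed.
#' @export
annotate_severity <- function(calls) {
  g <- grantham_matrix()
  std <- rownames(g)
  calls$grantham <- ifelse(
    calls$background_res %in% std & calls$focal_res %in% std,
    g[cbind(match(calls$background_res, std), match(calls$focal_res, std))],
    NA_integer_)
  calls
}
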