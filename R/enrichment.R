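#' Build an annotation table from gene-term pairs
#'
#' @param pairs data.frame (or two-column TSV path) with columns `gene`,
#'   `term`, one row per gene-term pair. The background universe is the set
#'   of all annotated genes.
#' @return an `annotation_table`: list with `gene2terms` (named list),
#'   `term_counts` (term -> number of universe genes carrying it), and
#'   `universe` (character vector).
#' @export
annotation_table <- function(pairs) {
  if (is.character(pairs) && length(pairs) == 1L)
    pairs <- utils::read.table(pairs, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "term") %in% names(pairs)))
  pairs <- unique(pairs[, c("gene", "term")])
  gene2terms <- split(pairs$term, pairs$gene)
  term_genes <- split(pairs$gene, pairs$term)
  structure(list(
    gene2terms = gene2terms,
    term_genes = term_genes,
    term_counts = vapply(term_genes, length, integer(1)),
    universe = sort(unique(pairs$gene))
  ), class = "annotation_table")
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes from a
#' universe of `N` of which `K` carry the term, the probability of at least
#' `k` hits. Computed in log space via [stats::phyper()].
#'
#' @param k observed hits in the study set.
#' @param n study-set size.
#' @param K term genes in the universe.
#' @param N universe size.
#' @return the upper-tail probability.
#' @export
hypergeometric_upper_tail <- function(k, n, K, N) {
  stopifnot(k == round(k), n == round(n), K == round(K), N == round(N),
            K >= 0, K <= N, n >= 0, n <= N, k >= 0, k <= min(n, K))
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment with monotonicity enforcement; the input
#' order is preserved in the output.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted q-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric over-representation test of a gene set
#'
#' Tests every annotation term with at least one hit in the study set
#' against the annotated universe. Mirrors the two conventions used for
#' ontology vs pathway terms: `correction = "BH"` flags terms with adjusted
#' q below `alpha` (the GO-style rule), `correction = "none"` flags raw
#' p below `alpha` (the KEGG-style rule).
#'
#' @param study_genes character vector of study genes; genes outside the
#'   universe are dropped with a warning.
#' @param table an [annotation_table()].
#' @param alpha significance threshold (default 0.05).
#' @param correction `"BH"` or `"none"`.
#' @return data.frame sorted by p then term: `term`, `k`, `n`, `K`, `N`,
#'   `p`, `q` (BH-adjusted over the tested terms), `significant`.
#' @export
enrich <- function(study_genes, table, alpha = 0.05,
                   correction = c("BH", "none")) {
  correction <- match.arg(correction)
  if (length(table$universe) == 0L) stop("empty annotation universe")
  study <- unique(study_genes)
  outside <- setdiff(study, table$universe)
  if (length(outside) > 0L) {
    warning(length(outside), " study gene(s) outside the annotated universe dropped")
    study <- setdiff(study, outside)
  }
  n <- length(study)
  N <- length(table$universe)
  hits <- table(unlist(table$gene2terms[study], use.names = FALSE))
  if (length(hits) == 0L)
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0), significant = logical(0)))
  terms <- names(hits)
  k <- as.integer(hits)
  K <- unname(table$term_counts[terms])
  p <- vapply(seq_along(terms), function(i)
    hypergeometric_upper_tail(k[i], n, K[i], N), numeric(1))
  q <- bh_adjust(p)
  res <- data.frame(term = terms, k = k, n = n, K = K, N = N, p = p, q = q,
                    significant = if (correction == "BH") q < alpha else p < alpha,
                    stringsAsFactors = FALSE)
  res[order(res$p, res$term), , drop = FALSE]
}
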