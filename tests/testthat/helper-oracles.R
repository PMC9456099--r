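# Independent oracles: deliberately naive implementations-by-definition used
# to validate the package's optimized code paths. None of them share code
# with the package internals they check.

## Brute-force pruning oracle: sum over all internal-node state assignments.
## Feasible only for trees with <= 3 internal nodes.
oracle_loglik_enum <- function(aln, tree, kappa, omega, pi) {
  code <- genetic_code()
  po <- stats::reorder(tree, "postorder")
  ntip <- length(po$tip.label)
  internal <- sort(unique(po$edge[po$edge > ntip]))
  stopifnot(length(internal) <= 3L)
  q <- build_rate_matrix(kappa, omega, pi)
  P <- lapply(po$edge.length, function(t)
    transition_probabilities(rate_matrix_eigen(q, pi), t))
  idx <- codon_index_matrix(aln)[po$tip.label, , drop = FALSE]
  root <- ntip + 1L
  nst <- 61L
  ## every joint assignment of states to the internal nodes, enumerated
  grid <- as.matrix(expand.grid(rep(list(seq_len(nst)), length(internal))))
  ## site-independent factor: root prior times internal-internal edges
  base <- pi[grid[, match(root, internal)]]
  tip_edge <- which(po$edge[, 2L] <= ntip)
  for (r in setdiff(seq_len(nrow(po$edge)), tip_edge)) {
    par_st <- grid[, match(po$edge[r, 1L], internal)]
    ch_st <- grid[, match(po$edge[r, 2L], internal)]
    base <- base * P[[r]][cbind(par_st, ch_st)]
  }
  ## per-tip-edge: probability rows for each assignment (n_assign x 61)
  tipM <- lapply(tip_edge, function(r)
    P[[r]][grid[, match(po$edge[r, 1L], internal)], , drop = FALSE])
  site_lik <- function(s) {
    p <- base
    for (k in seq_along(tip_edge)) {
      st <- idx[po$edge[tip_edge[k], 2L], s]
      if (!is.na(st)) p <- p * tipM[[k]][, st]
    }
    log(sum(p))
  }
  sum(vapply(seq_len(ncol(idx)), site_lik, numeric(1)))
}

## Definitional four-fold extraction: per-column loop applying the rule.
oracle_fourfold_columns <- function(aln, strict = TRUE) {
  code <- genetic_code()
  cm <- codon_matrix(aln)
  deg4 <- function(cd) {
    if (grepl("[^ACGT]", cd)) return(FALSE)
    aa <- code$aa[cd]
    if (is.na(aa) || aa == "*") return(FALSE)
    all(code$aa[paste0(substr(cd, 1, 2), c("A", "C", "G", "T"))] == aa)
  }
  keep <- integer(0)
  for (j in seq_len(ncol(cm))) {
    ok <- all(vapply(cm[, j], deg4, logical(1)))
    if (ok && strict)
      ok <- length(unique(substr(cm[, j], 1, 2))) == 1L
    if (ok) keep <- c(keep, j)
  }
  keep
}

## Definitional lineage-specific scanner over a residue matrix.
oracle_ls_columns <- function(m, focal, min_ident = 1, min_cov = 0.5) {
  std <- rownames(grantham_matrix())
  bg <- setdiff(rownames(m), focal)
  out <- integer(0)
  for (j in seq_len(ncol(m))) {
    f <- m[focal, j]
    if (!f %in% std) next
    res <- m[bg, j]
    res <- res[!res %in% c("-", "X", "*")]
    if (length(res) < min_cov * length(bg)) next
    tab <- sort(table(res), decreasing = TRUE)
    b <- names(tab)[1L]
    if (!b %in% std) next
    if (tab[[1L]] / length(res) < min_ident) next
    if (b == f) next
    if (f %in% res) next
    out <- c(out, j)
  }
  out
}

## Definitional convergent scanner.
oracle_conv_columns <- function(m, pair, min_ident = 1, min_cov = 0.5) {
  std <- rownames(grantham_matrix())
  bg <- setdiff(rownames(m), pair)
  out <- integer(0)
  for (j in seq_len(ncol(m))) {
    f1 <- m[pair[1L], j]; f2 <- m[pair[2L], j]
    if (f1 != f2 || !f1 %in% std) next
    res <- m[bg, j]
    res <- res[!res %in% c("-", "X", "*")]
    if (length(res) < min_cov * length(bg)) next
    tab <- sort(table(res), decreasing = TRUE)
    b <- names(tab)[1L]
    if (!b %in% std) next
    if (tab[[1L]] / length(res) < min_ident) next
    if (b == f1) next
    if (f1 %in% res) next
    out <- c(out, j)
  }
  out
}

## Step-up BH by direct formula (independent of stats::p.adjust).
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

## Hypergeometric upper tail by exhaustive enumeration of all draws.
oracle_hyper_enum <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # first K elements carry the term
  mean(hits >= k)
}

## Chi-square upper tail via numerical integration of the density.
oracle_chisq_tail <- function(stat, df) {
  stats::integrate(function(x) stats::dchisq(x, df), stat, Inf,
                   rel.tol = 1e-10)$value
}

## Random gappy codon alignment over a fixed taxa set (for definitional
## screen/4D comparisons). Avoids internal stops by construction.
random_codon_alignment <- function(n_taxa = 6L, n_codons = 15L,
                                   gap_prob = 0.08, n_prob = 0.03) {
  code <- genetic_code()
  taxa <- paste0("t", seq_len(n_taxa))
  base <- sample(code$sense_codons, n_codons, replace = TRUE)
  m <- matrix(base, nrow = n_taxa, ncol = n_codons, byrow = TRUE)
  ## sprinkle substitutions
  nmut <- rpois(1, n_taxa * n_codons * 0.15)
  if (nmut > 0) {
    ii <- sample(length(m), min(nmut, length(m)))
    m[ii] <- sample(code$sense_codons, length(ii), replace = TRUE)
  }
  m[runif(length(m)) < gap_prob] <- "---"
  nn <- runif(length(m)) < n_prob
  m[nn] <- vapply(m[nn], function(cd) {
    substr(cd, sample(3, 1), sample(3, 1)) <- "N"; cd
  }, character(1))
  seqs <- apply(m, 1L, paste, collapse = "")
  names(seqs) <- taxa
  codon_alignment(seqs, gene_id = "rand")
}
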