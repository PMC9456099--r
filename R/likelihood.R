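#' Precompute everything the pruning likelihood needs for one gene
#'
#' Prunes the tree to the alignment's taxa, reorders edges postorder,
#' compresses identical alignment columns into site patterns (which leaves
#' the likelihood unchanged but bounds the work by the number of distinct
#' columns), and builds per-tip partial-likelihood matrices. Codons
#' containing `N` or `-` contribute all-ones partials (missing data).
#'
#' @param aln a [codon_alignment()].
#' @param tree an `ape::phylo` covering the alignment's taxa (extra tips are
#'   pruned; foreground marks are remapped).
#' @param code a [genetic_code()].
#' @return a `likelihood_data` list used by [pattern_log_likelihoods()] and
#'   the fitting functions.
#' @export
likelihood_data <- function(aln, tree, code = genetic_code()) {
  if (length(aln$taxa) == 1L) return(single_taxon_data(aln, code))
  tr <- prune_to_taxa(tree, aln$taxa)
  idx <- codon_index_matrix(aln, code)
  idx <- idx[tr$tip.label, , drop = FALSE]   # rows in tip order
  key <- apply(idx, 2L, paste, collapse = ",")
  upat <- !duplicated(key)
  patterns <- idx[, upat, drop = FALSE]
  weights <- as.numeric(table(factor(key, levels = key[upat])))
  nst <- length(code$sense_codons)
  npat <- ncol(patterns)
  tipL <- lapply(seq_len(nrow(patterns)), function(i) {
    m <- matrix(0, nst, npat)
    st <- patterns[i, ]
    obs <- which(!is.na(st))
    m[cbind(st[obs], obs)] <- 1
    if (length(obs) < npat) m[, setdiff(seq_len(npat), obs)] <- 1
    m
  })
  po <- stats::reorder(tr, "postorder")
  ## carry foreground marks into the postorder edge ordering
  fg <- foreground_edges(tr)
  ord <- match(paste(po$edge[, 1L], po$edge[, 2L]),
               paste(tr$edge[, 1L], tr$edge[, 2L]))
  structure(list(
    tree = tr,
    edge = po$edge,
    edge_length = po$edge.length,
    foreground = fg[ord],
    ntip = length(tr$tip.label),
    root = length(tr$tip.label) + 1L,
    nnode = tr$Nnode,
    patterns = patterns,
    weights = weights,
    pattern_of_site = match(key, key[upat]),
    tipL = tipL,
    nstates = nst
  ), class = "likelihood_data")
}

## Pruning over one set of per-edge transition matrices (postorder order).
## Returns per-pattern log-likelihoods; numerically rescaled per internal node.
prune_patterns <- function(ld, P_list, pi) {
  npat <- ncol(ld$patterns)
  nst <- ld$nstates
  partial <- vector("list", ld$ntip + ld$nnode)
  logscale <- numeric(npat)
  edge <- ld$edge
  for (k in seq_len(nrow(edge))) {
    ch <- edge[k, 2L]
    if (ch <= ld$ntip) {
      Lch <- ld$tipL[[ch]]
    } else {
      Lch <- partial[[ch]]
      s <- .colSums(Lch, nst, npat)
      logscale <- logscale + log(s)
      Lch <- Lch / rep(s, each = nst)
    }
    tmp <- P_list[[k]] %*% Lch
    par <- edge[k, 1L]
    partial[[par]] <- if (is.null(partial[[par]])) tmp else partial[[par]] * tmp
  }
  root <- partial[[ld$root]]
  drop(log(pi %*% root)) + logscale
}

## Build the per-edge transition matrices for one omega assignment.
## omega_edge: numeric vector of omega per postorder edge (values repeat);
## one eigensystem per distinct omega value.
edge_transition_list <- function(ld, kappa, omega_edge, pi, scale = 1,
                                 lengths = NULL, code = genetic_code(),
                                 norm_omega = NULL) {
  lens <- (if (is.null(lengths)) ld$edge_length else lengths) * scale
  rc <- if (is.null(norm_omega)) NULL
    else raw_rate_constant(kappa, norm_omega, pi, code)
  uom <- unique(omega_edge)
  eigs <- lapply(uom, function(w)
    rate_matrix_eigen(build_rate_matrix(kappa, w, pi, code, rate_constant = rc),
                      pi))
  iom <- match(omega_edge, uom)
  lapply(seq_along(lens), function(k)
    transition_probabilities(eigs[[iom[k]]], lens[k]))
}

#' Per-pattern log-likelihoods under a single omega assignment
#'
#' @param ld a [likelihood_data()].
#' @param kappa transition/transversion ratio.
#' @param omega_edge either one omega (shared by all branches) or a numeric
#'   vector giving the omega of each postorder edge.
#' @param pi codon frequencies.
#' @param scale multiplier applied to all branch lengths (the per-gene rate).
#' @param lengths optional replacement branch lengths (postorder).
#' @param code a [genetic_code()].
#' @param norm_omega optional reference omega at which the generator is
#'   normalised (mixture classes share it); `NULL` normalises at each
#'   omega itself.
#' @return numeric vector of per-pattern log-likelihoods.
#' @export
pattern_log_likelihoods <- function(ld, kappa, omega_edge, pi, scale = 1,
                                    lengths = NULL, code = genetic_code(),
                                    norm_omega = NULL) {
  if (length(omega_edge) == 1L)
    omega_edge <- rep(omega_edge, nrow(ld$edge))
  if (ld$ntip == 1L)
    return(single_taxon_loglik(ld, pi))
  P <- edge_transition_list(ld, kappa, omega_edge, pi, scale, lengths, code,
                            norm_omega)
  prune_patterns(ld, P, pi)
}

single_taxon_data <- function(aln, code) {
  idx <- codon_index_matrix(aln, code)
  key <- as.character(idx[1L, ])
  key[is.na(idx[1L, ])] <- "NA"
  upat <- !duplicated(key)
  structure(list(
    tree = NULL, edge = matrix(integer(0), 0L, 2L), edge_length = numeric(0),
    foreground = logical(0), ntip = 1L, root = 1L, nnode = 0L,
    patterns = idx[, upat, drop = FALSE],
    weights = as.numeric(table(factor(key, levels = key[upat]))),
    pattern_of_site = match(key, key[upat]),
    tipL = NULL, nstates = length(code$sense_codons)
  ), class = "likelihood_data")
}

single_taxon_loglik <- function(ld, pi) {
  st <- ld$patterns[1L, ]
  out <- numeric(ncol(ld$patterns))
  out[!is.na(st)] <- log(pi[st[!is.na(st)]])
  out
}

#' Total log-likelihood of an alignment on a tree
#'
#' Felsenstein pruning over the 61 sense-codon states. `omega` may be a
#' single value (one-ratio model) or, with `foreground` marks present on the
#' tree, a pair `c(background, foreground)` applied to the marked branches
#' (two-ratio model).
#'
#' @param aln a [codon_alignment()].
#' @param tree an `ape::phylo` (optionally marked; see [mark_foreground()]).
#' @param kappa transition/transversion ratio.
#' @param omega one omega, or `c(omega_bg, omega_fg)`.
#' @param pi codon frequencies; default F3x4 from the alignment.
#' @param scale branch-length multiplier (default 1).
#' @param code a [genetic_code()].
#' @return the log-likelihood (sum over sites).
#' @export
log_likelihood <- function(aln, tree, kappa, omega, pi = NULL, scale = 1,
                           code = genetic_code()) {
  if (is.null(pi)) pi <- codon_frequencies(aln, "F3x4", code)
  ld <- likelihood_data(aln, tree, code)
  omega_edge <- if (length(omega) == 1L) rep(omega, nrow(ld$edge))
    else ifelse(ld$foreground, omega[2L], omega[1L])
  sum(ld$weights *
        pattern_log_likelihoods(ld, kappa, omega_edge, pi, scale, code = code))
}

## Branch-site (Model A) per-class site likelihood matrix.
## Classes: 0 (bg omega0 / fg omega0), 1 (1/1), 2a (omega0/omega2),
## 2b (1/omega2). Returns npat x 4 matrix of per-pattern likelihoods on the
## per-pattern *log* scale shifted by a common per-pattern constant to avoid
## underflow: list(logL = npat x 4 matrix of log-likelihoods).
branch_site_class_logliks <- function(ld, kappa, omega0, omega2, pi,
                                      scale = 1, norm_omega = 1,
                                      code = genetic_code()) {
  fg <- ld$foreground
  if (!any(fg)) stop("branch-site model requires foreground marks")
  om <- function(bg, f) ifelse(fg, f, bg)
  cls <- list(c0 = om(omega0, omega0), c1 = om(1, 1),
              c2a = om(omega0, omega2), c2b = om(1, omega2))
  sapply(cls, function(oe)
    pattern_log_likelihoods(ld, kappa, oe, pi, scale, code = code,
                            norm_omega = norm_omega))
}

## Mixture log-likelihood given per-class log site likelihoods and
## proportions; numerically stable via per-pattern max shift.
mixture_loglik <- function(class_logL, props, weights) {
  m <- apply(class_logL, 1L, max)
  lik <- exp(class_logL - m) %*% props
  sum(weights * (log(lik) + m))
}

## Model A site-class proportions from (p0, p1) via s = p0+p1, r = p0/(p0+p1)
modelA_props <- function(s, r) {
  c(c0 = s * r, c1 = s * (1 - r), c2a = (1 - s) * r, c2b = (1 - s) * (1 - r))
}
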