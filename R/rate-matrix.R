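## Structural masks for the 61-state GY94 generator: which codon pairs differ
## at exactly one position, whether that change is a transition, and whether
## it is nonsynonymous. Computed once per session from the code table.
codon_pair_masks <- function(code = genetic_code()) {
  if (!is.null(.omegascan_cache$masks)) return(.omegascan_cache$masks)
  sc <- code$sense_codons
  n <- length(sc)
  m1 <- matrix(unlist(strsplit(sc, "")), nrow = n, byrow = TRUE)
  diffs <- matrix(0L, n, n)
  pos <- matrix(0L, n, n)
  for (p in 1:3) {
    d <- outer(m1[, p], m1[, p], "!=")
    diffs <- diffs + d
    pos[d & diffs == 1L & pos == 0L] <- p  # position of (first) difference
  }
  single <- diffs == 1L
  ts_pair <- function(a, b) (a %in% c("A", "G") & b %in% c("A", "G")) |
    (a %in% c("C", "T") & b %in% c("C", "T"))
  is_ts <- matrix(FALSE, n, n)
  for (p in 1:3) {
    sel <- single & pos == p
    if (any(sel)) {
      idx <- which(sel, arr.ind = TRUE)
      is_ts[sel] <- ts_pair(m1[idx[, 1L], p], m1[idx[, 2L], p])
    }
  }
  aa <- code$aa[sc]
  nonsyn <- outer(aa, aa, "!=")
  masks <- list(
    syn_tv = single & !is_ts & !nonsyn,
    syn_ts = single & is_ts & !nonsyn,
    nsy_tv = single & !is_ts & nonsyn,
    nsy_ts = single & is_ts & nonsyn)
  .omegascan_cache$masks <- masks
  masks
}

#' Equilibrium codon frequencies
#'
#' @param aln a [codon_alignment()] (ignored for `"equal"`).
#' @param method `"F3x4"` (positional nucleotide frequencies, the default),
#'   `"F1x4"` (pooled nucleotide frequencies), `"equal"` (1/61), or
#'   `"empirical"` (observed codon frequencies).
#' @param code a [genetic_code()].
#' @param floor lower bound applied before renormalisation so no sense codon
#'   has zero frequency.
#' @return numeric vector of 61 frequencies (names = sense codons), sum 1.
#' @export
codon_frequencies <- function(aln = NULL,
                              method = c("F3x4", "F1x4", "equal", "empirical"),
                              code = genetic_code(), floor = 1e-8) {
  method <- match.arg(method)
  sc <- code$sense_codons
  if (method == "equal")
    return(setNames(rep(1 / length(sc), length(sc)), sc))
  stopifnot(!is.null(aln))
  cm <- codon_matrix(aln)
  chars <- matrix(unlist(strsplit(as.vector(cm), "")), nrow = 3L)
  scm <- matrix(unlist(strsplit(sc, "")), nrow = length(sc), byrow = TRUE)
  if (method == "F3x4") {
    pos_freq <- sapply(1:3, function(p) {
      x <- chars[p, ]
      x <- x[x %in% c("A", "C", "G", "T")]
      tab <- table(factor(x, levels = c("A", "C", "G", "T")))
      as.numeric(tab) / max(sum(tab), 1L)
    })
    rownames(pos_freq) <- c("A", "C", "G", "T")
    pi <- pos_freq[scm[, 1L], 1L] * pos_freq[scm[, 2L], 2L] * pos_freq[scm[, 3L], 3L]
  } else if (method == "F1x4") {
    x <- as.vector(chars)
    x <- x[x %in% c("A", "C", "G", "T")]
    tab <- table(factor(x, levels = c("A", "C", "G", "T")))
    nf <- as.numeric(tab) / max(sum(tab), 1L)
    names(nf) <- c("A", "C", "G", "T")
    pi <- nf[scm[, 1L]] * nf[scm[, 2L]] * nf[scm[, 3L]]
  } else {  # empirical
    obs <- as.vector(cm)
    obs <- obs[obs %in% sc]
    tab <- table(factor(obs, levels = sc))
    pi <- as.numeric(tab) / max(sum(tab), 1L)
  }
  pi <- pmax(pi, floor)
  pi <- pi / sum(pi)
  setNames(as.numeric(pi), sc)
}

#' GY94 codon rate generator
#'
#' Off-diagonal rate from codon i to j is zero if the codons differ at more
#' than one nucleotide, and otherwise
#' `s * pi_j * kappa^[transition] * omega^[nonsynonymous]`, with the diagonal
#' set to minus the row sum and the scale `s` chosen so the mean substitution
#' rate at stationarity is 1 (`-sum_i pi_i q_ii = 1`), i.e. branch lengths
#' are expected substitutions per codon site.
#'
#' When `rate_constant` is supplied the matrix is instead divided by that
#' constant. Site-class mixtures use this to share one synonymous rate
#' across classes (all class generators divided by the same constant, see
#' [raw_rate_constant()]), so that a class with elevated omega genuinely
#' evolves faster rather than being renormalised to unit rate.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega nonsynonymous/synonymous rate ratio (>= 0).
#' @param pi equilibrium codon frequencies from [codon_frequencies()].
#' @param code a [genetic_code()].
#' @param rate_constant optional common scaling divisor replacing the
#'   per-matrix normalisation.
#' @return 61 x 61 generator matrix (dimnames = sense codons).
#' @export
build_rate_matrix <- function(kappa, omega, pi, code = genetic_code(),
                              rate_constant = NULL) {
  stopifnot(is.finite(kappa), kappa > 0, is.finite(omega), omega >= 0,
            length(pi) == length(code$sense_codons))
  mk <- codon_pair_masks(code)
  fac <- mk$syn_tv + kappa * mk$syn_ts + omega * mk$nsy_tv +
    (kappa * omega) * mk$nsy_ts
  n <- length(pi)
  q <- fac * rep(pi, each = n)   # column j scaled by pi_j
  diag(q) <- -rowSums(q)
  s <- if (is.null(rate_constant)) -sum(pi * diag(q)) else rate_constant
  q <- q / s
  dimnames(q) <- list(code$sense_codons, code$sense_codons)
  q
}

#' Mean substitution rate of the unnormalised GY94 generator
#'
#' `-sum_i pi_i q_ii` of the raw (unscaled) generator at the given
#' parameters: the constant that [build_rate_matrix()] divides by when
#' normalising at its own omega. Mixture models divide every class matrix
#' by this constant evaluated at a single reference omega, which fixes the
#' synonymous rate across classes.
#'
#' @inheritParams build_rate_matrix
#' @return the mean raw rate (a positive scalar, linear in omega).
#' @export
raw_rate_constant <- function(kappa, omega, pi, code = genetic_code()) {
  mk <- codon_pair_masks(code)
  n <- length(pi)
  pp <- pi * rep(pi, each = n)  # pi_i * pi_j  (pi recycles over rows)
  ## pp[i,j] = pi_j * pi_i? rep(pi, each=n) is pi_j per column; pi recycles
  ## down rows giving pi_i: product is pi_i * pi_j either way (symmetric use)
  a <- sum(pp * mk$syn_tv); b <- sum(pp * mk$syn_ts)
  cc <- sum(pp * mk$nsy_tv); d <- sum(pp * mk$nsy_ts)
  a + kappa * b + omega * cc + kappa * omega * d
}

#' Eigensystem of a reversible codon generator
#'
#' Uses the pi-symmetrised form `S = diag(sqrt(pi)) Q diag(1/sqrt(pi))`,
#' whose symmetric eigendecomposition gives real eigenvalues and lets the
#' transition matrix be assembled with two dense multiplications per branch.
#'
#' @param q generator from [build_rate_matrix()].
#' @param pi its stationary frequencies.
#' @return list `A`, `B`, `d` with `P(t) = A %*% (exp(d t) * B)`.
#' @export
rate_matrix_eigen <- function(q, pi) {
  sp <- sqrt(pi)
  s <- q * (sp / rep(pi, each = length(pi)) * rep(sp, each = length(pi)))
  ## the line above computes diag(sp) %*% Q %*% diag(1/sp) elementwise:
  ## s_ij = sp_i * q_ij / sp_j
  s <- (s + t(s)) / 2  # enforce exact symmetry against rounding
  e <- eigen(s, symmetric = TRUE)
  A <- e$vectors / sp          # rows scaled by 1/sqrt(pi_i)
  B <- t(e$vectors * sp)       # columns of V scaled by sqrt(pi_j), transposed
  list(A = A, B = B, d = e$values)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param eig eigensystem from [rate_matrix_eigen()] (or a generator matrix,
#'   in which case `pi` must be supplied).
#' @param t branch length, >= 0.
#' @param pi stationary frequencies (only when `eig` is a raw generator).
#' @return stochastic 61 x 61 matrix; tiny negative entries from rounding
#'   are clamped to zero.
#' @export
transition_probabilities <- function(eig, t, pi = NULL) {
  if (is.matrix(eig)) {
    stopifnot(!is.null(pi))
    eig <- rate_matrix_eigen(eig, pi)
  }
  stopifnot(is.finite(t), t >= 0)
  p <- eig$A %*% (exp(eig$d * t) * eig$B)
  p[p < 0] <- 0
  p
}
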