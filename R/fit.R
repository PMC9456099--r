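## Parameter bounds shared by all fits (log-scale optimization).
.fit_bounds <- list(omega = c(1e-4, 50), kappa = c(0.01, 100),
                    scale = c(1e-3, 100), length = c(1e-8, 20))

.neg_big <- 1e10

#' Fit a one-ratio or two-ratio branch model by maximum likelihood
#'
#' The one-ratio (null) model shares a single omega across all branches and
#' estimates, per gene, a rate scale applied to the input tree's branch
#' lengths, kappa, and omega. The two-ratio (alternative) model gives the
#' marked foreground branches their own shared omega; following common
#' practice the scale and kappa are held at the null fit's estimates so the
#' test has one extra free parameter (`df = 1`).
#' `per_branch_omega = TRUE` instead gives each foreground branch its own
#' omega (`df =` number of foreground branches).
#'
#' @param aln a [codon_alignment()].
#' @param tree an `ape::phylo`; for `two_ratio` it must carry foreground
#'   marks (see [mark_foreground()]) or `foreground` must be given.
#' @param mode `"one_ratio"` or `"two_ratio"`.
#' @param foreground optional character vector of foreground leaf names.
#' @param freq codon frequency model (see [codon_frequencies()]); ignored
#'   when `pi` is supplied.
#' @param pi optional codon frequency vector.
#' @param null_fit for `two_ratio`: the gene's one-ratio fit, whose scale
#'   and kappa (and, in `"free"` mode, branch lengths) are reused. Fitted
#'   internally when omitted.
#' @param branch_lengths `"scale"` (default: one free rate multiplier of the
#'   input branch lengths) or `"free"` (every branch length free).
#' @param per_branch_omega in `two_ratio` mode, one omega per foreground
#'   branch instead of a single shared foreground omega.
#' @param control list: `omega_starts` (default `c(0.2, 1, 3)`), `kappa_start`
#'   (2), `factr` (1e7, passed to L-BFGS-B), `maxit` (200).
#' @param code a [genetic_code()].
#' @return a `codon_model_fit`: list with `mode`, `lnL`, `kappa`, `omega`
#'   (named vector: `omega` or `omega_bg`/`omega_fg`...), `scale`, `lengths`
#'   (postorder, unscaled input lengths), `pi`, `convergence` (0 = ok),
#'   `counts`, `np` (free parameters), and the `likelihood_data` used.
#' @export
fit_branch_model <- function(aln, tree, mode = c("one_ratio", "two_ratio"),
                             foreground = NULL,
                             freq = "F3x4", pi = NULL, null_fit = NULL,
                             branch_lengths = c("scale", "free"),
                             per_branch_omega = FALSE,
                             control = list(), code = genetic_code()) {
  mode <- match.arg(mode)
  branch_lengths <- match.arg(branch_lengths)
  ctl <- utils::modifyList(list(omega_starts = c(0.2, 1, 3), kappa_start = 2,
                                factr = 1e7, maxit = 200L), control)
  if (!is.null(foreground)) tree <- mark_foreground(tree, foreground)
  if (is.null(pi)) pi <- codon_frequencies(aln, freq, code)
  ld <- likelihood_data(aln, tree, code)
  if (mode == "one_ratio")
    fit_one_ratio(ld, pi, branch_lengths, ctl, code)
  else {
    if (!any(ld$foreground))
      stop("two_ratio model requires a non-empty foreground")
    if (is.null(null_fit))
      null_fit <- fit_one_ratio(ld, pi, branch_lengths, ctl, code)
    fit_two_ratio(ld, pi, null_fit, per_branch_omega, ctl, code)
  }
}

fit_one_ratio <- function(ld, pi, branch_lengths, ctl, code) {
  w <- ld$weights
  if (ld$ntip == 1L) {
    lnL <- sum(w * single_taxon_loglik(ld, pi))
    return(new_fit("one_ratio", lnL, kappa = NA_real_,
                   omega = c(omega = NA_real_), scale = 1, ld = ld, pi = pi,
                   convergence = 0L, counts = 0L, np = 0L))
  }
  nll_scale <- function(p) {  # p = (log scale, log kappa, log omega)
    v <- -sum(w * pattern_log_likelihoods(ld, exp(p[2L]), exp(p[3L]), pi,
                                          scale = exp(p[1L]), code = code))
    if (!is.finite(v)) .neg_big else v
  }
  ## stage A: pick the best omega start at scale 1, kappa start
  ws <- ctl$omega_starts
  a_val <- vapply(ws, function(om)
    nll_scale(log(c(1, ctl$kappa_start, om))), numeric(1))
  om0 <- ws[which.min(a_val)]
  b <- .fit_bounds
  if (branch_lengths == "scale") {
    opt <- stats::optim(log(c(1, ctl$kappa_start, om0)), nll_scale,
                        method = "L-BFGS-B",
                        lower = log(c(b$scale[1L], b$kappa[1L], b$omega[1L])),
                        upper = log(c(b$scale[2L], b$kappa[2L], b$omega[2L])),
                        control = list(factr = ctl$factr, maxit = ctl$maxit))
    new_fit("one_ratio", -opt$value, kappa = exp(opt$par[2L]),
            omega = c(omega = exp(opt$par[3L])), scale = exp(opt$par[1L]),
            ld = ld, pi = pi, convergence = opt$convergence,
            counts = opt$counts, np = 3L)
  } else {
    ne <- nrow(ld$edge)
    l0 <- pmax(ld$edge_length, 1e-4)
    nll_free <- function(p) {  # p = (log lengths..., log kappa, log omega)
      v <- -sum(w * pattern_log_likelihoods(
        ld, exp(p[ne + 1L]), exp(p[ne + 2L]), pi,
        lengths = exp(p[seq_len(ne)]), code = code))
      if (!is.finite(v)) .neg_big else v
    }
    opt <- stats::optim(log(c(l0, ctl$kappa_start, om0)), nll_free,
                        method = "L-BFGS-B",
                        lower = log(c(rep(b$length[1L], ne), b$kappa[1L], b$omega[1L])),
                        upper = log(c(rep(b$length[2L], ne), b$kappa[2L], b$omega[2L])),
                        control = list(factr = ctl$factr, maxit = ctl$maxit))
    fit <- new_fit("one_ratio", -opt$value, kappa = exp(opt$par[ne + 1L]),
                   omega = c(omega = exp(opt$par[ne + 2L])), scale = 1,
                   ld = ld, pi = pi, convergence = opt$convergence,
                   counts = opt$counts, np = ne + 2L)
    fit$lengths <- exp(opt$par[seq_len(ne)])
    fit
  }
}

fit_two_ratio <- function(ld, pi, null_fit, per_branch_omega, ctl, code) {
  w <- ld$weights
  fg <- ld$foreground
  kappa <- null_fit$kappa
  scale <- null_fit$scale
  lengths <- null_fit$lengths  # NULL unless free mode
  om_null <- unname(null_fit$omega[1L])
  b <- .fit_bounds$omega
  if (!per_branch_omega) {
    nll <- function(p) {  # (log w_bg, log w_fg)
      oe <- ifelse(fg, exp(p[2L]), exp(p[1L]))
      v <- -sum(w * pattern_log_likelihoods(ld, kappa, oe, pi, scale,
                                            lengths, code))
      if (!is.finite(v)) .neg_big else v
    }
    starts <- unique(c(om_null, ctl$omega_starts))
    sv <- vapply(starts, function(om) nll(log(c(om_null, om))), numeric(1))
    p0 <- log(c(om_null, starts[which.min(sv)]))
    opt <- stats::optim(p0, nll, method = "L-BFGS-B",
                        lower = log(rep(b[1L], 2L)), upper = log(rep(b[2L], 2L)),
                        control = list(factr = ctl$factr, maxit = ctl$maxit))
    lnL <- max(-opt$value, null_fit$lnL)  # alternative nests the null
    new_fit("two_ratio", lnL, kappa = kappa,
            omega = c(omega_bg = exp(opt$par[1L]), omega_fg = exp(opt$par[2L])),
            scale = scale, ld = ld, pi = pi,
            convergence = opt$convergence, counts = opt$counts,
            np = null_fit$np + 1L, lengths = lengths)
  } else {
    fgi <- which(fg)
    k <- length(fgi)
    nll <- function(p) {  # (log w_bg, log w_fg_1..k)
      oe <- rep(exp(p[1L]), nrow(ld$edge))
      oe[fgi] <- exp(p[1L + seq_len(k)])
      v <- -sum(w * pattern_log_likelihoods(ld, kappa, oe, pi, scale,
                                            lengths, code))
      if (!is.finite(v)) .neg_big else v
    }
    p0 <- log(rep(om_null, k + 1L))
    opt <- stats::optim(p0, nll, method = "L-BFGS-B",
                        lower = log(rep(b[1L], k + 1L)),
                        upper = log(rep(b[2L], k + 1L)),
                        control = list(factr = ctl$factr, maxit = ctl$maxit))
    om <- exp(opt$par)
    names(om) <- c("omega_bg", paste0("omega_fg", seq_len(k)))
    lnL <- max(-opt$value, null_fit$lnL)
    new_fit("two_ratio", lnL, kappa = kappa, omega = om, scale = scale,
            ld = ld, pi = pi, convergence = opt$convergence,
            counts = opt$counts, np = null_fit$np + k, lengths = lengths)
  }
}

new_fit <- function(mode, lnL, kappa, omega, scale, ld, pi, convergence,
                    counts, np, lengths = NULL, extra = list()) {
  structure(c(list(mode = mode, lnL = lnL, kappa = kappa, omega = omega,
                   scale = scale, lengths = lengths, pi = pi, ld = ld,
                   convergence = convergence, counts = counts, np = np),
              extra),
            class = "codon_model_fit")
}

#' @export
print.codon_model_fit <- function(x, ...) {
  cat("codon_model_fit [", x$mode, "] lnL = ", sprintf("%.4f", x$lnL),
      "\n  kappa = ", sprintf("%.3f", x$kappa),
      ", scale = ", sprintf("%.3f", x$scale), "\n  ", sep = "")
  cat(paste(names(x$omega), sprintf("%.4f", x$omega), sep = " = ",
            collapse = ", "), "\n")
  if (!is.null(x$props))
    cat("  props:", paste(names(x$props), sprintf("%.3f", x$props),
                          sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Fit the branch-site model (Model A) or its null
#'
#' Model A mixes four site classes over a foreground/background branch
#' partition: class 0 (omega0 on all branches), class 1 (omega 1 on all
#' branches), and classes 2a/2b in which foreground branches switch to
#' omega2 while the background keeps omega0 (2a) or 1 (2b). Proportions
#' derive from `(p0, p1)` as `p2a = (1-p0-p1) p0/(p0+p1)`,
#' `p2b = (1-p0-p1) p1/(p0+p1)`. The null fixes `omega2 = 1`.
#'
#' Branch lengths (via the per-gene scale) and kappa are held at a one-ratio
#' fit's estimates; the mixture proportions are profiled out in an inner
#' optimization, so the outer search is over omega0 (null) or
#' (omega0, omega2) (alternative) only — the same MLE, found faster.
#'
#' @inheritParams fit_branch_model
#' @param alternative `TRUE` for Model A (omega2 free, >= 1), `FALSE` for
#'   the null (omega2 = 1).
#' @param null_fit a one-ratio `codon_model_fit` for this gene (fitted
#'   internally when omitted).
#' @return a `codon_model_fit` with `omega = c(omega0, omega2)`, `props`
#'   (the four class proportions), `p0`, `p1`, and `class_logL` (per-pattern
#'   per-class log-likelihoods at the MLE, for [site_posteriors()]).
#' @export
fit_branch_site_model <- function(aln, tree, alternative = TRUE,
                                  foreground = NULL, freq = "F3x4", pi = NULL,
                                  null_fit = NULL, control = list(),
                                  code = genetic_code()) {
  ctl <- utils::modifyList(list(kappa_start = 2, factr = 1e7, maxit = 200L),
                           control)
  if (!is.null(foreground)) tree <- mark_foreground(tree, foreground)
  if (is.null(pi)) pi <- codon_frequencies(aln, freq, code)
  ld <- likelihood_data(aln, tree, code)
  if (!any(ld$foreground))
    stop("branch-site model requires a non-empty foreground")
  if (is.null(null_fit))
    null_fit <- fit_one_ratio(ld, pi, "scale", utils::modifyList(
      list(omega_starts = c(0.2, 1, 3)), ctl), code)
  kappa <- null_fit$kappa
  scale <- null_fit$scale
  ## classes share the synonymous rate: every class generator is divided by
  ## the rate constant at the gene's one-ratio omega, so branch lengths stay
  ## in expected substitutions per codon at the gene's average omega while
  ## omega2 > 1 classes genuinely evolve faster.
  ref_om <- max(unname(null_fit$omega[1L]), 1e-4)
  w <- ld$weights
  fg <- ld$foreground
  om_edge <- function(bg, f) ifelse(fg, f, bg)
  memo <- new.env(parent = emptyenv())
  class_ll <- function(bg, f) {
    key <- paste(signif(bg, 12), signif(f, 12))
    got <- memo[[key]]
    if (is.null(got)) {
      got <- pattern_log_likelihoods(ld, kappa, om_edge(bg, f), pi, scale,
                                     code = code, norm_omega = ref_om)
      memo[[key]] <- got
    }
    got
  }
  profile_props <- function(logL4) {
    obj <- function(q) {
      v <- -mixture_loglik(logL4, modelA_props(stats::plogis(q[1L]),
                                               stats::plogis(q[2L])), w)
      if (!is.finite(v)) .neg_big else v
    }
    ## Nelder-Mead: the logistic transform makes bounds unnecessary, and the
    ## inner objective is too cheap for gradient-based search to pay off
    best <- NULL
    for (st in list(c(1.4, 0.8), c(3, 0))) {
      o <- stats::optim(st, obj, method = "Nelder-Mead",
                        control = list(maxit = 500L, reltol = 1e-10))
      if (is.null(best) || o$value < best$value) best <- o
    }
    list(lnL = -best$value, s = stats::plogis(best$par[1L]),
         r = stats::plogis(best$par[2L]))
  }
  eval_point <- function(om0, om2) {
    logL4 <- cbind(c0 = class_ll(om0, om0), c1 = class_ll(1, 1),
                   c2a = class_ll(om0, om2), c2b = class_ll(1, om2))
    c(profile_props(logL4), list(logL4 = logL4))
  }
  b <- .fit_bounds$omega
  if (!alternative) {
    opt <- stats::optimize(function(lw) -eval_point(exp(lw), 1)$lnL,
                           lower = log(b[1L]), upper = 0, tol = 1e-4)
    om0 <- exp(opt$minimum); om2 <- 1
    conv <- 0L; counts <- NA_integer_
  } else {
    nll <- function(p) -eval_point(min(exp(p[1L]), 1), max(exp(p[2L]), 1))$lnL
    sv <- vapply(c(2, 5), function(o2) nll(log(c(0.2, o2))), numeric(1))
    p0 <- log(c(0.2, c(2, 5)[which.min(sv)]))
    opt <- stats::optim(p0, nll, method = "L-BFGS-B",
                        lower = log(c(b[1L], 1)), upper = log(c(1, b[2L])),
                        control = list(factr = ctl$factr, maxit = ctl$maxit))
    om0 <- min(exp(opt$par[1L]), 1); om2 <- max(exp(opt$par[2L]), 1)
    conv <- opt$convergence; counts <- opt$counts
  }
  at <- eval_point(om0, om2)
  props <- modelA_props(at$s, at$r)
  fit <- new_fit(if (alternative) "branch_site_alt" else "branch_site_null",
                 at$lnL, kappa = kappa,
                 omega = c(omega0 = om0, omega2 = om2), scale = scale,
                 ld = ld, pi = pi, convergence = conv, counts = counts,
                 np = null_fit$np + if (alternative) 4L else 3L,
                 extra = list(props = props, p0 = unname(props[1L]),
                              p1 = unname(props[2L]), class_logL = at$logL4))
  fit
}

#' Likelihood ratio test between nested fits
#'
#' @param null_fit,alt_fit `codon_model_fit`s of nested models on the same
#'   data (or bare log-likelihood numbers).
#' @param df degrees of freedom (positive integer).
#' @return an `lrt_result`: list with `lnL_null`, `lnL_alt`,
#'   `statistic = 2 (lnL_alt - lnL_null)` (clamped at 0), `df`, `p_value`
#'   (upper chi-square tail).
#' @export
likelihood_ratio_test <- function(null_fit, alt_fit, df = 1L) {
  if (!is.numeric(df) || length(df) != 1L || df <= 0 || df != round(df))
    stop("df must be a positive integer")
  l0 <- if (is.list(null_fit)) null_fit$lnL else null_fit
  l1 <- if (is.list(alt_fit)) alt_fit$lnL else alt_fit
  stopifnot(is.finite(l0), is.finite(l1))
  stat <- max(0, 2 * (l1 - l0))
  structure(list(lnL_null = l0, lnL_alt = l1, statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: 2*dlnL = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Naive empirical Bayes site posteriors under the branch-site model
#'
#' Posterior class probabilities per codon column, proportional to the MLE
#' class proportion times the class site likelihood (plug-in empirical
#' Bayes; no integration over parameter uncertainty). A site is flagged
#' positively selected when `P(class 2a) + P(class 2b) > threshold`.
#'
#' @param fit an alternative `codon_model_fit` from
#'   [fit_branch_site_model()].
#' @param threshold posterior probability cutoff, default 0.95.
#' @return data.frame with one row per codon column: `site`, `p0`, `p1`,
#'   `p2a`, `p2b`, `p_selected` and logical `flagged`.
#' @export
site_posteriors <- function(fit, threshold = 0.95) {
  stopifnot(!is.null(fit$class_logL), !is.null(fit$props))
  m <- apply(fit$class_logL, 1L, max)
  lik <- exp(fit$class_logL - m) * rep(fit$props, each = nrow(fit$class_logL))
  post <- lik / rowSums(lik)
  post_sites <- post[fit$ld$pattern_of_site, , drop = FALSE]
  psel <- post_sites[, "c2a"] + post_sites[, "c2b"]
  data.frame(site = seq_along(fit$ld$pattern_of_site),
             p0 = post_sites[, "c0"], p1 = post_sites[, "c1"],
             p2a = post_sites[, "c2a"], p2b = post_sites[, "c2b"],
             p_selected = psel, flagged = psel > threshold)
}
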