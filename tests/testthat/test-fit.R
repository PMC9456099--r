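fit_tree <- function() default_study_tree()

test_that("chi-square LRT machinery matches a numerical-integration oracle", {
  expect_error(likelihood_ratio_test(-10, -9, df = 0))
  r0 <- likelihood_ratio_test(-100, -100, df = 1)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  ## slightly negative statistics clamp to zero
  expect_equal(likelihood_ratio_test(-100, -100.0000001, df = 1)$statistic, 0)
  for (case in list(c(3.841, 1, 0.05), c(6.635, 1, 0.01))) {
    r <- likelihood_ratio_test(-100, -100 + case[1] / 2, df = case[2])
    expect_equal(r$p_value, case[3], tolerance = 1e-3)
    expect_equal(r$p_value, oracle_chisq_tail(case[1], case[2]),
                 tolerance = 1e-9)
  }
})

test_that("two-ratio alternative never falls below the one-ratio null", {
  tr <- fit_tree()
  set.seed(31)
  for (rep in 1:3) {
    om <- c(0.2, 1, 3)[rep]
    aln <- simulate_codon_alignment(tr, 150, list(type = "null", omega = om))
    n0 <- fit_branch_model(aln, tr, "one_ratio")
    a1 <- fit_branch_model(aln, tr, "two_ratio", null_fit = n0)
    expect_gte(a1$lnL, n0$lnL - 1e-6)
  }
})

test_that("two-taxon omega MLE matches a one-dimensional grid search", {
  set.seed(32)
  tr2 <- read_species_tree(text = "(A:0.4,B:0.4);")
  aln <- simulate_codon_alignment(tr2, 400, list(type = "null", omega = 0.5))
  pi <- codon_frequencies(aln, "F3x4")
  fit <- fit_branch_model(aln, tr2, "one_ratio", pi = pi,
                          control = list(kappa_start = 2))
  ## grid over omega at the fitted scale and kappa
  grid <- exp(seq(log(0.05), log(5), length.out = 121))
  gl <- vapply(grid, function(om)
    log_likelihood(aln, tr2, fit$kappa, om, pi = pi, scale = fit$scale),
    numeric(1))
  om_grid <- grid[which.max(gl)]
  step <- log(grid[2]) - log(grid[1])
  expect_lt(abs(log(unname(fit$omega[1])) - log(om_grid)), step)
  expect_gte(fit$lnL, max(gl) - 1e-4)
})

test_that("free-branch-length fitting agrees with the scaled fit on scale-true data", {
  set.seed(33)
  tr <- fit_tree()
  aln <- simulate_codon_alignment(tr, 200, list(type = "null", omega = 0.3))
  fs <- fit_branch_model(aln, tr, "one_ratio", branch_lengths = "scale")
  ff <- fit_branch_model(aln, tr, "one_ratio", branch_lengths = "free")
  ## the free model nests the scaled model
  expect_gte(ff$lnL, fs$lnL - 1e-3)
  ## omega estimates agree closely
  expect_equal(unname(ff$omega[1]), unname(fs$omega[1]), tolerance = 0.1)
})

test_that("per-branch foreground omegas nest the shared foreground omega", {
  set.seed(34)
  tr <- fit_tree()
  aln <- simulate_codon_alignment(
    tr, 150, list(type = "branch", omega_bg = 0.2, omega_fg = 3))
  n0 <- fit_branch_model(aln, tr, "one_ratio")
  shared <- fit_branch_model(aln, tr, "two_ratio", null_fit = n0)
  perbr <- fit_branch_model(aln, tr, "two_ratio", null_fit = n0,
                            per_branch_omega = TRUE)
  expect_gte(perbr$lnL, shared$lnL - 1e-4)
  expect_length(perbr$omega, 3L)  # bg + 2 foreground branches
})

test_that("branch-site alternative with omega2 pinned to 1 reproduces the null", {
  set.seed(35)
  tr <- fit_tree()
  aln <- simulate_codon_alignment(tr, 150, list(type = "null", omega = 0.3))
  n0 <- fit_branch_model(aln, tr, "one_ratio")
  b0 <- fit_branch_site_model(aln, tr, alternative = FALSE, null_fit = n0)
  b1 <- fit_branch_site_model(aln, tr, alternative = TRUE, null_fit = n0)
  expect_gte(b1$lnL, b0$lnL - 1e-4)
  ## class proportions are a simplex and derive from (p0, p1)
  expect_equal(sum(b1$props), 1, tolerance = 1e-12)
  s <- b1$p0 + b1$p1
  expect_equal(unname(b1$props["c2a"]), (1 - s) * b1$p0 / s, tolerance = 1e-9)
})

test_that("site posteriors normalise and respect a saturated null mixture", {
  set.seed(36)
  tr <- fit_tree()
  aln <- simulate_codon_alignment(
    tr, 200, list(type = "branch_site", p0 = 0.7, p1 = 0.2,
                  omega0 = 0.1, omega2 = 6))
  n0 <- fit_branch_model(aln, tr, "one_ratio")
  b1 <- fit_branch_site_model(aln, tr, alternative = TRUE, null_fit = n0)
  post <- site_posteriors(b1)
  expect_equal(nrow(post), 200L)
  expect_equal(post$p0 + post$p1 + post$p2a + post$p2b, rep(1, 200),
               tolerance = 1e-12)
  ## flagged sites are enriched for the truly selected site classes
  truth <- attr(aln, "site_class")
  flagged <- which(post$flagged)
  expect_gt(length(flagged), 0L)
  expect_gt(mean(truth[flagged] %in% c("c2a", "c2b")), 0.5)
  ## no class-2 mass -> nothing flagged
  b_nom <- b1
  b_nom$props <- c(c0 = 0.7, c1 = 0.3, c2a = 0, c2b = 0)
  expect_equal(sum(site_posteriors(b_nom)$flagged), 0L)
})
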