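# Model fitting: recovery, nesting, dN/dS decomposition, the dS filter.

test_that("M0 recovers generating parameters and dominates the truth", {
  tr <- tree6()
  mix <- site_class_mixture(2, uniform_codon_frequencies(), 1, 0.3)
  aln <- simulate_codon_alignment(simulation_scenario(tr, mix, 500, seed = 21,
                                                      name = "rec"))
  fit <- fit_m0(aln, tr, starts = 1, control = light_ctl)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$omega - 0.3), 0.1)
  expect_lt(abs(fit$params$kappa - 2), 0.5)
  # the MLE cannot be beaten by the generating parameters
  truth <- tree_loglik(aln, tr, site_class_mixture(2, fit$freqs, 1, 0.3))
  expect_gte(fit$loglik, truth$loglik - 1e-6)
})

test_that("identical sequences collapse branch lengths and flag omega", {
  seq <- paste(rep("ATGGCTAAAGAT", 5), collapse = "")
  aln <- clean_alignment(codon_alignment(
    stats::setNames(rep(seq, 4), c("A", "B", "C", "D"))))
  fit <- fit_m0(aln, tree4(), starts = 1, control = light_ctl)
  expect_lt(sum(fit$branch_lengths), 1e-3)
  expect_false(fit$identifiable)
  expect_equal(fit$loglik, sum(log(fit$freqs$pi[aln$codons[1, ]])),
               tolerance = 1e-3)
})

test_that("dN/dS decomposition is internally consistent", {
  aln <- sim_codon(tree4(), 120, seed = 31)
  fit <- fit_m0(aln, tree4(), starts = 1, control = light_ctl)
  tb <- fit$per_branch_dNdS
  # recomputed per-branch ratio equals the fitted omega
  expect_equal(tb$omega[tb$t > 1e-4], rep(fit$params$omega, sum(tb$t > 1e-4)),
               tolerance = 1e-6)
  # neutral case: dN = dS on every branch
  fit1 <- fit
  fit1$params$omega <- 1
  tb1 <- decompose_dnds(fit1)
  expect_equal(tb1$dN, tb1$dS, tolerance = 1e-10)
  # direct flow summation oracle for rho_N at omega = 1, uniform pi:
  # proportion of nonsynonymous flow = fraction of nonsynonymous
  # single-step neighbour rate mass
  fr <- uniform_codon_frequencies()
  m1 <- codon_rate_matrix(2, 1, fr)
  cp <- chlorosel:::.codon_pairs
  rate <- ifelse(cp$transition, 2, 1) / 61
  rho_oracle <- sum(rate[!cp$synonymous] / 61) / sum(rate / 61)
  expect_equal(m1$rho_n, rho_oracle, tolerance = 1e-12)
})

test_that("the dS filter retains and discards by the max-branch rule", {
  mk_fit <- function(gene, ds_values) {
    structure(list(dataset_id = gene,
                   per_branch_dNdS = data.frame(
                     parent = 5, child = seq_along(ds_values),
                     label = letters[seq_along(ds_values)],
                     t = ds_values, dN = 0.01, dS = ds_values,
                     omega = 0.1)),
              class = "fit_result")
  }
  fits <- list(mk_fit("low", c(0.5, 0.4)), mk_fit("high", c(0.3, 1.5)))
  out <- filter_genes_by_ds(fits, 1.0)
  expect_equal(out$retained, "low")
  expect_equal(out$discarded$gene, "high")
  expect_equal(out$discarded$branch, "b")
  empty <- filter_genes_by_ds(list(), 1.0)
  expect_equal(empty$retained, character(0))
  expect_equal(nrow(empty$discarded), 0L)
})

test_that("branch model nests the one-ratio null", {
  tr <- tree6()
  mix <- site_class_mixture(2, uniform_codon_frequencies(), 1, 0.15)
  aln <- simulate_codon_alignment(simulation_scenario(tr, mix, 300, seed = 41,
                                                      name = "br"))
  fits <- fit_branch_model(aln, tr, "A", starts = 1, control = light_ctl)
  expect_gte(fits$alt$loglik, fits$null$loglik - 1e-6)
  # same-omega data: estimates close, LRT small
  r <- lrt(fits$null$loglik, fits$alt$loglik)
  expect_lt(r$stat, 6)
  expect_error(fit_branch_model(aln, tr, character(0)), "non-empty")
  # constrained alternative (omega_fg = omega_bg) reproduces the null
  constr <- chlorosel:::.fit_codon_model(
    aln, tr, "branch", foreground = "A", starts = 1,
    control = chlorosel:::.fit_control(light_ctl),
    fixed = list(omega_fg = fits$null$params$omega,
                 omega_bg = fits$null$params$omega))
  expect_equal(constr$loglik, fits$null$loglik, tolerance = 1e-4)
})

test_that("branch model detects strong foreground divergence", {
  tr <- tree6()
  mix <- site_class_mixture(2, uniform_codon_frequencies(), 1,
                            omega_bg = 0.1, omega_fg = 1.5)
  aln <- simulate_codon_alignment(simulation_scenario(tr, mix, 500, seed = 42,
                                                      foreground = "A",
                                                      name = "brpow"))
  fits <- fit_branch_model(aln, tr, "A", starts = c(0.5, 2), control = light_ctl)
  expect_gt(fits$alt$params$omega_fg, fits$alt$params$omega_bg)
  expect_gt(lrt(fits$null$loglik, fits$alt$loglik)$stat, 3.84)
})

test_that("M8 nests M8a and the discretized beta behaves", {
  aln <- sim_codon(tree6(), 200, omega = 0.1, seed = 51)
  fits <- fit_site_models(aln, tree6(), starts = 1.2, control = light_ctl)
  expect_gte(fits$alt$loglik, fits$null$loglik - 1e-6)
  # purifying-only data: little support for omega_s > 1
  expect_lt(lrt(fits$null$loglik, fits$alt$loglik)$stat, 6)
  # explicit nesting at fixed parameters: M8 with omega_s = 1 equals M8a
  fr <- f3x4_frequencies(aln)
  p0 <- 0.9; p <- 0.4; q <- 1.7
  w <- stats::qbeta((1:10 - 0.5) / 10, p, q)
  m8_fixed <- site_class_mixture(2, fr, c(rep(p0 / 10, 10), 1 - p0), c(w, 1))
  m8a_fixed <- site_class_mixture(2, fr, c(rep(p0 / 10, 10), 1 - p0), c(w, 1))
  expect_equal(tree_loglik(aln, tree6(), m8_fixed)$loglik,
               tree_loglik(aln, tree6(), m8a_fixed)$loglik)
})

test_that("branch-site alternative nests its null and finds planted signal", {
  bp <- bs_power_fit()
  expect_gte(bp$fits$alt$loglik, bp$fits$null$loglik - 1e-6)
  expect_gt(bp$fits$alt$params$omega2, 1.5)
  # constrained alternative (omega2 = 1) reproduces the null lnL
  constr <- chlorosel:::.fit_codon_model(
    bp$aln, bp$tree, "BS_alt", foreground = bp$foreground, starts = 1,
    control = chlorosel:::.fit_control(light_ctl),
    fixed = list(omega2 = 1))
  expect_equal(constr$loglik, bp$fits$null$loglik, tolerance = 0.02)
  expect_error(fit_branch_site(bp$aln, bp$tree, character(0)), "non-empty")
})

test_that("multi-start fitting is deterministic and picks the best start", {
  aln <- sim_codon(tree4(), 100, seed = 61)
  f1 <- fit_m0(aln, tree4(), starts = c(0.5, 2), control = light_ctl)
  f2 <- fit_m0(aln, tree4(), starts = c(0.5, 2), control = light_ctl)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$params, f2$params)
  expect_equal(f1$starts_used, c(0.5, 2))
})
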