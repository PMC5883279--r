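# Likelihood-ratio tests, FDR control and empirical-Bayes site
# identification for the positive-selection analyses.

#' Likelihood-ratio test between nested fits
#'
#' @param lnL_null,lnL_alt maximized log-likelihoods (pass negated values if
#'   stored as -lnL).
#' @param df degrees of freedom of the chi-square null distribution.
#' @return list with `stat` (2 delta lnL, clamped to 0 within tolerance) and
#'   `p_value` (upper chi-square tail).
#' @export
lrt <- function(lnL_null, lnL_alt, df = 1L) {
  if (df < 1) stop("argument error: df must be >= 1")
  stat <- 2 * (lnL_alt - lnL_null)
  if (stat < -1e-6) {
    stop("nesting-violation error: alternative log-likelihood below null (2dlnL = ",
         format(stat), ")")
  }
  stat <- max(stat, 0)
  list(stat = stat, p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, order-preserving against the input.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return vector of q-values in input order.
#' @export
fdr_bh <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("argument error: p-values must lie in [0, 1]")
  }
  m <- length(p_values)
  ord <- order(p_values, decreasing = TRUE)
  q <- pmin(1, cummin(p_values[ord] * m / seq(m, 1)))
  q[order(ord)]
}

#' Build an LRT record table with FDR correction
#'
#' One family of tests (e.g. all genes for one comparison type and
#' foreground lineage): computes 2 delta lnL, chi-square p-values, BH
#' q-values and the significance flag.
#'
#' @param fits named list of `list(null = fit, alt = fit)` pairs.
#' @param comparison label for the comparison family.
#' @param df chi-square degrees of freedom (1 for all three comparisons:
#'   branch, M8 vs M8a, branch-site).
#' @param alpha FDR level.
#' @return data frame, one row per dataset: lnL pair, stat, p, q,
#'   significant.
#' @export
lrt_table <- function(fits, comparison = "test", df = 1L, alpha = 0.05) {
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    r <- lrt(f$null$loglik, f$alt$loglik, df)
    data.frame(dataset = nm, comparison = comparison,
               lnL_null = f$null$loglik, lnL_alt = f$alt$loglik,
               stat = r$stat, df = df, p_value = r$p_value)
  })
  tb <- do.call(rbind, rows)
  tb$q_value <- fdr_bh(tb$p_value)
  tb$significant <- tb$q_value < alpha
  tb
}

# Per-site per-class log-likelihoods of the branch-site model at given
# (kappa, omega0, omega2) with everything else from the fit.
.bs_class_site_loglik <- function(fit, aln, tree, foreground, omega2) {
  states <- .states_of(aln)
  ti <- .tree_index(fit$tree, rownames(states))
  pk <- .pack_states(states[ti$tree$tip.label, , drop = FALSE])
  fg <- .foreground_edges(ti, foreground)
  w0 <- fit$params$omega0
  mix <- site_class_mixture(fit$params$kappa, fit$freqs, rep(0.25, 4),
                            omega_bg = c(w0, 1, w0, 1),
                            omega_fg = c(w0, 1, omega2, omega2))
  ev <- .mixture_eval(ti, pk, mix, fit$branch_lengths, fg)
  ev$cls_loglik[pk$map, , drop = FALSE]
}

#' Bayes empirical Bayes positively selected sites
#'
#' Posterior probability per site of the foreground positive-selection
#' classes (2a + 2b) of branch-site Model A, averaging the class posteriors
#' over a parameter grid with uniform priors: 10 x 10 points for the
#' proportion pair (p0, p1) through the uniform-triangle map and 10 values
#' of omega2 on (1, `omega2_max`]; kappa, omega0 and branch lengths stay at
#' their MLEs.
#'
#' @param bs_alt the branch-site alternative `fit_result`.
#' @param aln the cleaned `codon_alignment` the model was fitted to.
#' @param tree ape `phylo` (topology; fitted branch lengths are used).
#' @param foreground the foreground branch used in the fit.
#' @param pp_threshold flagging threshold on the posterior probability.
#' @param omega2_max upper end of the omega2 grid.
#' @param n_grid grid resolution per axis.
#' @return data frame, one row per site: `site` (1-based), `pp_positive`,
#'   `flagged`, `map_residue` (residue of the first foreground taxon).
#' @export
beb_sites <- function(bs_alt, aln, tree, foreground, pp_threshold = 0.95,
                      omega2_max = 11, n_grid = 10L) {
  if (!identical(bs_alt$model_id, "BS_alt")) {
    stop("argument error: beb_sites needs a branch-site alternative fit")
  }
  mid <- (seq_len(n_grid) - 0.5) / n_grid
  # uniform-triangle map for (p0, p1): p0 = 1 - sqrt(u), p1 = v * sqrt(u)
  grid_props <- expand.grid(u = mid, v = mid)
  p0 <- 1 - sqrt(grid_props$u)
  p1 <- grid_props$v * sqrt(grid_props$u)
  w2_grid <- 1 + mid * (omega2_max - 1)
  # class site log-likelihoods: classes 0 and 1 are omega2-free; 2a/2b vary
  cls_by_w2 <- lapply(w2_grid, function(w2)
    .bs_class_site_loglik(bs_alt, aln, tree, foreground, w2))
  n_sites <- nrow(cls_by_w2[[1]])
  log_post_num <- rep(-Inf, n_sites) # accumulating log sum over grid
  log_marg <- -Inf                   # log of total grid mass
  log_site_acc <- NULL
  acc_pp <- matrix(0, n_sites, 0)
  log_grid_lik <- numeric(0)
  pp_list <- list()
  for (j in seq_along(w2_grid)) {
    cls <- cls_by_w2[[j]]
    for (g in seq_len(nrow(grid_props))) {
      pr <- c(p0[g], p1[g],
              (1 - p0[g] - p1[g]) * p0[g] / max(p0[g] + p1[g], 1e-12),
              (1 - p0[g] - p1[g]) * p1[g] / max(p0[g] + p1[g], 1e-12))
      lw <- sweep(cls, 2L, log(pmax(pr, 1e-300)), "+")
      mx <- as.vector(do.call(pmax, asplit(lw, 2L)))
      site_log <- mx + log(rowSums(exp(lw - mx)))
      pp_site <- rowSums(exp(lw[, 3:4, drop = FALSE] - site_log))
      log_grid_lik <- c(log_grid_lik, sum(site_log))
      pp_list[[length(pp_list) + 1L]] <- pp_site
    }
  }
  wts <- exp(log_grid_lik - max(log_grid_lik))
  wts <- wts / sum(wts)
  pp <- as.vector(do.call(cbind, pp_list) %*% wts)
  fg_taxon <- if (is.character(foreground)) foreground[1] else aln$taxa[1]
  res_idx <- codon_to_aa_index(aln$codons[fg_taxon, ])
  data.frame(site = seq_len(n_sites), pp_positive = pp,
             flagged = pp >= pp_threshold,
             map_residue = AA_LETTERS[res_idx])
}

#' Naive empirical Bayes site posteriors
#'
#' Class posteriors evaluated at the MLEs only (no grid averaging); the
#' cross-check estimator for the BEB calls.
#'
#' @param fit an M8 or branch-site `fit_result`.
#' @param aln,tree alignment and tree (used only if the fit does not carry
#'   its per-class site likelihoods).
#' @return matrix sites x classes of posterior probabilities (rows sum to 1),
#'   with attribute `positive_class` marking classes with foreground
#'   omega > 1.
#' @export
naive_eb_sites <- function(fit, aln = NULL, tree = NULL) {
  if (!fit$model_id %in% c("M8", "M8a", "BS_alt", "BS_null", "M0", "branch")) {
    stop("argument error: unsupported fit for empirical-Bayes posteriors")
  }
  cls <- fit$class_site_loglik
  if (is.null(cls)) stop("fit carries no per-class site likelihoods")
  lw <- sweep(cls, 2L, log(pmax(fit$mixture$classes$prop, 1e-300)), "+")
  mx <- as.vector(do.call(pmax, asplit(lw, 2L)))
  post <- exp(lw - (mx + log(rowSums(exp(lw - mx)))))
  attr(post, "positive_class") <- fit$mixture$classes$omega_fg > 1
  post
}
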