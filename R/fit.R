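# Maximum-likelihood fitting of the codon model families.
#
# Each fit alternates bounded quasi-Newton steps on the substitution/mixture
# parameters (nlminb, numerical gradients) with exact coordinate updates of
# individual branch lengths (Brent on eigen-decomposed edge messages), from
# several starting omega values; the best start wins, ties broken by the
# lowest starting omega.

.fit_control <- function(...) {
  ctl <- list(rel_tol = 1e-8, cycle_tol = 1e-6, max_cycles = 10L,
              sweeps_per_cycle = 2L, eval_max = 500L, iter_max = 200L,
              t_min = 1e-6, t_max = 50, t_init = 0.1,
              optimize_branch_lengths = TRUE)
  user <- list(...)
  if (length(user) == 1L && is.list(user[[1]]) && is.null(names(user))) user <- user[[1]]
  ctl[names(user)] <- user
  ctl
}

# Model descriptors: parameter vector layout, bounds, and the map from the
# parameter vector to site classes. kappa is always par[1]. Branch-site
# proportions use the (x, y) square parameterization p0 = x y, p1 = x (1 - y),
# p2a = (1 - x) y, p2b = (1 - x) (1 - y).
.model_descriptor <- function(model_id, K_beta = 10L) {
  eps <- 1e-6
  beta_cats <- function(p0, p, q) {
    w <- stats::qbeta((seq_len(K_beta) - 0.5) / K_beta, p, q)
    list(prop = rep(p0 / K_beta, K_beta), omega = w)
  }
  switch(model_id,
    M0 = list(
      par_names = c("kappa", "omega"),
      lower = c(0.02, 1e-6), upper = c(99, 999),
      init = function(w0) c(2, w0),
      classes = function(par) data.frame(prop = 1, omega_bg = par[2],
                                         omega_fg = par[2])),
    branch = list(
      par_names = c("kappa", "omega_bg", "omega_fg"),
      lower = c(0.02, 1e-6, 1e-6), upper = c(99, 999, 999),
      init = function(w0) c(2, w0, w0),
      classes = function(par) data.frame(prop = 1, omega_bg = par[2],
                                         omega_fg = par[3])),
    M8 = list(
      par_names = c("kappa", "p0", "p", "q", "omega_s"),
      lower = c(0.02, eps, 0.005, 0.005, 1), upper = c(99, 1 - eps, 99, 99, 999),
      init = function(w0) c(2, 0.9, 0.5, 1.5, max(w0, 1.05)),
      classes = function(par) {
        bc <- beta_cats(par[2], par[3], par[4])
        data.frame(prop = c(bc$prop, 1 - par[2]),
                   omega_bg = c(bc$omega, par[5]),
                   omega_fg = c(bc$omega, par[5]))
      }),
    M8a = list(
      par_names = c("kappa", "p0", "p", "q"),
      lower = c(0.02, eps, 0.005, 0.005), upper = c(99, 1 - eps, 99, 99),
      init = function(w0) c(2, 0.9, 0.5, 1.5),
      classes = function(par) {
        bc <- beta_cats(par[2], par[3], par[4])
        data.frame(prop = c(bc$prop, 1 - par[2]),
                   omega_bg = c(bc$omega, 1), omega_fg = c(bc$omega, 1))
      }),
    BS_alt = list(
      par_names = c("kappa", "x", "y", "omega0", "omega2"),
      lower = c(0.02, eps, eps, 1e-6, 1), upper = c(99, 1 - eps, 1 - eps, 1, 999),
      init = function(w0) c(2, 0.85, 0.9, 0.1, max(w0, 1.02)),
      classes = function(par) {
        x <- par[2]; y <- par[3]
        data.frame(prop = c(x * y, x * (1 - y), (1 - x) * y, (1 - x) * (1 - y)),
                   omega_bg = c(par[4], 1, par[4], 1),
                   omega_fg = c(par[4], 1, par[5], par[5]))
      }),
    BS_null = list(
      par_names = c("kappa", "x", "y", "omega0"),
      lower = c(0.02, eps, eps, 1e-6), upper = c(99, 1 - eps, 1 - eps, 1),
      init = function(w0) c(2, 0.85, 0.9, 0.1),
      classes = function(par) {
        x <- par[2]; y <- par[3]
        data.frame(prop = c(x * y, x * (1 - y), (1 - x) * y, (1 - x) * (1 - y)),
                   omega_bg = c(par[4], 1, par[4], 1),
                   omega_fg = c(par[4], 1, 1, 1))
      }),
    stop("unknown model id: ", model_id))
}

.mix_from_par <- function(desc, par, freqs) {
  cl <- desc$classes(par)
  site_class_mixture(par[1], freqs, cl$prop, cl$omega_bg, cl$omega_fg)
}

# One sweep of exact sequential coordinate ascent over branch lengths.
# cls: per-class list(bg, fg) eigensystems; props: class proportions.
# Classes with identical (bg, fg) signatures are merged, and edge transition
# matrices are shared between classes that use the same eigensystem.
.branch_sweep <- function(ti, pk, cls, props, tvec, fg_edges, ctl) {
  sig <- vapply(cls, function(cl) paste(cl$bg$id, cl$fg$id), character(1))
  keep_idx <- !duplicated(sig)
  merged_props <- as.vector(tapply(props, factor(sig, levels = sig[keep_idx]), sum))
  cls <- cls[keep_idx]
  props <- merged_props
  K <- length(cls)
  npat <- ncol(pk$states)
  for (k in seq_len(K)) {
    if (is.null(cls[[k]]$r_bg)) cls[[k]]$r_bg <- 1
    if (is.null(cls[[k]]$r_fg)) cls[[k]]$r_fg <- 1
  }
  edge_eig <- function(k, e) if (e %in% fg_edges) cls[[k]]$fg else cls[[k]]$bg
  edge_rate <- function(k, e) if (e %in% fg_edges) cls[[k]]$r_fg else cls[[k]]$r_bg
  Pcache <- new.env(parent = emptyenv())
  getP <- function(eig, r, e) {
    keyp <- paste0(eig$id, "|", e)
    if (is.null(Pcache[[keyp]])) Pcache[[keyp]] <- .P_from_eigen(eig, r * tvec[e])
    Pcache[[keyp]]
  }
  dropP <- function(e) {
    rm(list = grep(paste0("\\|", e, "$"), ls(Pcache), value = TRUE),
       envir = Pcache)
  }
  Pl <- lapply(seq_len(K), function(k)
    lapply(seq_len(ti$n_edge), function(e) getP(edge_eig(k, e), edge_rate(k, e), e)))
  downs <- lapply(seq_len(K), function(k)
    .down_pass(ti, pk$states, Pl[[k]], cls[[k]]$bg$pi))
  A <- lapply(seq_len(K), function(k) {
    a <- vector("list", ti$ntip + ti$nnode)
    a[[ti$root]] <- matrix(cls[[k]]$bg$pi, length(cls[[k]]$bg$pi), npat)
    a
  })
  slogA <- lapply(seq_len(K), function(k) {
    s <- vector("list", ti$ntip + ti$nnode)
    s[[ti$root]] <- rep(0, npat)
    s
  })
  lp <- log(props)
  tVs <- lapply(cls, function(cl) list(bg = t(cl$bg$V), fg = t(cl$fg$V)))
  for (nd in rev(ti$parents_order)) {
    ces <- ti$children_edges[[nd]]
    for (e in ces) {
      ch <- ti$edge[e, 2]
      G <- vector("list", K); sc <- vector("list", K)
      B <- vector("list", K); slB <- vector("list", K)
      for (k in seq_len(K)) {
        prod <- A[[k]][[nd]]; sl <- slogA[[k]][[nd]]
        for (e2 in setdiff(ces, e)) {
          prod <- prod * downs[[k]]$M[[e2]]
          ch2 <- ti$edge[e2, 2]
          if (ch2 > ti$ntip) sl <- sl + downs[[k]]$slog[[ch2]]
        }
        B[[k]] <- prod; slB[[k]] <- sl
        eig <- edge_eig(k, e)
        tV <- if (e %in% fg_edges) tVs[[k]]$fg else tVs[[k]]$bg
        TBU <- crossprod(prod, eig$U)
        if (ch <= ti$ntip) {
          tVD <- tV[pk$states[ch, ], , drop = FALSE]
          sch <- 0
        } else {
          tVD <- crossprod(downs[[k]]$partial[[ch]], tV)
          sch <- downs[[k]]$slog[[ch]]
        }
        G[[k]] <- TBU * tVD
        sc[[k]] <- sl + sch + lp[k]
      }
      lam <- lapply(seq_len(K), function(k)
        edge_eig(k, e)$lambda * edge_rate(k, e))
      negll <- function(t) {
        cl <- vapply(seq_len(K), function(k) {
          v <- as.vector(G[[k]] %*% exp(lam[[k]] * t))
          v[v <= 0] <- 1e-300
          log(v) + sc[[k]]
        }, numeric(npat))
        if (npat == 1L) cl <- matrix(cl, 1L)
        mx <- as.vector(do.call(pmax, asplit(cl, 2L)))
        -sum(pk$weights * (mx + log(rowSums(exp(cl - mx)))))
      }
      opt <- stats::optimize(negll, c(ctl$t_min, ctl$t_max), tol = 1e-7)
      if (opt$objective < negll(tvec[e])) tvec[e] <- opt$minimum
      dropP(e)
      for (k in seq_len(K)) {
        Pk <- getP(edge_eig(k, e), edge_rate(k, e), e)
        Pl[[k]][[e]] <- Pk
        downs[[k]]$M[[e]] <- if (ch <= ti$ntip) {
          Pk[, pk$states[ch, ], drop = FALSE]
        } else Pk %*% downs[[k]]$partial[[ch]]
        if (ch > ti$ntip) {
          Av <- crossprod(Pk, B[[k]])
          mx <- .colscale(Av)
          A[[k]][[ch]] <- Av / rep(mx, each = nrow(Av))
          slogA[[k]][[ch]] <- slB[[k]] + log(mx)
        }
      }
    }
  }
  tvec
}

# Core fitting loop for codon models.
.fit_codon_model <- function(aln, tree, model_id, foreground = NULL,
                             starts = c(0.5, 1, 2), control = .fit_control(),
                             freqs = NULL, fixed = NULL, init_override = NULL) {
  desc <- .model_descriptor(model_id)
  states <- .states_of(aln)
  ti <- .tree_index(tree, rownames(states))
  pk <- .pack_states(states[ti$tree$tip.label, , drop = FALSE])
  fg <- .foreground_edges(ti, foreground)
  if (is.null(freqs)) freqs <- f3x4_frequencies(aln)
  t0 <- if (!is.null(ti$tree$edge.length)) pmax(ti$tree$edge.length, control$t_min)
        else rep(control$t_init, ti$n_edge)
  n_eval <- 0L
  run_start <- function(w0) {
    par <- stats::setNames(desc$init(w0), desc$par_names)
    if (!is.null(init_override)) {
      ov <- init_override[names(init_override) %in% desc$par_names]
      idx <- match(names(ov), desc$par_names)
      par[idx] <- pmin(pmax(unlist(ov), desc$lower[idx]), desc$upper[idx])
    }
    if (!is.null(fixed)) par[names(fixed)] <- unlist(fixed)
    free <- if (is.null(fixed)) rep(TRUE, length(par)) else
      !(desc$par_names %in% names(fixed))
    tvec <- t0
    # Gauge choice for the optimization: single-class models use the
    # mixture (own-normalization) gauge, which decouples omega from the
    # total tree length; multi-class models use the neutral gauge, whose
    # per-class likelihood columns are independent of the class
    # proportions and can be cached while branch lengths are fixed.
    # Branch lengths are converted to the mixture scale at the end.
    K_classes <- nrow(desc$classes(stats::setNames(desc$init(1), desc$par_names)))
    gauge_int <- if (!control$optimize_branch_lengths || K_classes == 1L)
      "mixture" else "neutral"
    cache <- if (control$optimize_branch_lengths)
      new.env(parent = emptyenv()) else NULL
    obj <- function(p_free) {
      par2 <- par; par2[free] <- p_free
      mix <- .mix_from_par(desc, par2, freqs)
      n_eval <<- n_eval + 1L
      -.mixture_eval(ti, pk, mix, tvec, fg, cache = cache,
                     gauge = gauge_int)$loglik
    }
    ll <- -obj(par[free])
    ok <- TRUE
    for (cycle in seq_len(control$max_cycles)) {
      op <- tryCatch(
        stats::nlminb(par[free], obj, lower = desc$lower[free],
                      upper = desc$upper[free],
                      control = list(rel.tol = control$rel_tol,
                                     eval.max = control$eval_max,
                                     iter.max = control$iter_max)),
        error = function(e) NULL)
      if (is.null(op)) { ok <- FALSE; break }
      par[free] <- op$par
      ll_new <- -op$objective
      if (control$optimize_branch_lengths) {
        mix <- .mix_from_par(desc, par, freqs)
        ev <- .mixture_eval(ti, pk, mix, tvec, fg, keep = TRUE,
                            gauge = gauge_int)
        for (s in seq_len(control$sweeps_per_cycle)) {
          tvec <- .branch_sweep(ti, pk, ev$class_eig, mix$classes$prop,
                                tvec, fg, control)
        }
        ll_new <- .mixture_eval(ti, pk, mix, tvec, fg, gauge = gauge_int)$loglik
        # class-likelihood cache is only valid for fixed branch lengths
        rm(list = grep("^col\\|", ls(cache), value = TRUE), envir = cache)
      }
      improved <- ll_new - ll
      ll <- ll_new
      if (is.finite(improved) && improved < control$cycle_tol) break
    }
    list(par = par, tvec = tvec, loglik = ll, ok = ok, start = w0)
  }
  runs <- lapply(sort(starts), run_start)
  lls <- vapply(runs, function(r) r$loglik, numeric(1))
  best <- runs[[which(lls > max(lls) - 1e-6)[1]]]
  mix <- .mix_from_par(desc, best$par, freqs)
  K_classes <- nrow(mix$classes)
  gauge_int <- if (!control$optimize_branch_lengths || K_classes == 1L)
    "mixture" else "neutral"
  ev_gauge <- .mixture_eval(ti, pk, mix, best$tvec, fg, gauge = gauge_int)
  t_report <- best$tvec * ev_gauge$mix_rate
  ev <- .mixture_eval(ti, pk, mix, t_report, fg)
  best$tvec <- t_report
  fitted_tree <- ti$tree
  fitted_tree$edge.length <- best$tvec
  params <- as.list(stats::setNames(best$par, desc$par_names))
  if (model_id %in% c("BS_alt", "BS_null")) {
    x <- params$x; y <- params$y
    params$p0 <- x * y; params$p1 <- x * (1 - y)
    params$p2a <- (1 - x) * y; params$p2b <- (1 - x) * (1 - y)
  }
  at_bound <- abs(best$par - desc$upper) < 1e-8 |
    abs(best$par - desc$lower) < 1e-8
  res <- structure(list(
    model_id = model_id, dataset_id = aln$gene_name,
    loglik = ev$loglik, params = params,
    tree = fitted_tree, branch_lengths = best$tvec,
    foreground = foreground, freqs = freqs, mixture = mix,
    site_loglik = ev$site_log[pk$map],
    class_site_loglik = ev$cls_loglik[pk$map, , drop = FALSE],
    starts_used = sort(starts), n_eval = n_eval,
    converged = all(vapply(runs, function(r) r$ok, logical(1))),
    boundary = stats::setNames(at_bound, desc$par_names)),
    class = "fit_result")
  res
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result [", x$model_id, "] on '", x$dataset_id, "': lnL = ",
      format(x$loglik, digits = 10), "\n  params: ",
      paste(names(x$params), format(unlist(x$params), digits = 4),
            sep = "=", collapse = ", "), "\n", sep = "")
  if (any(x$boundary)) {
    cat("  at bound:", paste(names(x$boundary)[x$boundary], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Fit the one-ratio (M0) codon model
#'
#' Jointly estimates kappa, a single omega shared by all sites and branches,
#' and all branch lengths; per-branch dN and dS are decomposed from the
#' fitted rates.
#'
#' @param aln cleaned `codon_alignment`.
#' @param tree ape `phylo`; branch lengths, if present, are used as starting
#'   values and re-optimized.
#' @param starts starting omega values.
#' @param control optimizer settings from `.fit_control()` entries, e.g.
#'   `list(max_cycles = 4)`.
#' @return a `fit_result` with `per_branch_dNdS` populated; when the
#'   alignment carries no substitutions omega is flagged non-identifiable in
#'   `$identifiable`.
#' @export
fit_m0 <- function(aln, tree, starts = c(0.5, 1, 2), control = list()) {
  ctl <- .fit_control(control)
  fit <- .fit_codon_model(aln, tree, "M0", starts = starts, control = ctl)
  fit$identifiable <- sum(fit$branch_lengths) > length(fit$branch_lengths) * 2 * ctl$t_min
  fit$per_branch_dNdS <- decompose_dnds(fit)
  fit
}

#' Per-branch dN and dS decomposition
#'
#' Splits each branch length into synonymous and nonsynonymous distances
#' using the flow through the normalized rate matrix: with rho_N the
#' nonsynonymous share of the total substitution rate and f_N, f_S the
#' per-codon nonsynonymous/synonymous site fractions of the neutral
#' (omega = 1) matrix, `dN = t rho_N / (3 f_N)` and `dS = t rho_S / (3 f_S)`.
#'
#' @param fit an M0-style `fit_result` (single omega).
#' @return data frame with one row per branch: `parent`, `child`, `t`, `dN`,
#'   `dS`, `omega`.
#' @export
decompose_dnds <- function(fit) {
  kappa <- fit$params$kappa
  omega <- fit$params$omega
  if (is.null(omega)) stop("argument error: decompose_dnds needs a single-omega fit")
  m <- codon_rate_matrix(kappa, omega, fit$freqs)
  m1 <- codon_rate_matrix(kappa, 1, fit$freqs)
  rho_n <- m$rho_n
  f_n <- m1$rho_n # nonsynonymous site fraction, codeml convention
  f_s <- 1 - f_n
  t <- fit$branch_lengths
  dN <- t * rho_n / (3 * f_n)
  dS <- if (rho_n >= 1) rep(NA_real_, length(t)) else t * (1 - rho_n) / (3 * f_s)
  data.frame(parent = fit$tree$edge[, 1], child = fit$tree$edge[, 2],
             label = ifelse(fit$tree$edge[, 2] <= length(fit$tree$tip.label),
                            fit$tree$tip.label[fit$tree$edge[, 2]], ""),
             t = t, dN = dN, dS = dS,
             omega = ifelse(is.na(dS) | dS == 0, NA_real_, dN / dS))
}

#' Filter genes by their maximum branch dS
#'
#' Genes whose largest per-branch synonymous distance reaches the threshold
#' are discarded to avoid dN/dS misestimation from saturated synonymous
#' sites.
#'
#' @param fits named list of per-gene M0 `fit_result`s (with
#'   `per_branch_dNdS`).
#' @param threshold maximum tolerated branch dS (default 1).
#' @return list with `retained` (gene names), `discarded` (data frame: gene,
#'   max_ds, branch label of the offending branch).
#' @export
filter_genes_by_ds <- function(fits, threshold = 1.0) {
  retained <- character(0)
  disc <- data.frame(gene = character(0), max_ds = numeric(0),
                     branch = character(0))
  for (fit in fits) {
    tb <- fit$per_branch_dNdS
    if (is.null(tb)) tb <- decompose_dnds(fit)
    mx <- suppressWarnings(max(tb$dS, na.rm = TRUE))
    if (is.finite(mx) && mx < threshold) {
      retained <- c(retained, fit$dataset_id)
    } else {
      i <- which.max(tb$dS)
      lab <- if (tb$label[i] != "") tb$label[i] else
        paste0(tb$parent[i], "->", tb$child[i])
      disc <- rbind(disc, data.frame(gene = fit$dataset_id, max_ds = mx,
                                     branch = lab))
    }
  }
  list(retained = retained, discarded = disc)
}

#' Fit the two-ratio branch model against the one-ratio null
#'
#' The null is M0 (one omega for the whole tree); the alternative gives the
#' foreground branches their own omega.
#'
#' @param aln cleaned `codon_alignment`.
#' @param tree ape `phylo`.
#' @param foreground foreground tip labels (or edge indices); must be a
#'   non-empty proper subset of branches.
#' @param starts starting omega values.
#' @param control optimizer settings.
#' @return list with `null` and `alt` `fit_result`s.
#' @export
fit_branch_model <- function(aln, tree, foreground, starts = c(0.5, 1, 2),
                             control = list()) {
  ctl <- .fit_control(control)
  states <- .states_of(aln)
  ti <- .tree_index(tree, rownames(states))
  fg <- .foreground_edges(ti, foreground)
  if (length(fg) == 0L) stop("argument error: foreground must be non-empty")
  if (length(fg) >= ti$n_edge) {
    stop("argument error: foreground covers all branches; model collapses to the null")
  }
  null_fit <- .fit_codon_model(aln, tree, "M0", starts = starts, control = ctl)
  alt_fit <- .fit_codon_model(aln, tree, "branch", foreground = foreground,
                              starts = starts, control = ctl,
                              init_override = c(kappa = null_fit$params$kappa,
                                                omega_bg = null_fit$params$omega,
                                                omega_fg = null_fit$params$omega))
  alt_fit <- .ensure_nested(null_fit, alt_fit, "branch", function(p) {
    list(kappa = p$kappa, omega_bg = p$omega, omega_fg = p$omega)
  })
  list(null = null_fit, alt = alt_fit)
}

# The null is nested in the alternative: if the alternative search ends below
# the null optimum (within optimizer noise), the null solution -- a valid
# point of the alternative space -- is adopted as the alternative MLE.
.ensure_nested <- function(null_fit, alt_fit, alt_id, promote) {
  if (alt_fit$loglik >= null_fit$loglik) return(alt_fit)
  adopted <- null_fit
  adopted$model_id <- alt_id
  adopted$params <- promote(null_fit$params)
  adopted$starts_used <- alt_fit$starts_used
  adopted$foreground <- alt_fit$foreground
  adopted$boundary <- alt_fit$boundary & FALSE
  adopted$adopted_null <- TRUE
  adopted
}

#' Fit the M8a/M8 site-model pair
#'
#' M8: a proportion p0 of sites with omega from a discretized Beta(p, q)
#' (equal-probability categories at their medians) plus a class at
#' omega_s >= 1. M8a fixes omega_s = 1. The M8 fit is warm-started from the
#' M8a optimum over the configured omega_s starts.
#'
#' @param aln cleaned `codon_alignment`.
#' @param tree ape `phylo`.
#' @param starts starting values for omega_s (values below 1 are lifted
#'   just above the boundary).
#' @param control optimizer settings.
#' @return list with `null` (M8a) and `alt` (M8) `fit_result`s.
#' @export
fit_site_models <- function(aln, tree, starts = c(0.5, 1, 2), control = list()) {
  ctl <- .fit_control(control)
  null_fit <- .fit_codon_model(aln, tree, "M8a", starts = 1, control = ctl)
  ws_starts <- unique(pmax(starts, 1.05))
  warm <- unlist(null_fit$params[c("kappa", "p0", "p", "q")])
  alt_runs <- lapply(ws_starts, function(ws) {
    .fit_codon_model(aln, null_fit$tree, "M8",
                     starts = ws, control = ctl,
                     freqs = null_fit$freqs, init_override = warm)
  })
  lls <- vapply(alt_runs, function(f) f$loglik, numeric(1))
  alt_fit <- alt_runs[[which(lls > max(lls) - 1e-6)[1]]]
  alt_fit <- .ensure_nested(null_fit, alt_fit, "M8", function(p) {
    c(p[c("kappa", "p0", "p", "q")], list(omega_s = 1))
  })
  list(null = null_fit, alt = alt_fit)
}

#' Fit the branch-site Model A pair
#'
#' Four site classes: purifying (0 <= omega0 <= 1) and neutral (omega1 = 1)
#' everywhere, plus two classes that switch to omega2 >= 1 on the foreground
#' branches. The null fixes omega2 = 1; the alternative bounds omega2 at 999
#' and flags boundary hits.
#'
#' @param aln cleaned `codon_alignment`.
#' @param tree ape `phylo`.
#' @param foreground foreground branch (tip label), typically one terminal
#'   branch per run.
#' @param starts starting omega2 values for the alternative (lifted above 1).
#' @param control optimizer settings.
#' @return list with `null` and `alt` `fit_result`s.
#' @export
fit_branch_site <- function(aln, tree, foreground, starts = c(0.5, 1, 2),
                            control = list()) {
  ctl <- .fit_control(control)
  states <- .states_of(aln)
  ti <- .tree_index(tree, rownames(states))
  fg <- .foreground_edges(ti, foreground)
  if (length(fg) == 0L) stop("argument error: foreground must be non-empty")
  if (length(fg) >= ti$n_edge) stop("argument error: foreground covers all branches")
  null_fit <- .fit_codon_model(aln, tree, "BS_null", foreground = foreground,
                               starts = 1, control = ctl)
  w2_starts <- unique(pmax(starts, 1.02))
  warm <- unlist(null_fit$params[c("kappa", "x", "y", "omega0")])
  alt_runs <- lapply(w2_starts, function(w2) {
    .fit_codon_model(aln, null_fit$tree, "BS_alt",
                     foreground = foreground, starts = w2, control = ctl,
                     freqs = null_fit$freqs, init_override = warm)
  })
  lls <- vapply(alt_runs, function(f) f$loglik, numeric(1))
  alt_fit <- alt_runs[[which(lls > max(lls) - 1e-6)[1]]]
  # guard against an under-converged null inflating the statistic: when the
  # LRT would be non-trivial, polish the null from the alternative's optimum
  # (omega2 collapsed to 1), which is a valid null starting point
  if (2 * (alt_fit$loglik - null_fit$loglik) > 1.0) {
    warm2 <- unlist(alt_fit$params[c("kappa", "x", "y", "omega0")])
    ctl_polish <- ctl
    ctl_polish$max_cycles <- 1L
    null2 <- .fit_codon_model(aln, alt_fit$tree, "BS_null",
                              foreground = foreground, starts = 1,
                              control = ctl_polish, freqs = null_fit$freqs,
                              init_override = warm2)
    if (null2$loglik > null_fit$loglik) null_fit <- null2
  }
  alt_fit <- .ensure_nested(null_fit, alt_fit, "BS_alt", function(p) {
    c(p[c("kappa", "x", "y", "omega0")], list(omega2 = 1),
      p[c("p0", "p1", "p2a", "p2b")])
  })
  list(null = null_fit, alt = alt_fit)
}
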