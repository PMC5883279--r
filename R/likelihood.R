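# Phylogenetic likelihood engine.
#
# Felsenstein pruning over site patterns with per-node log-scaling, shared by
# the 61-state codon models and the 20-state amino-acid models. Reversibility
# is exploited throughout: transition matrices come from one symmetric
# eigendecomposition per omega class, and "up" messages make per-branch
# likelihood curves one matrix-vector product per evaluation.

.colmax <- function(m) {
  m[cbind(max.col(t(m), ties.method = "first"), seq_len(ncol(m)))]
}

# Positive per-column scaling factors (any positive factor keeps the scaled
# pruning exact; column sums avoid the transpose a per-column max would need).
.colscale <- function(m) {
  cs <- colSums(m)
  cs[!is.finite(cs)] <- 1
  cs
}

# Index an ape tree against an ordered taxon set.
.tree_index <- function(tree, taxa) {
  if (!inherits(tree, "phylo")) stop("argument error: tree must be an ape 'phylo'")
  miss <- setdiff(taxa, tree$tip.label)
  if (length(miss)) {
    stop("data error: taxa missing from tree: ", paste(miss, collapse = ", "))
  }
  extra <- setdiff(tree$tip.label, taxa)
  if (length(extra)) tree <- ape::keep.tip(tree, taxa)
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  nn <- ntip + tree$Nnode
  children_edges <- vector("list", nn)
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]
    children_edges[[p]] <- c(children_edges[[p]], e)
  }
  parents_order <- unique(edge[, 1])
  parent_edge <- integer(nn)
  parent_edge[edge[, 2]] <- seq_len(nrow(edge))
  list(tree = tree, edge = edge, ntip = ntip, nnode = tree$Nnode,
       root = ntip + 1L, n_edge = nrow(edge),
       children_edges = children_edges, parents_order = parents_order,
       parent_edge = parent_edge,
       tip_order = match(taxa, tree$tip.label))
}

# Collapse an integer state matrix (taxa x sites) to unique site patterns.
.pack_states <- function(state_mat) {
  key <- apply(state_mat, 2L, paste, collapse = ".")
  first <- !duplicated(key)
  map <- match(key, key[first])
  list(states = state_mat[, first, drop = FALSE],
       weights = as.numeric(tabulate(map, nbins = sum(first))),
       map = map, n_sites = ncol(state_mat))
}

# Terminal edges for a set of foreground tip labels (or edge indices).
.foreground_edges <- function(ti, foreground) {
  if (is.null(foreground) || length(foreground) == 0L) return(integer(0))
  if (is.numeric(foreground)) {
    fe <- as.integer(foreground)
    if (any(fe < 1L | fe > ti$n_edge)) stop("argument error: foreground edge index out of range")
    return(fe)
  }
  idx <- match(foreground, ti$tree$tip.label)
  if (anyNA(idx)) {
    stop("argument error: foreground taxa not in tree: ",
         paste(foreground[is.na(idx)], collapse = ", "))
  }
  ti$parent_edge[idx]
}

# Per-edge transition matrices for one site class: background eigensystem on
# all edges, foreground eigensystem on tagged edges.
.class_P <- function(eig_bg, eig_fg, tvec, fg_edges) {
  P <- vector("list", length(tvec))
  for (e in seq_along(tvec)) {
    eig <- if (e %in% fg_edges) eig_fg else eig_bg
    P[[e]] <- .P_from_eigen(eig, tvec[e])
  }
  P
}

# Pruning pass. tips: ntip x npat integer states in tree tip order.
# Returns per-node conditional likelihoods (internal nodes), the per-edge
# products M_e = P_e L_child, per-node cumulative log scaling factors and
# per-pattern log-likelihood given stationary frequencies pi.
#
# `reuse` (a previous pass over the same tree) together with `changed`
# (edge indices whose P differs) recomputes only the affected root path.
.down_pass <- function(ti, tips, Plist, pi, reuse = NULL, changed = NULL) {
  npat <- ncol(tips)
  nn <- ti$ntip + ti$nnode
  if (!is.null(reuse)) {
    dirty <- rep(FALSE, nn)
    for (e in changed) dirty[ti$edge[e, 1]] <- TRUE
    partial <- reuse$partial; M <- reuse$M; slog <- reuse$slog
  } else {
    dirty <- NULL
    partial <- vector("list", nn)
    M <- vector("list", ti$n_edge)
    slog <- vector("list", nn)
  }
  for (nd in ti$parents_order) {
    ces <- ti$children_edges[[nd]]
    if (!is.null(dirty)) {
      needs <- dirty[nd] || any(vapply(ti$edge[ces, 2], function(ch)
        ch > ti$ntip && isTRUE(dirty[ch]), logical(1)))
      if (!needs) next
      dirty[nd] <- TRUE
    }
    prod <- NULL
    sl <- 0
    for (e in ces) {
      ch <- ti$edge[e, 2]
      if (ch <= ti$ntip) {
        Me <- Plist[[e]][, tips[ch, ], drop = FALSE]
      } else {
        Me <- Plist[[e]] %*% partial[[ch]]
        sl <- sl + slog[[ch]]
      }
      M[[e]] <- Me
      prod <- if (is.null(prod)) Me else prod * Me
    }
    mx <- .colscale(prod)
    if (any(mx <= 0)) {
      stop("numerical error: zero partial likelihood at pattern ",
           which(mx <= 0)[1])
    }
    partial[[nd]] <- prod / rep(mx, each = nrow(prod))
    slog[[nd]] <- sl + log(mx)
  }
  lik <- as.vector(pi %*% partial[[ti$root]])
  list(partial = partial, M = M, slog = slog,
       loglik_pat = log(lik) + slog[[ti$root]])
}

# Outward messages. For edge e = (u, v), B_e(i) is the likelihood of all data
# outside the subtree below e conditional on state i at u, with the stationary
# frequencies folded in at the root; the per-pattern site likelihood is
# sum_i sum_j B_e(i) P_ij(t_e) L_v(j).
.up_messages <- function(ti, tips, Plist, down, pi) {
  npat <- length(down$loglik_pat)
  nn <- ti$ntip + ti$nnode
  A <- vector("list", nn); slogA <- vector("list", nn)
  B <- vector("list", ti$n_edge); slogB <- vector("list", ti$n_edge)
  A[[ti$root]] <- matrix(pi, length(pi), npat)
  slogA[[ti$root]] <- rep(0, npat)
  for (nd in rev(ti$parents_order)) {
    ces <- ti$children_edges[[nd]]
    for (e in ces) {
      prod <- A[[nd]]
      sl <- slogA[[nd]]
      for (e2 in setdiff(ces, e)) {
        prod <- prod * down$M[[e2]]
        ch2 <- ti$edge[e2, 2]
        if (ch2 > ti$ntip) sl <- sl + down$slog[[ch2]]
      }
      B[[e]] <- prod
      slogB[[e]] <- sl
      ch <- ti$edge[e, 2]
      if (ch > ti$ntip) {
        Av <- crossprod(Plist[[e]], prod)
        mx <- .colscale(Av)
        A[[ch]] <- Av / rep(mx, each = nrow(Av))
        slogA[[ch]] <- sl + log(mx)
      }
    }
  }
  list(A = A, slogA = slogA, B = B, slogB = slogB)
}

#' Site-class mixture over omega categories
#'
#' The omega-class structure shared by all model families: each class has a
#' proportion, a background omega and a foreground omega (equal unless a
#' branch or branch-site structure is requested).
#'
#' @param kappa transition/transversion rate ratio.
#' @param freqs a `codon_frequencies` object.
#' @param proportions class proportions (nonnegative, summing to 1).
#' @param omega_bg per-class omega on background branches.
#' @param omega_fg per-class omega on foreground branches (defaults to
#'   `omega_bg`).
#' @param label model family label.
#' @return object of class `site_class_mixture`.
#' @export
site_class_mixture <- function(kappa, freqs, proportions, omega_bg,
                               omega_fg = omega_bg, label = "custom") {
  if (any(proportions < -1e-12) || abs(sum(proportions) - 1) > 1e-8) {
    stop("argument error: class proportions must be nonnegative and sum to 1")
  }
  if (kappa <= 0) stop("argument error: kappa must be > 0")
  if (any(c(omega_bg, omega_fg) < 0)) stop("argument error: omega must be >= 0")
  structure(list(kappa = kappa, freqs = freqs,
                 classes = data.frame(prop = pmax(proportions, 0),
                                      omega_bg = omega_bg,
                                      omega_fg = omega_fg),
                 label = label),
            class = "site_class_mixture")
}

# Raw synonymous (B) and nonsynonymous (A) substitution flows of the
# GY94 matrix before normalization: the mean rate at omega is B + omega A.
.syn_nonsyn_flow <- function(kappa, freqs) {
  cp <- .codon_pairs
  pi <- freqs$pi
  flow <- pi[cp$i] * pi[cp$j] * ifelse(cp$transition, kappa, 1)
  c(B = sum(flow[cp$synonymous]), A = sum(flow[!cp$synonymous]))
}

# Evaluate a mixture likelihood. Returns total log-likelihood, per-pattern
# log-likelihoods, the npat x K matrix of per-class per-pattern
# log-likelihoods, and the per-edge P lists for downstream reuse.
#
# All classes share one time scale: class omega rescales the substitution
# rate (s(omega) = B + omega A), so positively selected classes evolve
# faster, not just with a different synonymous/nonsynonymous composition.
# Under gauge = "mixture" a branch length is the expected number of
# substitutions per codon averaged over the background classes; gauge =
# "neutral" measures branch lengths in neutral (omega = 1) substitutions,
# which leaves per-class likelihood columns independent of the class
# proportions (so they can be cached during optimization). The two gauges
# differ only by a rescaling of all branch lengths.
.mixture_eval <- function(ti, pk, mix, tvec, fg_edges, keep = FALSE,
                          cache = NULL, gauge = c("mixture", "neutral")) {
  gauge <- match.arg(gauge)
  classes <- mix$classes
  pi <- mix$freqs$pi
  omegas <- sort(unique(c(classes$omega_bg, classes$omega_fg)))
  key <- function(w) sprintf("%.17g", w)
  kk <- key(mix$kappa)
  fl <- .syn_nonsyn_flow(mix$kappa, mix$freqs)
  s_of <- function(w) fl[["B"]] + w * fl[["A"]]
  C_mix <- sum(classes$prop * s_of(classes$omega_bg))
  C0 <- if (gauge == "mixture") C_mix else s_of(1)
  rate_bg <- s_of(classes$omega_bg) / C0
  rate_fg <- s_of(classes$omega_fg) / C0
  eig_for <- function(w) {
    ekey <- paste0("eig|", kk, "|", key(w))
    if (!is.null(cache) && !is.null(cache[[ekey]])) return(cache[[ekey]])
    e <- eigen_rate_matrix(codon_rate_matrix(mix$kappa, w, mix$freqs))
    if (!is.null(cache)) cache[[ekey]] <- e
    e
  }
  eigs <- lapply(omegas, eig_for)
  names(eigs) <- vapply(omegas, key, character(1))
  K <- nrow(classes)
  npat <- ncol(pk$states)
  cls_loglik <- matrix(0, npat, K)
  P_all <- list()     # per-omega full edge P lists, built once
  P_fg <- list()      # per-omega foreground-edge P lists
  P_for <- function(w) {
    kw <- key(w)
    if (is.null(P_all[[kw]])) {
      r <- s_of(w) / C0
      P_all[[kw]] <<- lapply(tvec * r, function(t) .P_from_eigen(eigs[[kw]], t))
    }
    P_all[[kw]]
  }
  P_for_fg <- function(w) {
    kw <- key(w)
    if (is.null(P_fg[[kw]])) {
      r <- s_of(w) / C0
      P_fg[[kw]] <<- lapply(tvec[fg_edges] * r, function(t)
        .P_from_eigen(eigs[[kw]], t))
    }
    P_fg[[kw]]
  }
  seen <- list() # within-evaluation dedup of identical class signatures
  for (k in seq_len(K)) {
    wb <- classes$omega_bg[k]; wf <- classes$omega_fg[k]
    ckey <- paste0("col|", kk, "|", key(wb), "|", key(wf))
    if (!is.null(seen[[ckey]])) {
      cls_loglik[, k] <- cls_loglik[, seen[[ckey]]]
      next
    }
    seen[[ckey]] <- k
    if (!is.null(cache) && !is.null(cache[[ckey]])) {
      cls_loglik[, k] <- cache[[ckey]]
      next
    }
    Pl <- P_for(wb)
    if (wf != wb && length(fg_edges)) {
      Pl[fg_edges] <- P_for_fg(wf)
    }
    lp_pat <- prune_loglik_cpp(ti$edge, ti$children_edges, ti$parents_order,
                               Pl, pk$states, pi, ti$ntip, ti$nnode)
    cls_loglik[, k] <- lp_pat
    if (!is.null(cache)) cache[[ckey]] <- lp_pat
  }
  lp <- log(classes$prop)
  lw <- sweep(cls_loglik, 2L, lp, "+")
  mx <- as.vector(do.call(pmax, c(asplit(lw, 2L), list(-Inf))))
  site_log <- mx + log(rowSums(exp(lw - mx)))
  out <- list(loglik = sum(pk$weights * site_log), site_log = site_log,
              cls_loglik = cls_loglik,
              mix_rate = C_mix / C0, rate_bg = rate_bg, rate_fg = rate_fg)
  if (keep) {
    out$class_eig <- lapply(seq_len(K), function(k)
      list(bg = eigs[[key(classes$omega_bg[k])]],
           fg = eigs[[key(classes$omega_fg[k])]],
           r_bg = rate_bg[k], r_fg = rate_fg[k]))
  }
  out
}

# Same interface for a fixed generic rate matrix (amino-acid analyses).
.single_eval <- function(ti, pk, eig, tvec, keep = FALSE) {
  Pl <- .class_P(eig, eig, tvec, integer(0))
  lp <- prune_loglik_cpp(ti$edge, ti$children_edges, ti$parents_order,
                         Pl, pk$states, eig$pi, ti$ntip, ti$nnode)
  out <- list(loglik = sum(pk$weights * lp), site_log = lp,
              cls_loglik = matrix(lp, ncol = 1))
  if (keep) {
    out$class_eig <- list(list(bg = eig, fg = eig))
  }
  out
}

.states_of <- function(aln) {
  if (inherits(aln, "codon_alignment")) {
    if (anyNA(aln$codons)) stop("alignment must be cleaned before likelihood evaluation")
    aln$codons
  } else if (inherits(aln, "aa_alignment")) {
    aln$aa
  } else stop("argument error: need a codon_alignment or aa_alignment")
}

#' Phylogenetic log-likelihood of an alignment
#'
#' Pruning likelihood under either a single reversible rate matrix or a
#' site-class mixture with optional foreground branches (branch and
#' branch-site structures). Sites are independent; per-site values are
#' returned alongside the total.
#'
#' @param aln a cleaned `codon_alignment` or an `aa_alignment`.
#' @param tree ape `phylo` with branch lengths (expected substitutions per
#'   codon or per residue).
#' @param model a `site_class_mixture` or a `rate_matrix`.
#' @param foreground tip labels (or edge indices) of foreground branches.
#' @return list with `loglik`, `site_loglik` (per alignment site), and
#'   `class_site_loglik` (sites x classes matrix of per-class
#'   log-likelihoods).
#' @export
tree_loglik <- function(aln, tree, model, foreground = NULL) {
  states <- .states_of(aln)
  ti <- .tree_index(tree, rownames(states))
  if (is.null(ti$tree$edge.length)) stop("data error: tree has no branch lengths")
  tvec <- ti$tree$edge.length
  if (any(tvec < 0)) stop("data error: negative branch length")
  pk <- .pack_states(states[ti$tree$tip.label, , drop = FALSE])
  fg <- .foreground_edges(ti, foreground)
  ev <- if (inherits(model, "site_class_mixture")) {
    .mixture_eval(ti, pk, model, tvec, fg)
  } else if (inherits(model, "rate_matrix")) {
    .single_eval(ti, pk, eigen_rate_matrix(model), tvec)
  } else stop("argument error: model must be a site_class_mixture or rate_matrix")
  list(loglik = ev$loglik,
       site_loglik = ev$site_log[pk$map],
       class_site_loglik = ev$cls_loglik[pk$map, , drop = FALSE])
}
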