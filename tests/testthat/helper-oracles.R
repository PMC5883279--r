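# Independent oracles: never share code with the implementation paths they
# check.

# Matrix exponential by scaling-and-squaring of the Taylor series.
expm_series <- function(Q, t, order = 24L) {
  A <- Q * t
  k <- max(0L, ceiling(log2(max(1, max(abs(A))))) + 4L)
  A <- A / 2^k
  S <- diag(nrow(A))
  term <- diag(nrow(A))
  for (i in seq_len(order)) {
    term <- term %*% A / i
    S <- S + term
  }
  for (i in seq_len(k)) S <- S %*% S
  S
}

# Exhaustive-enumeration log-likelihood for small trees: sums over all joint
# internal-node state assignments. Uses only exported building blocks
# (codon_rate_matrix, transition_matrix) plus the documented time-scale
# convention: class omega rescales the rate by s(omega)/s_mix, with s the
# pre-normalization mean rate and s_mix its proportion-weighted mean over
# the background classes.
enum_loglik <- function(aln, tree, mix, foreground = NULL) {
  tree <- ape::reorder.phylo(tree, "postorder")
  states <- aln$codons[tree$tip.label, , drop = FALSE]
  ntip <- nrow(states)
  edge <- tree$edge
  tvec <- tree$edge.length
  classes <- mix$classes
  s_of <- vapply(seq_len(nrow(classes)), function(k)
    codon_rate_matrix(mix$kappa, classes$omega_bg[k], mix$freqs)$scale,
    numeric(1))
  s_mix <- sum(classes$prop * s_of)
  fg_edges <- if (is.null(foreground)) integer(0) else
    which(edge[, 2] %in% match(foreground, tree$tip.label))
  internal <- sort(unique(edge[, 1]))
  n_int <- length(internal)
  S <- 61L
  combos <- as.matrix(expand.grid(rep(list(seq_len(S)), n_int)))
  colnames(combos) <- internal
  root <- ntip + 1L
  n_sites <- ncol(states)
  total_lik <- matrix(0, n_sites, 1)
  for (k in seq_len(nrow(classes))) {
    m_bg <- codon_rate_matrix(mix$kappa, classes$omega_bg[k], mix$freqs)
    m_fg <- codon_rate_matrix(mix$kappa, classes$omega_fg[k], mix$freqs)
    r_bg <- m_bg$scale / s_mix
    r_fg <- m_fg$scale / s_mix
    P <- lapply(seq_len(nrow(edge)), function(e) {
      if (e %in% fg_edges) transition_matrix(m_fg, tvec[e] * r_fg)
      else transition_matrix(m_bg, tvec[e] * r_bg)
    })
    base <- mix$freqs$pi[combos[, as.character(root)]]
    for (e in seq_len(nrow(edge))) {
      ch <- edge[e, 2]
      if (ch > ntip) {
        base <- base * P[[e]][cbind(combos[, as.character(edge[e, 1])],
                                    combos[, as.character(ch)])]
      }
    }
    for (s in seq_len(n_sites)) {
      lik <- base
      for (e in seq_len(nrow(edge))) {
        ch <- edge[e, 2]
        if (ch <= ntip) {
          lik <- lik * P[[e]][cbind(combos[, as.character(edge[e, 1])],
                                    states[ch, s])]
        }
      }
      total_lik[s, 1] <- total_lik[s, 1] + classes$prop[k] * sum(lik)
    }
  }
  sum(log(total_lik))
}

# Poisson tail probabilities by direct pmf summation.
pois_upper_pmf <- function(k, lambda, upto = 200L) {
  x <- k:(k + upto)
  sum(exp(-lambda + x * log(lambda) - lfactorial(x)))
}
pois_lower_pmf <- function(k, lambda) {
  x <- 0:k
  sum(exp(-lambda + x * log(lambda) - lfactorial(x)))
}

# Benjamini-Hochberg by the textbook step-up rule, straight from the
# definition (find the largest i with p_(i) <= i/m * alpha by scanning).
bh_adjust_textbook <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ps[i:m] * m / seq(i, m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}
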