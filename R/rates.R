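# Stationary frequencies and reversible rate matrices for codon (61-state)
# and amino-acid (20-state) processes.
#
# All matrices are normalized so that -sum(pi * diag(Q)) = 1: branch lengths
# are expected substitutions per codon (codon models) or per residue
# (amino-acid models).

#' F3x4 codon frequencies
#'
#' Position-specific nucleotide proportions pooled over taxa; sense-codon
#' frequencies are products over the three positions, renormalized after
#' excluding stop codons.
#'
#' @param aln cleaned `codon_alignment`.
#' @return object of class `codon_frequencies`: list with `pos_freqs`
#'   (3 x 4 matrix, rows sum to 1) and `pi` (61-vector summing to 1).
#' @export
f3x4_frequencies <- function(aln) {
  if (anyNA(aln$codons)) stop("alignment must be cleaned before computing frequencies")
  pos_freqs <- matrix(0, 3, 4, dimnames = list(paste0("pos", 1:3), NUCS))
  for (p in 1:3) {
    counts <- tabulate(CODON_NUC[aln$codons, p], nbins = 4L)
    if (sum(counts) == 0) stop("degenerate-data error: no observed nucleotides at position ", p)
    pos_freqs[p, ] <- counts / sum(counts)
  }
  pi <- pos_freqs[1, CODON_NUC[, 1]] * pos_freqs[2, CODON_NUC[, 2]] *
    pos_freqs[3, CODON_NUC[, 3]]
  if (sum(pi) <= 0) stop("degenerate-data error: all sense codons have zero F3x4 frequency")
  structure(list(pos_freqs = pos_freqs,
                 pi = stats::setNames(pi / sum(pi), SENSE_CODONS)),
            class = "codon_frequencies")
}

#' Uniform codon frequencies (1/61 per sense codon)
#' @return a `codon_frequencies` object.
#' @export
uniform_codon_frequencies <- function() {
  structure(list(pos_freqs = matrix(1 / 4, 3, 4,
                                    dimnames = list(paste0("pos", 1:3), NUCS)),
                 pi = stats::setNames(rep(1 / N_CODON, N_CODON), SENSE_CODONS)),
            class = "codon_frequencies")
}

.normalize_q <- function(Q, pi) {
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale <= 0) stop("degenerate rate matrix: zero total rate")
  list(Q = Q / scale, scale = scale)
}

#' Goldman-Yang codon rate matrix
#'
#' Target-frequency parameterization: a single-nucleotide change i -> j has
#' rate pi_j, multiplied by `kappa` for transitions and by `omega` for
#' nonsynonymous changes; multi-nucleotide changes are forbidden.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega dN/dS ratio (>= 0).
#' @param freqs a `codon_frequencies` object.
#' @return object of class `rate_matrix`: list with `states` (61), `Q`
#'   (normalized, rows sum to 0), `pi`, `scale` (pre-normalization mean rate)
#'   and `rho_n` (proportion of the total rate that is nonsynonymous).
#' @export
codon_rate_matrix <- function(kappa, omega, freqs) {
  if (!is.finite(kappa) || kappa <= 0) stop("argument error: kappa must be > 0")
  if (!is.finite(omega) || omega < 0) stop("argument error: omega must be >= 0")
  cp <- .codon_pairs
  pi <- freqs$pi
  rate <- pi[cp$j] * ifelse(cp$transition, kappa, 1) *
    ifelse(cp$synonymous, 1, omega)
  Q <- matrix(0, N_CODON, N_CODON, dimnames = list(SENSE_CODONS, SENSE_CODONS))
  Q[cbind(cp$i, cp$j)] <- rate
  nrm <- .normalize_q(Q, pi)
  flow <- pi[cp$i] * rate
  rho_n <- sum(flow[!cp$synonymous]) / sum(flow)
  structure(list(states = N_CODON, Q = nrm$Q, pi = pi, scale = nrm$scale,
                 rho_n = rho_n, kappa = kappa, omega = omega),
            class = "rate_matrix")
}

#' General reversible rate matrix from exchangeabilities and frequencies
#'
#' @param S symmetric exchangeability matrix with zero diagonal.
#' @param f equilibrium frequencies (nonnegative, summing to 1).
#' @return a `rate_matrix` with `Q_ij = S_ij * f_j`, normalized to mean rate 1.
#' @export
reversible_rate_matrix <- function(S, f) {
  if (!isSymmetric(unname(S), tol = 1e-10)) stop("argument error: exchangeability matrix must be symmetric")
  if (any(f < 0) || abs(sum(f) - 1) > 1e-8) stop("argument error: frequencies must be nonnegative and sum to 1")
  Q <- S * rep(f, each = nrow(S))
  nrm <- .normalize_q(Q, f)
  structure(list(states = nrow(S), Q = nrm$Q, pi = f, scale = nrm$scale),
            class = "rate_matrix")
}

#' Empirical amino-acid rate matrix
#'
#' Combines an empirical exchangeability matrix with gene-specific amino-acid
#' frequencies (the "+F" convention). The default exchangeabilities are the
#' chloroplast-protein cpREV matrix.
#'
#' @param exchangeabilities 20 x 20 symmetric matrix, or a model name accepted
#'   by [aa_exchangeabilities()].
#' @param f_gene 20-vector of amino-acid frequencies (alphabetical
#'   single-letter order), e.g. from [aa_frequencies()].
#' @return a `rate_matrix` over 20 states.
#' @export
aa_rate_matrix <- function(exchangeabilities = "cpREV", f_gene) {
  if (is.character(exchangeabilities)) {
    exchangeabilities <- aa_exchangeabilities(exchangeabilities)$S
  }
  if (!all(dim(exchangeabilities) == c(20L, 20L))) {
    stop("argument error: exchangeability matrix must be 20 x 20")
  }
  m <- reversible_rate_matrix(exchangeabilities, f_gene)
  dimnames(m$Q) <- list(AA_LETTERS, AA_LETTERS)
  names(m$pi) <- AA_LETTERS
  m
}

#' Observed amino-acid frequencies of a gene
#'
#' A pseudocount avoids zero equilibrium frequencies in short genes.
#'
#' @param aa_aln an `aa_alignment`.
#' @param pseudocount added to each residue count before normalization.
#' @return 20-vector of frequencies in alphabetical single-letter order.
#' @export
aa_frequencies <- function(aa_aln, pseudocount = 0.1) {
  counts <- tabulate(aa_aln$aa, nbins = 20L) + pseudocount
  stats::setNames(counts / sum(counts), AA_LETTERS)
}

#' Empirical exchangeability matrices
#'
#' Retrieves a published amino-acid exchangeability matrix and its reference
#' frequencies. `cpREV` (chloroplast proteins) is the default model for the
#' convergence analyses; `WAG`, `JTT` and `LG` are available as alternatives.
#' Matrices are taken from the model collection shipped with phangorn.
#'
#' @param model model name.
#' @return list with `S` (20 x 20 symmetric matrix, zero diagonal, rows/cols
#'   in alphabetical single-letter order) and `freq` (the model's reference
#'   frequencies).
#' @export
aa_exchangeabilities <- function(model = c("cpREV", "WAG", "JTT", "LG")) {
  model <- match.arg(model)
  obj <- switch(model,
                cpREV = phangorn:::.cpREV,
                WAG = phangorn:::.WAG,
                JTT = phangorn:::.JTT,
                LG = phangorn:::.LG)
  # phangorn stores the lower triangle in its amino-acid order (ARNDCQEGHILKMFPSTWYV)
  phang_order <- c("a","r","n","d","c","q","e","g","h","i",
                   "l","k","m","f","p","s","t","w","y","v")
  S <- matrix(0, 20, 20, dimnames = list(toupper(phang_order), toupper(phang_order)))
  S[lower.tri(S)] <- obj$Q
  S <- S + t(S)
  ord <- match(AA_LETTERS, toupper(phang_order))
  list(S = S[ord, ord],
       freq = stats::setNames(as.numeric(obj$bf[phang_order][ord]), AA_LETTERS))
}

#' Read an empirical matrix in PAML .dat layout
#'
#' Lower-triangular exchangeabilities (19 rows) followed by 20 equilibrium
#' frequencies, amino acids in PAML order (ARNDCQEGHILKMFPSTWYV); published
#' matrices such as gcpREV drop in unchanged.
#'
#' @param path file path.
#' @return list with `S` and `freq` as in [aa_exchangeabilities()].
#' @export
read_paml_dat <- function(path) {
  nums <- scan(path, what = numeric(), comment.char = "#", quiet = TRUE)
  if (length(nums) < 210) stop("format error: expected 190 exchangeabilities + 20 frequencies")
  paml <- c("A","R","N","D","C","Q","E","G","H","I",
            "L","K","M","F","P","S","T","W","Y","V")
  S <- matrix(0, 20, 20, dimnames = list(paml, paml))
  # .dat files list the lower triangle row by row = upper triangle in
  # column-major order
  S[upper.tri(S)] <- nums[1:190]
  S <- S + t(S)
  f <- nums[191:210]
  ord <- match(AA_LETTERS, paml)
  list(S = S[ord, ord], freq = stats::setNames(f[ord] / sum(f), AA_LETTERS))
}

#' Eigendecomposition of a reversible rate matrix
#'
#' Symmetrizes Q with the stationary frequencies so a symmetric eigensolver
#' can be used; the result supports fast transition matrices
#' `P(t) = U exp(L t) V`.
#'
#' @param m a `rate_matrix`.
#' @return list with `U`, `V` (= U^-1), `lambda`, `pi`.
#' @export
eigen_rate_matrix <- function(m) {
  # states with zero stationary frequency are unreachable (no rate leads
  # into them); a small floor keeps the similarity transform finite and
  # well-conditioned, leaving ordinary data untouched
  sq <- sqrt(pmax(m$pi, 1e-8))
  B <- m$Q * (sq %o% (1 / sq))
  B <- (B + t(B)) / 2 # symmetric up to rounding
  e <- eigen(B, symmetric = TRUE)
  U <- e$vectors / sq
  V <- t(e$vectors * sq)
  list(U = U, V = V, lambda = e$values, pi = m$pi, states = m$states,
       id = .next_eig_id())
}

# identity tags let downstream caches recognize shared eigensystems
.eig_counter <- new.env(parent = emptyenv())
.next_eig_id <- function() {
  n <- (.eig_counter$n %||% 0L) + 1L
  .eig_counter$n <- n
  sprintf("eig%d", n)
}

.P_from_eigen <- function(eig, t) {
  P <- eig$U %*% (exp(eig$lambda * t) * eig$V)
  P[P < 0] <- 0
  P
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param m a `rate_matrix` (or the result of [eigen_rate_matrix()]).
#' @param t branch length (>= 0), expected substitutions per site.
#' @return row-stochastic states x states matrix.
#' @export
transition_matrix <- function(m, t) {
  if (!is.finite(t) || t < 0) stop("argument error: t must be >= 0")
  eig <- if (!is.null(m$U)) m else eigen_rate_matrix(m)
  .P_from_eigen(eig, t)
}
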