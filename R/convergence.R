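# Amino-acid ancestral reconstruction and the convergent/parallel
# substitution analysis between species pairs.

#' Re-estimate branch lengths and reconstruct ancestral amino acids
#'
#' Branch lengths are ML-optimized under the given empirical amino-acid
#' model; marginal posteriors at every internal node are then computed per
#' site from the inward (pruning) and outward messages. MAP ties break
#' toward the alphabetically first residue.
#'
#' @param aa_aln an `aa_alignment` (translated, cleaned).
#' @param tree ape `phylo`; branch lengths, if present, are starting values.
#' @param model a 20-state `rate_matrix`, e.g. from [aa_rate_matrix()].
#' @param control optimizer settings (see `fit_m0`).
#' @return object of class `ancestral_states`: list with `tree` (postorder,
#'   re-estimated branch lengths), `map` (internal nodes x sites MAP residue
#'   indices; rownames are ape node numbers), `post_max` (their posterior
#'   probabilities), `posterior` (nodes x 20 x sites array), `tip_states`,
#'   `loglik` and `model`.
#' @export
reconstruct_ancestors <- function(aa_aln, tree, model, control = list()) {
  ctl <- .fit_control(control)
  states <- .states_of(aa_aln)
  if (anyNA(states)) stop("data error: amino-acid alignment contains undetermined residues")
  ti <- .tree_index(tree, rownames(states))
  pk <- .pack_states(states[ti$tree$tip.label, , drop = FALSE])
  eig <- eigen_rate_matrix(model)
  tvec <- if (!is.null(ti$tree$edge.length)) pmax(ti$tree$edge.length, ctl$t_min)
          else rep(ctl$t_init, ti$n_edge)
  cls <- list(list(bg = eig, fg = eig))
  ll_old <- -Inf
  for (it in seq_len(ctl$max_cycles)) {
    tvec <- .branch_sweep(ti, pk, cls, 1, tvec, integer(0), ctl)
    ll <- .single_eval(ti, pk, eig, tvec)$loglik
    if (ll - ll_old < ctl$cycle_tol) break
    ll_old <- ll
  }
  Pl <- .class_P(eig, eig, tvec, integer(0))
  down <- .down_pass(ti, pk$states, Pl, eig$pi)
  up <- .up_messages(ti, pk$states, Pl, down, eig$pi)
  internal <- ti$ntip + seq_len(ti$nnode)
  npat <- ncol(pk$states)
  post <- array(0, dim = c(ti$ntip + ti$nnode, 20L, pk$n_sites))
  map <- matrix(NA_integer_, ti$nnode, pk$n_sites,
                dimnames = list(internal, NULL))
  post_max <- matrix(NA_real_, ti$nnode, pk$n_sites,
                     dimnames = list(internal, NULL))
  for (nd in internal) {
    # marginal posterior: conditional likelihood below times outward message
    w <- if (nd == ti$root) {
      down$partial[[nd]] * eig$pi
    } else {
      down$partial[[nd]] * up$A[[nd]]
    }
    w <- w / rep(colSums(w), each = nrow(w))
    w_sites <- w[, pk$map, drop = FALSE]
    post[nd, , ] <- w_sites
    mp <- max.col(t(w_sites), ties.method = "first")
    map[as.character(nd), ] <- mp
    post_max[as.character(nd), ] <- w_sites[cbind(mp, seq_len(pk$n_sites))]
  }
  fitted_tree <- ti$tree
  fitted_tree$edge.length <- tvec
  structure(list(tree = fitted_tree, map = map, post_max = post_max,
                 posterior = post,
                 tip_states = states[ti$tree$tip.label, , drop = FALSE],
                 loglik = sum(pk$weights * down$loglik_pat),
                 model = model, gene_name = aa_aln$gene_name),
            class = "ancestral_states")
}

#' @export
print.ancestral_states <- function(x, ...) {
  cat("ancestral_states '", x$gene_name, "': ", nrow(x$map),
      " internal nodes x ", ncol(x$map), " sites, lnL = ",
      format(x$loglik, digits = 10), "\n", sep = "")
  invisible(x)
}

.pair_context <- function(asr, pair) {
  tree <- asr$tree
  tips <- match(pair, tree$tip.label)
  if (anyNA(tips)) {
    stop("argument error: pair members must be leaves of the tree: ",
         paste(pair[is.na(tips)], collapse = ", "))
  }
  edge_of <- function(tip) which(tree$edge[, 2] == tip)
  eA <- edge_of(tips[1]); eB <- edge_of(tips[2])
  if (identical(eA, eB)) stop("argument error: pair must name two distinct taxa")
  list(tree = tree, tipA = tips[1], tipB = tips[2],
       parentA = tree$edge[eA, 1], parentB = tree$edge[eB, 1],
       tA = tree$edge.length[eA], tB = tree$edge.length[eB])
}

#' Identify parallel and convergent substitution sites for a species pair
#'
#' A site qualifies when both extant residues are identical (x) and both
#' lineages changed relative to the MAP states of their parent nodes
#' (aA != x and aB != x). Sites are parallel when the two ancestral states
#' agree and convergent when they differ; labels record ancestral-derived
#' residues in three-letter code (e.g. "Val-Ile").
#'
#' @param asr an `ancestral_states` object.
#' @param pair character vector of two tip labels.
#' @return list with data frames `parallel` and `convergent` (columns
#'   `site`, `label`, plus ancestral/derived residues).
#' @export
find_pair_substitution_sites <- function(asr, pair) {
  pc <- .pair_context(asr, pair)
  x_A <- asr$tip_states[pc$tipA, ]
  x_B <- asr$tip_states[pc$tipB, ]
  aA <- asr$map[as.character(pc$parentA), ]
  aB <- asr$map[as.character(pc$parentB), ]
  same_tip <- x_A == x_B
  changed <- aA != x_A & aB != x_A
  qual <- same_tip & changed
  is_par <- qual & aA == aB
  is_con <- qual & aA != aB
  three <- function(i) unname(AA_THREE[AA_LETTERS[i]])
  par_idx <- which(is_par)
  con_idx <- which(is_con)
  par_df <- if (length(par_idx)) data.frame(
    site = par_idx,
    ancestral = three(aA[par_idx]), derived = three(x_A[par_idx]),
    label = paste0(three(aA[par_idx]), "-", three(x_A[par_idx])),
    stringsAsFactors = FALSE) else data.frame(
    site = integer(0), ancestral = character(0), derived = character(0),
    label = character(0), stringsAsFactors = FALSE)
  con_df <- if (length(con_idx)) data.frame(
    site = con_idx,
    ancestral_A = three(aA[con_idx]), ancestral_B = three(aB[con_idx]),
    derived = three(x_A[con_idx]),
    label = paste0(three(aA[con_idx]), "/", three(aB[con_idx]), "-",
                   three(x_A[con_idx])),
    stringsAsFactors = FALSE) else data.frame(
    site = integer(0), ancestral_A = character(0), ancestral_B = character(0),
    derived = character(0), label = character(0), stringsAsFactors = FALSE)
  list(parallel = par_df, convergent = con_df)
}

#' Expected numbers of parallel and convergent sites for a pair
#'
#' Under the fitted amino-acid model, conditioning on the MAP states of the
#' two parent nodes: a site with equal parent states a contributes
#' `sum_{x != a} P_tA(a, x) P_tB(a, x)` to the expected parallel count; a
#' site with unequal parent states aA, aB contributes
#' `sum_{x != aA, aB} P_tA(aA, x) P_tB(aB, x)` to the expected convergent
#' count. tA and tB are the terminal branch lengths.
#'
#' @param asr an `ancestral_states` object.
#' @param pair character vector of two tip labels.
#' @return list with `expected_parallel` and `expected_convergent`.
#' @export
expected_pair_convergence <- function(asr, pair) {
  pc <- .pair_context(asr, pair)
  eig <- eigen_rate_matrix(asr$model)
  PA <- .P_from_eigen(eig, pc$tA)
  PB <- .P_from_eigen(eig, pc$tB)
  aA <- asr$map[as.character(pc$parentA), ]
  aB <- asr$map[as.character(pc$parentB), ]
  exp_par <- 0; exp_con <- 0
  for (s in seq_along(aA)) {
    if (aA[s] == aB[s]) {
      a <- aA[s]
      exp_par <- exp_par + sum(PA[a, -a] * PB[a, -a])
    } else {
      drop_idx <- c(aA[s], aB[s])
      exp_con <- exp_con + sum(PA[aA[s], -drop_idx] * PB[aB[s], -drop_idx])
    }
  }
  list(expected_parallel = exp_par, expected_convergent = exp_con)
}

#' Poisson test for observed vs expected convergence counts
#'
#' The observed count is referred to a Poisson distribution with mean equal
#' to the model-expected count: the upper tail P(X >= observed) when the
#' observation exceeds the expectation, the lower tail P(X <= observed) when
#' it falls short, and p = 1 at equality.
#'
#' @param observed nonnegative integer count.
#' @param expected nonnegative Poisson mean.
#' @return list with `p_value` and `tail` ("upper", "lower" or "none").
#' @export
poisson_convergence_test <- function(observed, expected) {
  if (observed < 0 || expected < 0) stop("argument error: counts must be nonnegative")
  if (observed != round(observed)) stop("argument error: observed must be an integer")
  if (observed > expected) {
    list(p_value = stats::ppois(observed - 1, expected, lower.tail = FALSE),
         tail = "upper")
  } else if (observed < expected) {
    list(p_value = stats::ppois(observed, expected), tail = "lower")
  } else {
    list(p_value = 1, tail = "none")
  }
}

#' Full convergence analysis of one gene for one species pair
#'
#' @param asr an `ancestral_states` object for the gene.
#' @param pair character vector of two tip labels.
#' @param mode `"pooled"` tests parallel + convergent counts against the
#'   summed expectation (one p per gene); `"separate"` tests the two types
#'   individually.
#' @return object of class `pair_convergence`: observed site lists, counts,
#'   expectations and Poisson p-value(s).
#' @export
pair_convergence_test <- function(asr, pair, mode = c("pooled", "separate")) {
  mode <- match.arg(mode)
  obs <- find_pair_substitution_sites(asr, pair)
  ex <- expected_pair_convergence(asr, pair)
  n_par <- nrow(obs$parallel)
  n_con <- nrow(obs$convergent)
  res <- list(gene = asr$gene_name, pair = pair, mode = mode,
              parallel_sites = obs$parallel, convergent_sites = obs$convergent,
              observed_parallel = n_par, observed_convergent = n_con,
              expected_parallel = ex$expected_parallel,
              expected_convergent = ex$expected_convergent)
  if (mode == "pooled") {
    t <- poisson_convergence_test(n_par + n_con,
                                  ex$expected_parallel + ex$expected_convergent)
    res$p_value <- t$p_value
    res$tail <- t$tail
  } else {
    tp <- poisson_convergence_test(n_par, ex$expected_parallel)
    tc <- poisson_convergence_test(n_con, ex$expected_convergent)
    res$p_parallel <- tp$p_value; res$tail_parallel <- tp$tail
    res$p_convergent <- tc$p_value; res$tail_convergent <- tc$tail
    res$p_value <- min(1, 2 * min(tp$p_value, tc$p_value)) # Bonferroni over the two types
  }
  structure(res, class = "pair_convergence")
}

#' @export
print.pair_convergence <- function(x, ...) {
  cat("pair_convergence '", x$gene, "' (", paste(x$pair, collapse = " vs "),
      "): ", x$observed_parallel, " parallel / ", x$observed_convergent,
      " convergent observed; expected ",
      format(x$expected_parallel, digits = 3), " / ",
      format(x$expected_convergent, digits = 3), "; p = ",
      format(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Genes with both positive-selection and convergence signatures
#'
#' The stringent intersection criterion: a conservative signature of
#' adaptive evolution requires a gene to carry a significant branch-site
#' positive-selection signal and a significant excess of convergent
#' substitutions.
#'
#' @param psg character vector of positively selected genes.
#' @param conv character vector of genes with significant convergence
#'   (q < FDR level).
#' @return character vector (sorted) with attribute `provenance`, a data
#'   frame recording which test supplied each membership.
#' @export
conservative_adaptive_genes <- function(psg, conv) {
  both <- sort(intersect(unique(psg), unique(conv)))
  attr(both, "provenance") <- data.frame(
    gene = both,
    positive_selection = rep(TRUE, length(both)),
    convergence = rep(TRUE, length(both)))
  both
}
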