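# Site and alignment likelihoods under (possibly branch-heterogeneous)
# GTR: a literal sum-over-internal-states evaluator for validation, the
# pruning (post-order factorised) computation used everywhere else, and the
# root-placement dependence diagnostic.

# Precompute per-node transition matrices for a tree under an assignment.
# Returns list(P = 4 x 4 x (2s-1) array, root_pi, eigs per vector).
# Each composition vector's generator shares the model's exchangeabilities
# and is calibrated to mean rate 1 under its own pi.
branch_matrices <- function(tree, assignment, model) {
  map <- resolve_branch_map(assignment, tree)
  vecs <- assignment$vectors
  eigs <- lapply(vecs, function(v) {
    m <- gtr_model(model$rho, v)
    rate_matrix_eigen(gtr_rate_matrix(m))
  })
  nn <- 2L * tree$s - 1L
  P <- array(NA_real_, c(4L, 4L, nn))
  for (k in seq_len(nn - 1L)) {
    P[, , k] <- if (tree$brlen[k] == 0) diag(4) else
      ptrans_from_eigen(eigs[[map[k]]], tree$brlen[k])
  }
  list(P = P, root_pi = as.numeric(vecs[[map[nn]]]), eigs = eigs, map = map)
}

as_assignment <- function(assignment) {
  if (inherits(assignment, "composition_assignment")) return(assignment)
  if (inherits(assignment, "composition_vector"))
    return(composition_assignment(assignment))
  stop("need a composition_assignment or composition_vector", call. = FALSE)
}

# encode a pattern (character or integer states) to 1..4 / NA
encode_pattern <- function(pattern) {
  if (is.character(pattern)) {
    pattern <- toupper(pattern)
    pattern[pattern == "U"] <- "T"
    st <- match(pattern, .nuc_bases)
  } else st <- as.integer(pattern)
  st
}

#' Exact site likelihood by state enumeration
#'
#' Literal evaluation of the site likelihood as the sum over all joint
#' assignments of states to the s-1 internal nodes:
#' \deqn{L = \sum_y \pi_{y_{2s-1}} \prod_{k=1}^{s} p_{y_{\sigma(k)},x_k}(v_k)
#'   \prod_{k=s+1}^{2s-2} p_{y_{\sigma(k)},y_k}(v_k)}
#' with the root term weighted by the root's composition vector.  Cost is
#' `4^(s-1)`; guarded to 8 taxa.  Exists as the independent reference for
#' [site_likelihood_pruning()].
#'
#' @param tree A `phylo_tree`.
#' @param assignment A [composition_assignment()] (or a single
#'   [composition_vector()] for the homogeneous model).
#' @param model A [gtr_model()] supplying exchangeabilities and rate scale.
#' @param pattern Character (A/C/G/T, anything else = missing) or integer
#'   states, length s, in tip order.
#' @return The site likelihood, a scalar in (0, 1].
#' @export
site_likelihood_bruteforce <- function(tree, assignment, model, pattern) {
  stopifnot(inherits(tree, "phylo_tree"))
  if (tree$s > 8L)
    stop("brute-force evaluation is guarded to 8 taxa", call. = FALSE)
  assignment <- as_assignment(assignment)
  bm <- branch_matrices(tree, assignment, model)
  x <- encode_pattern(pattern)
  stopifnot(length(x) == tree$s)
  s <- tree$s
  root <- 2L * s - 1L
  internals <- seq(s + 1L, root)
  grid <- as.matrix(expand.grid(rep(list(1:4), s - 1L)))
  total <- 0
  for (r in seq_len(nrow(grid))) {
    y <- grid[r, ]
    state_of <- function(k) if (k <= s) x[k] else y[k - s]
    term <- bm$root_pi[y[root - s]]
    for (k in seq_len(2L * s - 2L)) {
      sk <- state_of(k)
      if (is.na(sk)) next   # missing tip: conditional likelihood 1
      term <- term * bm$P[state_of(tree$parent[k]), sk, k]
    }
    total <- total + term
  }
  total
}

# Core pruning over a matrix of patterns (s x m integer states, NA =
# missing).  Returns per-pattern log likelihoods.  The fast path carries
# raw partials (safe for small trees); if any site underflows to zero it
# recomputes with per-node rescaling (threshold 1e-100) and accumulated
# log factors, so deep trees cannot lose sites.

tip_contrib <- function(P, S, child, m) {
  st <- S[child, ]
  Pk <- P[, , child]
  if (!anyNA(st)) return(Pk[, st, drop = FALSE])
  cc <- matrix(1, 4L, m)
  ok <- which(!is.na(st))
  if (length(ok)) cc[, ok] <- Pk[, st[ok]]
  cc
}

prune_pattern_loglik <- function(tree, P, root_pi, S) {
  s <- tree$s
  m <- ncol(S)
  part <- vector("list", 2L * s - 1L)
  ch <- tree$children
  for (k in tree$postorder) {
    c1 <- ch[1L, k]; c2 <- ch[2L, k]
    L1 <- if (c1 <= s) tip_contrib(P, S, c1, m) else P[, , c1] %*% part[[c1]]
    L2 <- if (c2 <= s) tip_contrib(P, S, c2, m) else P[, , c2] %*% part[[c2]]
    part[[k]] <- L1 * L2
  }
  lik <- colSums(root_pi * part[[2L * s - 1L]])
  if (all(lik > 0)) return(log(lik))
  prune_pattern_loglik_scaled(tree, P, root_pi, S)
}

prune_pattern_loglik_scaled <- function(tree, P, root_pi, S) {
  s <- tree$s
  m <- ncol(S)
  logscale <- numeric(m)
  part <- vector("list", 2L * s - 1L)
  for (k in tree$postorder) {
    L <- matrix(1, 4L, m)
    for (child in tree$children[, k]) {
      L <- L * (if (child <= s) tip_contrib(P, S, child, m)
                else P[, , child] %*% part[[child]])
    }
    cm <- pmax(L[1L, ], L[2L, ], L[3L, ], L[4L, ])
    low <- cm < 1e-100
    if (any(low)) {
      idx <- which(low)
      L[, idx] <- L[, idx, drop = FALSE] / rep(cm[idx], each = 4L)
      logscale[idx] <- logscale[idx] + log(cm[idx])
    }
    part[[k]] <- L
  }
  log(colSums(root_pi * part[[2L * s - 1L]])) + logscale
}

#' Site likelihood by Felsenstein pruning
#'
#' Post-order factorisation of the same sum [site_likelihood_bruteforce()]
#' evaluates literally; cost linear in the number of taxa, with per-node
#' rescaling against underflow.
#'
#' @inheritParams site_likelihood_bruteforce
#' @return The site likelihood (scalar).
#' @export
site_likelihood_pruning <- function(tree, assignment, model, pattern) {
  stopifnot(inherits(tree, "phylo_tree"))
  assignment <- as_assignment(assignment)
  bm <- branch_matrices(tree, assignment, model)
  x <- encode_pattern(pattern)
  stopifnot(length(x) == tree$s)
  exp(prune_pattern_loglik(tree, bm$P, bm$root_pi, matrix(x, ncol = 1L)))
}

#' Log-likelihood of an alignment on a tree
#'
#' Sites are independent, so \eqn{\ln L = \sum_{j=1}^{n} \ln L_j}.
#' Identical columns are collapsed into weighted site patterns and computed
#' once; the result is identical to the uncompressed sum.
#'
#' @param aln A [nucleotide_alignment()]; its taxa must match the tree's.
#' @param tree A `phylo_tree`.
#' @param assignment A [composition_assignment()] or single
#'   [composition_vector()].
#' @param model A [gtr_model()].
#' @param per_site Also return the n per-site log likelihoods?
#' @return `ln L` (scalar), or if `per_site` a list with `log_likelihood`
#'   and `per_site`.
#' @export
log_likelihood <- function(aln, tree, assignment, model, per_site = FALSE) {
  stopifnot(inherits(aln, "nucleotide_alignment"),
            inherits(tree, "phylo_tree"))
  if (!setequal(aln$taxa, tree$labels))
    stop(sprintf(
      "taxa mismatch: alignment-only {%s}, tree-only {%s}",
      paste(setdiff(aln$taxa, tree$labels), collapse = ","),
      paste(setdiff(tree$labels, aln$taxa), collapse = ",")), call. = FALSE)
  assignment <- as_assignment(assignment)
  bm <- branch_matrices(tree, assignment, model)
  cp <- compress_patterns(aln)
  # reorder alignment rows to tip order
  ord <- match(tree$labels, aln$taxa)
  S <- cp$states[ord, , drop = FALSE]
  ll <- prune_pattern_loglik(tree, bm$P, bm$root_pi, S)
  total <- sum(cp$weights * ll)
  if (!per_site) return(total)
  list(log_likelihood = total, per_site = ll[cp$site_pattern])
}

#' Root-placement dependence of the likelihood
#'
#' Re-roots the tree's unrooted shape on every branch (splitting the branch
#' length in half) and reports `ln L` for each placement.  Under a
#' homogeneous reversible model all entries coincide (pulley principle);
#' with two or more composition vectors they generally differ — the
#' diagnostic signature of nonstationary composition.
#'
#' Because branch identity changes under re-rooting, heterogeneity is
#' specified here by tip groups (as in [assign_compositions()]), which
#' transfer unambiguously across root placements.
#'
#' @param aln A [nucleotide_alignment()].
#' @param tree A `phylo_tree`.
#' @param model A [gtr_model()].
#' @param vectors Optional list of composition vectors
#'   (`vectors[[1]]` = background); `NULL` for the homogeneous model.
#' @param groups Tip-label groups for the non-background vectors.
#' @return List: `table` (data.frame of root edge and `log_likelihood`),
#'   `best` (row index of the maximising placement), `spread` (max - min).
#' @export
root_dependence <- function(aln, tree, model, vectors = NULL, groups = NULL) {
  stopifnot(inherits(tree, "phylo_tree"))
  ed <- unrooted_edges(tree)
  lls <- numeric(nrow(ed))
  desc <- character(nrow(ed))
  tips <- descendant_tips(tree)
  for (e in seq_len(nrow(ed))) {
    tr <- root_on_edge(tree, e)
    assignment <- if (is.null(vectors)) composition_assignment(model$pi)
      else assign_compositions(tr, vectors, groups)
    lls[e] <- log_likelihood(aln, tr, assignment, model)
    side <- if (!is.na(ed$node[e])) tree$labels[tips[[ed$node[e]]]] else
      tree$labels[tips[[unrooted_edges(tree)$v[e]]]]
    desc[e] <- paste(side, collapse = "|")
  }
  tab <- data.frame(edge = desc, log_likelihood = lls)
  list(table = tab, best = which.max(lls), spread = max(lls) - min(lls))
}
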