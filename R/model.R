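# GTR substitution model: composition vectors, exchangeabilities, rate
# matrix construction, calibration, transition probabilities, stationary
# distribution, and the branch -> composition-vector assignment machinery
# for tree-heterogeneous composition.

.pair_names <- c("AC", "AG", "AT", "CG", "CT", "GT")

#' Stationary nucleotide composition vector
#'
#' The vector of stationary frequencies (pi_A, pi_C, pi_G, pi_T).  Entries
#' must be strictly positive; the vector is normalised to sum exactly to 1.
#'
#' @param pi Numeric vector of 4 positive frequencies, order A, C, G, T.
#' @return Named numeric vector of class `"composition_vector"`.
#' @examples
#' composition_vector(c(0.1, 0.2, 0.3, 0.4))
#' @export
composition_vector <- function(pi = rep(0.25, 4)) {
  pi <- as.numeric(pi)
  if (length(pi) != 4L || anyNA(pi) || any(!is.finite(pi)))
    stop("composition vector needs 4 finite frequencies", call. = FALSE)
  if (any(pi <= 0))
    stop("composition frequencies must be strictly positive", call. = FALSE)
  pi <- pi / sum(pi)
  structure(stats::setNames(pi, .nuc_bases), class = "composition_vector")
}

#' GTR exchangeabilities
#'
#' The six symmetric relative rates for unordered nucleotide pairs
#' AC, AG, AT, CG, CT, GT.  Normalised so the GT rate equals 1
#' (identifiability convention).
#'
#' @param rho Numeric vector of 6 positive rates, order AC, AG, AT, CG, CT,
#'   GT.  A named vector is reordered by name.
#' @return Named numeric vector of class `"exchangeabilities"`.
#' @export
exchangeabilities <- function(rho = rep(1, 6)) {
  rho <- if (!is.null(names(rho)) && all(.pair_names %in% names(rho)))
    as.numeric(rho[.pair_names]) else as.numeric(rho)
  if (length(rho) != 6L || anyNA(rho) || any(!is.finite(rho)) || any(rho <= 0))
    stop("exchangeabilities need 6 finite positive rates", call. = FALSE)
  rho <- rho / rho[6L]
  structure(stats::setNames(rho, .pair_names), class = "exchangeabilities")
}

#' General time-reversible substitution model
#'
#' Bundles exchangeabilities, a stationary composition vector and the
#' overall rate scale mu.  By default mu is calibrated with
#' [calibrate_mu()] so that the expected substitution rate at
#' stationarity is 1, making branch lengths expected substitutions per
#' site.
#'
#' @param rho An [exchangeabilities()] vector (or coercible numeric).
#' @param pi A [composition_vector()] (or coercible numeric).
#' @param mu Overall rate scale; `NULL` (default) calibrates to mean rate 1.
#' @return Object of class `"gtr_model"` with elements `rho`, `pi`, `mu`.
#' @examples
#' gtr_model()                      # Jukes-Cantor special case
#' gtr_model(c(1, 2, 1, 1, 2, 1), c(0.3, 0.2, 0.2, 0.3))
#' @export
gtr_model <- function(rho = exchangeabilities(), pi = composition_vector(),
                      mu = NULL) {
  rho <- exchangeabilities(rho)
  pi <- composition_vector(pi)
  if (is.null(mu)) mu <- calibrate_mu(rho, pi)
  if (!is.finite(mu) || mu <= 0)
    stop("mu must be a positive finite scalar", call. = FALSE)
  structure(list(rho = rho, pi = pi, mu = mu), class = "gtr_model")
}

#' @export
print.gtr_model <- function(x, ...) {
  cat("GTR substitution model\n")
  cat("  exchangeabilities:",
      paste(sprintf("%s=%.4g", .pair_names, x$rho), collapse = " "), "\n")
  cat("  composition:     ",
      paste(sprintf("%s=%.4g", .nuc_bases, x$pi), collapse = " "), "\n")
  cat(sprintf("  rate scale mu:    %.6g\n", x$mu))
  invisible(x)
}

# Symmetric rho matrix with zero diagonal.
rho_matrix <- function(rho) {
  R <- matrix(0, 4, 4, dimnames = list(.nuc_bases, .nuc_bases))
  R["A", "C"] <- R["C", "A"] <- rho[1L]
  R["A", "G"] <- R["G", "A"] <- rho[2L]
  R["A", "T"] <- R["T", "A"] <- rho[3L]
  R["C", "G"] <- R["G", "C"] <- rho[4L]
  R["C", "T"] <- R["T", "C"] <- rho[5L]
  R["G", "T"] <- R["T", "G"] <- rho[6L]
  R
}

#' Calibrate the overall rate scale
#'
#' Returns the mu for which the GTR generator built from `rho` and `pi` has
#' expected substitution rate 1 at stationarity, i.e.
#' \eqn{-\sum_i \pi_i q_{ii} = 1}.  With this calibration branch lengths are
#' expected substitutions per site.
#'
#' @param rho An [exchangeabilities()] vector.
#' @param pi A [composition_vector()].
#' @return Positive scalar mu.
#' @export
calibrate_mu <- function(rho, pi) {
  rho <- exchangeabilities(rho)
  pi <- composition_vector(pi)
  R <- rho_matrix(rho)
  # mean rate with mu = 1: sum_i pi_i sum_{j != i} rho_ij pi_j
  rate1 <- sum(pi * (R %*% pi))
  if (!is.finite(rate1) || rate1 <= 0)
    stop("degenerate model: zero mean substitution rate", call. = FALSE)
  1 / rate1
}

#' Build the GTR instantaneous rate matrix
#'
#' Constructs the 4x4 generator Q with off-diagonals
#' \eqn{q_{ij} = \mu \rho_{ij} \pi_j} (rows index the current nucleotide,
#' order A, C, G, T) and diagonals set so each row sums to zero.  Q
#' satisfies detailed balance \eqn{\pi_i q_{ij} = \pi_j q_{ji}}.
#'
#' @param model A [gtr_model()].
#' @return 4x4 numeric matrix with A,C,G,T dimnames; the model's `pi` is
#'   attached as attribute `"pi"`.
#' @export
gtr_rate_matrix <- function(model) {
  stopifnot(inherits(model, "gtr_model"))
  if (any(!is.finite(c(model$rho, model$pi, model$mu))))
    stop("non-finite model parameters", call. = FALSE)
  Q <- model$mu * rho_matrix(model$rho) * rep(model$pi, each = 4L)
  diag(Q) <- -rowSums(Q)
  attr(Q, "pi") <- as.numeric(model$pi)
  Q
}

# Eigendecomposition of a reversible generator via its symmetrised form
# D^{1/2} Q D^{-1/2} (D = diag(pi)), which is symmetric and therefore has a
# real, orthogonal eigensystem.  Returns the factors of P(t) = A exp(Lt) B.
rate_matrix_eigen <- function(Q, pi = attr(Q, "pi")) {
  if (is.null(pi)) pi <- as.numeric(stationary_distribution(Q))
  sq <- sqrt(pi)
  Sym <- (sq * Q) * rep(1 / sq, each = 4L)
  Sym <- (Sym + t(Sym)) / 2   # kill rounding asymmetry
  e <- eigen(Sym, symmetric = TRUE)
  list(A = e$vectors / sq * 1,          # D^{-1/2} U (column ops below)
       A_ = (1 / sq) * e$vectors,
       B = t(e$vectors * sq),           # U' D^{1/2}
       values = e$values)
}

ptrans_from_eigen <- function(eig, t) {
  P <- eig$A_ %*% (exp(eig$values * t) * eig$B)
  # clamp roundoff: entries must be probabilities
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computes the matrix exponential of a reversible generator scaled by a
#' branch length, by eigendecomposition of the symmetrised form.  Rows sum
#' to 1 and P(0) is exactly the identity.
#'
#' @param Q A 4x4 generator from [gtr_rate_matrix()] (the stationary
#'   distribution is recovered from the `"pi"` attribute, or numerically if
#'   absent).
#' @param t Branch length, `t >= 0`.
#' @return 4x4 stochastic matrix.
#' @export
transition_matrix <- function(Q, t) {
  if (length(t) != 1L || !is.finite(t) || t < 0)
    stop("branch length t must be a single finite value >= 0", call. = FALSE)
  if (t == 0) {
    P <- diag(4)
    dimnames(P) <- list(.nuc_bases, .nuc_bases)
    return(P)
  }
  P <- ptrans_from_eigen(rate_matrix_eigen(Q), t)
  dimnames(P) <- list(.nuc_bases, .nuc_bases)
  P
}

#' Stationary distribution of a generator
#'
#' Solves \eqn{\pi Q = 0}, \eqn{\sum \pi = 1} by the left null vector of Q
#' (eigenvector of t(Q) at eigenvalue 0).
#'
#' @param Q A 4x4 rate matrix.
#' @return A [composition_vector()].
#' @export
stationary_distribution <- function(Q) {
  e <- eigen(t(Q))
  k <- which.min(abs(e$values))
  if (abs(e$values[k]) > 1e-8)
    stop("no zero eigenvalue: Q is not a proper generator", call. = FALSE)
  v <- Re(e$vectors[, k])
  v <- v / sum(v)
  if (any(v <= 0))
    stop("generator appears reducible: stationary vector not positive",
         call. = FALSE)
  composition_vector(v)
}

#' Branch-wise composition assignment
#'
#' Maps every node's parent branch (and the root) to one of a set of
#' composition vectors, the mechanism for tree-heterogeneous base
#' composition.  With a single vector this reduces to the homogeneous,
#' time-reversible model.  The root's entry doubles as the root frequency
#' vector of the likelihood.
#'
#' Exchangeabilities are shared across vectors; each vector's generator is
#' calibrated separately to mean rate 1 so branch lengths keep their
#' expected-substitutions interpretation everywhere on the tree.
#'
#' @param vectors A [composition_vector()] or list of them.
#' @param branch_map Integer vector over nodes `1..2s-1` giving the vector
#'   index for each node's parent branch (root entry = root frequencies), or
#'   `NULL` for homogeneous assignment of the single supplied vector.
#' @return Object of class `"composition_assignment"`.
#' @seealso [assign_compositions()] to build the map from tip groups.
#' @export
composition_assignment <- function(vectors, branch_map = NULL) {
  if (inherits(vectors, "composition_vector")) vectors <- list(vectors)
  if (!length(vectors) || !all(vapply(vectors, inherits, logical(1),
                                      "composition_vector")))
    stop("vectors must be composition_vector objects", call. = FALSE)
  if (is.null(branch_map)) {
    if (length(vectors) != 1L)
      stop("branch_map is required when more than one vector is supplied",
           call. = FALSE)
  } else {
    branch_map <- as.integer(branch_map)
    if (anyNA(branch_map) || any(branch_map < 1L) ||
        any(branch_map > length(vectors)))
      stop("branch_map entries must index the supplied vectors", call. = FALSE)
  }
  structure(list(vectors = vectors, branch_map = branch_map),
            class = "composition_assignment")
}

# Resolve an assignment against a tree: returns integer map over 1..2s-1.
resolve_branch_map <- function(assignment, tree) {
  nn <- 2L * tree$s - 1L
  if (is.null(assignment$branch_map)) return(rep(1L, nn))
  if (length(assignment$branch_map) != nn)
    stop(sprintf("branch_map length %d does not match tree with %d nodes",
                 length(assignment$branch_map), nn), call. = FALSE)
  assignment$branch_map
}

#' Build a composition assignment from tip groups
#'
#' Assigns composition vector `k+1` to every branch whose full descendant
#' tip set lies inside the `k`-th group (so a group of one tip marks just
#' that terminal branch, and a clade's tips mark the whole clade).  All
#' other branches, and the root, take the first (background) vector.
#'
#' @param tree A `phylo_tree`.
#' @param vectors List of composition vectors; `vectors[[1]]` is the
#'   background.
#' @param groups List of character vectors of tip labels, one per non-background
#'   vector (`length(groups) == length(vectors) - 1`).
#' @return A [composition_assignment()] with a resolved `branch_map`.
#' @export
assign_compositions <- function(tree, vectors, groups) {
  stopifnot(inherits(tree, "phylo_tree"))
  if (inherits(vectors, "composition_vector")) vectors <- list(vectors)
  if (length(groups) != length(vectors) - 1L)
    stop("need one tip group per non-background vector", call. = FALSE)
  unknown <- setdiff(unlist(groups), tree$labels)
  if (length(unknown))
    stop(sprintf("tip labels not in tree: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  nn <- 2L * tree$s - 1L
  map <- rep(1L, nn)
  tipsets <- descendant_tips(tree)
  for (g in seq_along(groups)) {
    grp <- groups[[g]]
    for (k in seq_len(nn - 1L)) {      # root keeps background frequencies
      if (all(tree$labels[tipsets[[k]]] %in% grp)) map[k] <- g + 1L
    }
  }
  composition_assignment(vectors, map)
}
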