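# The user-facing model-fitting interface: phylo_mcmc() runs the coupled
# sampler and wraps the posterior summaries in a classed object with the
# usual accessor methods.

#' Fit a Bayesian phylogeny by Metropolis-coupled MCMC
#'
#' The package's main fitting function: samples the posterior over rooted
#' topologies, branch lengths and GTR parameters for an aligned set of DNA
#' sequences, using `k_chains` heated chains with state swapping, and
#' returns the posterior summaries as a `"phylo_mcmc"` object.
#'
#' @param alignment A [nucleotide_alignment()] (or a path to a FASTA file).
#' @param ... Passed to [run_mcmcmc()] (tree, model, vectors/groups,
#'   iteration counts, chain settings, move weights).
#' @param seed Master seed; the run is bit-reproducible given it.
#' @param consensus_threshold Majority-rule threshold for the reported
#'   consensus.
#' @return Object of class `"phylo_mcmc"` with the trace, the topology
#'   posterior, the majority-rule consensus, the MAP tree and run
#'   statistics.  Methods: `print`, `summary`, `coef`, `logLik`, `plot`.
#' @examples
#' sc <- scenario_presets()$homoclean
#' sc$n_sites <- 300L
#' aln <- simulate_alignment(sc)
#' fit <- phylo_mcmc(aln, model = sc$model, n_iter = 2000, k_chains = 2,
#'                   seed = 1)
#' fit
#' @export
phylo_mcmc <- function(alignment, ..., seed = 1L, consensus_threshold = 0.5) {
  if (is.character(alignment)) alignment <- read_fasta_alignment(alignment)
  stopifnot(inherits(alignment, "nucleotide_alignment"))
  trace <- run_mcmcmc(alignment, ..., seed = seed)
  sp <- summarize_posterior(trace, threshold = consensus_threshold)
  best <- which.max(trace$samples$log_post)
  structure(list(call = match.call(), s = alignment$s, n = alignment$n,
                 trace = trace, posterior = sp$topologies,
                 consensus = sp$consensus,
                 map_topology = sp$map_topology, map_prob = sp$map_prob,
                 map_tree = trace$trees[best],
                 map_log_post = trace$samples$log_post[best],
                 acceptance = trace$acceptance, swap = trace$swap,
                 settings = trace$settings),
            class = "phylo_mcmc")
}

#' @export
print.phylo_mcmc <- function(x, ...) {
  st <- x$settings
  cat(sprintf(
    "Bayesian phylogeny (MC^3): %d taxa, %d sites, %d chains, %d iterations\n",
    x$s, x$n, st$k_chains, st$n_iter))
  cat(sprintf("  MAP topology (posterior %.3f): %s\n",
              x$map_prob, x$map_topology))
  cat("  consensus:", x$consensus$newick, "\n")
  invisible(x)
}

#' @export
summary.phylo_mcmc <- function(object, n_top = 5L, ...) {
  x <- object
  print(x)
  cat("\nTop topologies:\n")
  print(utils::head(x$posterior, n_top), row.names = FALSE)
  cat("\nAcceptance rates:\n")
  print(round(x$acceptance, 3))
  if (x$settings$k_chains > 1L) {
    swp <- ifelse(x$swap$attempted > 0,
                  x$swap$accepted / x$swap$attempted, NA_real_)
    cat("\nSwap acceptance (adjacent pairs):", round(swp, 3), "\n")
  }
  invisible(x)
}

#' @export
coef.phylo_mcmc <- function(object, ...) {
  out <- c(colMeans(object$trace$pi),
           stats::setNames(colMeans(object$trace$rho),
                           paste0("rho.", colnames(object$trace$rho))))
  names(out)[1:4] <- paste0("pi.", colnames(object$trace$pi))
  out
}

#' @export
logLik.phylo_mcmc <- function(object, ...) {
  structure(max(object$trace$samples$log_lik),
            df = NA_integer_, class = "logLik")
}

#' @export
plot.phylo_mcmc <- function(x, ...) {
  s <- x$trace$samples
  graphics::plot(s$iteration, s$log_post, type = "l",
                 xlab = "iteration", ylab = "log posterior (unnormalised)",
                 main = "Cold-chain trace", ...)
  invisible(x)
}
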