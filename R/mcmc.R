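# Posterior formulation and Metropolis-coupled MCMC over rooted trees:
# Metropolis-Hastings-Green acceptance, the heat ladder
# beta_i = 1/(1 + c(i-1)), tempered densities f_i = f_1^beta_i, state
# swapping between chains, and an exhaustive small-tree posterior used as
# the sampler's reference.

# ---- deterministic RNG substreams ----------------------------------------
# One master seed spawns named substreams (per chain, per module) so that
# adding chains or stages does not perturb existing streams.  Streams are
# realised as saved .Random.seed vectors swapped in and out around use.

substream_seed <- function(master, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147480009
  as.integer((as.numeric(master) %% 2147480009 * 48271 + h) %% 2147480009)
}

rng_state <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  st <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  st
}

rng_load <- function(state) assign(".Random.seed", state, globalenv())
rng_save <- function() get(".Random.seed", globalenv())

# ---- priors ---------------------------------------------------------------

log_double_factorial <- function(k) sum(log(seq(1, k, by = 2)))

# Priors: uniform over rooted topologies, iid Exponential branch lengths
# (mean brlen_mean), flat Dirichlet on composition and on normalised
# exchangeabilities.
log_prior_tree <- function(tree, brlen_mean = 0.1) {
  v <- tree$brlen[-(2L * tree$s - 1L)]
  sum(stats::dexp(v, rate = 1 / brlen_mean, log = TRUE)) -
    log_double_factorial(2L * tree$s - 3L)
}

ldirichlet <- function(x, alpha)
  sum((alpha - 1) * log(x)) - sum(lgamma(alpha)) + lgamma(sum(alpha))

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# ---- the coupling formulas, exported -------------------------------------

#' Chain heat ladder
#'
#' \eqn{\beta_i = 1 / (1 + c(i-1))}: the cold chain (`i = 1`) has
#' \eqn{\beta = 1}; larger `c` flattens the heated chains faster.  `c = 0`
#' makes every chain cold.
#'
#' @param i Chain index, `>= 1`.
#' @param c Heat coefficient, `>= 0`.
#' @return The heat \eqn{\beta_i}.
#' @export
chain_heat <- function(i, c) {
  if (any(i < 1)) stop("chain index must be >= 1", call. = FALSE)
  if (any(c < 0)) stop("heat coefficient must be >= 0", call. = FALSE)
  1 / (1 + c * (i - 1))
}

#' Tempered log density
#'
#' The heated chain's state value is \eqn{f_i(s) = f_1(s)^{\beta_i}}, i.e.
#' on the log scale simply \eqn{\beta \cdot \ln f_1(s)} with \eqn{f_1} the
#' unnormalised cold posterior.
#'
#' @param log_posterior Unnormalised cold log posterior of the state.
#' @param beta Chain heat in `(0, 1]`.
#' @return `beta * log_posterior`.
#' @export
heated_log_density <- function(log_posterior, beta) beta * log_posterior

#' Metropolis-Hastings-Green acceptance
#'
#' Accepts the proposed state with probability
#' \eqn{\min(1, \exp(\beta \Delta \ln f + \ln H))} where
#' \eqn{\Delta \ln f} is the change in unnormalised log posterior
#' (likelihood ratio times prior ratio) and \eqn{\ln H} the log Hastings
#' ratio of the proposal.  Heat tempers the posterior only, never the
#' Hastings term.  Draws exactly one uniform variate.  A non-finite
#' proposed density is auto-rejected.
#'
#' @param log_post_current,log_post_proposed Unnormalised cold log
#'   posteriors.
#' @param log_hastings Log Hastings ratio (0 for symmetric proposals).
#' @param beta Chain heat.
#' @return List: `accept` (logical), `log_ratio`.
#' @export
mh_accept <- function(log_post_current, log_post_proposed,
                      log_hastings = 0, beta = 1) {
  u <- stats::runif(1)
  if (!is.finite(log_post_proposed))
    return(list(accept = FALSE, log_ratio = -Inf))
  lr <- beta * (log_post_proposed - log_post_current) + log_hastings
  list(accept = (lr >= 0) || (u < exp(lr)), log_ratio = lr)
}

#' Log swap ratio between two heated chains
#'
#' For the exchange rate
#' \eqn{R = f_i(s_j) f_j(s_i) / (f_i(s_i) f_j(s_j))} with
#' \eqn{f_i = f_1^{\beta_i}}, the log simplifies to
#' \eqn{(\beta_i - \beta_j)(\ln f_1(s_j) - \ln f_1(s_i))}.  The swap is
#' applied with probability \eqn{\min(1, R)} — certain when `R >= 1`.
#'
#' @param beta_i,beta_j Heats of the two chains.
#' @param log_post_i,log_post_j Unnormalised cold log posteriors of their
#'   current states.
#' @return The log swap ratio.
#' @export
swap_log_ratio <- function(beta_i, beta_j, log_post_i, log_post_j)
  (beta_i - beta_j) * (log_post_j - log_post_i)

# ---- chain state ----------------------------------------------------------

new_chain_state <- function(tree, model, vectors, groups, S, w, beta,
                            brlen_mean) {
  assignment <- if (is.null(vectors)) composition_assignment(model$pi)
    else assign_compositions(tree, vectors, groups)
  bm <- branch_matrices(tree, assignment, model)
  ll <- sum(w * prune_pattern_loglik(tree, bm$P, bm$root_pi, S))
  if (!is.finite(ll))
    stop("zero-probability initial state: check starting tree and model",
         call. = FALSE)
  list(tree = tree, model = model, vectors = vectors, groups = groups,
       bm = bm, log_lik = ll,
       log_prior = log_prior_tree(tree, brlen_mean), beta = beta)
}

chain_log_post <- function(ch) ch$log_lik + ch$log_prior

# one MCMC update of one chain; ctx carries data, tuning and move weights
step_chain <- function(ch, ctx) {
  kind <- sample(names(ctx$weights), 1L, prob = ctx$weights)
  prop <- ch
  log_hastings <- 0
  if (kind == "topology") {
    pick <- ctx$nni[sample.int(nrow(ctx$nni), 1L), ]
    prop$tree <- rooted_nni(ch$tree, pick[["k"]], pick[["j"]])
    if (!is.null(ch$vectors)) {
      # group-based heterogeneity: branch map follows the new topology
      asn <- assign_compositions(prop$tree, ch$vectors, ch$groups)
      prop$bm <- branch_matrices(prop$tree, asn, ch$model)
    }
  } else if (kind == "brlen") {
    k <- sample.int(2L * ch$tree$s - 2L, 1L)
    x <- ch$tree$brlen[k]
    xp <- x * exp(ctx$lambda * (stats::runif(1) - 0.5))
    prop$tree$brlen[k] <- xp
    prop$bm$P[, , k] <- ptrans_from_eigen(prop$bm$eigs[[prop$bm$map[k]]], xp)
    prop$log_prior <- log_prior_tree(prop$tree, ctx$brlen_mean)
    log_hastings <- log(xp / x)
  } else if (kind == "pi") {
    vlist <- if (is.null(ch$vectors)) list(ch$model$pi) else ch$vectors
    vi <- sample.int(length(vlist), 1L)
    cur <- as.numeric(vlist[[vi]])
    a_fwd <- ctx$conc * cur
    newpi <- rdirichlet1(a_fwd)
    if (any(newpi < 1e-8)) return(ch_reject(ch, kind))
    log_hastings <- ldirichlet(cur, ctx$conc * newpi) -
      ldirichlet(newpi, a_fwd)
    newvec <- composition_vector(newpi)
    if (is.null(ch$vectors)) {
      prop$model <- gtr_model(ch$model$rho, newvec)
      asn <- composition_assignment(newvec)
    } else {
      prop$vectors[[vi]] <- newvec
      asn <- assign_compositions(ch$tree, prop$vectors, ch$groups)
    }
    prop$bm <- branch_matrices(ch$tree, asn, prop$model)
  } else if (kind == "rho") {
    cur <- as.numeric(ch$model$rho)
    curn <- cur / sum(cur)
    a_fwd <- ctx$conc * curn
    newn <- rdirichlet1(a_fwd)
    if (any(newn < 1e-8)) return(ch_reject(ch, kind))
    log_hastings <- ldirichlet(curn, ctx$conc * newn) -
      ldirichlet(newn, a_fwd)
    prop$model <- gtr_model(exchangeabilities(newn / newn[6L]),
                            ch$model$pi)
    asn <- if (is.null(ch$vectors)) composition_assignment(prop$model$pi)
      else assign_compositions(ch$tree, ch$vectors, ch$groups)
    prop$bm <- branch_matrices(ch$tree, asn, prop$model)
  }
  prop$log_lik <- sum(ctx$w *
    prune_pattern_loglik(prop$tree, prop$bm$P, prop$bm$root_pi, ctx$S))
  res <- mh_accept(chain_log_post(ch), chain_log_post(prop),
                   log_hastings, ch$beta)
  out <- if (res$accept) prop else ch
  attr(out, "move") <- kind
  attr(out, "accepted") <- res$accept
  out
}

ch_reject <- function(ch, kind) {
  attr(ch, "move") <- kind
  attr(ch, "accepted") <- FALSE
  ch
}

# ---- the sampler ----------------------------------------------------------

#' Metropolis-coupled MCMC over phylogenies
#'
#' Runs `k_chains` coupled chains at heats \eqn{\beta_i = 1/(1+c(i-1))}.
#' Each chain advances by Metropolis-Hastings-Green updates (rooted-NNI
#' topology moves, branch-length multipliers, Dirichlet-centred composition
#' and exchangeability moves); every `swap_interval` iterations a uniformly
#' random adjacent pair is proposed for a state exchange with probability
#' \eqn{\min(1, R)} on the swap ratio.  Only cold-chain states are
#' recorded.  Fully deterministic for a fixed `seed`: each chain and the
#' swap scheduler run on named RNG substreams of the master seed.
#'
#' @param aln A [nucleotide_alignment()].
#' @param tree Starting `phylo_tree`; a random topology with prior-mean
#'   branch lengths if `NULL`.
#' @param model Starting [gtr_model()].
#' @param vectors,groups Optional tree-heterogeneous composition
#'   specification (see [assign_compositions()]); the branch map follows
#'   topology proposals.
#' @param n_iter Total iterations.
#' @param burn_in Iterations discarded before sampling (default 25%).
#' @param thin Record every `thin`-th iteration.
#' @param k_chains Number of coupled chains (`1` = plain single-chain MHG).
#' @param heat_c Heat coefficient `c` of the ladder.
#' @param swap_interval Iterations between swap attempts.
#' @param move_weights Named weights over move kinds `topology`, `brlen`,
#'   `pi`, `rho`.  Kinds with weight 0 are never proposed; `fix_brlen` and
#'   `fix_model` zero the corresponding kinds (topology-only sampling uses
#'   both).
#' @param fix_brlen,fix_model Keep branch lengths / substitution parameters
#'   at their starting values.
#' @param brlen_prior_mean Mean of the exponential branch-length prior.
#' @param multiplier_lambda Scale of the branch-length multiplier proposal.
#' @param dirichlet_conc Concentration of the Dirichlet-centred proposals.
#' @param seed Master seed (integer).
#' @return Object of class `"phylo_trace"`: `samples` (data.frame with
#'   iteration, topology, log_lik, log_prior, log_post), `trees` (newick
#'   per sample), `pi`, `rho` (parameter draws), `acceptance` (per move
#'   kind), `swap` (attempted/accepted per adjacent pair), `betas`,
#'   `settings`.
#' @seealso [run_chain()], [summarize_posterior()], [phylo_mcmc()]
#' @export
run_mcmcmc <- function(aln, tree = NULL, model = gtr_model(),
                       vectors = NULL, groups = NULL,
                       n_iter = 10000L, burn_in = floor(0.25 * n_iter),
                       thin = 10L, k_chains = 4L, heat_c = 0.1,
                       swap_interval = 1L,
                       move_weights = c(topology = 0.4, brlen = 0.4,
                                        pi = 0.1, rho = 0.1),
                       fix_brlen = FALSE, fix_model = FALSE,
                       brlen_prior_mean = 0.1, multiplier_lambda = 1,
                       dirichlet_conc = 200, seed = 1L) {
  stopifnot(inherits(aln, "nucleotide_alignment"),
            n_iter > burn_in, burn_in >= 0L, k_chains >= 1L)
  w <- c(topology = 0, brlen = 0, pi = 0, rho = 0)
  w[names(move_weights)] <- move_weights
  if (fix_brlen) w["brlen"] <- 0
  if (fix_model) w[c("pi", "rho")] <- 0
  if (sum(w) <= 0) stop("no moves enabled", call. = FALSE)

  start_rng <- rng_state(substream_seed(seed, "init"))
  rng_load(start_rng)
  if (is.null(tree)) {
    tree <- random_topology(aln$taxa, brlen = brlen_prior_mean)
  }
  if (!setequal(tree$labels, aln$taxa))
    stop("starting tree and alignment have different taxa", call. = FALSE)
  if (tree$s < 3L) w["topology"] <- 0   # a two-tip tree has one topology
  if (sum(w) <= 0) stop("no moves enabled", call. = FALSE)

  cp <- compress_patterns(aln)
  S <- cp$states[match(tree$labels, aln$taxa), , drop = FALSE]
  ctx <- list(S = S, w = cp$weights, weights = w[w > 0],
              nni = nni_choices(tree), lambda = multiplier_lambda,
              conc = dirichlet_conc, brlen_mean = brlen_prior_mean)

  betas <- chain_heat(seq_len(k_chains), heat_c)
  chains <- lapply(betas, function(b)
    new_chain_state(tree, model, vectors, groups, S, cp$weights, b,
                    brlen_prior_mean))
  chain_rng <- lapply(seq_len(k_chains), function(i)
    rng_state(substream_seed(seed, paste0("chain", i))))
  swap_rng <- rng_state(substream_seed(seed, "swap"))

  n_rec <- max(0L, (n_iter - burn_in) %/% thin)
  rec_iter <- integer(n_rec); rec_topo <- character(n_rec)
  rec_ll <- numeric(n_rec); rec_lp <- numeric(n_rec)
  rec_tree <- character(n_rec)
  rec_pi <- matrix(NA_real_, n_rec, 4L,
                   dimnames = list(NULL, .nuc_bases))
  rec_rho <- matrix(NA_real_, n_rec, 6L,
                    dimnames = list(NULL, .pair_names))
  acc <- att <- stats::setNames(numeric(length(ctx$weights)),
                                names(ctx$weights))
  swap_att <- swap_acc <- numeric(max(1L, k_chains - 1L))
  r <- 0L

  for (it in seq_len(n_iter)) {
    for (i in seq_len(k_chains)) {
      rng_load(chain_rng[[i]])
      chains[[i]] <- step_chain(chains[[i]], ctx)
      mv <- attr(chains[[i]], "move")
      att[mv] <- att[mv] + 1
      if (attr(chains[[i]], "accepted")) acc[mv] <- acc[mv] + 1
      chain_rng[[i]] <- rng_save()
    }
    if (k_chains >= 2L && it %% swap_interval == 0L) {
      rng_load(swap_rng)
      i <- sample.int(k_chains - 1L, 1L)
      j <- i + 1L
      lr <- swap_log_ratio(betas[i], betas[j],
                           chain_log_post(chains[[i]]),
                           chain_log_post(chains[[j]]))
      u <- stats::runif(1)
      swap_att[i] <- swap_att[i] + 1
      if (lr >= 0 || u < exp(lr)) {
        tmp <- chains[[i]]; chains[[i]] <- chains[[j]]; chains[[j]] <- tmp
        chains[[i]]$beta <- betas[i]; chains[[j]]$beta <- betas[j]
        swap_acc[i] <- swap_acc[i] + 1
      }
      swap_rng <- rng_save()
    }
    if (it > burn_in && (it - burn_in) %% thin == 0L && r < n_rec) {
      r <- r + 1L
      cold <- chains[[1L]]
      rec_iter[r] <- it
      rec_topo[r] <- canonical_topology(cold$tree)
      rec_ll[r] <- cold$log_lik
      rec_lp[r] <- cold$log_prior
      rec_tree[r] <- write_newick(cold$tree)
      rec_pi[r, ] <- as.numeric(cold$model$pi)
      rec_rho[r, ] <- as.numeric(cold$model$rho)
    }
  }
  structure(list(
    samples = data.frame(iteration = rec_iter[seq_len(r)],
                         topology = rec_topo[seq_len(r)],
                         log_lik = rec_ll[seq_len(r)],
                         log_prior = rec_lp[seq_len(r)],
                         log_post = (rec_ll + rec_lp)[seq_len(r)],
                         stringsAsFactors = FALSE),
    trees = rec_tree[seq_len(r)],
    pi = rec_pi[seq_len(r), , drop = FALSE],
    rho = rec_rho[seq_len(r), , drop = FALSE],
    acceptance = ifelse(att > 0, acc / att, NA_real_),
    swap = list(attempted = swap_att, accepted = swap_acc),
    betas = betas,
    settings = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                    k_chains = k_chains, heat_c = heat_c,
                    swap_interval = swap_interval, seed = seed,
                    move_weights = w, brlen_prior_mean = brlen_prior_mean)),
    class = "phylo_trace")
}

#' Single-chain Metropolis-Hastings-Green sampler
#'
#' The `k = 1` special case of [run_mcmcmc()] (no heating, no swaps).
#'
#' @inheritParams run_mcmcmc
#' @param ... Further arguments passed to [run_mcmcmc()].
#' @return A `phylo_trace`.
#' @export
run_chain <- function(aln, ..., seed = 1L)
  run_mcmcmc(aln, ..., k_chains = 1L, seed = seed)

#' Summarise a posterior tree sample
#'
#' Topology posterior frequencies, the majority-rule consensus with
#' per-split posterior support, and the maximum-a-posteriori topology with
#' its sample frequency.
#'
#' @param trace A `phylo_trace`.
#' @param threshold Consensus retention threshold.
#' @return List: `topologies` (data.frame of topology, count, prob),
#'   `consensus` (a [majority_consensus()] result), `map_topology`,
#'   `map_prob`, `n_samples`.
#' @export
summarize_posterior <- function(trace, threshold = 0.5) {
  stopifnot(inherits(trace, "phylo_trace"))
  if (!nrow(trace$samples)) stop("empty trace", call. = FALSE)
  tab <- sort(table(trace$samples$topology), decreasing = TRUE)
  topo <- data.frame(topology = names(tab), count = as.integer(tab),
                     prob = as.numeric(tab) / sum(tab),
                     stringsAsFactors = FALSE)
  trees <- lapply(topo$topology, parse_newick)
  cons <- majority_consensus(trees, weights = topo$count,
                             threshold = threshold)
  list(topologies = topo, consensus = cons,
       map_topology = topo$topology[1L], map_prob = topo$prob[1L],
       n_samples = sum(topo$count))
}

#' Exhaustive topology posterior for small trees
#'
#' Normalises \eqn{f(X|\tau_j) f(\tau_j)} over *all* `B(s)` topologies
#' (every branch length clamped to a common value, matching the
#' discrete-tree posterior), by enumeration and log-sum-exp.  Guarded to 5
#' taxa.  This is the exact reference the samplers are validated against.
#'
#' @param aln A [nucleotide_alignment()].
#' @param model A [gtr_model()].
#' @param branch_length The common clamped branch length.
#' @param rooted Enumerate rooted (default) or unrooted topologies.
#' @return data.frame with `topology` (canonical form), `log_lik`, `prob`
#'   (summing to 1).
#' @export
exhaustive_posterior <- function(aln, model, branch_length = 0.1,
                                 rooted = TRUE) {
  stopifnot(inherits(aln, "nucleotide_alignment"))
  if (aln$s > 5L)
    stop("exhaustive posterior is guarded to 5 taxa", call. = FALSE)
  topos <- enumerate_topologies(aln$taxa, rooted = rooted,
                                brlen = branch_length)
  asn <- composition_assignment(model$pi)
  ll <- vapply(topos, function(tr) log_likelihood(aln, tr, asn, model),
               numeric(1))
  lp <- ll - max(ll)
  prob <- exp(lp) / sum(exp(lp))   # uniform prior cancels
  data.frame(topology = vapply(topos, canonical_topology, character(1)),
             log_lik = ll, prob = prob, stringsAsFactors = FALSE)
}

#' Sampled posterior probability of one topology
#'
#' The fraction of cold-chain samples whose topology equals the given one;
#' by default compared as unrooted shapes (under a homogeneous reversible
#' model the data cannot place the root, so posterior mass spreads over
#' rootings of the same unrooted tree).
#'
#' @param x A `phylo_trace` or `phylo_mcmc` object.
#' @param tree A `phylo_tree`, newick string, or canonical topology string.
#' @param rooted Compare rooted topologies instead?
#' @return Posterior probability in `[0, 1]`.
#' @export
topology_posterior <- function(x, tree, rooted = FALSE) {
  trace <- if (inherits(x, "phylo_mcmc")) x$trace else x
  stopifnot(inherits(trace, "phylo_trace"))
  if (is.character(tree)) tree <- parse_newick(tree)
  topo <- trace$samples$topology
  if (rooted) return(mean(topo == canonical_topology(tree)))
  key <- unrooted_key(tree)
  uniq <- unique(topo)
  ukeys <- vapply(uniq, function(t) unrooted_key(parse_newick(t)),
                  character(1))
  mean(topo %in% uniq[ukeys == key])
}

#' Sampled posterior support of one bipartition
#'
#' The fraction of cold-chain samples whose topology contains the given
#' split — the posterior analogue of bootstrap branch support.
#'
#' @param x A `phylo_trace` or `phylo_mcmc` object.
#' @param split One side of the bipartition, as a character vector of tip
#'   labels.
#' @return Posterior support in `[0, 1]`.
#' @export
split_posterior <- function(x, split) {
  trace <- if (inherits(x, "phylo_mcmc")) x$trace else x
  stopifnot(inherits(trace, "phylo_trace"))
  topo <- trace$samples$topology
  uniq <- unique(topo)
  labels <- parse_newick(uniq[1L])$labels
  key <- split_key(split, labels)
  has <- vapply(uniq, function(t) key %in% split_set(parse_newick(t)),
                logical(1))
  mean(topo %in% uniq[has])
}

# total-variation distance between a sampled topology table and an
# exhaustive posterior (both keyed by canonical topology)
topology_tv <- function(sample_probs, exact) {
  keys <- union(names(sample_probs), exact$topology)
  p <- stats::setNames(rep(0, length(keys)), keys)
  q <- p
  p[names(sample_probs)] <- sample_probs
  q[exact$topology] <- exact$prob
  sum(abs(p - q)) / 2
}
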