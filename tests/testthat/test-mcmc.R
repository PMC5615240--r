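test_that("the heat ladder follows beta_i = 1/(1 + c(i-1))", {
  expect_equal(chain_heat(1, 0.7), 1)
  expect_equal(chain_heat(3, 0.5), 0.5)
  expect_equal(chain_heat(1:5, 0), rep(1, 5))
  betas <- chain_heat(1:6, 0.1)
  expect_true(all(diff(betas) < 0))
  expect_error(chain_heat(0, 0.1), ">= 1")
  expect_error(chain_heat(2, -1), ">= 0")
})

test_that("tempered density and swap ratio follow the closed forms", {
  expect_equal(heated_log_density(-10, 0.5), -5)
  expect_equal(heated_log_density(-3.2, 1), -3.2)
  # equal heats or equal states cancel exactly
  expect_equal(swap_log_ratio(0.7, 0.7, -12, -40), 0)
  expect_equal(swap_log_ratio(1, 0.5, -10, -10), 0)
  # worked example: beta (1, 0.5), ln f (-10, -8) -> ln R = 0.5 * 2 = 1
  lr <- swap_log_ratio(1, 0.5, -10, -8)
  expect_equal(lr, 1)
  expect_gte(exp(lr), 1)   # R >= 1: the exchange is certain
})

test_that("MHG acceptance is exact for certain moves and correct in frequency", {
  set.seed(1)
  # identity proposal and uphill moves are always accepted
  expect_true(mh_accept(-5, -5)$accept)
  expect_true(mh_accept(-5, -4)$accept)
  expect_false(mh_accept(-5, -Inf)$accept)
  expect_false(mh_accept(-5, NaN)$accept)

  # downhill by 1 at beta = 1: acceptance frequency -> e^{-1}
  set.seed(123)
  acc <- 0L
  for (i in 1:20000) acc <- acc + mh_accept(-5, -6)$accept
  expect_equal(acc / 20000, exp(-1), tolerance = 0.02)

  # heat tempers the posterior difference
  set.seed(5)
  acc <- 0L
  for (i in 1:20000) acc <- acc + mh_accept(-5, -7, beta = 0.5)$accept
  expect_equal(acc / 20000, exp(-1), tolerance = 0.02)
})

test_that("mh_accept leaves a two-state target invariant (detailed balance)", {
  # toy target p = (0.3, 0.7), symmetric flip proposal
  target <- log(c(0.3, 0.7))
  set.seed(77)
  state <- 1L
  visits <- c(0L, 0L)
  for (i in 1:1e6) {
    prop <- 3L - state
    if (mh_accept(target[state], target[prop])$accept) state <- prop
    visits[state] <- visits[state] + 1L
  }
  expect_equal(visits[1] / 1e6, 0.3, tolerance = 0.01)
})

test_that("the exhaustive posterior normalises and is flat on uninformative data", {
  m <- gtr_model()
  flat <- nucleotide_alignment(c(a = "AAAAA", b = "AAAAA", c = "AAAAA",
                                 d = "AAAAA"))
  exu <- exhaustive_posterior(flat, m, rooted = FALSE)
  expect_equal(sum(exu$prob), 1, tolerance = 1e-12)
  expect_equal(exu$prob, rep(1 / 3, 3), tolerance = 1e-12)
  # rooted: shape classes differ only marginally through the clamped lengths
  exr <- exhaustive_posterior(flat, m, rooted = TRUE)
  expect_equal(nrow(exr), 15L)
  expect_equal(exr$prob, rep(1 / 15, 15), tolerance = 1e-3)

  # strongly informative data puts the argmax on the generating topology
  fx <- informative_aln4(n_sites = 800L, seed = 13L)
  ex <- exhaustive_posterior(fx$aln, fx$model, rooted = FALSE)
  best <- parse_newick(ex$topology[which.max(ex$prob)])
  expect_true(same_topology(best, fx$tree))
  expect_error(exhaustive_posterior(
    nucleotide_alignment(stats::setNames(rep("ACGT", 6),
                                         paste0("t", 1:6))), m),
    "guarded")
})

test_that("a seeded run is bit-reproducible and records only cold samples", {
  fx <- informative_aln4(n_sites = 200L)
  a <- run_mcmcmc(fx$aln, model = fx$model, n_iter = 800, burn_in = 200,
                  thin = 5, k_chains = 2, seed = 99)
  b <- run_mcmcmc(fx$aln, model = fx$model, n_iter = 800, burn_in = 200,
                  thin = 5, k_chains = 2, seed = 99)
  expect_identical(a$samples, b$samples)
  expect_identical(a$trees, b$trees)
  expect_equal(nrow(a$samples), (800 - 200) / 5)
  expect_true(all(diff(a$samples$iteration) > 0))

  # cached log posterior stays consistent with the recorded state
  last <- nrow(a$samples)
  tr <- parse_newick(a$trees[last])
  m <- gtr_model(a$rho[last, ], a$pi[last, ])
  ll <- log_likelihood(fx$aln, tr, composition_assignment(m$pi), m)
  expect_equal(ll, a$samples$log_lik[last], tolerance = 1e-6)
})

test_that("swapping is live and the cold marginal does not depend on coupling", {
  fx <- informative_aln4(n_sites = 300L)
  mc3 <- run_mcmcmc(fx$aln, model = fx$model, n_iter = 6000, burn_in = 1500,
                    thin = 5, k_chains = 3, heat_c = 0.2, seed = 7,
                    fix_model = TRUE)
  expect_gt(sum(mc3$swap$accepted), 0)
  expect_equal(mc3$betas, chain_heat(1:3, 0.2))

  single <- run_chain(fx$aln, model = fx$model, n_iter = 6000,
                      burn_in = 1500, thin = 5, seed = 8, fix_model = TRUE)
  # under the homogeneous reversible model the data cannot place the root,
  # so the comparable cold-chain marginal is over unrooted shapes
  uprob <- function(trace) {
    tab <- summarize_posterior(trace)$topologies
    keys <- vapply(tab$topology, function(t)
      phylohet:::unrooted_key(parse_newick(t)), character(1))
    tapply(tab$prob, keys, sum)
  }
  v1 <- uprob(single); v3 <- uprob(mc3)
  keys <- union(names(v1), names(v3))
  a <- stats::setNames(rep(0, length(keys)), keys); a[names(v1)] <- v1
  b <- stats::setNames(rep(0, length(keys)), keys); b[names(v3)] <- v3
  expect_lt(sum(abs(a - b)) / 2, 0.1)
})

test_that("posterior summaries aggregate topologies and build a consensus", {
  fx <- informative_aln4(n_sites = 400L)
  tr <- run_chain(fx$aln, tree = fx$tree, model = fx$model, n_iter = 1000,
                  burn_in = 200, thin = 5, seed = 3,
                  move_weights = c(brlen = 1))   # topology held fixed
  sp <- summarize_posterior(tr)
  expect_equal(nrow(sp$topologies), 1L)
  expect_equal(sp$map_prob, 1)
  expect_true(same_topology(parse_newick(sp$map_topology), fx$tree,
                            rooted = TRUE))
  expect_equal(sum(sp$topologies$prob), 1)
  expect_error(summarize_posterior(structure(
    list(samples = data.frame()), class = "phylo_trace")), "empty")
})

test_that("acceptance rates are tracked per move kind within sane bounds", {
  fx <- informative_aln4(n_sites = 300L)
  tr <- run_chain(fx$aln, model = fx$model, n_iter = 3000, burn_in = 500,
                  seed = 21)
  expect_true(all(names(tr$acceptance) %in%
                    c("topology", "brlen", "pi", "rho")))
  # branch-length multiplier should be neither frozen nor free-wheeling
  expect_gt(tr$acceptance[["brlen"]], 0.05)
  expect_lt(tr$acceptance[["brlen"]], 0.95)
})
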