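# Shared fixtures: all data is generated in code, no files needed.

# random GTR model with moderately spread parameters
random_gtr <- function() {
  gtr_model(stats::runif(6, 0.3, 3), stats::runif(4, 0.2, 1))
}

# random rooted binary tree with uniform branch lengths via ape
rand_tree <- function(s, labels = paste0("t", seq_len(s)),
                      lmin = 0.05, lmax = 0.6) {
  phy <- ape::rtree(s, tip.label = labels, br = function(n)
    stats::runif(n, lmin, lmax))
  parse_newick(ape::write.tree(phy))
}

# a small informative alignment simulated on a known 4-taxon tree
informative_aln4 <- function(n_sites = 500L, seed = 42L) {
  tr <- parse_newick("((a:0.15,b:0.12):0.1,(c:0.1,d:0.14):0.1);")
  m <- gtr_model(c(1, 2, 1, 1, 2, 1), c(0.3, 0.2, 0.2, 0.3))
  sc <- simulation_scenario(tr, m, n_sites = n_sites, seed = seed)
  list(aln = simulate_alignment(sc), tree = tr, model = m)
}

write_tmp <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}
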