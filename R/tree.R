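# Rooted binary phylogenetic trees with the node-indexing convention used
# by the likelihood: tips 1..s (in taxon order), internal nodes s+1..2s-1
# with the root at 2s-1, a parent map, and branch lengths v_k on the branch
# above each non-root node.  Newick I/O is delegated to ape; the structure
# here exists because the pruning likelihood, the heterogeneous composition
# assignment and the MCMC moves all address nodes by this indexing.

new_phylo_tree <- function(parent, brlen, labels) {
  s <- length(labels)
  nn <- 2L * s - 1L
  stopifnot(length(parent) == nn, length(brlen) == nn)
  children <- matrix(NA_integer_, 2L, nn)
  slot <- rep(0L, nn)
  for (k in seq_len(nn)) {
    p <- parent[k]
    if (p > 0L) {
      slot[p] <- slot[p] + 1L
      if (slot[p] > 2L) stop("node has more than 2 children", call. = FALSE)
      children[slot[p], p] <- k
    }
  }
  tr <- structure(list(s = s, labels = labels, parent = as.integer(parent),
                       children = children, brlen = as.numeric(brlen)),
                  class = "phylo_tree")
  tr$postorder <- compute_postorder(tr)
  tr
}

# Internal nodes in postorder (children before parents, root last).
compute_postorder <- function(tree) {
  s <- tree$s
  out <- integer(s - 1L)
  pos <- 0L
  visit <- function(k) {
    if (k > s) {
      visit(tree$children[1L, k])
      visit(tree$children[2L, k])
      pos <<- pos + 1L
      out[pos] <<- k
    }
  }
  visit(2L * s - 1L)
  if (pos != s - 1L) stop("tree structure is not connected", call. = FALSE)
  out
}

refresh_postorder <- function(tree) {
  tree$postorder <- compute_postorder(tree)
  tree
}

#' @export
print.phylo_tree <- function(x, ...) {
  cat(sprintf("Rooted binary tree: %d tips, %d nodes\n", x$s, 2L * x$s - 1L))
  cat(" ", write_newick(x), "\n")
  invisible(x)
}

# Tip-index sets below every node (list over 1..2s-1).
descendant_tips <- function(tree) {
  nn <- 2L * tree$s - 1L
  out <- vector("list", nn)
  for (k in seq_len(tree$s)) out[[k]] <- k
  for (k in tree$postorder)
    out[[k]] <- sort(c(out[[tree$children[1L, k]]],
                       out[[tree$children[2L, k]]]))
  out
}

#' Parse a newick tree
#'
#' Reads a newick string into the package's rooted binary tree structure.
#' Binary rooted inputs are taken as-is; a trifurcating root is resolved
#' deterministically by rooting on the first child edge with a zero-length
#' stub.  Other polytomies are rejected.  Missing branch lengths default to
#' 0.1.
#'
#' @param text A newick string (must end in `;`).
#' @return A `phylo_tree`.
#' @examples
#' tr <- parse_newick("((a:1,b:2):0.5,c:3);")
#' @export
parse_newick <- function(text) {
  text <- trimws(text)
  depth <- 0L
  for (i in seq_len(nchar(text))) {
    ch <- substr(text, i, i)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("newick parse error: unbalanced ')' at character %d", i),
             call. = FALSE)
    }
  }
  if (depth != 0L)
    stop(sprintf("newick parse error: %d unclosed '(' at end of string", depth),
         call. = FALSE)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy))
    stop("newick parse error: malformed tree string", call. = FALSE)
  if (anyDuplicated(phy$tip.label))
    stop(sprintf("newick parse error: duplicate label '%s'",
                 phy$tip.label[duplicated(phy$tip.label)][1L]), call. = FALSE)
  s <- length(phy$tip.label)
  if (s < 2L) stop("a tree needs at least 2 tips", call. = FALSE)
  if (is.null(phy$edge) || any(phy$edge < 1L) ||
      any(phy$edge > s + phy$Nnode) || any(!nzchar(phy$tip.label)))
    stop("newick parse error: malformed tree string", call. = FALSE)
  # generic adjacency keyed by ape node ids
  n_ape <- s + phy$Nnode
  par <- rep(0L, n_ape)
  len <- rep(NA_real_, n_ape)
  for (r in seq_len(nrow(phy$edge))) {
    par[phy$edge[r, 2L]] <- phy$edge[r, 1L]
    len[phy$edge[r, 2L]] <- if (is.null(phy$edge.length)) NA_real_ else
      phy$edge.length[r]
  }
  len[is.na(len)] <- 0.1
  root_ape <- s + 1L
  # children in newick (edge-table) order, so "first child" is well defined
  childlist <- vector("list", n_ape)
  for (r in seq_len(nrow(phy$edge)))
    childlist[[phy$edge[r, 1L]]] <-
      c(childlist[[phy$edge[r, 1L]]], phy$edge[r, 2L])
  kids <- function(p) if (p > length(childlist)) integer(0) else
    childlist[[p]]
  nk <- vapply(seq_len(n_ape), function(k) length(kids(k)), integer(1))
  if (any(nk[seq_len(n_ape) != root_ape] > 2L) || nk[root_ape] > 3L)
    stop("newick parse error: polytomy (only a trifurcating root is accepted)",
         call. = FALSE)
  if (nk[root_ape] == 3L) {
    # root on the first child edge with a zero-length stub
    first <- kids(root_ape)[1L]
    newroot <- n_ape + 1L
    par <- c(par, 0L); len <- c(len, NA_real_)
    par[first] <- newroot
    par[root_ape] <- newroot
    len[root_ape] <- 0
    childlist[[root_ape]] <- setdiff(childlist[[root_ape]], first)
    childlist[[newroot]] <- c(first, root_ape)
    root_ape <- newroot
    n_ape <- n_ape + 1L
  }
  if (sum(par == root_ape) != 2L || n_ape != 2L * s - 1L)
    stop("newick parse error: tree is not binary", call. = FALSE)
  # map ape ids -> package ids: tips keep order, internals by postorder
  map <- integer(n_ape)
  map[seq_len(s)] <- seq_len(s)
  nxt <- s
  assign_post <- function(k) {
    for (c in kids(k)) assign_post(c)
    if (k > s) {  # internal (ape ids > s, as is the synthetic root)
      nxt <<- nxt + 1L
      map[k] <<- nxt
    }
  }
  assign_post(root_ape)
  parent2 <- integer(2L * s - 1L)
  brlen2 <- rep(NA_real_, 2L * s - 1L)
  for (k in seq_len(n_ape)) {
    if (map[k] == 0L) next
    parent2[map[k]] <- if (par[k] > 0L) map[par[k]] else 0L
    brlen2[map[k]] <- len[k]
  }
  brlen2[2L * s - 1L] <- NA_real_   # the root has no parent branch
  new_phylo_tree(parent2, brlen2, phy$tip.label)
}

#' Serialise a tree as newick
#'
#' Branch lengths are written with 12 significant digits so that a
#' parse/write round trip preserves them.
#'
#' @param tree A `phylo_tree`.
#' @param digits Significant digits for branch lengths.
#' @return A newick string ending in `;`.
#' @export
write_newick <- function(tree, digits = 12L) {
  stopifnot(inherits(tree, "phylo_tree"))
  fmt <- function(k) {
    base <- if (k <= tree$s) tree$labels[k] else
      paste0("(", fmt(tree$children[1L, k]), ",",
             fmt(tree$children[2L, k]), ")")
    if (tree$parent[k] > 0L)
      paste0(base, ":", sprintf("%.*g", digits, tree$brlen[k]))
    else base
  }
  paste0(fmt(2L * tree$s - 1L), ";")
}

# Convert to an ape "phylo" object (used for cross-checks and plotting).
as_ape_phylo <- function(tree) {
  ape::read.tree(text = write_newick(tree))
}

# Canonical rooted topology string: children ordered lexicographically.
canonical_topology <- function(tree) {
  fmt <- function(k) {
    if (k <= tree$s) return(tree$labels[k])
    a <- fmt(tree$children[1L, k]); b <- fmt(tree$children[2L, k])
    if (a <= b) paste0("(", a, ",", b, ")") else paste0("(", b, ",", a, ")")
  }
  paste0(fmt(2L * tree$s - 1L), ";")
}

# Canonical key of one split side (vector of labels): the side NOT
# containing the alphabetically first label, sorted and joined.
split_key <- function(side, all_labels) {
  ref <- min(all_labels)
  if (ref %in% side) side <- setdiff(all_labels, side)
  paste(sort(side), collapse = "|")
}

#' Non-trivial bipartitions of a tree's unrooted shape
#'
#' One canonical split per internal branch of the unrooted shape; the two
#' branches adjacent to the root induce the same split and are counted
#' once.  Trivial splits (singleton or complement-singleton sides) are
#' dropped.
#'
#' @param tree A `phylo_tree`.
#' @return Named list of character vectors (the canonical side of each
#'   split, the one not containing the alphabetically first taxon); names
#'   are `|`-joined keys.
#' @export
bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo_tree"))
  tips <- descendant_tips(tree)
  keys <- character(0)
  sides <- list()
  for (k in seq_len(2L * tree$s - 2L)) {
    side <- tree$labels[tips[[k]]]
    m <- length(side)
    if (m < 2L || m > tree$s - 2L) next
    key <- split_key(side, tree$labels)
    if (!(key %in% keys)) {
      keys <- c(keys, key)
      sides <- c(sides, list(sort(strsplit(key, "|", fixed = TRUE)[[1L]])))
    }
  }
  stats::setNames(sides, keys)
}

split_set <- function(tree) names(bipartitions(tree))

#' Compare two tree topologies
#'
#' Unrooted comparison (`rooted = FALSE`, default) tests equality of the
#' bipartition sets; rooted comparison additionally requires the same root
#' position.
#'
#' @param t1,t2 `phylo_tree` objects on the same taxon set.
#' @param rooted Compare as rooted trees?
#' @return Logical.
#' @export
same_topology <- function(t1, t2, rooted = FALSE) {
  stopifnot(inherits(t1, "phylo_tree"), inherits(t2, "phylo_tree"))
  if (!setequal(t1$labels, t2$labels))
    stop("trees have different taxon sets", call. = FALSE)
  if (rooted) return(canonical_topology(t1) == canonical_topology(t2))
  setequal(split_set(t1), split_set(t2))
}

#' Majority-rule consensus of a tree sample
#'
#' Retains exactly the splits present in more than `threshold` of the input
#' trees (strict inequality; a split at exactly the threshold is dropped)
#' and reports each retained split's occurrence fraction as its support.
#'
#' @param trees List of `phylo_tree` objects on a shared taxon set.
#' @param weights Optional numeric weights (e.g. sample counts per unique
#'   topology); default 1 each.
#' @param threshold Retention threshold, in `[0.5, 1]`.
#' @return Object of class `"consensus_tree"`: list with `newick` (support
#'   values as internal node labels), `support` (named vector over retained
#'   splits), `splits` (all observed splits with occurrence fractions) and
#'   `n_trees`.
#' @export
majority_consensus <- function(trees, weights = NULL, threshold = 0.5) {
  if (!length(trees)) stop("no trees supplied", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(trees))
  stopifnot(length(weights) == length(trees))
  labels <- sort(trees[[1L]]$labels)
  total <- sum(weights)
  counts <- new.env(parent = emptyenv())
  for (i in seq_along(trees)) {
    if (!setequal(trees[[i]]$labels, labels))
      stop("trees have different taxon sets", call. = FALSE)
    for (key in split_set(trees[[i]]))
      assign(key, (if (exists(key, counts)) get(key, counts) else 0) +
               weights[i], counts)
  }
  keys <- ls(counts)
  freq <- vapply(keys, function(k) get(k, counts) / total, numeric(1))
  keep <- freq > threshold
  retained <- freq[keep]
  # assemble the (possibly multifurcating) consensus newick, smallest
  # retained splits first so groups nest
  items <- stats::setNames(as.list(labels), labels)
  itemtips <- stats::setNames(lapply(labels, identity), labels)
  ord <- order(vapply(names(retained), function(k)
    length(strsplit(k, "|", fixed = TRUE)[[1L]]), integer(1)))
  for (key in names(retained)[ord]) {
    side <- strsplit(key, "|", fixed = TRUE)[[1L]]
    inside <- vapply(itemtips, function(tp) all(tp %in% side), logical(1))
    if (!any(inside)) next
    newick <- paste0("(", paste(unlist(items[inside]), collapse = ","), ")",
                     format(round(retained[[key]], 4)))
    newtips <- sort(unlist(itemtips[inside]))
    items <- c(items[!inside], list(newick))
    itemtips <- c(itemtips[!inside], list(newtips))
  }
  newick <- paste0("(", paste(unlist(items), collapse = ","), ");")
  structure(list(newick = newick, support = retained,
                 splits = sort(freq, decreasing = TRUE), n_trees = total,
                 threshold = threshold),
            class = "consensus_tree")
}

#' @export
print.consensus_tree <- function(x, ...) {
  cat(sprintf("Majority-rule consensus (> %.2f) of %g trees\n",
              x$threshold, x$n_trees))
  cat(" ", x$newick, "\n")
  if (length(x$support)) {
    cat("  retained splits:\n")
    for (k in names(x$support))
      cat(sprintf("    %-40s %.3f\n", k, x$support[[k]]))
  } else cat("  no splits above threshold (star consensus)\n")
  invisible(x)
}

# ---- topology enumeration -------------------------------------------------

# nested-list representation: a tip label (character) or list(left, right)
nested_to_newick <- function(x) {
  if (is.character(x)) x else
    paste0("(", nested_to_newick(x[[1L]]), ",", nested_to_newick(x[[2L]]), ")")
}

# all ways to attach `tip` onto a nested tree (on every node incl. root)
attach_everywhere <- function(tr, tip) {
  out <- list(list(tip, tr))
  if (is.list(tr)) {
    for (side in 1:2) {
      for (sub in attach_everywhere(tr[[side]], tip)) {
        cp <- tr
        cp[[side]] <- sub
        out <- c(out, list(cp))
      }
    }
  }
  out
}

#' Enumerate all tree topologies
#'
#' Generates every distinct rooted (or unrooted) binary topology on the
#' given taxa by recursive tip attachment.  Counts follow the double
#' factorials: `(2s-3)!!` rooted, `(2s-5)!!` unrooted.  Guarded to
#' `3 <= s <= 7`.
#'
#' @param taxa Character vector of tip labels.
#' @param rooted Enumerate rooted topologies?  Unrooted topologies are
#'   returned as rooted representatives (rooted on the first taxon's
#'   terminal branch).
#' @param brlen Branch length given to every branch of the returned trees.
#' @return List of `phylo_tree` objects.
#' @export
enumerate_topologies <- function(taxa, rooted = TRUE, brlen = 0.1) {
  s <- length(taxa)
  if (s < 3L || s > 7L)
    stop("topology enumeration is guarded to 3..7 taxa", call. = FALSE)
  enum_rooted <- function(labs) {
    trees <- list(list(labs[1L], labs[2L]))
    for (k in seq(3L, length(labs), length.out = max(0L, length(labs) - 2L))) {
      trees <- unlist(lapply(trees, attach_everywhere, tip = labs[k]),
                      recursive = FALSE)
    }
    trees
  }
  nested <- if (rooted) enum_rooted(taxa) else
    lapply(enum_rooted(taxa[-1L]), function(tr) list(taxa[1L], tr))
  lapply(nested, function(tr) {
    t0 <- parse_newick(paste0(nested_to_newick(tr), ";"))
    t0$brlen[-(2L * t0$s - 1L)] <- brlen
    t0
  })
}

# ---- NNI moves ------------------------------------------------------------

# exchange two subtrees (neither may be an ancestor of the other); branch
# lengths travel with their subtree
swap_subtrees <- function(tree, a, b) {
  pa <- tree$parent[a]; pb <- tree$parent[b]
  tree$children[tree$children[, pa] == a, pa] <- b
  tree$children[tree$children[, pb] == b, pb] <- a
  tree$parent[a] <- pb
  tree$parent[b] <- pa
  refresh_postorder(tree)
}

sibling_of <- function(tree, k) {
  p <- tree$parent[k]
  ch <- tree$children[, p]
  ch[ch != k]
}

# the rooted-NNI proposal used by the MCMC: swap child `j` of internal
# non-root node `k` with k's sibling
rooted_nni <- function(tree, k, j) {
  swap_subtrees(tree, tree$children[j, k], sibling_of(tree, k))
}

# all (k, j) choices eligible for rooted NNI
nni_choices <- function(tree) {
  ks <- setdiff(seq(tree$s + 1L, 2L * tree$s - 1L), 2L * tree$s - 1L)
  cbind(k = rep(ks, each = 2L), j = rep(1:2, length(ks)))
}

#' Nearest-neighbour-interchange alternatives across an internal branch
#'
#' For the internal branch of the unrooted shape identified by a
#' bipartition, returns the two topologies that differ from the input by
#' one NNI across that branch.
#'
#' @param tree A `phylo_tree`.
#' @param split One side of the bipartition: a character vector of tip
#'   labels, or a `|`-joined key as produced by [bipartitions()].
#' @return List of two `phylo_tree` objects.
#' @export
nni_neighbors <- function(tree, split) {
  stopifnot(inherits(tree, "phylo_tree"))
  if (is.character(split) && length(split) == 1L && grepl("|", split, fixed = TRUE))
    split <- strsplit(split, "|", fixed = TRUE)[[1L]]
  if (!all(split %in% tree$labels))
    stop("split contains labels not in the tree", call. = FALSE)
  m <- length(split)
  if (m < 2L || m > tree$s - 2L)
    stop("not an internal branch: the split is trivial", call. = FALSE)
  tips <- descendant_tips(tree)
  root <- 2L * tree$s - 1L
  target <- NA_integer_
  for (k in seq(tree$s + 1L, 2L * tree$s - 2L)) {
    side <- tree$labels[tips[[k]]]
    if (setequal(side, split) || setequal(side, setdiff(tree$labels, split))) {
      target <- k
      break
    }
  }
  if (is.na(target))
    stop("no internal branch matches the given bipartition", call. = FALSE)
  p <- tree$parent[target]
  if (p != root)
    return(list(rooted_nni(tree, target, 1L), rooted_nni(tree, target, 2L)))
  sib <- sibling_of(tree, target)
  if (sib <= tree$s)
    stop("not an internal branch of the unrooted shape", call. = FALSE)
  list(swap_subtrees(tree, tree$children[2L, target], tree$children[1L, sib]),
       swap_subtrees(tree, tree$children[2L, target], tree$children[2L, sib]))
}

# ---- random trees ---------------------------------------------------------

# random rooted binary topology by sequential random attachment
random_topology <- function(labels, brlen = 0.1) {
  s <- length(labels)
  stopifnot(s >= 2L)
  tr <- list(labels[1L], labels[2L])
  if (s > 2L) {
    for (k in 3L:s) {
      spots <- attach_everywhere(tr, labels[k])
      tr <- spots[[sample.int(length(spots), 1L)]]
    }
  }
  t0 <- parse_newick(paste0(nested_to_newick(tr), ";"))
  t0$brlen[-(2L * t0$s - 1L)] <- brlen
  t0
}

# ---- unrooted edge view and re-rooting ------------------------------------

# edges of the unrooted shape: the root is suppressed and its two child
# branches merged.  Node ids: tips 1..s keep theirs; internal non-root keep
# theirs.  Returns data.frame(u, v, length, node) where `node` is the
# package node whose parent branch the edge came from (NA for the merged
# root edge).
unrooted_edges <- function(tree) {
  root <- 2L * tree$s - 1L
  c1 <- tree$children[1L, root]; c2 <- tree$children[2L, root]
  ks <- setdiff(which(tree$parent > 0L), c(c1, c2))
  data.frame(u = c(tree$parent[ks], c1),
             v = c(ks, c2),
             length = c(tree$brlen[ks], tree$brlen[c1] + tree$brlen[c2]),
             node = c(ks, NA_integer_))
}

# re-root the unrooted shape on edge row `e`, splitting its length in two
root_on_edge <- function(tree, e, frac = 0.5) {
  ed <- unrooted_edges(tree)
  stopifnot(e >= 1L, e <= nrow(ed))
  s <- tree$s
  # adjacency with lengths
  adj <- vector("list", 2L * s - 2L)
  addedge <- function(u, v, len) {
    adj[[u]] <<- rbind(adj[[u]], c(v, len))
    adj[[v]] <<- rbind(adj[[v]], c(u, len))
  }
  for (r in seq_len(nrow(ed))) {
    if (r == e) next
    addedge(ed$u[r], ed$v[r], ed$length[r])
  }
  lu <- ed$length[e] * frac
  lv <- ed$length[e] * (1 - frac)
  build <- function(k, from, stub) {
    # newick of subtree at k entered from `from`, branch length `stub`
    nb <- adj[[k]]
    outs <- if (is.null(nb)) integer(0) else which(nb[, 1L] != from)
    if (k <= s && !length(outs))
      return(sprintf("%s:%.12g", tree$labels[k], stub))
    parts <- vapply(outs, function(i) build(nb[i, 1L], k, nb[i, 2L]),
                    character(1))
    sprintf("(%s):%.12g", paste(parts, collapse = ","), stub)
  }
  txt <- sprintf("(%s,%s);", build(ed$u[e], -1L, lu), build(ed$v[e], -1L, lv))
  parse_newick(txt)
}
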