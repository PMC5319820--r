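# Tanglegram simulator: a host tree grown under a Yule (uniform lineage
# splitting) process, a virus tree that starts as a tip-relabeled copy of the
# expanded host tree (pure co-divergence) and is then perturbed by a known
# number of host switches, each emulated as a subtree-prune-regraft move --
# the topological footprint of a transfer event. Because successive switches
# can partially cancel, the generator records the *realized* number of
# incongruent host clades alongside the switch log.

#' Simulate a host tree under a Yule process
#'
#' Grows a rooted binary tree by uniform random lineage splitting: starting
#' from two lineages, a uniformly chosen extant lineage bifurcates until `n`
#' tips exist. Only the topology is used downstream, so no branching times
#' are attached. Tips are labeled `h1..hn`.
#'
#' @param n number of tips (at least 2).
#' @param seed integer seed.
#' @return a rooted binary `phylo` with `n` tips.
#' @export
yule_tree <- function(n, seed = NULL) {
  if (!is.numeric(n) || n < 2) stop_codiverge("`n` must be at least 2")
  n <- as.integer(n)
  with_seed(seed, {
    kids <- vector("list", 2L * n - 1L)
    kids[[1L]] <- c(2L, 3L)                 # node 1 = root
    active <- c(2L, 3L)
    nxt <- 4L
    while (length(active) < n) {
      i <- active[sample.int(length(active), 1L)]
      kids[[i]] <- c(nxt, nxt + 1L)
      active <- c(setdiff(active, i), nxt, nxt + 1L)
      nxt <- nxt + 2L
    }
    tip_lab <- integer(0)
    build <- function(v) {
      if (is.null(kids[[v]])) {
        tip_lab <<- c(tip_lab, v)
        return(list(label = paste0("h", length(tip_lab)),
                    support = NA_real_, children = NULL))
      }
      list(label = NULL, support = NA_real_,
           children = lapply(kids[[v]], build))
    }
    clist_to_phylo(build(1L))
  })
}

# ---- SPR machinery on the recursive representation -------------------------

# Collect paths (integer child-index vectors from the root) to every non-root
# node; a path identifies the edge above that node.
node_paths <- function(cl) {
  out <- list()
  rec <- function(node, path) {
    if (length(path)) out[[length(out) + 1L]] <<- path
    if (!is_clist_leaf(node)) {
      for (i in seq_along(node$children)) rec(node$children[[i]], c(path, i))
    }
  }
  rec(cl, integer(0))
  out
}

clist_at <- function(cl, path) {
  for (i in path) cl <- cl$children[[i]]
  cl
}

clist_replace <- function(cl, path, value) {
  if (!length(path)) return(value)
  cl$children[[path[1L]]] <-
    clist_replace(cl$children[[path[1L]]], path[-1L], value)
  cl
}

# Remove the node at `path` from a binary clist, splicing its (now unary)
# parent out. Returns the remaining tree.
clist_prune <- function(cl, path) {
  parent_path <- path[-length(path)]
  parent <- clist_at(cl, parent_path)
  sibling <- parent$children[[setdiff(seq_along(parent$children),
                                      path[length(path)])]]
  clist_replace(cl, parent_path, sibling)
}

# One SPR move: prune a uniformly chosen non-root clade and regraft it onto a
# uniformly chosen edge of the remaining tree. Moves that leave the unrooted
# topology unchanged (possible when pruning next to the old attachment point)
# are rejected and redrawn.
spr_move <- function(phy, max_tries = 100L) {
  if (length(phy$tip.label) < 4L) {
    stop_codiverge("SPR needs at least 4 tips")
  }
  cl <- phylo_to_clist(phy)
  for (try in seq_len(max_tries)) {
    paths <- node_paths(cl)
    prune_path <- paths[[sample.int(length(paths), 1L)]]
    pruned <- clist_at(cl, prune_path)
    rest <- clist_prune(cl, prune_path)
    if (is_clist_leaf(rest)) next
    sites <- node_paths(rest)
    site <- sites[[sample.int(length(sites), 1L)]]
    at <- clist_at(rest, site)
    grafted <- clist_replace(rest, site, list(
      label = NULL, support = NA_real_, children = list(at, pruned)))
    cand <- clist_to_phylo(grafted)
    if (ph85(cand, phy) > 0) {
      return(list(tree = cand,
                  pruned_clade = sort(clist_tips(pruned)),
                  regraft_clade = sort(clist_tips(at))))
    }
  }
  stop_codiverge("could not find a topology-changing SPR move")
}

#' Derive a perturbed virus tree from a host tree
#'
#' Builds a virus tree that co-diverged perfectly with `host` -- a
#' tip-relabeled copy of the host tree expanded to one or more viruses per
#' host -- and then applies `n_switches` random subtree-prune-regraft moves,
#' each emulating one host jump. Every move is logged (pruned clade and
#' regraft position) and the realized number of incongruent host clades is
#' recorded, since later switches can partially undo earlier ones.
#'
#' @param host rooted binary host tree (`phylo`).
#' @param n_switches number of host-switch (SPR) perturbations.
#' @param viruses_per_host a single count, or a vector (recycled over host
#'   tips in tip-label order) giving how many viruses infect each host.
#' @param low_support_fraction fraction of virus internal nodes given weak
#'   support (below 0.8); see [assign_supports()]. 0 leaves supports off.
#' @param seed integer seed.
#' @return an object of class `simulated_pair`: `host`, `virus`, `assoc`,
#'   `switch_log` (list of moves), `n_incongruent`.
#' @export
derive_virus_tree <- function(host, n_switches = 0, viruses_per_host = 1,
                              low_support_fraction = 0, seed = NULL) {
  if (!is_binary_rooted(host)) stop_codiverge("`host` must be rooted binary")
  stopifnot(n_switches >= 0, low_support_fraction >= 0,
            low_support_fraction <= 1)
  htips <- host$tip.label
  m <- rep_len(as.integer(viruses_per_host), length(htips))
  if (any(m < 1L)) stop_codiverge("each host needs at least one virus")
  assoc <- association(
    virus = unlist(mapply(function(h, k) paste0(h, "_v", seq_len(k)),
                          htips, m, SIMPLIFY = FALSE), use.names = FALSE),
    host = rep(htips, m))
  seeds <- derive_seeds(seed, 3L)
  hx <- expand_host_tree(host, assoc)
  virus <- resolve_polytomies(hx, seeds[[1L]])
  switch_log <- list()
  if (n_switches > 0) {
    virus <- with_seed(seeds[[2L]], {
      v <- virus
      for (s in seq_len(n_switches)) {
        mv <- spr_move(v)
        v <- mv$tree
        switch_log[[s]] <- mv[c("pruned_clade", "regraft_clade")]
      }
      v
    })
  }
  if (low_support_fraction > 0) {
    virus <- assign_supports(virus, low_support_fraction, seeds[[3L]])
  }
  structure(list(host = host, virus = virus, assoc = assoc,
                 switch_log = switch_log,
                 n_incongruent = length(incongruent_host_clades(hx, virus))),
            class = "simulated_pair")
}

#' Simulate a virus-host tanglegram with known host switches
#'
#' Convenience wrapper: grows a Yule host tree ([yule_tree()]) and derives a
#' perturbed virus tree from it ([derive_virus_tree()]).
#'
#' @param n_hosts number of host tips (at least 3).
#' @inheritParams derive_virus_tree
#' @return a `simulated_pair`, see [derive_virus_tree()].
#' @examples
#' sim <- simulate_tanglegram(n_hosts = 10, n_switches = 2, seed = 1)
#' sim$n_incongruent
#' @export
simulate_tanglegram <- function(n_hosts, n_switches = 0, viruses_per_host = 1,
                                low_support_fraction = 0, seed = NULL) {
  if (n_hosts < 3) stop_codiverge("`n_hosts` must be at least 3")
  seeds <- derive_seeds(seed, 2L)
  host <- yule_tree(n_hosts, seeds[[1L]])
  derive_virus_tree(host, n_switches, viruses_per_host,
                    low_support_fraction, seeds[[2L]])
}

#' @export
print.simulated_pair <- function(x, ...) {
  cat("Simulated virus-host pair:", length(x$host$tip.label), "hosts,",
      length(x$virus$tip.label), "viruses,",
      length(x$switch_log), "host switch(es),",
      x$n_incongruent, "incongruent host clade(s)\n")
  invisible(x)
}

#' Assign branch supports to a tree
#'
#' Draws a support value for every internal node except the root: with
#' probability `low_support_fraction` from U\[0, 0.8) (weak, collapsible at
#' the conventional 0.8 cutoff), otherwise from U\[0.8, 1\]. Used to exercise
#' the collapse/resolve pipeline on simulated trees.
#'
#' @param phy a `phylo` object.
#' @param low_support_fraction probability of a weak support, in \[0, 1\].
#' @param seed integer seed.
#' @return `phy` with supports written as internal node labels.
#' @export
assign_supports <- function(phy, low_support_fraction, seed = NULL) {
  stopifnot(low_support_fraction >= 0, low_support_fraction <= 1)
  cl <- phylo_to_clist(phy)
  rec <- function(node, is_root) {
    if (is_clist_leaf(node)) return(node)
    if (!is_root) {
      node$support <- if (stats::runif(1) < low_support_fraction) {
        stats::runif(1, 0, 0.8 - 1e-9)
      } else {
        stats::runif(1, 0.8, 1)
      }
    }
    node$children <- lapply(node$children, rec, is_root = FALSE)
    node
  }
  clist_to_phylo(with_seed(seed, rec(cl, TRUE)))
}
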