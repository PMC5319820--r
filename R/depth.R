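# Where in the host tree does incongruence sit?  Node depth counts the
# internal nodes contained in a host clade (including the clade's own node);
# dividing by the largest such count over all nontrivial internal nodes gives
# a relative depth in (0, 1]: near 0 for host switches at the tips of the
# phylogeny, 1 when the deepest nontrivial clade is disrupted.

# Per-internal-node clade table of a rooted tree: tips of each clade and the
# number of internal nodes in its subtree (itself included). Root excluded.
host_clade_table <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  tips_of <- vector("list", ntip + nnode)
  idepth <- integer(ntip + nnode)
  rec <- function(v) {
    if (v <= ntip) {
      tips_of[[v]] <<- phy$tip.label[v]
      idepth[v] <<- 0L
      return(invisible())
    }
    ch <- kids[[as.character(v)]]
    for (u in ch) rec(u)
    tips_of[[v]] <<- unlist(tips_of[ch], use.names = FALSE)
    idepth[v] <<- 1L + sum(idepth[ch])
    invisible()
  }
  root <- ntip + 1L
  rec(root)
  nodes <- setdiff((ntip + 1L):(ntip + nnode), root)
  list(nodes = nodes, tips = tips_of[nodes], depth = idepth[nodes])
}

# Rooted-clade incompatibility: clades A and B conflict iff they are neither
# nested nor disjoint. This is the rooted analog of the four-intersection
# split test (equivalent to adding a virtual outgroup at the root), so
# polytomies behave exactly as in the distance module: a collapsed clade is
# compatible with all of its resolutions.
clades_conflict <- function(a, b) {
  i <- length(intersect(a, b))
  i > 0L && i < length(a) && i < length(b)
}

#' Host clades incongruent with the virus tree
#'
#' Identifies the nontrivial clades of the rooted host tree (root and leaves
#' excluded) that are incompatible with the rooted virus tree -- i.e. that
#' overlap some virus clade without either containing the other. Both trees
#' must be rooted over an identical tip set (expand the host tree first).
#'
#' @param host rooted host tree (`phylo`), tips matching the virus tree.
#' @param virus rooted virus tree (`phylo`).
#' @return a list of character vectors, the tip sets of incongruent clades.
#' @export
incongruent_host_clades <- function(host, virus) {
  assert_same_tips(host, virus)
  ht <- host_clade_table(host)
  vt <- host_clade_table(virus)
  vclades <- vt$tips
  keep <- vapply(ht$tips, function(cl) {
    any(vapply(vclades, clades_conflict, logical(1), a = cl))
  }, logical(1))
  ht$tips[keep]
}

#' Relative node depths of incongruent host clades
#'
#' For every incongruent host clade (see [incongruent_host_clades()]) the raw
#' node depth is the number of internal nodes within that clade's subtree,
#' counting the clade's own node; the relative depth divides by the largest
#' raw depth over all nontrivial internal host nodes, so it ranges in
#' (0, 1\]: 1 when the pair differs at the deepest node, approaching 0 when
#' only very shallow nodes (cherries) differ.
#'
#' @inheritParams incongruent_host_clades
#' @return a data frame of class `depth_result` with columns `clade`
#'   (comma-joined tip labels), `raw_depth` and `relative_depth`; zero rows
#'   when the trees agree.
#' @examples
#' h <- read_newick(text = "((((a,b),c),d),e);")
#' v <- read_newick(text = "((((a,c),b),d),e);")
#' relative_node_depths(h, v)
#' @export
relative_node_depths <- function(host, virus) {
  assert_same_tips(host, virus)
  ht <- host_clade_table(host)
  if (!length(ht$nodes)) {
    return(empty_depth_result())
  }
  max_depth <- max(ht$depth)
  vt <- host_clade_table(virus)
  keep <- vapply(ht$tips, function(cl) {
    any(vapply(vt$tips, clades_conflict, logical(1), a = cl))
  }, logical(1))
  if (!any(keep)) return(empty_depth_result())
  out <- data.frame(
    clade = vapply(ht$tips[keep], function(x) paste(sort(x), collapse = ","),
                   character(1)),
    raw_depth = ht$depth[keep],
    relative_depth = ht$depth[keep] / max_depth,
    stringsAsFactors = FALSE)
  out <- out[order(-out$raw_depth), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("depth_result", "data.frame")
  out
}

empty_depth_result <- function() {
  structure(data.frame(clade = character(0), raw_depth = integer(0),
                       relative_depth = numeric(0), stringsAsFactors = FALSE),
            class = c("depth_result", "data.frame"))
}
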