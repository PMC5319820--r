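# Topological distance between a virus tree and its host tree.
#
# PH85 here counts, on each side, the bipartitions (clades of the unrooted
# view) that are *incompatible* with the other tree, and sums the two counts.
# On a pair of binary trees this equals the classic symmetric-difference
# (Penny-Hendy) distance, because a binary tree's split set is maximal
# compatible: a split absent from the other binary tree necessarily conflicts
# with it. On polytomous trees the conflict reading is what makes an
# unresolved clade sit at distance zero from any of its resolutions.

# Membership matrix of nontrivial splits: logical, rows = splits, columns =
# sorted tip labels. Canonical row orientation excludes the first tip.
split_matrix <- function(phy, tips = NULL) {
  if (is.null(tips)) tips <- sort(phy$tip.label)
  n <- length(tips)
  pp <- ape::prop.part(phy)
  labs <- attr(pp, "labels")
  rows <- list()
  for (cl in pp) {
    memb <- tips %in% labs[cl]
    sz <- sum(memb)
    if (sz < 2L || sz > n - 2L) next          # trivial in the unrooted view
    if (memb[1L]) memb <- !memb               # canonical orientation
    rows[[length(rows) + 1L]] <- memb
  }
  if (!length(rows)) {
    m <- matrix(FALSE, 0L, n)
  } else {
    m <- unique(do.call(rbind, rows))
  }
  colnames(m) <- tips
  m
}

# Conflict (incompatibility) matrix between two split sets given as
# membership matrices over the same tip columns. Splits s1, s2 conflict iff
# all four side intersections are non-empty.
conflict_matrix <- function(m1, m2) {
  k1 <- nrow(m1); k2 <- nrow(m2)
  if (k1 == 0L || k2 == 0L) return(matrix(FALSE, k1, k2))
  n <- ncol(m1)
  inter <- m1 %*% t(m2)                       # |A  n  B|
  r1 <- rowSums(m1); r2 <- rowSums(m2)
  a <- inter
  b <- outer(r1, rep(1, k2)) - inter          # |A n Bc|
  c_ <- outer(rep(1, k1), r2) - inter         # |Ac n B|
  d <- n - outer(r1, rep(1, k2)) - outer(rep(1, k1), r2) + inter
  a > 0 & b > 0 & c_ > 0 & d > 0
}

ph85_from_matrices <- function(m1, m2) {
  cm <- conflict_matrix(m1, m2)
  sum(apply(cm, 1L, any)) + sum(apply(cm, 2L, any))
}

#' Nontrivial splits of a tree
#'
#' Returns the bipartitions of the unrooted view of `phy` induced by its
#' internal edges, excluding trivial splits (one side smaller than two tips).
#' Each split is reported canonically as its smaller side (ties broken toward
#' the side holding the alphabetically first tip); rootedness is ignored.
#'
#' @param phy a `phylo` object.
#' @return an object of class `split_set`: a list of character vectors (one
#'   canonical split side each) with attribute `tips`, the full tip set.
#' @examples
#' nontrivial_splits(read_newick(text = "(((a,b),c),d,e);"))
#' @export
nontrivial_splits <- function(phy) {
  tips <- sort(phy$tip.label)
  n <- length(tips)
  m <- split_matrix(phy, tips)
  out <- lapply(seq_len(nrow(m)), function(i) {
    side <- m[i, ]
    # canonical representative: the smaller side; on ties the side holding
    # the alphabetically first tip
    if (sum(side) > n / 2 || (2 * sum(side) == n && !side[1L])) side <- !side
    tips[side]
  })
  structure(out, tips = tips, class = "split_set")
}

#' @export
print.split_set <- function(x, ...) {
  cat(length(x), "nontrivial split(s) over", length(attr(x, "tips")), "tips\n")
  for (s in x) {
    cat("  ", paste(s, collapse = ","), "|",
        paste(setdiff(attr(x, "tips"), s), collapse = ","), "\n")
  }
  invisible(x)
}

#' Do two splits conflict?
#'
#' Two bipartitions of the same tip set are incompatible (cannot occur in one
#' tree) exactly when all four pairwise side intersections are non-empty.
#'
#' @param s1,s2 character vectors: one side of each bipartition.
#' @param tips the full tip set both splits partition.
#' @return `TRUE` if the splits are incompatible.
#' @export
splits_conflict <- function(s1, s2, tips) {
  if (!all(s1 %in% tips) || !all(s2 %in% tips)) {
    stop_codiverge("splits must be subsets of `tips`")
  }
  c1 <- setdiff(tips, s1); c2 <- setdiff(tips, s2)
  length(intersect(s1, s2)) > 0 && length(intersect(s1, c2)) > 0 &&
    length(intersect(c1, s2)) > 0 && length(intersect(c1, c2)) > 0
}

#' PH85 topological distance
#'
#' Counts the clades unique to each tree -- those incompatible with the other
#' tree's topology -- over the unrooted views, and returns the total (which
#' is twice the number of unique clades when the conflicts pair up, as they
#' always do for binary trees). Symmetric in its arguments; branch lengths
#' and rootedness are ignored. The distance between a polytomous clade and
#' any of its full resolutions is zero.
#'
#' @param t1,t2 `phylo` objects over an identical tip set.
#' @return a non-negative integer count.
#' @examples
#' a <- read_newick(text = "((a,b),(c,d));")
#' b <- read_newick(text = "((a,c),(b,d));")
#' ph85(a, b)
#' @export
ph85 <- function(t1, t2) {
  assert_same_tips(t1, t2)
  tips <- sort(t1$tip.label)
  ph85_from_matrices(split_matrix(t1, tips), split_matrix(t2, tips))
}

#' Randomized maximum PH85 distance
#'
#' Estimates the maximum attainable PH85 for a pair of topologies by
#' shuffling the tip labels of the second tree `n_randomizations` times and
#' recording the largest PH85 seen; the observed (unshuffled) distance is
#' included alongside the replicates, so a normalized distance never exceeds
#' 1. One thousand randomizations is robust even for large trees; the running
#' maximum typically stabilizes within far fewer replicates.
#'
#' @param t1,t2 `phylo` objects over an identical tip set.
#' @param n_randomizations number of tip shuffles (default 1000).
#' @param seed integer seed for the shuffles.
#' @param trace if `TRUE`, attach the running maximum per replicate as
#'   attribute `"trace"` (useful to check convergence of the null maximum).
#' @return integer maximum PH85, optionally with a `"trace"` attribute.
#' @export
randomized_max_ph85 <- function(t1, t2, n_randomizations = 1000, seed = NULL,
                                trace = FALSE) {
  assert_same_tips(t1, t2)
  stopifnot(n_randomizations >= 1)
  tips <- sort(t1$tip.label)
  m1 <- split_matrix(t1, tips)
  m2 <- split_matrix(t2, tips)
  observed <- ph85_from_matrices(m1, m2)
  vals <- with_seed(seed, {
    vapply(seq_len(n_randomizations), function(i) {
      perm <- sample.int(ncol(m2))
      ph85_from_matrices(m1, m2[, perm, drop = FALSE])
    }, numeric(1))
  })
  out <- as.integer(max(observed, vals))
  if (trace) attr(out, "trace") <- as.integer(cummax(vals))
  out
}

#' Normalized PH85 distance (nPH85)
#'
#' The PH85 distance divided by its randomization-derived maximum. nPH85
#' ranges between 0, for identical topologies (strong evidence for
#' co-divergence), and 1, for trees with no clades in common (co-divergence
#' implausible), and is comparable between data sets of different size. It
#' does not depend on *where* in the tree the mismatched clades sit. When the
#' numerator is zero, or no nontrivial conflict is attainable (denominator
#' zero, e.g. two star trees), the distance is 0 -- the co-divergent extreme.
#'
#' @inheritParams randomized_max_ph85
#' @return a number in \[0, 1\].
#' @export
nph85 <- function(t1, t2, n_randomizations = 1000, seed = NULL) {
  obs <- ph85(t1, t2)
  if (obs == 0) return(0)
  den <- randomized_max_ph85(t1, t2, n_randomizations, seed)
  if (den == 0) return(0)
  obs / den
}

#' nPH85 with support collapsing and resolution uncertainty
#'
#' The full distance pipeline for a virus-host pair: the host tree is
#' expanded to the virus tip set ([expand_host_tree()]); virus nodes with
#' support below `support_threshold` are collapsed into polytomies
#' ([collapse_low_support()]); the *overall* nPH85 is computed directly on
#' the (possibly polytomous) pair; then all polytomies in both trees are
#' randomly resolved `n_resolutions` times and nPH85 recomputed on each
#' binary replicate, summarized as the mean and equal-tail 95% percentile
#' range. The same randomization stream is used for the null maximum in
#' every replicate so that replicate variation reflects topology resolution
#' only.
#'
#' @param host host tree (`phylo`), a cladogram, possibly polytomous.
#' @param virus virus tree (`phylo`) with optional internal-node supports.
#' @param assoc association data frame mapping virus tips to host tips.
#' @param support_threshold collapse supports strictly below this (default 0.8).
#' @param n_resolutions number of random polytomy resolutions (default 100).
#' @param n_randomizations tip shuffles for the null maximum (default 1000).
#' @param seed integer seed governing all randomness.
#' @return a list of class `nph85_summary`: `ph85`, `denominator`, `overall`,
#'   `mean`, `percentile_low`, `percentile_high`, and the per-resolution
#'   `values`.
#' @export
nph85_summary <- function(host, virus, assoc,
                          support_threshold = 0.8,
                          n_resolutions = 100,
                          n_randomizations = 1000,
                          seed = NULL) {
  stopifnot(n_resolutions >= 1)
  validate_association(assoc, virus_tree = virus, host_tree = host)
  hx <- expand_host_tree(host, assoc)
  vc <- collapse_low_support(virus, support_threshold)
  assert_same_tips(hx, vc)

  obs <- ph85(hx, vc)
  den <- randomized_max_ph85(hx, vc, n_randomizations, seed)
  overall <- if (obs == 0 || den == 0) 0 else obs / den

  if (is_binary_rooted(hx) && is_binary_rooted(vc)) {
    vals <- rep(overall, n_resolutions)
  } else {
    seeds <- derive_seeds(seed, 2L * n_resolutions)
    vals <- vapply(seq_len(n_resolutions), function(r) {
      hr <- resolve_polytomies(hx, seeds[[2L * r - 1L]])
      vr <- resolve_polytomies(vc, seeds[[2L * r]])
      nph85(hr, vr, n_randomizations, seed)
    }, numeric(1))
  }
  q <- stats::quantile(vals, c(0.025, 0.975), names = FALSE)
  structure(list(ph85 = obs, denominator = den, overall = overall,
                 mean = mean(vals), percentile_low = q[1],
                 percentile_high = q[2], values = vals),
            class = "nph85_summary")
}

#' @export
print.nph85_summary <- function(x, digits = 2, ...) {
  cat("nPH85 distance summary\n")
  cat("  PH85:", x$ph85, " randomized max:", x$denominator, "\n")
  cat("  overall nPH85:", format(round(x$overall, digits), nsmall = digits), "\n")
  cat("  mean over resolutions:", format(round(x$mean, digits), nsmall = digits),
      " 95% percentile range: [",
      format(round(x$percentile_low, digits), nsmall = digits), ", ",
      format(round(x$percentile_high, digits), nsmall = digits), "]\n", sep = "")
  invisible(x)
}
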