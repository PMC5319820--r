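#' Quantify co-divergence between a virus tree and its host tree
#'
#' The end-to-end analysis for one virus family. The host cladogram is
#' expanded so that its tips match the virus tips one-for-one (several
#' viruses per host become within-host polytomies); poorly supported virus
#' nodes are collapsed; then three complementary views of the tanglegram are
#' computed:
#'
#' * **distance** -- the overall nPH85 topological distance, its PH85
#'   numerator and randomized-maximum denominator, and the mean and 95%
#'   percentile range over random resolutions of all polytomies
#'   ([nph85_summary()]). 0 means identical topologies (co-divergence),
#'   1 means no shared clades (pervasive host jumping).
#' * **depths** -- the relative node depth of every incongruent host clade
#'   ([relative_node_depths()]): whether host switching concentrates near
#'   the tips (values near 0) or reaches the root (values near 1).
#' * **reconciliation** -- a minimum-cost event history (co-divergence,
#'   duplication, host jump, extinction) on seeded random resolutions of the
#'   two trees ([reconcile()]), with event proportions.
#'
#' A crossing-minimized tanglegram layout ([untangle()]) is kept for
#' plotting.
#'
#' @param host host tree: a `phylo`, or a path/Newick string accepted by
#'   [read_newick()]. A cladogram, possibly with polytomies.
#' @param virus virus tree, same forms accepted; internal-node labels in
#'   \[0, 1\] are read as supports.
#' @param assoc association data frame ([association()]) or path to a TSV
#'   read by [read_association()].
#' @param support_threshold collapse virus nodes with support strictly below
#'   this (default 0.8, the conventional aLRT cutoff).
#' @param n_resolutions random polytomy resolutions for the uncertainty
#'   summary (default 100).
#' @param n_randomizations tip shuffles for the nPH85 denominator
#'   (default 1000).
#' @param costs event costs for the reconciliation ([event_costs()]).
#' @param reconciliation compute the event reconciliation? Set `FALSE` to
#'   skip (it is the slow part on large trees).
#' @param seed integer seed governing all randomness.
#' @return an object of class `codivergence` with components `distance`,
#'   `depths`, `reconciliation` (or `NULL`), `layout`, the input trees and
#'   association, and the configuration used.
#' @examples
#' sim <- simulate_tanglegram(n_hosts = 8, n_switches = 2, seed = 42)
#' fit <- codivergence(sim$host, sim$virus, sim$assoc,
#'                     n_randomizations = 200, seed = 1)
#' fit
#' summary(fit)
#' @export
codivergence <- function(host, virus, assoc,
                         support_threshold = 0.8,
                         n_resolutions = 100,
                         n_randomizations = 1000,
                         costs = event_costs(),
                         reconciliation = TRUE,
                         seed = NULL) {
  cl <- match.call()
  host <- as_tree(host)
  virus <- as_tree(virus)
  if (is.character(assoc)) assoc <- read_association(assoc)
  validate_association(assoc, virus_tree = virus, host_tree = host)

  dist <- nph85_summary(host, virus, assoc,
                        support_threshold = support_threshold,
                        n_resolutions = n_resolutions,
                        n_randomizations = n_randomizations,
                        seed = seed)
  hx <- expand_host_tree(host, assoc)
  vc <- collapse_low_support(virus, support_threshold)
  depths <- relative_node_depths(hx, vc)

  rec <- NULL
  if (isTRUE(reconciliation)) {
    seeds <- derive_seeds(seed, 2L)
    hr <- resolve_polytomies(host, seeds[[1L]])
    vr <- resolve_polytomies(vc, seeds[[2L]])
    rec <- reconcile(hr, vr, assoc, costs)
  }
  layout <- untangle(host, virus, assoc)

  structure(list(call = cl, host = host, virus = virus, assoc = assoc,
                 distance = dist, depths = depths, reconciliation = rec,
                 layout = layout,
                 config = list(support_threshold = support_threshold,
                               n_resolutions = n_resolutions,
                               n_randomizations = n_randomizations,
                               costs = costs, seed = seed)),
            class = "codivergence")
}

# accept a phylo, a file path, or a Newick string
as_tree <- function(x) {
  if (inherits(x, "phylo")) return(validate_tree(x))
  if (is.character(x) && length(x) == 1L) {
    if (file.exists(x)) return(read_newick(file = x))
    return(read_newick(text = x))
  }
  stop_codiverge("expected a `phylo`, a file path, or a Newick string")
}

#' @export
print.codivergence <- function(x, digits = 2, ...) {
  d <- x$distance
  cat("Virus-host co-divergence analysis\n")
  cat("  ", length(x$host$tip.label), " hosts, ",
      length(x$virus$tip.label), " viruses\n", sep = "")
  cat(sprintf("  overall nPH85 = %.*f (PH85 = %d / randomized max = %d)\n",
              digits, d$overall, d$ph85, d$denominator))
  cat(sprintf("  resolution uncertainty: mean = %.*f, 95%% range [%.*f, %.*f]\n",
              digits, d$mean, digits, d$percentile_low, digits,
              d$percentile_high))
  cat("  incongruent host clades:", nrow(x$depths), "\n")
  if (!is.null(x$reconciliation)) {
    p <- x$reconciliation$proportions
    cat(sprintf("  reconciliation: cost %g; host-jump proportion %.2f\n",
                x$reconciliation$cost, p[["host_jump"]]))
  }
  invisible(x)
}

#' @export
summary.codivergence <- function(object, ...) {
  structure(list(fit = object), class = "summary.codivergence")
}

#' @export
print.summary.codivergence <- function(x, ...) {
  f <- x$fit
  print(f)
  if (nrow(f$depths)) {
    cat("\nRelative node depths of incongruent host clades:\n")
    print.data.frame(utils::head(as.data.frame(f$depths), 20), row.names = FALSE)
    if (nrow(f$depths) > 20) cat("  ...", nrow(f$depths) - 20, "more\n")
  }
  if (!is.null(f$reconciliation)) {
    cat("\n")
    print(f$reconciliation)
  }
  cat("\nTanglegram:", f$layout$crossings, "crossing(s) after untangling",
      sprintf("(initial %d)\n", f$layout$initial_crossings))
  invisible(x)
}

#' Plot a co-divergence analysis as a tanglegram
#'
#' @param x a `codivergence` fit.
#' @param ... passed to [plot.tanglegram_layout()].
#' @export
plot.codivergence <- function(x, ...) {
  plot(x$layout, ...)
  invisible(x)
}
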