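# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds it, evaluates `code`, and restores the
#' previous state, so seeded operations do not perturb the global RNG stream.
#' A `NULL` seed evaluates `code` under the current stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive k reproducible child seeds from one seed (all < 2^31).
derive_seeds <- function(seed, k) {
  if (is.null(seed)) return(rep(list(NULL), k))
  as.list(with_seed(seed, sample.int(.Machine$integer.max - 1L, k)))
}

stop_codiverge <- function(...) stop(..., call. = FALSE)

# ---- recursive ("clist") tree representation -------------------------------
# A node is list(label = chr | NULL, support = num | NA, children = list()|NULL).
# Used for topology surgery (collapse / resolve / expand / growth); branch
# lengths are deliberately not carried: every downstream statistic is
# topology-only.

is_clist_leaf <- function(node) is.null(node$children)

# Parse an internal-node label as a support value: numeric within [0, 1],
# otherwise treated as absent (NA).
parse_support <- function(lab) {
  if (is.null(lab) || is.na(lab) || !nzchar(lab)) return(NA_real_)
  x <- suppressWarnings(as.numeric(lab))
  if (is.na(x) || x < 0 || x > 1) NA_real_ else x
}

phylo_to_clist <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  ntip <- length(phy$tip.label)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  nl <- phy$node.label
  build <- function(v) {
    if (v <= ntip) {
      return(list(label = phy$tip.label[v], support = NA_real_, children = NULL))
    }
    sup <- if (!is.null(nl)) parse_support(nl[v - ntip]) else NA_real_
    list(label = NULL, support = sup,
         children = lapply(kids[[as.character(v)]], build))
  }
  build(ntip + 1L)
}

quote_label <- function(lab) {
  if (grepl("[][ ():;,']", lab)) {
    paste0("'", gsub("'", "''", lab), "'")
  } else lab
}

clist_to_newick <- function(node) {
  rec <- function(nd) {
    if (is_clist_leaf(nd)) return(quote_label(nd$label))
    inner <- paste(vapply(nd$children, rec, character(1)), collapse = ",")
    sup <- if (!is.na(nd$support)) format(nd$support, digits = 15) else ""
    paste0("(", inner, ")", sup)
  }
  paste0(rec(node), ";")
}

clist_to_phylo <- function(node) {
  ape::read.tree(text = clist_to_newick(node))
}

clist_tips <- function(node) {
  if (is_clist_leaf(node)) return(node$label)
  unlist(lapply(node$children, clist_tips), use.names = FALSE)
}

# Internal-node supports of a phylo, parsed from node labels.
node_supports <- function(phy) {
  ntip <- length(phy$tip.label)
  nn <- phy$Nnode
  if (is.null(phy$node.label)) return(rep(NA_real_, nn))
  vapply(phy$node.label, parse_support, numeric(1), USE.NAMES = FALSE)
}

assert_same_tips <- function(t1, t2) {
  a <- sort(t1$tip.label); b <- sort(t2$tip.label)
  if (!identical(a, b)) {
    only1 <- setdiff(a, b); only2 <- setdiff(b, a)
    stop_codiverge(
      "trees must share an identical tip set; ",
      if (length(only1)) paste0("only in first: ", paste(only1, collapse = ", "), "; ") else "",
      if (length(only2)) paste0("only in second: ", paste(only2, collapse = ", ")) else "")
  }
  invisible(TRUE)
}
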