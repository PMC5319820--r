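#' Read a phylogenetic tree from Newick
#'
#' Thin wrapper around [ape::read.tree()] that validates the input before and
#' after parsing: parentheses must balance (the error names the offending
#' character position), tip labels must be unique and non-empty, and every
#' internal node must have at least two children. Internal-node labels that
#' parse as numbers in \[0, 1\] are interpreted downstream as branch support
#' (e.g. aLRT values); anything else is treated as an unsupported node.
#' Branch lengths are parsed but ignored by all topology statistics.
#'
#' @param file path to a Newick file (one tree). Exactly one of `file`/`text`.
#' @param text a Newick string.
#' @return an object of class `phylo`.
#' @examples
#' tr <- read_newick(text = "((a,b)0.95,c,d);")
#' tree_supports(tr)
#' @seealso [tree_supports()], [collapse_low_support()]
#' @export
read_newick <- function(file = NULL, text = NULL) {
  if (is.null(text) == is.null(file)) {
    stop_codiverge("supply exactly one of `file` or `text`")
  }
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  check_newick_syntax(text)
  phy <- ape::read.tree(text = text)
  if (is.null(phy)) stop_codiverge("could not parse Newick string")
  validate_tree(phy)
  phy
}

# Pre-parse scan so malformed input fails with a character position rather
# than an opaque parser error.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  quoted <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") quoted <- !quoted
    if (quoted) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop_codiverge("malformed Newick: unmatched ')' at character ", i)
      }
    }
  }
  if (depth > 0L) {
    stop_codiverge("malformed Newick: ", depth,
                   " unclosed '(' at end of string (position ", nchar(text), ")")
  }
  if (!grepl(";", text, fixed = TRUE)) {
    stop_codiverge("malformed Newick: missing terminating ';' (position ",
                   nchar(text), ")")
  }
  invisible(TRUE)
}

validate_tree <- function(phy) {
  tips <- phy$tip.label
  if (any(!nzchar(tips))) stop_codiverge("empty tip labels are not allowed")
  dup <- unique(tips[duplicated(tips)])
  if (length(dup)) {
    stop_codiverge("duplicate tip labels: ", paste(dup, collapse = ", "))
  }
  deg <- tabulate(phy$edge[, 1], nbins = length(tips) + phy$Nnode)
  internal <- deg[(length(tips) + 1L):(length(tips) + phy$Nnode)]
  # a one-tip tree is allowed as the degenerate host of a within-host clade
  if (any(internal < 2L) && length(tips) > 1L) {
    stop_codiverge("internal nodes must have at least two children")
  }
  invisible(phy)
}

#' Write a tree to Newick
#'
#' @param phy a `phylo` object.
#' @param file optional path; when `NULL` the Newick string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(phy, file = NULL) {
  s <- ape::write.tree(phy)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Internal-node support values of a tree
#'
#' Supports are read from internal-node labels: labels that parse as a number
#' in \[0, 1\] (the aLRT convention, 0 = no support, 1 = strong support) are
#' returned, all others come back as `NA` and are never collapsed.
#'
#' @param phy a `phylo` object.
#' @return numeric vector, one entry per internal node in `phylo` node order.
#' @export
tree_supports <- function(phy) node_supports(phy)

#' Virus-host association table
#'
#' Builds the many-to-one map from virus tips to host tips. Several viruses
#' may map to one host (virus families routinely sample multiple viruses from
#' a single host species); every virus must map to exactly one host.
#'
#' @param virus,host character vectors of equal length.
#' @return a data frame with columns `virus` and `host`.
#' @export
association <- function(virus, host) {
  virus <- as.character(virus); host <- as.character(host)
  if (length(virus) != length(host)) {
    stop_codiverge("`virus` and `host` must have equal length")
  }
  if (anyDuplicated(virus)) {
    stop_codiverge("each virus may appear only once: ",
                   paste(unique(virus[duplicated(virus)]), collapse = ", "))
  }
  data.frame(virus = virus, host = host, stringsAsFactors = FALSE)
}

#' Read a virus-host association table
#'
#' Expects a two-column tab-separated file with header `virus<TAB>host`.
#'
#' @param file path to the TSV file.
#' @return a data frame with columns `virus` and `host`.
#' @export
read_association <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("virus", "host") %in% names(df))) {
    stop_codiverge("association table needs columns `virus` and `host`; found: ",
                   paste(names(df), collapse = ", "))
  }
  association(df$virus, df$host)
}

#' Write an association table
#' @param assoc association data frame.
#' @param file output path.
#' @export
write_association <- function(assoc, file) {
  utils::write.table(assoc[, c("virus", "host")], file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

validate_association <- function(assoc, virus_tree = NULL, host_tree = NULL) {
  if (!is.null(virus_tree)) {
    missing_v <- setdiff(virus_tree$tip.label, assoc$virus)
    if (length(missing_v)) {
      stop_codiverge("virus tips without a host mapping: ",
                     paste(missing_v, collapse = ", "))
    }
  }
  if (!is.null(host_tree)) {
    bad <- setdiff(assoc$host, host_tree$tip.label)
    if (length(bad)) {
      stop_codiverge("associations point at hosts absent from the host tree: ",
                     paste(unique(bad), collapse = ", "))
    }
  }
  invisible(assoc)
}

#' Expand a host tree to the virus tip set
#'
#' Virus data sets usually contain more taxa than their hosts because several
#' viruses can infect the same host species. To compare topologies tip-for-tip
#' the host tree is expanded: a host tip carrying m mapped viruses becomes a
#' polytomy of m tips labeled by those viruses (a single virus is a relabeling
#' in place), so the returned tip set equals the virus tip set exactly. Host
#' tips with no mapped virus are pruned. Adding these within-host polytomies
#' does not affect the nPH85 distance, because an unresolved clade is at zero
#' distance from any of its resolutions.
#'
#' @param host host tree (`phylo`), possibly polytomous.
#' @param assoc association data frame (see [association()]).
#' @return a `phylo` whose tips are the virus labels.
#' @examples
#' h <- read_newick(text = "(h1,h2);")
#' a <- association(c("v1", "v2", "v3"), c("h1", "h1", "h2"))
#' write_newick(expand_host_tree(h, a))
#' @export
expand_host_tree <- function(host, assoc) {
  validate_association(assoc, host_tree = host)
  used <- unique(assoc$host)
  drop <- setdiff(host$tip.label, used)
  if (length(drop)) {
    if (length(used) < 2L) {
      stop_codiverge("fewer than two host tips carry viruses; cannot expand")
    }
    host <- ape::drop.tip(host, drop, collapse.singles = TRUE)
  }
  by_host <- split(assoc$virus, assoc$host)
  cl <- phylo_to_clist(host)
  expand <- function(node) {
    if (is_clist_leaf(node)) {
      vir <- by_host[[node$label]]
      if (length(vir) == 1L) {
        node$label <- vir
        return(node)
      }
      return(list(label = NULL, support = NA_real_,
                  children = lapply(vir, function(v) {
                    list(label = v, support = NA_real_, children = NULL)
                  })))
    }
    node$children <- lapply(node$children, expand)
    node
  }
  clist_to_phylo(expand(cl))
}

#' Collapse poorly supported nodes into polytomies
#'
#' Contracts every internal edge whose child node carries a support value
#' strictly below `threshold`, promoting its children into the parent. The
#' default 0.8 is the conventional aLRT cutoff corresponding to a
#' false-positive rate below 0.1. Nodes without a parseable support value in
#' \[0, 1\] are never collapsed (host cladograms taken from the literature
#' carry no supports and must pass through unchanged), so the function is a
#' no-op on unsupported trees.
#'
#' @param phy a `phylo` object.
#' @param threshold support cutoff in \[0, 1\]; strictly smaller values are
#'   collapsed.
#' @return a `phylo`, possibly with polytomies.
#' @examples
#' tr <- read_newick(text = "(((a,b)0.79,c)0.95,d,e);")
#' write_newick(collapse_low_support(tr, 0.8))
#' @export
collapse_low_support <- function(phy, threshold = 0.8) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  cl <- phylo_to_clist(phy)
  rec <- function(node) {
    if (is_clist_leaf(node)) return(node)
    out <- list()
    for (child in node$children) {
      child <- rec(child)
      if (!is_clist_leaf(child) && !is.na(child$support) &&
          child$support < threshold) {
        out <- c(out, child$children)   # promote grandchildren
      } else {
        out <- c(out, list(child))
      }
    }
    node$children <- out
    node
  }
  clist_to_phylo(rec(cl))
}

#' Randomly resolve polytomies into a binary tree
#'
#' Each polytomy is resolved by iterative uniform pairing: while a node has
#' more than two children, a uniformly chosen pair is merged under a new
#' unsupported node. Every binary refinement is reachable with positive
#' probability and the input's clades are all preserved. Deterministic for a
#' given seed.
#'
#' @param phy a `phylo` object.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return a binary `phylo` refining `phy`.
#' @export
resolve_polytomies <- function(phy, seed = NULL) {
  cl <- phylo_to_clist(phy)
  rec <- function(node) {
    if (is_clist_leaf(node)) return(node)
    node$children <- lapply(node$children, rec)
    while (length(node$children) > 2L) {
      pick <- sample.int(length(node$children), 2L)
      merged <- list(label = NULL, support = NA_real_,
                     children = node$children[pick])
      node$children <- c(node$children[-pick], list(merged))
    }
    node
  }
  clist_to_phylo(with_seed(seed, rec(cl)))
}

# TRUE when every internal node of the rooted tree has exactly two children
# (a one-tip tree counts as binary).
is_binary_rooted <- function(phy) {
  if (length(phy$tip.label) == 1L) return(TRUE)
  deg <- tabulate(phy$edge[, 1], nbins = length(phy$tip.label) + phy$Nnode)
  all(deg[deg > 0L] == 2L)
}
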