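# Tanglegram layout and comparative statistics. A tanglegram draws the host
# tree on the left and the virus tree on the right with a line per virus
# connecting it to its host; congruent topologies admit layouts with few or
# no crossing lines, so minimizing crossings by rotating internal nodes
# ("untangling") makes co-divergence visually apparent.

#' Count crossing association lines in a tanglegram layout
#'
#' Given the tip orders of the two trees, each virus contributes one line
#' from its host's position to its own; two lines cross exactly when their
#' endpoints are ordered oppositely on the two sides. Counted as the number
#' of inversions of the induced sequence (merge sort), so large layouts stay
#' cheap. Lines sharing a host endpoint (several viruses in one host) never
#' cross each other at the shared end.
#'
#' @param host_order character vector: host tips, top to bottom.
#' @param virus_order character vector: virus tips, top to bottom.
#' @param assoc association data frame mapping each virus to a host.
#' @return non-negative integer crossing count.
#' @export
count_crossings <- function(host_order, virus_order, assoc) {
  if (anyDuplicated(host_order) || anyDuplicated(virus_order)) {
    stop_codiverge("leaf orders must be permutations (no duplicates)")
  }
  hp <- match(assoc$host, host_order)
  vp <- match(assoc$virus, virus_order)
  if (anyNA(hp) || anyNA(vp)) {
    stop_codiverge("leaf orders must cover every associated tip")
  }
  if (length(setdiff(virus_order, assoc$virus))) {
    stop_codiverge("virus tips without association: ",
                   paste(setdiff(virus_order, assoc$virus), collapse = ", "))
  }
  ord <- order(hp, vp)
  count_inversions(vp[ord])
}

# merge-sort inversion count
count_inversions <- function(x) {
  rec <- function(v) {
    n <- length(v)
    if (n < 2L) return(list(v = v, inv = 0))
    mid <- n %/% 2L
    a <- rec(v[seq_len(mid)]); b <- rec(v[(mid + 1L):n])
    va <- a$v; vb <- b$v
    out <- numeric(n); i <- 1L; j <- 1L; inv <- a$inv + b$inv
    for (k in seq_len(n)) {
      if (i <= length(va) && (j > length(vb) || va[i] <= vb[j])) {
        out[k] <- va[i]; i <- i + 1L
      } else {
        out[k] <- vb[j]; j <- j + 1L
        inv <- inv + (length(va) - i + 1L)
      }
    }
    list(v = out, inv = inv)
  }
  rec(x)$inv
}

#' Untangle a tanglegram by rotating internal nodes
#'
#' Hill-climbing crossing minimization: internal nodes of the virus and host
#' trees are visited in alternating passes; at each node the children are
#' reordered by the barycenter (mean partner position on the other side) and
#' the rotation is kept only if it reduces the crossing count. Iterates until
#' no single rotation improves, so the returned layout never has more
#' crossings than the input orders. Deterministic; a heuristic, not an exact
#' minimizer.
#'
#' @param host host tree (`phylo`).
#' @param virus virus tree (`phylo`).
#' @param assoc association data frame.
#' @return an object of class `tanglegram_layout`: rotated `host`/`virus`
#'   trees, `host_order`, `virus_order`, `assoc`, `crossings`, and
#'   `initial_crossings`.
#' @export
untangle <- function(host, virus, assoc) {
  validate_association(assoc, virus_tree = virus, host_tree = host)
  hcl <- phylo_to_clist(host)
  vcl <- phylo_to_clist(virus)
  cross <- function(h, v) {
    count_crossings(clist_tips(h), clist_tips(v), assoc)
  }
  best <- cross(hcl, vcl)
  repeat {
    improved <- FALSE
    for (side in c("virus", "host")) {
      active <- if (side == "virus") vcl else hcl
      other_order <- if (side == "virus") clist_tips(hcl) else clist_tips(vcl)
      partner_pos <- partner_positions(side, other_order, assoc)
      paths <- c(list(integer(0)), node_paths(active))
      for (path in paths) {
        node <- clist_at(active, path)
        if (is_clist_leaf(node) || length(node$children) < 2L) next
        bary <- vapply(node$children, function(ch) {
          p <- partner_pos[clist_tips(ch)]
          if (all(is.na(p))) Inf else mean(p, na.rm = TRUE)
        }, numeric(1))
        ord <- order(bary)
        if (identical(ord, seq_along(ord))) next
        node$children <- node$children[ord]
        cand <- clist_replace(active, path, node)
        new_cross <- if (side == "virus") cross(hcl, cand) else cross(cand, vcl)
        if (new_cross < best) {
          best <- new_cross
          if (side == "virus") vcl <- cand else hcl <- cand
          active <- cand
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  structure(list(host = clist_to_phylo(hcl), virus = clist_to_phylo(vcl),
                 host_order = clist_tips(hcl), virus_order = clist_tips(vcl),
                 assoc = assoc, crossings = best,
                 initial_crossings = count_crossings(
                   phylo_to_clist(host) |> clist_tips(),
                   phylo_to_clist(virus) |> clist_tips(), assoc)),
            class = "tanglegram_layout")
}

# position of each tip's partner(s) on the other side, as a named vector of
# mean positions
partner_positions <- function(side, other_order, assoc) {
  pos <- seq_along(other_order)
  names(pos) <- other_order
  if (side == "virus") {
    out <- pos[assoc$host]
    names(out) <- assoc$virus
  } else {
    out <- tapply(pos[assoc$virus], assoc$host, mean)
  }
  out
}

#' @export
print.tanglegram_layout <- function(x, ...) {
  cat("Tanglegram layout:", length(x$host_order), "hosts,",
      length(x$virus_order), "viruses;",
      x$crossings, "crossing(s) (initial", paste0(x$initial_crossings, ")"),
      "\n")
  invisible(x)
}

#' Draw a tanglegram
#'
#' Plots the host tree (left) facing the virus tree (right) as cladograms
#' with a line per virus connecting it to its host. Supply an untangled
#' layout to reduce crossings first.
#'
#' @param x a `tanglegram_layout` (from [untangle()]).
#' @param line_col line color, one value or one per association row.
#' @param tip_cex tip label size; 0 suppresses labels.
#' @param ... ignored.
#' @return the layout, invisibly.
#' @export
plot.tanglegram_layout <- function(x, line_col = "grey40", tip_cex = 0.6,
                                   ...) {
  hc <- tree_plot_coords(phylo_to_clist(x$host))
  vc <- tree_plot_coords(phylo_to_clist(x$virus))
  nh <- length(x$host_order); nv <- length(x$virus_order)
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 1), ylim = c(0, 1))
  draw_cladogram(hc, x0 = 0, x1 = 0.40, n = nh)
  draw_cladogram(vc, x0 = 1, x1 = 0.60, n = nv)
  hy <- stats::setNames(hc$tip_y / max(nh - 1, 1), x$host_order)
  vy <- stats::setNames(vc$tip_y / max(nv - 1, 1), x$virus_order)
  graphics::segments(0.40, hy[x$assoc$host], 0.60, vy[x$assoc$virus],
                     col = line_col)
  if (tip_cex > 0) {
    graphics::text(0.40, hy, x$host_order, pos = 4, cex = tip_cex, offset = 0.15)
    graphics::text(0.60, vy, x$virus_order, pos = 2, cex = tip_cex, offset = 0.15)
  }
  invisible(x)
}

# node coordinates for a cladogram: tip y = 0..(n-1) in clist order, internal
# y = mean of children, x = depth fraction toward the tips; tip branches are
# extended to the margin (leaf flag = NA depth)
tree_plot_coords <- function(cl) {
  segs <- list()
  tip_y <- numeric(0)
  ycount <- 0
  rec <- function(node, depth) {
    if (is_clist_leaf(node)) {
      y <- ycount; ycount <<- ycount + 1
      tip_y <<- c(tip_y, y)
      return(list(y = y, leaf = TRUE))
    }
    ch <- lapply(node$children, rec, depth = depth + 1)
    ys <- vapply(ch, `[[`, numeric(1), "y")
    y <- mean(ys)
    for (i in seq_along(ch)) {
      segs[[length(segs) + 1L]] <<- c(depth, y, ch[[i]]$y,
                                      if (ch[[i]]$leaf) NA else depth + 1)
    }
    list(y = y, leaf = FALSE)
  }
  rec(cl, 0)
  depths <- vapply(segs, function(s) s[4], numeric(1))
  list(segs = segs, tip_y = tip_y,
       max_depth = max(c(depths[!is.na(depths)], 1)) + 1)
}

draw_cladogram <- function(coords, x0, x1, n) {
  sy <- function(y) y / max(n - 1, 1)
  sx <- function(d) x0 + (x1 - x0) * d / coords$max_depth
  for (s in coords$segs) {
    xc <- if (is.na(s[4])) x1 else sx(s[4])
    graphics::segments(sx(s[1]), sy(s[2]), sx(s[1]), sy(s[3]))
    graphics::segments(sx(s[1]), sy(s[3]), xc, sy(s[3]))
  }
}

#' Family-level comparison of co-divergence signal
#'
#' Given one record per virus family -- its nPH85 distance, the number of
#' viruses sampled, and the genome type -- computes (i) Pearson's correlation
#' between nPH85 and the number of viruses (more densely sampled families
#' are expected to reveal more host jumps) and (ii) a Welch two-sample t test
#' of nPH85 between DNA and RNA families (RNA viruses are expected to sit
#' closer to the host-jumping extreme).
#'
#' @param records data frame with columns `family`, `nph85`, `n_viruses`,
#'   `genome_type` (values `"DNA"`/`"RNA"`).
#' @return an object of class `family_comparison`: `correlation` (estimate,
#'   p.value, n), `ttest` (statistic, p.value, group means), and `flags`
#'   naming any statistic omitted for degenerate variance.
#' @export
family_comparison <- function(records) {
  need <- c("family", "nph85", "n_viruses", "genome_type")
  if (!all(need %in% names(records))) {
    stop_codiverge("`records` needs columns: ", paste(need, collapse = ", "))
  }
  if (any(records$nph85 < 0 | records$nph85 > 1)) {
    stop_codiverge("nph85 values must lie in [0, 1]")
  }
  flags <- character(0)
  correlation <- NULL
  if (nrow(records) >= 3 && stats::sd(records$nph85) > 0 &&
      stats::sd(records$n_viruses) > 0) {
    ct <- stats::cor.test(records$n_viruses, records$nph85,
                          method = "pearson")
    correlation <- list(estimate = unname(ct$estimate),
                        p.value = ct$p.value, n = nrow(records))
  } else {
    flags <- c(flags, "correlation: fewer than 3 records or zero variance")
  }
  ttest <- NULL
  g <- split(records$nph85, records$genome_type)
  if (all(c("DNA", "RNA") %in% names(g))) {
    means <- vapply(g[c("DNA", "RNA")], mean, numeric(1))
    if (stats::sd(c(g$DNA, g$RNA)) > 0 &&
        min(length(g$DNA), length(g$RNA)) >= 2) {
      tt <- stats::t.test(g$DNA, g$RNA, var.equal = FALSE)
      ttest <- list(statistic = unname(tt$statistic), p.value = tt$p.value,
                    mean_dna = means[["DNA"]], mean_rna = means[["RNA"]])
    } else {
      flags <- c(flags, "t-test: degenerate variance or group too small")
      ttest <- list(statistic = NA_real_, p.value = NA_real_,
                    mean_dna = means[["DNA"]], mean_rna = means[["RNA"]])
    }
  } else {
    flags <- c(flags, "t-test: need both DNA and RNA families")
  }
  structure(list(correlation = correlation, ttest = ttest, flags = flags),
            class = "family_comparison")
}

#' @export
print.family_comparison <- function(x, ...) {
  cat("Family-level comparison\n")
  if (!is.null(x$correlation)) {
    cat(sprintf("  nPH85 vs number of viruses: Pearson r = %.2f (p = %.3g, n = %d)\n",
                x$correlation$estimate, x$correlation$p.value,
                x$correlation$n))
  }
  if (!is.null(x$ttest)) {
    cat(sprintf("  DNA mean nPH85 = %.2f, RNA mean nPH85 = %.2f",
                x$ttest$mean_dna, x$ttest$mean_rna))
    if (!is.na(x$ttest$statistic)) {
      cat(sprintf(" (Welch t = %.2f, p = %.3g)", x$ttest$statistic,
                  x$ttest$p.value))
    }
    cat("\n")
  }
  for (f in x$flags) cat("  note:", f, "\n")
  invisible(x)
}
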