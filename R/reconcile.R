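# Event-cost reconciliation of a virus tree with its host tree under the
# untimed duplication-transfer-loss model: each internal virus node is
# explained as a co-divergence (cospeciation), a within-host duplication, or
# a host jump (transfer of one child lineage to a host lineage neither
# ancestral nor descendant), with extinction (loss) charged per host edge a
# virus lineage passes without diversifying. Dynamic programming over
# (virus node x host node) gives the global cost optimum in polynomial time;
# co-optimal event-count vectors are recovered by exhaustive backtracking.

#' Event costs for reconciliation
#'
#' The default cost vector (0 for co-divergence, 1 each for duplication,
#' host jump and extinction) is deliberately conservative toward
#' co-divergence: any incongruence-generating event is penalized equally
#' while co-divergence is free.
#'
#' @param codivergence,duplication,host_jump,extinction non-negative costs.
#' @return a named numeric vector of class `event_costs`.
#' @export
event_costs <- function(codivergence = 0, duplication = 1,
                        host_jump = 1, extinction = 1) {
  x <- c(codivergence = codivergence, duplication = duplication,
         host_jump = host_jump, extinction = extinction)
  if (any(!is.finite(x)) || any(x < 0)) {
    stop_codiverge("event costs must be finite and non-negative")
  }
  structure(x, class = c("event_costs", class(x)))
}

# Structural tables for a rooted tree: children lists, postorder, ancestry
# (ancestor-or-equal) and comparability matrices, clade label per node.
tree_tables <- function(phy) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  kids <- vector("list", nn)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]; ch <- phy$edge[i, 2]
    kids[[p]] <- c(kids[[p]], ch)
  }
  root <- ntip + 1L
  post <- integer(0)
  tips_of <- vector("list", nn)
  rec <- function(v) {
    if (v > ntip) for (u in kids[[v]]) rec(u)
    tips_of[[v]] <<- if (v <= ntip) phy$tip.label[v] else
      unlist(tips_of[kids[[v]]], use.names = FALSE)
    post <<- c(post, v)
    invisible()
  }
  rec(root)
  # ancestor-or-equal matrix by postorder accumulation of descendant sets
  anc <- matrix(FALSE, nn, nn)
  for (v in post) {
    anc[v, v] <- TRUE
    if (v > ntip) for (u in kids[[v]]) anc[v, ] <- anc[v, ] | anc[u, ]
  }
  comp <- anc | t(anc)
  list(ntip = ntip, nn = nn, root = root, kids = kids, post = post,
       tips_of = tips_of, anc = anc, comp = comp,
       label = vapply(tips_of, function(x) paste(sort(x), collapse = ","),
                      character(1)))
}

INF <- 1e18

# Fill the DP tables. Returns everything backtracking needs.
dtl_tables <- function(host, virus, assoc, costs) {
  H <- tree_tables(host)
  V <- tree_tables(virus)
  cs <- unname(costs["codivergence"]); cd <- unname(costs["duplication"])
  ct <- unname(costs["host_jump"]);    cl <- unname(costs["extinction"])
  map <- match(assoc$host[match(virus$tip.label, assoc$virus)], host$tip.label)
  cmat <- matrix(INF, V$nn, H$nn)
  inm  <- matrix(INF, V$nn, H$nn)
  incomp <- lapply(seq_len(H$nn), function(h) which(!H$comp[h, ]))
  for (p in V$post) {
    if (p <= V$ntip) {
      cmat[p, ] <- INF
      cmat[p, map[p]] <- 0
    } else {
      qs <- V$kids[[p]]
      q1 <- qs[1]; q2 <- qs[2]
      out1 <- vapply(incomp, function(idx)
        if (length(idx)) min(cmat[q1, idx]) else INF, numeric(1))
      out2 <- vapply(incomp, function(idx)
        if (length(idx)) min(cmat[q2, idx]) else INF, numeric(1))
      for (h in seq_len(H$nn)) {
        best <- cd + inm[q1, h] + inm[q2, h]
        if (h > H$ntip && length(H$kids[[h]]) == 2L) {
          hc <- H$kids[[h]]
          spec <- cs + min(inm[q1, hc[1]] + inm[q2, hc[2]],
                           inm[q1, hc[2]] + inm[q2, hc[1]])
          if (spec < best) best <- spec
        }
        tr <- ct + min(inm[q1, h] + out2[h], inm[q2, h] + out1[h])
        if (tr < best) best <- tr
        cmat[p, h] <- best
      }
    }
    for (h in H$post) {
      v <- cmat[p, h]
      if (h > H$ntip) {
        for (hc in H$kids[[h]]) {
          w <- inm[p, hc] + cl
          if (w < v) v <- w
        }
      }
      inm[p, h] <- v
    }
  }
  list(H = H, V = V, cmat = cmat, inm = inm, map = map,
       costs = c(cs = cs, cd = cd, ct = ct, cl = cl), incomp = incomp)
}

#' Reconcile a virus tree with its host tree
#'
#' Finds a minimum-cost reconciliation under the duplication-transfer-loss
#' event model: every internal virus node is assigned a host node and an
#' event -- co-divergence, duplication, or host jump -- with extinctions
#' charged for host lineages traversed without diversification. Both trees
#' must be rooted and fully binary (resolve polytomies first, see
#' [resolve_polytomies()]); the association may be many-to-one. Among equal
#' cost options at a node, co-divergence is preferred, then duplication, then
#' host jump; use [enumerate_optima()] to see all co-optimal event counts.
#'
#' @param host rooted binary host tree (`phylo`).
#' @param virus rooted binary virus tree (`phylo`).
#' @param assoc association data frame mapping every virus tip to a host tip.
#' @param costs an [event_costs()] vector.
#' @return an object of class `reconciliation`: `cost`, `counts` (named:
#'   codivergence, duplication, host_jump, extinction), `proportions`, and
#'   `events`, a data frame placing each virus clade on a host clade with its
#'   event label.
#' @examples
#' h <- read_newick(text = "((h1,h2),h3);")
#' v <- read_newick(text = "((v1,v3),v2);")
#' a <- association(c("v1", "v2", "v3"), c("h1", "h2", "h3"))
#' reconcile(h, v, a)
#' @export
reconcile <- function(host, virus, assoc, costs = event_costs()) {
  check_reconcile_inputs(host, virus, assoc)
  dp <- dtl_tables(host, virus, assoc, costs)
  h_opt <- which.min(dp$cmat[dp$V$root, ])
  total <- dp$cmat[dp$V$root, h_opt]
  bt <- backtrack_one(dp, dp$V$root, h_opt)
  counts <- bt$counts
  props <- if (sum(counts) > 0) counts / sum(counts) else counts
  structure(list(cost = total, counts = counts,
                 proportions = props, events = bt$events),
            class = "reconciliation")
}

check_reconcile_inputs <- function(host, virus, assoc) {
  if (!is_binary_rooted(host) || !is_binary_rooted(virus)) {
    stop_codiverge("reconciliation requires rooted binary trees; ",
                   "resolve polytomies first (see resolve_polytomies())")
  }
  validate_association(assoc, virus_tree = virus, host_tree = host)
  invisible(TRUE)
}

# Deterministic backtrack of a single optimum; ties resolved toward
# co-divergence, then duplication, then host jump.
backtrack_one <- function(dp, p0, h0) {
  eps <- 1e-9
  counts <- c(codivergence = 0L, duplication = 0L,
              host_jump = 0L, extinction = 0L)
  ev <- list()
  H <- dp$H; V <- dp$V
  note <- function(p, h, event) {
    ev[[length(ev) + 1L]] <<- data.frame(
      virus_clade = V$label[p], host_clade = H$label[h],
      event = event, stringsAsFactors = FALSE)
  }
  bt_in <- function(p, h) {
    repeat {
      if (dp$inm[p, h] >= dp$cmat[p, h] - eps) break
      moved <- FALSE
      if (h > H$ntip) {
        for (hc in H$kids[[h]]) {
          if (abs(dp$inm[p, hc] + dp$costs["cl"] - dp$inm[p, h]) < eps) {
            counts["extinction"] <<- counts["extinction"] + 1L
            h <- hc; moved <- TRUE; break
          }
        }
      }
      if (!moved) break
    }
    bt_c(p, h)
  }
  bt_c <- function(p, h) {
    if (p <= V$ntip) { note(p, h, "tip"); return(invisible()) }
    qs <- V$kids[[p]]; q1 <- qs[1]; q2 <- qs[2]
    target <- dp$cmat[p, h]
    if (h > H$ntip && length(H$kids[[h]]) == 2L) {
      hc <- H$kids[[h]]
      for (ord in list(c(1, 2), c(2, 1))) {
        if (abs(dp$costs["cs"] + dp$inm[q1, hc[ord[1]]] +
                dp$inm[q2, hc[ord[2]]] - target) < eps) {
          counts["codivergence"] <<- counts["codivergence"] + 1L
          note(p, h, "codivergence")
          bt_in(q1, hc[ord[1]]); bt_in(q2, hc[ord[2]])
          return(invisible())
        }
      }
    }
    if (abs(dp$costs["cd"] + dp$inm[q1, h] + dp$inm[q2, h] - target) < eps) {
      counts["duplication"] <<- counts["duplication"] + 1L
      note(p, h, "duplication")
      bt_in(q1, h); bt_in(q2, h)
      return(invisible())
    }
    idx <- dp$incomp[[h]]
    for (sw in list(c(q1, q2), c(q2, q1))) {
      stay <- sw[1]; jump <- sw[2]
      rest <- target - dp$costs["ct"] - dp$inm[stay, h]
      if (length(idx)) {
        kbest <- idx[which(abs(dp$cmat[jump, idx] - rest) < eps)]
        if (length(kbest)) {
          counts["host_jump"] <<- counts["host_jump"] + 1L
          note(p, h, "host_jump")
          bt_in(stay, h); bt_c(jump, kbest[1])
          return(invisible())
        }
      }
    }
    stop_codiverge("internal error: backtracking found no consistent event")
  }
  bt_c(p0, h0)
  list(counts = counts, events = do.call(rbind, ev))
}

#' Enumerate event counts of all minimum-cost reconciliations
#'
#' Backtracks every co-optimal solution of the reconciliation DP and returns
#' the distinct event-count vectors, together with the per-event minimum and
#' maximum across optima (the range boxplots of event proportions are drawn
#' from these). Ties are all retained rather than broken arbitrarily.
#'
#' @inheritParams reconcile
#' @param limit maximum number of distinct count vectors retained per DP
#'   state; when exceeded the result carries `truncated = TRUE`.
#' @return a list of class `reconciliation_set`: `cost`, `counts` (matrix,
#'   one row per distinct optimum), `ranges` (min/max per event type), and
#'   `truncated`.
#' @export
enumerate_optima <- function(host, virus, assoc, costs = event_costs(),
                             limit = 10000) {
  check_reconcile_inputs(host, virus, assoc)
  dp <- dtl_tables(host, virus, assoc, costs)
  eps <- 1e-9
  H <- dp$H; V <- dp$V
  truncated <- FALSE
  memo <- new.env(parent = emptyenv())
  clip <- function(m) {
    m <- unique(m)
    if (nrow(m) > limit) { truncated <<- TRUE; m <- m[seq_len(limit), , drop = FALSE] }
    m
  }
  cross_add <- function(a, b) {
    if (nrow(a) == 0L || nrow(b) == 0L) return(matrix(0L, 0L, 4L))
    out <- a[rep(seq_len(nrow(a)), each = nrow(b)), , drop = FALSE] +
      b[rep(seq_len(nrow(b)), times = nrow(a)), , drop = FALSE]
    clip(out)
  }
  unit <- function(i) { v <- matrix(0L, 1L, 4L); v[1L, i] <- 1L; v }
  enum_c <- function(p, h) {
    key <- paste0("c", p, ".", h)
    if (!is.null(memo[[key]])) return(memo[[key]])
    target <- dp$cmat[p, h]
    if (target >= INF) return(memo[[key]] <- matrix(0L, 0L, 4L))
    if (p <= V$ntip) return(memo[[key]] <- matrix(0L, 1L, 4L))
    qs <- V$kids[[p]]; q1 <- qs[1]; q2 <- qs[2]
    acc <- matrix(0L, 0L, 4L)
    if (h > H$ntip && length(H$kids[[h]]) == 2L) {
      hc <- H$kids[[h]]
      for (ord in list(c(1, 2), c(2, 1))) {
        if (abs(dp$costs["cs"] + dp$inm[q1, hc[ord[1]]] +
                dp$inm[q2, hc[ord[2]]] - target) < eps) {
          part <- cross_add(enum_in(q1, hc[ord[1]]), enum_in(q2, hc[ord[2]]))
          if (nrow(part)) acc <- rbind(acc, sweep_add(part, unit(1L)))
        }
      }
    }
    if (abs(dp$costs["cd"] + dp$inm[q1, h] + dp$inm[q2, h] - target) < eps) {
      part <- cross_add(enum_in(q1, h), enum_in(q2, h))
      if (nrow(part)) acc <- rbind(acc, sweep_add(part, unit(2L)))
    }
    idx <- dp$incomp[[h]]
    if (length(idx)) {
      for (sw in list(c(q1, q2), c(q2, q1))) {
        stay <- sw[1]; jump <- sw[2]
        rest <- target - dp$costs["ct"] - dp$inm[stay, h]
        for (k in idx[abs(dp$cmat[jump, idx] - rest) < eps]) {
          part <- cross_add(enum_in(stay, h), enum_c(jump, k))
          if (nrow(part)) acc <- rbind(acc, sweep_add(part, unit(3L)))
        }
      }
    }
    memo[[key]] <- clip(acc)
  }
  enum_in <- function(p, h) {
    key <- paste0("i", p, ".", h)
    if (!is.null(memo[[key]])) return(memo[[key]])
    target <- dp$inm[p, h]
    if (target >= INF) return(memo[[key]] <- matrix(0L, 0L, 4L))
    acc <- matrix(0L, 0L, 4L)
    if (abs(dp$cmat[p, h] - target) < eps) acc <- rbind(acc, enum_c(p, h))
    if (h > H$ntip) {
      for (hc in H$kids[[h]]) {
        if (abs(dp$inm[p, hc] + dp$costs["cl"] - target) < eps) {
          sub <- enum_in(p, hc)
          if (nrow(sub)) acc <- rbind(acc, sweep_add(sub, unit(4L)))
        }
      }
    }
    memo[[key]] <- clip(acc)
  }
  total <- min(dp$cmat[V$root, ])
  acc <- matrix(0L, 0L, 4L)
  for (h in which(abs(dp$cmat[V$root, ] - total) < eps)) {
    acc <- rbind(acc, enum_c(V$root, h))
  }
  acc <- unique(acc)
  colnames(acc) <- c("codivergence", "duplication", "host_jump", "extinction")
  ranges <- rbind(min = apply(acc, 2L, min), max = apply(acc, 2L, max))
  structure(list(cost = total, counts = acc, ranges = ranges,
                 truncated = truncated),
            class = "reconciliation_set")
}

# add a unit event vector to every row
sweep_add <- function(m, u) m + matrix(u, nrow(m), 4L, byrow = TRUE)

#' Event proportions of a reconciliation
#'
#' Divides the event counts by the total number of events. A host-jump
#' proportion near 1 indicates pervasive cross-species transmission; near 0,
#' dominant co-divergence.
#'
#' @param x a `reconciliation` object, or a named count vector with names
#'   `codivergence`, `duplication`, `host_jump`, `extinction`.
#' @return named numeric proportions summing to 1.
#' @examples
#' event_proportions(c(codivergence = 9, duplication = 0,
#'                     extinction = 1, host_jump = 13))
#' @export
event_proportions <- function(x) {
  counts <- if (inherits(x, "reconciliation")) x$counts else x
  need <- c("codivergence", "duplication", "host_jump", "extinction")
  if (!all(need %in% names(counts))) {
    stop_codiverge("counts must be named: ", paste(need, collapse = ", "))
  }
  counts <- counts[need]
  if (any(counts < 0)) stop_codiverge("negative event counts")
  tot <- sum(counts)
  if (tot == 0) stop_codiverge("no events: proportions undefined")
  counts / tot
}

#' @export
print.reconciliation <- function(x, ...) {
  cat("Reconciliation (duplication-transfer-loss), total cost", x$cost, "\n")
  cat("  events: ", paste(names(x$counts), x$counts, sep = " = ",
                          collapse = "; "), "\n", sep = "")
  cat("  proportions:", paste(names(x$proportions),
                              sprintf("%.2f", x$proportions),
                              sep = " = ", collapse = "; "), "\n")
  invisible(x)
}

#' @export
print.reconciliation_set <- function(x, ...) {
  cat("Co-optimal reconciliations: cost", x$cost, ",",
      nrow(x$counts), "distinct event-count vector(s)",
      if (x$truncated) "(truncated)" else "", "\n")
  print(x$ranges)
  invisible(x)
}
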