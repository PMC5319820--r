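# Independent oracles and fixture builders used across the suite. These
# deliberately avoid the package's own code paths: the split-distance oracle
# goes through ape, the reconciliation oracle enumerates event-labeled
# placements directly, and the crossing oracle is a quadratic pair scan.

# random binary tree with tips t1..tn (ape's uniform-split generator)
rand_binary <- function(n, seed = NULL) {
  gen <- function() ape::rtree(n, tip.label = paste0("t", seq_len(n)), br = NULL)
  if (is.null(seed)) gen() else {
    set.seed(seed)
    gen()
  }
}

# caterpillar (ladder) tree over the given tip order
caterpillar <- function(tips) {
  s <- tips[1]
  for (i in seq_along(tips)[-1]) s <- paste0("(", s, ",", tips[i], ")")
  read_newick(text = paste0(s, ";"))
}

# classic symmetric-difference PH85 on binary trees, via ape
rf_oracle <- function(t1, t2) {
  as.numeric(ape::dist.topo(ape::unroot(t1), ape::unroot(t2), method = "PH85"))
}

# all permutations of a vector (small n)
all_perms <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (p in all_perms(x[-i])) out[[length(out) + 1L]] <- c(x[i], p)
  }
  out
}

# exact maximum PH85 over every relabeling of t2 (tiny trees only)
max_ph85_oracle <- function(t1, t2) {
  tips <- t2$tip.label
  best <- 0
  for (p in all_perms(tips)) {
    t2p <- t2
    t2p$tip.label <- p
    best <- max(best, ph85(t1, t2p))
  }
  best
}

# quadratic crossing scan: lines cross iff endpoints are ordered oppositely
crossings_oracle <- function(host_order, virus_order, assoc) {
  hp <- match(assoc$host, host_order)
  vp <- match(assoc$virus, virus_order)
  n <- length(hp)
  cnt <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if ((hp[i] - hp[j]) * (vp[i] - vp[j]) < 0) cnt <- cnt + 1L
    }
  }
  cnt
}

# ---- brute-force duplication-transfer-loss oracle --------------------------
# Enumerates every placement of internal virus nodes on host nodes together
# with every event labeling, scores valid combinations (losses implied by
# the depth gaps), and returns the minimum cost. Exponential; tiny trees only.
dtl_oracle <- function(host, virus, assoc,
                       costs = c(codivergence = 0, duplication = 1,
                                 host_jump = 1, extinction = 1)) {
  tab <- function(phy) {
    ntip <- length(phy$tip.label)
    nn <- ntip + phy$Nnode
    kids <- vector("list", nn)
    for (i in seq_len(nrow(phy$edge))) {
      kids[[phy$edge[i, 1]]] <- c(kids[[phy$edge[i, 1]]], phy$edge[i, 2])
    }
    depth <- integer(nn)
    sub <- vector("list", nn)
    rec <- function(v, d) {
      depth[v] <<- d
      sub[[v]] <<- v
      if (v > ntip) {
        for (u in kids[[v]]) {
          rec(u, d + 1L)
          sub[[v]] <<- c(sub[[v]], sub[[u]])
        }
      }
    }
    rec(ntip + 1L, 0L)
    list(ntip = ntip, nn = nn, kids = kids, depth = depth, sub = sub)
  }
  H <- tab(host)
  V <- tab(virus)
  vmap <- match(assoc$host[match(virus$tip.label, assoc$virus)],
                host$tip.label)
  internal <- (V$ntip + 1L):(V$ntip + virus$Nnode)
  k <- length(internal)
  in_sub <- function(x, h) x %in% H$sub[[h]]
  comparable <- function(a, b) in_sub(a, b) || in_sub(b, a)
  score_node <- function(p, sigma, ev) {
    h <- sigma[p]
    q <- V$kids[[p]]
    hq <- sigma[q]
    if (ev == "C") {
      if (h <= H$ntip) return(Inf)
      hc <- H$kids[[h]]
      best <- Inf
      for (ord in list(hc, rev(hc))) {
        if (in_sub(hq[1], ord[1]) && in_sub(hq[2], ord[2])) {
          loss <- (H$depth[hq[1]] - H$depth[ord[1]]) +
            (H$depth[hq[2]] - H$depth[ord[2]])
          best <- min(best, costs["codivergence"] + loss * costs["extinction"])
        }
      }
      return(best)
    }
    if (ev == "D") {
      if (!in_sub(hq[1], h) || !in_sub(hq[2], h)) return(Inf)
      loss <- (H$depth[hq[1]] - H$depth[h]) + (H$depth[hq[2]] - H$depth[h])
      return(costs["duplication"] + loss * costs["extinction"])
    }
    # transfer: one child stays below h, the other lands incomparably
    best <- Inf
    for (sw in list(c(1, 2), c(2, 1))) {
      stay <- hq[sw[1]]; jump <- hq[sw[2]]
      if (in_sub(stay, h) && !comparable(jump, h)) {
        loss <- H$depth[stay] - H$depth[h]
        best <- min(best, costs["host_jump"] + loss * costs["extinction"])
      }
    }
    best
  }
  sigma <- integer(V$nn)
  sigma[seq_len(V$ntip)] <- vmap
  placements <- as.matrix(expand.grid(rep(list(seq_len(H$nn)), k)))
  events <- as.matrix(expand.grid(rep(list(c("C", "D", "T")), k),
                                  stringsAsFactors = FALSE))
  best <- Inf
  for (i in seq_len(nrow(placements))) {
    sigma[internal] <- placements[i, ]
    for (j in seq_len(nrow(events))) {
      total <- 0
      for (idx in seq_len(k)) {
        total <- total + score_node(internal[idx], sigma, events[j, idx])
        if (total >= best) break
      }
      best <- min(best, total)
    }
  }
  unname(best)
}

# random reconciliation instance: host and virus trees plus a random
# (surjective-ish) association
rand_instance <- function(n_host, n_virus, seed) {
  set.seed(seed)
  host <- ape::rtree(n_host, tip.label = paste0("h", seq_len(n_host)), br = NULL)
  virus <- ape::rtree(n_virus, tip.label = paste0("v", seq_len(n_virus)), br = NULL)
  hosts <- sample(host$tip.label, n_virus, replace = TRUE)
  list(host = host, virus = virus,
       assoc = association(virus$tip.label, hosts))
}

# canonical sorted split keys of a tree, for topology comparison
split_keys <- function(tr) {
  sort(vapply(nontrivial_splits(tr),
              function(x) paste(sort(x), collapse = "+"), character(1)))
}
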