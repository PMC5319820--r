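test_that("crossing counts match the quadratic pair-scan oracle", {
  a2 <- association(c("v1", "v2"), c("h1", "h2"))
  expect_equal(count_crossings(c("h1", "h2"), c("v1", "v2"), a2), 0)
  expect_equal(count_crossings(c("h2", "h1"), c("v1", "v2"), a2), 1)

  for (seed in 1:8) {
    set.seed(seed)
    nh <- sample(3:8, 1)
    hosts <- paste0("h", 1:nh)
    m <- sample(1:2, nh, replace = TRUE)
    assoc <- association(paste0("v", seq_len(sum(m))),
                         rep(hosts, m))
    ho <- sample(hosts)
    vo <- sample(assoc$virus)
    expect_equal(count_crossings(ho, vo, assoc),
                 crossings_oracle(ho, vo, assoc))
  }

  expect_error(count_crossings(c("h1", "h1"), c("v1", "v2"), a2),
               "permutations")
})

test_that("crossings are invariant under simultaneous relabeling", {
  set.seed(42)
  hosts <- paste0("h", 1:6)
  assoc <- association(paste0("v", 1:6), sample(hosts, 6, replace = TRUE))
  ho <- sample(hosts); vo <- sample(assoc$virus)
  base <- count_crossings(ho, vo, assoc)
  ren <- setNames(paste0("X", seq_along(hosts)), hosts)
  assoc2 <- association(assoc$virus, unname(ren[assoc$host]))
  expect_equal(count_crossings(unname(ren[ho]), vo, assoc2), base)
})

test_that("untangling never increases crossings and solves congruent pairs", {
  for (seed in 1:5) {
    sim <- simulate_tanglegram(n_hosts = 10, n_switches = 0, seed = seed)
    lay <- untangle(sim$host, sim$virus, sim$assoc)
    expect_equal(lay$crossings, 0)
  }
  for (seed in 6:10) {
    sim <- simulate_tanglegram(n_hosts = 12, n_switches = 3, seed = seed)
    lay <- untangle(sim$host, sim$virus, sim$assoc)
    expect_lte(lay$crossings, lay$initial_crossings)
    expect_equal(count_crossings(lay$host_order, lay$virus_order, sim$assoc),
                 lay$crossings)
    # deterministic
    lay2 <- untangle(sim$host, sim$virus, sim$assoc)
    expect_identical(lay$host_order, lay2$host_order)
    expect_identical(lay$virus_order, lay2$virus_order)
  }
})

test_that("heuristic untangling is near the exhaustive rotation optimum", {
  # exhaustive minimum over all rotation combinations of both 6-tip trees
  exhaustive_min <- function(host, virus, assoc) {
    orders <- function(phy) {
      cl <- codiverge:::phylo_to_clist(phy)
      paths <- c(list(integer(0)), codiverge:::node_paths(cl))
      internal <- Filter(function(p) {
        !codiverge:::is_clist_leaf(codiverge:::clist_at(cl, p))
      }, paths)
      combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(internal)))
      out <- character(0)
      for (i in seq_len(nrow(combos))) {
        cur <- cl
        for (j in seq_along(internal)) {
          if (combos[i, j]) {
            nd <- codiverge:::clist_at(cur, internal[[j]])
            nd$children <- rev(nd$children)
            cur <- codiverge:::clist_replace(cur, internal[[j]], nd)
          }
        }
        out <- c(out, paste(codiverge:::clist_tips(cur), collapse = "|"))
      }
      unique(out)
    }
    ho <- orders(host); vo <- orders(virus)
    best <- Inf
    for (h in ho) for (v in vo) {
      best <- min(best, count_crossings(strsplit(h, "|", fixed = TRUE)[[1]],
                                        strsplit(v, "|", fixed = TRUE)[[1]],
                                        assoc))
    }
    best
  }
  gaps <- sapply(1:4, function(seed) {
    sim <- simulate_tanglegram(n_hosts = 6, n_switches = 2, seed = seed + 40)
    lay <- untangle(sim$host, sim$virus, sim$assoc)
    opt <- exhaustive_min(sim$host, sim$virus, sim$assoc)
    expect_gte(lay$crossings, opt)
    lay$crossings - opt
  })
  # the hill climb is a heuristic: the contract is no worse than the input
  # layout, so the gap to the exhaustive optimum is reported, not forced to 0
  expect_true(all(gaps >= 0))
  message("untangle optimality gaps on 6-tip instances: ",
          paste(gaps, collapse = ", "))
})

test_that("family comparison recovers correlation and group contrasts", {
  # perfectly linear relation
  rec <- data.frame(family = paste0("f", 1:6),
                    nph85 = 0.1 * (1:6),
                    n_viruses = 10 * (1:6),
                    genome_type = rep(c("DNA", "RNA"), 3))
  fc <- family_comparison(rec)
  expect_equal(fc$correlation$estimate, 1)

  # identical DNA and RNA samples: t = 0
  rec2 <- data.frame(family = paste0("f", 1:8),
                     nph85 = rep(c(0.5, 0.7, 0.8, 0.9), 2),
                     n_viruses = rep(20, 8),
                     genome_type = rep(c("DNA", "RNA"), each = 4))
  fc2 <- family_comparison(rec2)
  expect_equal(fc2$ttest$statistic, 0)
  expect_equal(fc2$ttest$mean_dna, fc2$ttest$mean_rna)

  # closed-form check of Pearson r on a 5-point hand dataset
  x <- c(12, 25, 33, 47, 60); y <- c(0.61, 0.72, 0.70, 0.88, 0.97)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  rec3 <- data.frame(family = paste0("f", 1:5), nph85 = y, n_viruses = x,
                     genome_type = c("DNA", "DNA", "RNA", "RNA", "RNA"))
  fc3 <- family_comparison(rec3)
  expect_equal(fc3$correlation$estimate, r_hand)

  # degenerate variance is flagged, not fatal
  rec4 <- data.frame(family = paste0("f", 1:4), nph85 = rep(0.9, 4),
                     n_viruses = c(5, 6, 7, 8),
                     genome_type = c("DNA", "DNA", "RNA", "RNA"))
  fc4 <- family_comparison(rec4)
  expect_true(length(fc4$flags) >= 1)
  expect_true(is.na(fc4$ttest$statistic))
})
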