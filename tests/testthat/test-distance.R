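test_that("nontrivial splits enumerate internal edges of the unrooted view", {
  expect_length(nontrivial_splits(read_newick(text = "((a,b),(c,d));")), 1)
  expect_length(nontrivial_splits(read_newick(text = "(a,b,c,d,e);")), 0)
  cat5 <- read_newick(text = "(((a,b),c),d,e);")
  keys <- split_keys(cat5)
  expect_identical(keys, sort(c("a+b", "d+e")))  # ab|cde and abc|de
})

test_that("split conflict is the four-intersection test", {
  tips4 <- c("a", "b", "c", "d")
  expect_true(splits_conflict(c("a", "b"), c("a", "c"), tips4))
  tips5 <- c("a", "b", "c", "d", "e")
  expect_false(splits_conflict(c("a", "b"), c("a", "b", "c"), tips5))
  expect_false(splits_conflict(c("a", "b"), c("a", "b"), tips5))
  expect_error(splits_conflict(c("a", "x"), c("a", "b"), tips5), "subsets")
})

test_that("ph85 counts conflicting clades and is symmetric", {
  a <- read_newick(text = "((a,b),(c,d));")
  b <- read_newick(text = "((a,c),(b,d));")
  expect_identical(ph85(a, a), 0L + 0L)
  expect_equal(ph85(a, b), 2)

  poly <- read_newick(text = "((a,b,c),d,e);")
  res <- read_newick(text = "(((a,b),c),d,e);")
  expect_equal(ph85(poly, res), 0)

  for (seed in 1:10) {
    t1 <- rand_binary(7, seed = seed)
    t2 <- rand_binary(7, seed = seed + 50)
    expect_equal(ph85(t1, t2), ph85(t2, t1))
    expect_equal(ph85(t1, t2), rf_oracle(t1, t2))
  }
  expect_error(ph85(a, read_newick(text = "((a,b),(c,e));")), "tip set")
})

test_that("randomized maximum covers the attainable extreme and traces", {
  t4 <- read_newick(text = "((a,b),(c,d));")
  # oracle: enumerate all 24 relabelings
  expect_equal(max_ph85_oracle(t4, t4), 2)
  expect_equal(randomized_max_ph85(t4, t4, 1000, seed = 1), 2)

  star <- read_newick(text = "(a,b,c,d,e);")
  expect_equal(randomized_max_ph85(star, star, 100, seed = 1), 0)

  t1 <- rand_binary(8, seed = 4)
  t2 <- rand_binary(8, seed = 5)
  mx <- randomized_max_ph85(t1, t2, 500, seed = 2, trace = TRUE)
  tr <- attr(mx, "trace")
  expect_length(tr, 500)
  expect_true(all(diff(tr) >= 0))
  expect_equal(max(tr[1], mx), as.integer(mx))
})

test_that("nPH85 hits its extremes and the hand-worked middle case", {
  t <- rand_binary(12, seed = 9)
  expect_equal(nph85(t, t, 100, seed = 1), 0)

  c1 <- caterpillar(paste0("x", 1:10))
  c2 <- caterpillar(paste0("x", c(1, 6, 2, 7, 3, 8, 4, 9, 5, 10)))
  expect_length(intersect(split_keys(c1), split_keys(c2)), 0)
  expect_equal(nph85(c1, c2, 1000, seed = 3), 1)

  t1 <- read_newick(text = "(((a,b),c),d,e);")
  t2 <- read_newick(text = "(((a,c),b),d,e);")
  expect_equal(ph85(t1, t2), 2)
  expect_equal(max_ph85_oracle(t1, t2), 4)   # exhaustive over 120 relabelings
  expect_equal(nph85(t1, t2, 1000, seed = 4), 0.5)

  # always within [0, 1] on random pairs
  for (seed in 1:10) {
    v <- nph85(rand_binary(6, seed = seed), rand_binary(6, seed = seed + 30),
               n_randomizations = 50, seed = seed)
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("distance to any resolution of a polytomous tree is zero", {
  for (seed in 1:8) {
    bin <- rand_binary(10, seed = seed)
    poly <- collapse_low_support(
      assign_supports(bin, low_support_fraction = 0.5, seed = seed), 0.8)
    res <- resolve_polytomies(poly, seed = seed + 7)
    expect_equal(ph85(poly, res), 0)
  }
})

test_that("within-host polytomies do not influence the distance", {
  for (seed in 1:5) {
    host <- rand_binary(6, seed = seed)
    set.seed(seed)
    m <- sample(1:3, 6, replace = TRUE)
    assoc <- association(
      unlist(mapply(function(h, k) paste0(h, "v", seq_len(k)),
                    host$tip.label, m, SIMPLIFY = FALSE)),
      rep(host$tip.label, m))
    hx <- expand_host_tree(host, assoc)
    virus <- resolve_polytomies(hx, seed = seed + 99)
    expect_equal(nph85(hx, virus, 200, seed = seed), 0)
  }
})

test_that("summary pipeline: no polytomies means a degenerate spread", {
  host <- rand_binary(8, seed = 21)
  assoc <- association(paste0(host$tip.label, "v"), host$tip.label)
  virus <- expand_host_tree(host, assoc)
  # make it disagree somewhere but stay binary and fully supported
  virus2 <- rand_binary(8, seed = 22)
  virus2$tip.label <- paste0(virus2$tip.label, "v")
  s <- nph85_summary(host, virus2, assoc, n_resolutions = 20,
                     n_randomizations = 200, seed = 5)
  expect_equal(s$mean, s$overall)
  expect_equal(s$percentile_low, s$overall)
  expect_equal(s$percentile_high, s$overall)

  ident <- nph85_summary(host, virus, assoc, n_resolutions = 10,
                         n_randomizations = 100, seed = 6)
  expect_equal(ident$ph85, 0)
  expect_equal(ident$overall, 0)
  expect_equal(ident$mean, 0)
  expect_equal(ident$percentile_high, 0)
})

test_that("summary over resolutions brackets the mean and stays in [0,1]", {
  virus <- read_newick(text = "((((a,b)0.5,c)0.9,(d,e)0.95),(f,g)0.99);")
  host <- caterpillar(letters[1:7])
  assoc <- association(letters[1:7], letters[1:7])
  s <- nph85_summary(host, virus, assoc, n_resolutions = 30,
                     n_randomizations = 100, seed = 8)
  expect_gte(s$mean, min(s$values))
  expect_lte(s$mean, max(s$values))
  expect_true(all(s$values >= 0 & s$values <= 1))
  expect_gte(s$percentile_high, s$percentile_low)
})
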