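test_that("Newick parsing reads polytomies, supports, and round-trips", {
  star <- read_newick(text = "(a,b,c);")
  expect_s3_class(star, "phylo")
  expect_setequal(star$tip.label, c("a", "b", "c"))
  expect_length(nontrivial_splits(star), 0)

  sup <- read_newick(text = "((a,b)0.95,c,d);")
  expect_true(0.95 %in% tree_supports(sup))

  # non-numeric or out-of-range internal labels are not supports
  named <- read_newick(text = "((a,b)cladeX,c,d);")
  expect_true(all(is.na(tree_supports(named))))

  for (n in c(4, 7, 12)) {
    tr <- rand_binary(n, seed = n)
    back <- read_newick(text = write_newick(tr))
    expect_identical(split_keys(back), split_keys(tr))
  }
})

test_that("malformed Newick fails with a character position", {
  expect_error(read_newick(text = "((a,b),c;"), "position|character")
  expect_error(read_newick(text = "(a,b))c;"), "character 6")
  expect_error(read_newick(text = "(a,(b,c))"), "';'")
  expect_error(read_newick(text = "((a,b),(a,c));"), "duplicate")
})

test_that("host-tree expansion replaces tips by within-host clades", {
  h <- read_newick(text = "(h1,h2);")

  a3 <- association(c("v1", "v2", "v3"), c("h1", "h1", "h2"))
  ex <- expand_host_tree(h, a3)
  expect_setequal(ex$tip.label, a3$virus)
  expect_length(incongruent_host_clades(ex, read_newick(text = "((v1,v2),v3);")), 0)

  # one virus per host is a pure relabeling
  a2 <- association(c("v1", "v2"), c("h1", "h2"))
  expect_setequal(expand_host_tree(h, a2)$tip.label, c("v1", "v2"))

  # three viruses in one host become a trifurcation
  a4 <- association(c("v1", "v2", "v3", "v4"), c("h1", "h1", "h1", "h2"))
  ex4 <- expand_host_tree(h, a4)
  pp <- ape::prop.part(ex4)
  sizes <- lengths(pp)
  expect_true(3 %in% sizes)

  expect_error(expand_host_tree(h, association("v1", "h9")), "h9")
})

test_that("expanded tip set equals the virus tip set on random fixtures", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(4:10, 1)
    host <- rand_binary(n)
    m <- sample(1:3, n, replace = TRUE)
    assoc <- association(
      unlist(mapply(function(h, k) paste0(h, "v", seq_len(k)),
                    host$tip.label, m, SIMPLIFY = FALSE)),
      rep(host$tip.label, m))
    ex <- expand_host_tree(host, assoc)
    expect_setequal(ex$tip.label, assoc$virus)
  }
})

test_that("support collapse uses a strict threshold and keeps tips", {
  tr <- read_newick(text = "(((a,b)0.79,c)0.95,d,e);")
  col <- collapse_low_support(tr, 0.8)
  expect_false(any(vapply(nontrivial_splits(col), setequal, logical(1),
                          c("a", "b"))))
  expect_setequal(col$tip.label, tr$tip.label)

  kept <- collapse_low_support(read_newick(text = "(((a,b)0.80,c)0.95,d,e);"), 0.8)
  expect_true(any(vapply(nontrivial_splits(kept), setequal, logical(1),
                         c("a", "b"))))

  strong <- read_newick(text = "(((a,b)1.0,c)1.0,d,e);")
  expect_identical(split_keys(collapse_low_support(strong, 0.8)),
                   split_keys(strong))

  # trees without supports pass through unchanged
  plain <- rand_binary(8, seed = 3)
  expect_identical(split_keys(collapse_low_support(plain, 0.8)),
                   split_keys(plain))
})

test_that("random resolution refines, is seeded, and covers all resolutions", {
  bin <- rand_binary(9, seed = 2)
  expect_identical(split_keys(resolve_polytomies(bin, 1)), split_keys(bin))

  poly <- read_newick(text = "((a,b,c),d,e);")
  r7a <- resolve_polytomies(poly, seed = 7)
  r7b <- resolve_polytomies(poly, seed = 7)
  expect_identical(write_newick(r7a), write_newick(r7b))

  # each of the 3 resolutions of a trichotomy near-uniform over 3000 draws
  key <- function(tr) {
    s <- nontrivial_splits(tr)
    paste(sort(vapply(s, function(x) paste(sort(x), collapse = "+"),
                      character(1))), collapse = ";")
  }
  draws <- vapply(1:3000, function(i) key(resolve_polytomies(poly, seed = i)),
                  character(1))
  counts <- table(draws)
  expect_length(counts, 3)
  # 3 sigma around 1000 for binomial(3000, 1/3)
  sigma <- sqrt(3000 * (1 / 3) * (2 / 3))
  expect_true(all(abs(counts - 1000) < 3 * sigma))
})

test_that("resolution output refines input splits; collapse keeps strong splits", {
  for (seed in 1:5) {
    bin <- rand_binary(10, seed = seed)
    withsup <- assign_supports(bin, low_support_fraction = 0.4, seed = seed)
    col <- collapse_low_support(withsup, 0.8)
    res <- resolve_polytomies(col, seed = seed + 100)
    expect_true(codiverge:::is_binary_rooted(res))
    expect_true(all(split_keys(col) %in% split_keys(res)))
    # splits with support >= threshold survive the collapse
    strong <- split_keys(collapse_low_support(withsup, 1e-9))
    expect_true(all(split_keys(col) %in% strong))
  }
})
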