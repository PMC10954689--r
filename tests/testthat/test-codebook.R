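test_that("enumeration matches the closed forms and brute-force string counts", {
  for (n in 1:5) for (k in 1:n) {
    expect_length(enumerate_barcodes(n, k), choose(n, k) * 3^k)
    expect_equal(length(enumerate_barcodes(n, k, TRUE)),
                 count_barcodes_bruteforce(n, k, TRUE))
  }
  for (n in 6:8) for (k in c(1L, 3L, n)) {
    expect_length(enumerate_barcodes(n, k), choose(n, k) * 3^k)
    expect_length(enumerate_barcodes(n, k, TRUE),
                  choose(n, k) * (3^k - 3))
  }
  bc <- enumerate_barcodes(2, 1)
  expect_length(bc, 6L)
  expect_false(is.unsorted(bc))
  expect_false(anyDuplicated(bc) > 0)
  # every multicolor barcode uses >1 channel across its on rounds
  mc <- enumerate_barcodes(4, 2, TRUE)
  expect_true(all(vapply(strsplit(mc, ""), function(d) {
    ch <- d[d != "0"]
    length(unique(ch)) > 1L
  }, logical(1L))))
  expect_error(enumerate_barcodes(0, 1), "n")
  expect_error(enumerate_barcodes(6, 7), "k")
})

test_that("hamming distance counts differing digits", {
  expect_identical(barcode_hamming("132000", "132000"), 0L)
  expect_identical(barcode_hamming("100000", "200000"), 1L)
  expect_identical(barcode_hamming("132000", "000132"), 6L)
  expect_error(barcode_hamming("10", "100"), "equal length")
})

test_that("conflict graph edges are exactly the distance-1 pairs", {
  bc <- enumerate_barcodes(3, 2, TRUE)
  g <- conflict_graph(bc)
  dm <- string_distmat(bc)
  expect_identical(nrow(g$edges), sum(dm == 1L & upper.tri(dm)))
  for (e in seq_len(nrow(g$edges)))
    expect_identical(barcode_hamming(bc[g$edges[e, 1L]], bc[g$edges[e, 2L]]), 1L)
  expect_true(all(g$edges[, 1L] < g$edges[, 2L]))  # no self loops
})

test_that("seed sets are pairwise at distance > 2 and maximal", {
  expect_identical(find_seed_set("132000"), "132000")
  expect_length(find_seed_set(c("100000", "200000"), rng_seed = 4), 1L)
  pool <- enumerate_barcodes(6, 3, TRUE)
  q <- find_seed_set(pool, n_restarts = 50L, rng_seed = 1)
  dm <- string_distmat(q)
  expect_true(all(dm[upper.tri(dm)] > 2L))
  # maximality: no leftover barcode is at distance > 2 from all of q
  left <- setdiff(pool, q)
  cross <- outer(left, q, Vectorize(barcode_hamming))
  expect_true(all(apply(cross, 1L, min) <= 2L))
})

test_that("select_mis returns a seeded, independent, maximal set", {
  # edgeless graph keeps every node
  bc3 <- c("111000", "000111", "110100")
  expect_length(select_mis(conflict_graph(bc3), n_runs = 10L), 3L)
  # path a-b-c seeded at a must pick up c
  path <- c("110000", "210000", "220000")
  g <- conflict_graph(path)
  expect_identical(nrow(g$edges), 2L)
  mis <- select_mis(g, "110000", n_runs = 5L, rng_seed = 1)
  expect_setequal(as.character(mis), c("110000", "220000"))
  expect_error(select_mis(g, c("110000", "210000"), 5L), "independent")

  pool <- enumerate_barcodes(6, 3, TRUE)
  gg <- conflict_graph(pool)
  seed <- find_seed_set(pool, n_restarts = 50L, rng_seed = 1)
  mis <- select_mis(gg, seed, n_runs = 500L, rng_seed = 1)
  expect_true(all(seed %in% mis))
  dm <- string_distmat(as.character(mis))
  expect_true(all(dm[upper.tri(dm)] >= 2L))       # independent in G
  left <- setdiff(pool, mis)
  cross <- outer(left, as.character(mis), Vectorize(barcode_hamming))
  expect_true(all(apply(cross, 1L, min) == 1L))   # maximal
  # deterministic given the seed
  mis2 <- select_mis(gg, seed, n_runs = 500L, rng_seed = 1)
  expect_identical(as.character(mis), as.character(mis2))
})

test_that("randomized MIS matches the exact optimum on a small subgraph", {
  skip_if_not_installed("igraph")
  pool <- enumerate_barcodes(6, 3, TRUE)
  sub <- pool[1:30]
  g <- conflict_graph(sub)
  ig <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0L, length(sub) - igraph::vcount(ig)))
  exact <- igraph::ivs_size(ig)
  mis <- select_mis(g, n_runs = 2000L, rng_seed = 1)
  expect_equal(length(mis), as.integer(exact))
})

test_that("augmentation minimizes induced conflict edges", {
  mis <- c("111000", "000111")
  expect_identical(as.character(augment_barcodes(mis, mis, 0L)), mis)
  pool <- c(mis, "222000")
  out <- augment_barcodes(mis, pool, 1L, n_trials = 10L)
  expect_setequal(as.character(out), c(mis, "222000"))
  expect_identical(attr(out, "induced_edges"), 0L)
  # exhaustive oracle on a toy pool
  pool10 <- enumerate_barcodes(3, 2, TRUE)[1:10]
  mis0 <- pool10[1:2]
  cand <- setdiff(pool10, mis0)
  best_exh <- min(apply(utils::combn(length(cand), 2L), 2L, function(p) {
    sel <- c(mis0, cand[p])
    dm <- string_distmat(sel)
    sum(dm[upper.tri(dm)] == 1L)
  }))
  out <- augment_barcodes(mis0, pool10, 2L, n_trials = 500L, rng_seed = 2)
  dm <- string_distmat(as.character(out))
  expect_identical(sum(dm[upper.tri(dm)] == 1L), as.integer(best_exh))
  expect_error(augment_barcodes(mis0, pool10, 99L), "pool")
})

test_that("gene assignment is a bijection and the one-hot layout is exact", {
  v <- barcode_onehot("132000")
  expect_identical(which(v == 1) - 1L, c(0L, 5L, 7L))  # r1c1, r2c3, r3c2
  expect_identical(sum(v), 3)

  pool <- enumerate_barcodes(6, 3, TRUE)
  cb <- assign_genes(pool[1:20], sprintf("g%d", 1:15), n_empty = 3L,
                     rng_seed = 7)
  expect_identical(cb$N, 18L)
  expect_identical(sum(cb$is_empty), 3L)
  expect_false(anyDuplicated(cb$barcodes) > 0)
  expect_setequal(cb$genes[!cb$is_empty], sprintf("g%d", 1:15))
  # X round-trips from the compact strings
  expect_identical(unname(colSums(cb$X)), rep(3, 18L))
  for (i in seq_len(cb$N))
    expect_identical(cb$X[, i], barcode_onehot(cb$barcodes[i]))
  expect_error(assign_genes(pool[1:3], c("a", "b", "c"), 1L), "barcodes")
})

test_that("the brain-scale design yields its printed codebook shape", {
  pool <- enumerate_barcodes(6, 3, TRUE)
  g <- conflict_graph(pool)
  seed <- find_seed_set(pool, rng_seed = 0)
  mis <- select_mis(g, seed, n_runs = 2000L, rng_seed = 0)
  expect_gte(length(mis), 159L)
  cb <- assign_genes(as.character(mis), sprintf("gene%03d", 1:121),
                     n_empty = 8L, rng_seed = 0)
  expect_identical(cb$N, 129L)
  expect_identical(dim(cb$X), c(18L, 129L))
})
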