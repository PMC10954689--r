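# weight_maps built directly from an entries table, for controlled inputs
manual_maps <- function(entries, cb, dim = c(64L, 64L)) {
  structure(list(entries = entries, dim = dim, codebook = cb,
                 coefficients = rep(1, 3L * cb$n), n_foreground = NA_integer_,
                 n_nonconverged = 0L),
            class = "weight_maps")
}

blob_entries <- function(r0, c0, barcode, peak = 0.6, sigma = 2) {
  g <- expand.grid(row = (r0 - 6):(r0 + 6), col = (c0 - 6):(c0 + 6))
  w <- peak * exp(-((g$row - r0)^2 + (g$col - c0)^2) / (2 * sigma^2))
  data.frame(row = g$row, col = g$col, barcode = barcode, weight = w)
}

test_that("spot calling segments blobs and measures their features", {
  cb <- toy_codebook()
  expect_identical(nrow(call_spots(manual_maps(
    data.frame(row = integer(0), col = integer(0), barcode = integer(0),
               weight = numeric(0)), cb))), 0L)

  one <- call_spots(manual_maps(blob_entries(30L, 40L, 1L), cb))
  expect_identical(nrow(one), 1L)
  # centroid in 0-based coordinates, within one pixel of the blob center
  expect_lt(abs(one$row - 29), 1)
  expect_lt(abs(one$col - 39), 1)
  expect_equal(one$max_weight, 0.6)
  expect_identical(one$gene, "geneA")
  expect_true(one$mean_weight <= one$max_weight && one$area >= 1)

  two_e <- rbind(blob_entries(20L, 20L, 2L), blob_entries(40L, 20L, 2L))
  two <- call_spots(manual_maps(two_e, cb))
  expect_identical(nrow(two), 2L)
  # disjoint areas covering the map's non-zero region (smoothing spreads it,
  # so compare against the connected-component count instead)
  expect_identical(sort(round(two$row)), c(19, 39))
})

test_that("spot areas partition each barcode's support", {
  cb <- overlap_codebook()
  sim <- simulate_fov(cb, 60L, shape = c(128, 128), rng_seed = 6)
  maps <- decode_fov(sim$stack, cb, sim$coefficients,
                     config = spd_config(rng_seed = 1))
  spots <- call_spots(maps)
  for (b in unique(spots$barcode_index)) {
    sp <- spots[spots$barcode_index == b, ]
    # total segmented area cannot exceed the dilated support of the map
    expect_lte(sum(sp$area),
               nrow(maps$entries[maps$entries$barcode == b, ]) * 9)
  }
  expect_true(all(spots$row >= 0 & spots$row <= 127))
})

test_that("empty classifier separates a separable toy set and not noise", {
  cb <- assign_genes(enumerate_barcodes(6, 3, TRUE)[1:10],
                     c("g1", "g2"), n_empty = 8L, rng_seed = 1)
  empty_idx <- which(cb$is_empty)
  gene_idx <- which(!cb$is_empty)
  n <- 120L
  spots <- data.frame(
    spot_id = seq_len(2 * n),
    gene = c(rep("g1", n), cb$genes[empty_idx[1L]] |> rep(n)),
    barcode_index = c(rep(gene_idx[1L], n), rep(empty_idx[1L], n)),
    area = c(rep(20L, n), rep(1L, n)) ,
    max_weight = c(rep(0.6, n), rep(0.1, n)),
    mean_weight = c(rep(0.5, n), rep(0.08, n)))
  clf <- train_empty_classifier(spots, cb, sample_fraction = 1, rng_seed = 1)
  prob <- predict_emptiness(clf, spots)
  expect_true(all((prob > 0.5) == cb$is_empty[spots$barcode_index]))

  # label-permuted control: features carry no signal, held-out accuracy ~0.5
  set.seed(2)
  noise <- spots
  noise$area <- sample(noise$area)
  noise$max_weight <- sample(noise$max_weight)
  noise$mean_weight <- sample(noise$mean_weight)
  tr <- sample(nrow(noise), nrow(noise) / 2)
  clf2 <- train_empty_classifier(noise[tr, ], cb, sample_fraction = 1,
                                 rng_seed = 2)
  acc <- mean((predict_emptiness(clf2, noise[-tr, ]) >= 0.5) ==
                cb$is_empty[noise$barcode_index[-tr]])
  expect_gt(acc, 0.35)
  expect_lt(acc, 0.65)

  single <- spots[spots$barcode_index == gene_idx[1L], ]
  expect_error(train_empty_classifier(single, cb), "single class")
})

test_that("filtering respects the threshold and reports the empty rate", {
  cb <- assign_genes(enumerate_barcodes(6, 3, TRUE)[1:4], c("g1", "g2"),
                     n_empty = 2L, rng_seed = 1)
  spots <- data.frame(spot_id = 1:3, gene = c("g1", "g2", "g1"),
                      barcode_index = which(!cb$is_empty)[c(1, 2, 1)],
                      area = c(5L, 6L, 7L),
                      max_weight = c(0.5, 0.6, 0.7),
                      mean_weight = c(0.4, 0.5, 0.6),
                      empty_prob = c(0.1, 0.2, 0.5))
  expect_identical(nrow(filter_spots(spots, threshold = 1)$spots), 3L)
  expect_warning(out0 <- filter_spots(spots, threshold = 0), "no spots")
  expect_identical(nrow(out0$spots), 0L)
  expect_identical(out0$empty_rate, 0)
  out <- filter_spots(spots, threshold = 0.325, codebook = cb)
  expect_identical(nrow(out$spots), 2L)
  expect_identical(out$empty_rate, 0)
  # kept set grows with the threshold
  kept_sizes <- vapply(c(0.05, 0.15, 0.25, 0.6, 1),
                       function(t) nrow(filter_spots(spots, threshold = t)$spots),
                       integer(1L))
  expect_true(all(diff(kept_sizes) >= 0L))
})
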