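test_that("pure-barcode pixels follow the closed-form detection threshold", {
  cb <- toy_codebook()
  expect_identical(max_undetected_weight(6, 3, 0.05), 0.3)
  expect_identical(max_undetected_weight(6, 3, 0), 0)
  expect_equal(max_undetected_weight(7, 3, 0.05), 0.35)
  expect_error(max_undetected_weight(6, 0, 0.05), "k")

  expect_true(all(decode_pixel(numeric(18), cb, 0.05) == 0))
  # weight 0.25 < w_max = 0.3 is invisible at alpha = 0.05
  expect_true(all(decode_pixel(0.25 * cb$X[, 1L], cb, 0.05, alpha2 = 0) == 0))
  # weight 0.4 shrinks to 0.4 - 0.3 = 0.1; OLS refit recovers 0.4
  w <- decode_pixel(0.4 * cb$X[, 1L], cb, 0.05, alpha2 = 0)
  expect_equal(w[1L], 0.1, tolerance = 1e-6)
  expect_identical(attr(w, "support"), 1L)
  expect_equal(unname(attr(w, "w_ols")), 0.4, tolerance = 1e-8)
})

test_that("the solver agrees with two independent convex-optimization oracles", {
  cb <- assign_genes(enumerate_barcodes(6, 3, TRUE)[seq(1, 120, by = 2)],
                     sprintf("g%d", 1:55), n_empty = 5L, rng_seed = 3)
  X <- cb$X
  set.seed(42)
  for (i in 1:40) {
    pick <- sample(cb$N, 2L)
    y <- drop(X[, pick] %*% runif(2, 0.3, 0.7)) + abs(rnorm(18, 0, 0.01))
    y <- pmin(y, 1)
    alpha <- runif(1, 0.02, 0.08)
    alpha2 <- alpha / 100
    mine <- as.numeric(decode_pixel(y, cb, alpha, alpha2, tol = 1e-10))
    orac <- fista_nnen(y, X, alpha, alpha2)
    expect_lt(max(abs(mine - orac)), 1e-4)
    expect_lt(abs(nnen_objective(mine, y, X, alpha, alpha2) -
                    nnen_objective(orac, y, X, alpha, alpha2)), 1e-8)
    if (requireNamespace("glmnet", quietly = TRUE)) {
      gl <- glmnet_nnen(y, X, alpha, alpha2)
      expect_lt(max(abs(mine - gl)), 1e-4)
    }
  }
})

test_that("lasso L1 norm is non-increasing in alpha", {
  cb <- overlap_codebook()
  set.seed(7)
  for (i in 1:10) {
    y <- pmin(1, drop(cb$X %*% runif(2, 0.2, 0.8)) + abs(rnorm(18, 0, 0.02)))
    l1 <- vapply(seq(0.01, 0.1, by = 0.005),
                 function(a) sum(decode_pixel(y, cb, a)), numeric(1L))
    expect_true(all(diff(l1) <= 1e-8))
  }
})

test_that("elbow filter keeps 0, 1 or 2 weights per its ratios", {
  w <- numeric(10)
  expect_identical(elbow_filter(w), integer(0))
  w[c(2, 5, 9)] <- c(0.5, 0.20, 0.05)
  expect_identical(elbow_filter(w), 2L)
  w[c(2, 5, 9)] <- c(0.5, 0.30, 0.10)
  expect_identical(elbow_filter(w), c(2L, 5L))
  w[c(2, 5, 9)] <- c(0.5, 0.30, 0.20)
  expect_identical(elbow_filter(w), integer(0))
  # single non-zero weight passes alone
  expect_identical(elbow_filter(c(0, 0.4)), 2L)
  expect_error(elbow_filter(c(-0.1, 0.5)), "non-negative")
})

test_that("OLS refit solves the normal equations and clips at zero", {
  cb <- toy_codebook()
  expect_equal(unname(ols_refit(0.4 * cb$X[, 1L], cb, 1L)), 0.4)
  y <- 0.3 * cb$X[, 1L] + 0.2 * cb$X[, 2L]
  expect_equal(unname(ols_refit(y, cb, 1:2)), c(0.3, 0.2))
  # noisy 2-support against a closed-form 2x2 solve
  ov <- overlap_codebook()
  set.seed(5)
  y <- drop(ov$X %*% c(0.5, 0.3)) + rnorm(18, 0, 0.02)
  S <- ov$X
  ref <- solve(crossprod(S), crossprod(S, y))
  expect_lt(max(abs(ols_refit(y, ov, 1:2) - drop(ref))), 1e-10)
  # identical columns fall back to the first support index
  Xdup <- cbind(cb$X[, 1L], cb$X[, 1L])
  b <- ols_refit(0.4 * cb$X[, 1L], Xdup, 1:2)
  expect_identical(names(b), "1")
  expect_equal(unname(b), 0.4)
})

test_that("channel coefficients are recovered from simulation", {
  # brain-scale codebook: every plane carried by several barcodes, as in a
  # realistic design
  cb <- benchmark_codebook(0, n_runs = 2000L)
  expect_true(all(rowSums(cb$X) > 1))
  cfg <- spd_config(train_pixels = 20000L, rng_seed = 1)
  # identity gains recovered within 3% at the reference rolony density
  # (10^4 spots per 1024^2 FOV, i.e. ~600 on this 256^2 window)
  sim1 <- simulate_fov(cb, 600L, shape = c(256, 256),
                       coeff_range = c(1, 1), rng_seed = 8)
  c1 <- estimate_channel_coefficients(sim1$stack, cb, cfg)
  expect_true(all(abs(c1 - 1) < 0.03))
  # drawn gains recovered closely
  sim2 <- simulate_fov(cb, 600L, shape = c(256, 256), rng_seed = 9)
  c2 <- estimate_channel_coefficients(sim2$stack, cb, cfg)
  expect_lt(median(abs(c2 - sim2$coefficients) / sim2$coefficients), 0.03)
  expect_gt(cor(c2, sim2$coefficients), 0.9)
})

test_that("planes without qualifying pixels keep their unit coefficient", {
  # two barcodes cover only 6 of 18 planes; the rest must stay at 1
  cb <- toy_codebook()
  sim <- simulate_fov(cb, 200L, shape = c(128, 128), coeff_range = c(1, 1),
                      rng_seed = 3)
  cf <- suppressWarnings(
    estimate_channel_coefficients(sim$stack, cb, spd_config(rng_seed = 1)))
  off <- rowSums(cb$X) == 0
  expect_true(all(cf[off] == 1))
})

test_that("alpha lookup reproduces a direct exhaustive evaluation", {
  cb <- overlap_codebook()
  sim <- simulate_fov(cb, 300L, shape = c(128, 128), rng_seed = 4)
  cfg <- spd_config(train_pixels = 400L, rng_seed = 2)
  lk <- build_alpha_lookup(sim$stack, cb, sim$coefficients, cfg)
  expect_s3_class(lk, "alpha_lookup")
  expect_true(all(lk$alphas %in% cfg$alpha_grid))
  expect_length(lk$alphas, 50L)
  # single-alpha grid collapses to that alpha everywhere
  lk1 <- build_alpha_lookup(sim$stack, cb, sim$coefficients,
                            spd_config(alpha_grid = 0.04,
                                       train_pixels = 500L, rng_seed = 2))
  expect_true(all(lk1$alphas == 0.04))
  # query clamps to the grid endpoints
  expect_identical(lookup_alpha(lk, -5), lk$alphas[1L])
  expect_identical(lookup_alpha(lk, 99), lk$alphas[50L])
  # exhaustive re-evaluation of the argmax at a few grid norms
  fg <- which(spdecon:::stack_norms(sim$stack, sim$coefficients) >
                cfg$foreground_norm)
  sel <- spdecon:::with_seed(cfg$rng_seed + 1L,
                             sample(fg, min(cfg$train_pixels, length(fg))))
  Y <- spdecon:::stack_pixels(sim$stack, sel) / sim$coefficients
  norms <- sqrt(colSums(Y^2))
  for (ui in c(5L, 20L, 40L)) {
    u <- cfg$norm_grid[ui]
    scores <- vapply(cfg$alpha_grid, function(a) {
      l1 <- vapply(seq_len(ncol(Y)), function(i) {
        w <- decode_pixel(Y[, i], cb, a, a * cfg$alpha_ratio)
        sum(attr(w, "w_ols"))
      }, numeric(1L))
      sum(exp(-((u - norms) / cfg$kernel_bandwidth)^2 / 2) * l1)
    }, numeric(1L))
    best <- cfg$alpha_grid[max(which(scores == max(scores)))]
    expect_equal(lk$alphas[ui], best)
  }
})

test_that("decode_fov zeroes background and is channel-gain invariant", {
  cb <- toy_codebook()
  cfg <- spd_config(rng_seed = 1)
  empty <- fov_stack(array(0, dim = c(32, 32, 18)))
  maps <- decode_fov(empty, cb, config = cfg)
  expect_identical(nrow(maps$entries), 0L)

  truth <- data.frame(spot_id = 1L, row = 16, col = 16, barcode_index = 1L,
                      peak = 0.5, sigma = 2)
  arr <- render_spots(truth, cb, c(32, 32))
  maps1 <- decode_fov(fov_stack(arr), cb, config = cfg)
  expect_true(all(maps1$entries$barcode == 1L))
  expect_true(all(maps1$entries$weight >= 0))
  expect_lt(abs(max(maps1$entries$weight) - 0.5) / 0.5, 0.1)
  # doubling all gains and telling the decoder gives identical maps
  maps2 <- decode_fov(fov_stack(pmin(arr * 2, 1)), cb,
                      coefficients = rep(2, 18), config = cfg)
  expect_equal(maps1$entries, maps2$entries)
  expect_error(decode_fov(fov_stack(array(0, c(8, 8, 12))), cb),
               "rounds")
})

test_that("at most two barcodes survive per pixel and weights are non-negative", {
  cb <- assign_genes(enumerate_barcodes(6, 3, TRUE)[1:30],
                     sprintf("g%d", 1:30), rng_seed = 1)
  sim <- simulate_fov(cb, 800L, shape = c(128, 128), rng_seed = 12)
  maps <- decode_fov(sim$stack, cb, sim$coefficients,
                     config = spd_config(rng_seed = 1))
  expect_true(all(maps$entries$weight >= 0))
  per_pixel <- table(paste(maps$entries$row, maps$entries$col))
  expect_lte(max(per_pixel), 2L)
})
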