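#' Decoder configuration
#'
#' Collects every tunable of the sparse-deconvolution decoder. The per-pixel
#' problem solved is
#'   min_\{w >= 0\} 1/(2*3n) ||y - X w||^2 + alpha ||w||_1 + (alpha2/2) ||w||_2^2
#' with alpha2 = alpha * alpha_ratio. Under this scaling a pixel made purely
#' of one barcode with weight w stays undetected (at alpha2 = 0) exactly when
#' w < (3n/k) * alpha, which anchors the choice of alpha.
#'
#' @param alpha base L1 penalty, used whenever no norm-adaptive lookup is
#'   supplied (default 0.05).
#' @param alpha_ratio alpha2/alpha, the small ridge stabilizer (default
#'   1/100).
#' @param foreground_norm pixels with ||y||_2 at or below this are background
#'   (default 0.25).
#' @param elbow_second_ratio keep only the top weight when the second is
#'   below this fraction of it (default 0.5).
#' @param elbow_third_ratio keep the top two when the third is below this
#'   fraction of the top (default 0.3).
#' @param coeff_iterations channel-gain estimation iterations (default 2).
#' @param coeff_weight_window OLS-weight window selecting pixels with one
#'   dominant unsaturated weight (default c(0.1, 0.5)).
#' @param alpha_grid candidate alphas for the adaptive lookup (default 0.01
#'   to 0.1 in steps of 0.005).
#' @param norm_grid pixel-norm grid for the lookup (default 50 steps spanning
#'   0 to 2.8).
#' @param kernel_bandwidth Gaussian bandwidth weighting training pixels by
#'   norm proximity (default 0.1, about two norm-grid steps).
#' @param train_pixels foreground pixels sampled for gain and alpha training
#'   (default 50000, or all if fewer).
#' @param tol coordinate-descent convergence tolerance (max coordinate
#'   change; default 1e-8).
#' @param obj_tol alternative stopping rule: end when a full sweep lowers the
#'   objective by less than this (default 1e-12; ends the near-flat drift of
#'   ridge-degenerate supports on crowded pixels).
#' @param maxit coordinate-descent sweep cap (default 2000).
#' @param rng_seed integer seed for the training-pixel samples (default 0).
#' @return object of class `spd_config`.
#' @export
spd_config <- function(alpha = 0.05, alpha_ratio = 1 / 100,
                       foreground_norm = 0.25,
                       elbow_second_ratio = 0.5, elbow_third_ratio = 0.3,
                       coeff_iterations = 2L,
                       coeff_weight_window = c(0.1, 0.5),
                       alpha_grid = seq(0.01, 0.1, by = 0.005),
                       norm_grid = seq(0, 2.8, length.out = 50L),
                       kernel_bandwidth = 0.1,
                       train_pixels = 50000L,
                       tol = 1e-8, obj_tol = 1e-12, maxit = 2000L,
                       rng_seed = 0L) {
  cfg <- list(alpha = alpha, alpha_ratio = alpha_ratio,
              foreground_norm = foreground_norm,
              elbow_second_ratio = elbow_second_ratio,
              elbow_third_ratio = elbow_third_ratio,
              coeff_iterations = as.integer(coeff_iterations),
              coeff_weight_window = coeff_weight_window,
              alpha_grid = alpha_grid, norm_grid = norm_grid,
              kernel_bandwidth = kernel_bandwidth,
              train_pixels = as.integer(train_pixels),
              tol = tol, obj_tol = obj_tol, maxit = as.integer(maxit),
              rng_seed = as.integer(rng_seed))
  stopifnot(alpha >= 0, alpha_ratio >= 0, foreground_norm > 0,
            elbow_second_ratio > 0, elbow_third_ratio > 0,
            all(diff(alpha_grid) > 0), kernel_bandwidth > 0, tol > 0,
            obj_tol > 0)
  structure(cfg, class = "spd_config")
}

#' Largest undetectable pure-barcode weight
#'
#' For a pixel made purely of one barcode, the non-negative lasso (ridge term
#' zero) returns an all-zero solution exactly when the underlying weight is
#' below (3n/k) * alpha.
#'
#' @param n number of rounds.
#' @param k number of on rounds.
#' @param alpha L1 penalty.
#' @return the detection threshold 3*n*alpha/k.
#' @examples
#' max_undetected_weight(6, 3, 0.05)  # 0.3
#' @export
max_undetected_weight <- function(n, k, alpha) {
  if (k <= 0) stop("`k` must be positive")
  3 * n * alpha / k
}

#' Decode a single pixel by non-negative elastic net
#'
#' @param y numeric 3n-vector of pixel intensities in \[0, 1\].
#' @param X codebook matrix (3n x N) or a [codebook()].
#' @param alpha L1 penalty.
#' @param alpha2 ridge penalty (default alpha/100).
#' @param tol,obj_tol,maxit solver controls (see [spd_config()]).
#' @return the sparse weight vector w_lasso (length N), with attributes
#'   `support` (elbow-filtered barcode indices, up to 2), `w_ols` (their
#'   refit weights) and `converged`. A non-convergent pixel returns zeros
#'   with a warning.
#' @export
decode_pixel <- function(y, X, alpha, alpha2 = alpha / 100,
                         tol = 1e-8, obj_tol = 1e-12, maxit = 2000L) {
  if (inherits(X, "codebook")) X <- X$X
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (alpha < 0) stop("`alpha` must be >= 0")
  ratio <- if (alpha > 0) alpha2 / alpha else 0
  res <- cpp_spd_batch(crossprod(X, matrix(y)), crossprod(X), nrow(X),
                       alpha, ratio, 0.5, 0.3, tol, obj_tol,
                       as.integer(maxit), TRUE)
  w <- numeric(ncol(X))
  if (!res$converged[1L]) {
    warning("pixel solver did not converge; returning zero weights")
  } else {
    w[res$lasso$barcode] <- res$lasso$weight
  }
  sup <- res$support[, 1L]
  structure(w, support = sup[sup > 0L],
            w_ols = res$w_ols[sup > 0L, 1L],
            converged = res$converged[1L] == 1L)
}

#' Elbow filter on a pixel's weight vector
#'
#' Accepts the top weight alone when the second largest is below half of it;
#' otherwise accepts the top two when the third largest is below 30% of the
#' top; otherwise rejects the pixel. Ratios are configurable.
#'
#' @param w non-negative weight vector.
#' @param second_ratio,third_ratio acceptance ratios (defaults 0.5, 0.3).
#' @return integer vector of 0, 1 or 2 indices into `w` (decreasing weight,
#'   ties broken toward the smaller index).
#' @export
elbow_filter <- function(w, second_ratio = 0.5, third_ratio = 0.3) {
  if (any(w < 0)) stop("`w` must be non-negative")
  if (length(w) == 0L || max(w) <= 0) return(integer(0))
  ord <- order(-w, seq_along(w))
  top <- w[ord[1L]]
  w2 <- if (length(w) >= 2L) w[ord[2L]] else 0
  w3 <- if (length(w) >= 3L) w[ord[3L]] else 0
  if (w2 < second_ratio * top) return(ord[1L])
  if (w3 < third_ratio * top) return(ord[1:2])
  integer(0)
}

#' OLS refit on an accepted support
#'
#' Ordinary least squares of the pixel on the one or two supported barcode
#' columns, giving unbiased weights after the shrinkage of the elastic net.
#' Negative refit weights are physically meaningless and are removed by
#' support reduction (refit on the remaining column); near-collinear supports
#' fall back to the first index.
#'
#' @param y pixel vector.
#' @param X codebook matrix or [codebook()].
#' @param support integer indices (length 1 or 2).
#' @return named numeric vector of refit weights on (a subset of) `support`.
#' @export
ols_refit <- function(y, X, support) {
  if (inherits(X, "codebook")) X <- X$X
  if (!length(support) %in% 1:2) stop("support must hold 1 or 2 indices")
  S <- X[, support, drop = FALSE]
  G <- crossprod(S)
  if (length(support) == 2L &&
      abs(det(G)) <= 1e-12 * G[1L, 1L] * G[2L, 2L]) {
    support <- support[1L]
    S <- X[, support, drop = FALSE]
    G <- crossprod(S)
  }
  b <- drop(solve(G, crossprod(S, y)))
  names(b) <- as.character(support)
  if (any(b < 0)) {
    keep <- which(b > 0)
    if (length(keep) == 0L) return(setNames(numeric(0), character(0)))
    return(ols_refit(y, X, support[keep[1L]]))
  }
  b
}

# Batch solve with pixel deduplication: identical (pixel vector, alpha)
# pairs — ubiquitous once crowded pixels clip to full scale — are solved
# once and fanned back out.
spd_batch <- function(Y, X, alphas, config, keep_lasso = FALSE) {
  DT <- data.table::as.data.table(t(Y))
  DT[["..alpha"]] <- alphas
  gid <- data.table::frankv(DT, ties.method = "dense")
  rep_idx <- which(!duplicated(gid))
  rep_idx <- rep_idx[order(gid[rep_idx])]       # representative per group
  res <- cpp_spd_batch(crossprod(X, Y[, rep_idx, drop = FALSE]), crossprod(X),
                       nrow(X), alphas[rep_idx], config$alpha_ratio,
                       config$elbow_second_ratio, config$elbow_third_ratio,
                       config$tol, config$obj_tol, config$maxit, keep_lasso)
  out <- list(support = res$support[, gid, drop = FALSE],
              w_ols = res$w_ols[, gid, drop = FALSE],
              l1_lasso = res$l1_lasso[gid],
              nnz = res$nnz[gid],
              converged = res$converged[gid])
  if (keep_lasso) out$lasso <- res$lasso   # representative-indexed
  out
}

# pixel matrix (3n x P) of selected pixel indices from an fov_stack
stack_pixels <- function(stack, idx) {
  C <- 3L * stack$n_rounds
  out <- matrix(0, C, length(idx))
  for (p in seq_len(C)) out[p, ] <- stack$data[, , p][idx]
  out
}

# per-pixel L2 norms over planes (optionally gain-normalized), H x W matrix
stack_norms <- function(stack, coefficients = NULL) {
  C <- 3L * stack$n_rounds
  if (is.null(coefficients)) coefficients <- rep(1, C)
  acc <- matrix(0, stack$H, stack$W)
  for (p in seq_len(C)) acc <- acc + (stack$data[, , p] / coefficients[p])^2
  sqrt(acc)
}

#' Estimate channel-specific gain coefficients
#'
#' Models per-plane brightness variation as y = c * X w (elementwise). Starting
#' from c = 1, a fixed random sample of foreground pixels is repeatedly
#' (1) normalized by the current c, (2) decoded, (3) reduced to pixels with a
#' single dominant unsaturated OLS weight inside `coeff_weight_window`, and
#' (4) used to update each c_j by a scalar least-squares fit of the observed
#' intensities on the model intensities m = X w.
#'
#' @param stack a [fov_stack()] with foreground pixels.
#' @param codebook a [codebook()].
#' @param config an [spd_config()].
#' @return length-3n positive coefficient vector; attribute `n_qualifying`
#'   records the pixels used per iteration. Planes with no qualifying pixel
#'   keep their current value with a warning.
#' @export
estimate_channel_coefficients <- function(stack, codebook, config = spd_config()) {
  C <- 3L * codebook$n
  if (3L * stack$n_rounds != C) stop("stack and codebook disagree on rounds")
  # single unsaturated rolonies have norm <= ~0.5*sqrt(k); anything brighter
  # than the top of the norm grid cannot qualify and is not sampled
  nm <- stack_norms(stack)
  fg <- which(nm > config$foreground_norm & nm <= max(config$norm_grid))
  if (length(fg) == 0L) fg <- which(nm > config$foreground_norm)
  if (length(fg) == 0L) stop("stack has no foreground pixels")
  n_take <- min(config$train_pixels, length(fg))
  sel <- with_seed(config$rng_seed, sample(fg, n_take))
  Y <- stack_pixels(stack, sel)
  cvec <- rep(1, C)
  nq <- integer(0)
  for (it in seq_len(config$coeff_iterations)) {
    res <- spd_batch(Y / cvec, codebook$X, rep(config$alpha, ncol(Y)),
                     config)
    one <- res$support[1L, ] > 0L & res$support[2L, ] == 0L &
      res$w_ols[1L, ] >= config$coeff_weight_window[1L] &
      res$w_ols[1L, ] <= config$coeff_weight_window[2L]
    nq <- c(nq, sum(one))
    if (!any(one)) {
      warning("no qualifying pixels; channel coefficients left unchanged")
      next
    }
    M <- codebook$X[, res$support[1L, one], drop = FALSE] *
      rep(res$w_ols[1L, one], each = C)   # model intensities X w, 3n x q
    Yq <- Y[, one, drop = FALSE]
    num <- rowSums(Yq * M)
    den <- rowSums(M * M)
    upd <- den > 0
    if (!all(upd))
      warning(sprintf("%d plane(s) had no qualifying pixels; kept previous value",
                      sum(!upd)))
    cvec[upd] <- num[upd] / den[upd]
  }
  structure(cvec, n_qualifying = nq)
}

#' Build the norm-adaptive regularization lookup
#'
#' For every pixel norm u on `norm_grid`, chooses the alpha on `alpha_grid`
#' maximizing the Gaussian-weighted sum (bandwidth `kernel_bandwidth`,
#' centered at u) of the L1 norms of the elbow-filtered OLS refits of a
#' training sample of foreground pixels. Ties go to the larger alpha (the
#' sparser solution).
#'
#' @param stack a [fov_stack()].
#' @param codebook a [codebook()].
#' @param coefficients channel gains from
#'   [estimate_channel_coefficients()] (default: all 1).
#' @param config an [spd_config()].
#' @return object of class `alpha_lookup`: list(norms, alphas).
#' @export
build_alpha_lookup <- function(stack, codebook, coefficients = NULL,
                               config = spd_config()) {
  C <- 3L * codebook$n
  if (is.null(coefficients)) coefficients <- rep(1, C)
  # pixels several kernel bandwidths beyond the top grid norm get negligible
  # kernel weight at every u on the grid and are not trained on
  nm <- stack_norms(stack, coefficients)
  fg <- which(nm > config$foreground_norm &
                nm <= max(config$norm_grid) + 5 * config$kernel_bandwidth)
  if (length(fg) == 0L) fg <- which(nm > config$foreground_norm)
  if (length(fg) == 0L) stop("no foreground pixels to train the lookup on")
  n_take <- min(config$train_pixels, length(fg))
  sel <- with_seed(config$rng_seed + 1L, sample(fg, n_take))
  Y <- stack_pixels(stack, sel) / coefficients
  norms <- sqrt(colSums(Y^2))
  grid <- sort(config$alpha_grid)
  # duplicate pixels (clipped, identical vectors) are trained once
  gid <- data.table::frankv(data.table::as.data.table(t(Y)),
                            ties.method = "dense")
  rep_idx <- which(!duplicated(gid))
  rep_idx <- rep_idx[order(gid[rep_idx])]
  L1 <- cpp_spd_grid_l1(crossprod(codebook$X, Y[, rep_idx, drop = FALSE]),
                        crossprod(codebook$X), C,
                        rev(grid), config$alpha_ratio,
                        config$elbow_second_ratio, config$elbow_third_ratio,
                        config$tol, config$obj_tol, config$maxit)
  L1 <- L1[gid, rev(seq_along(grid)), drop = FALSE]  # expand, ascending alpha
  alphas <- vapply(config$norm_grid, function(u) {
    g <- exp(-((u - norms) / config$kernel_bandwidth)^2 / 2)
    score <- as.numeric(crossprod(L1, g))
    grid[length(score) + 1L - which.max(rev(score))]  # ties -> larger alpha
  }, numeric(1L))
  structure(list(norms = config$norm_grid, alphas = alphas),
            class = "alpha_lookup")
}

#' Query the alpha lookup at pixel norms
#'
#' @param lookup an `alpha_lookup`.
#' @param u numeric vector of pixel norms; values outside the grid clamp to
#'   the nearest endpoint.
#' @return alphas at the nearest grid norms.
#' @export
lookup_alpha <- function(lookup, u) {
  stopifnot(inherits(lookup, "alpha_lookup"))
  g <- lookup$norms
  mid <- (g[-1L] + g[-length(g)]) / 2
  idx <- findInterval(u, mid) + 1L
  lookup$alphas[idx]
}

#' Decode a full field of view
#'
#' Background pixels (norm at or below `foreground_norm`) get zero weights.
#' Every foreground pixel is normalized by the channel coefficients, decoded
#' with the alpha given by the lookup at its norm (or the fixed
#' `config$alpha` when no lookup is supplied), elbow-filtered, and OLS-refit.
#'
#' @param stack a [fov_stack()].
#' @param codebook a [codebook()].
#' @param coefficients channel gains (default all 1).
#' @param lookup an `alpha_lookup` or NULL for a constant alpha.
#' @param config an [spd_config()].
#' @param chunk pixels decoded per solver call (memory knob).
#' @return object of class `weight_maps`: list with `entries` (data frame
#'   `row,col,barcode,weight` of OLS weights, 1-based matrix indices, at most
#'   two barcodes per pixel), `dim`, `codebook`, `coefficients`,
#'   `n_foreground`, `n_nonconverged`.
#' @export
decode_fov <- function(stack, codebook, coefficients = NULL, lookup = NULL,
                       config = spd_config(), chunk = 50000L) {
  C <- 3L * codebook$n
  if (3L * stack$n_rounds != C) stop("stack and codebook disagree on rounds")
  if (is.null(coefficients)) coefficients <- rep(1, C)
  if (length(coefficients) != C || any(coefficients <= 0))
    stop("coefficients must be a positive length-3n vector")
  # foreground is judged on gain-normalized intensities so a decode is
  # invariant to jointly rescaling the stack and its coefficients
  fg <- which(stack_norms(stack, coefficients) > config$foreground_norm)
  ent <- list()
  nonconv <- 0L
  i <- 1L
  while (i <= length(fg)) {
    sel <- fg[i:min(i + chunk - 1L, length(fg))]
    Y <- stack_pixels(stack, sel) / coefficients
    alphas <- if (is.null(lookup)) rep(config$alpha, ncol(Y))
              else lookup_alpha(lookup, sqrt(colSums(Y^2)))
    res <- spd_batch(Y, codebook$X, alphas, config)
    nonconv <- nonconv + sum(res$converged == 0L)
    for (lev in 1:2) {
      hit <- which(res$support[lev, ] > 0L)
      if (length(hit))
        ent[[length(ent) + 1L]] <-
          data.frame(pixel = sel[hit], barcode = res$support[lev, hit],
                     weight = res$w_ols[lev, hit])
    }
    i <- i + chunk
  }
  ent <- if (length(ent)) do.call(rbind, ent) else
    data.frame(pixel = integer(0), barcode = integer(0), weight = numeric(0))
  ent <- ent[order(ent$pixel, ent$barcode), , drop = FALSE]
  entries <- data.frame(row = ((ent$pixel - 1L) %% stack$H) + 1L,
                        col = ((ent$pixel - 1L) %/% stack$H) + 1L,
                        barcode = ent$barcode, weight = ent$weight)
  if (nonconv > 0L)
    warning(sprintf("%d pixel(s) did not converge and were zeroed", nonconv))
  structure(list(entries = entries, dim = c(stack$H, stack$W),
                 codebook = codebook, coefficients = coefficients,
                 n_foreground = length(fg), n_nonconverged = nonconv),
            class = "weight_maps")
}

#' @export
print.weight_maps <- function(x, ...) {
  cat(sprintf("weight_maps: %d x %d FOV, %d non-zero entries over %d barcodes\n",
              x$dim[1L], x$dim[2L], nrow(x$entries),
              length(unique(x$entries$barcode))))
  invisible(x)
}

# dense H x W map of one barcode's OLS weights
barcode_map <- function(maps, barcode) {
  m <- matrix(0, maps$dim[1L], maps$dim[2L])
  e <- maps$entries[maps$entries$barcode == barcode, , drop = FALSE]
  m[cbind(e$row, e$col)] <- e$weight
  m
}
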