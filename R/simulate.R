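#' FOV stack container
#'
#' Holds an n-round, 3-channel image stack as an (H, W, 3n) array with values
#' in \[0, 1\]. Plane 3*(round-1)+channel carries round `round`, channel
#' `channel`; a pixel's 3n values stacked over planes form the vector y that
#' the decoder works on.
#'
#' @param data numeric array (H, W, 3n).
#' @return object of class `fov_stack` with fields `data`, `n_rounds`, `H`,
#'   `W`.
#' @export
fov_stack <- function(data) {
  d <- dim(data)
  if (length(d) != 3L || d[3L] %% 3L != 0L)
    stop("`data` must be an (H, W, 3n) array with 3n planes")
  structure(list(data = data, n_rounds = as.integer(d[3L] / 3L),
                 H = as.integer(d[1L]), W = as.integer(d[2L])),
            class = "fov_stack")
}

#' @export
print.fov_stack <- function(x, ...) {
  cat(sprintf("fov_stack: %d x %d pixels, %d rounds x 3 channels (%d planes)\n",
              x$H, x$W, x$n_rounds, 3L * x$n_rounds))
  invisible(x)
}

#' Render a truth table of Gaussian rolonies into a raw stack
#'
#' Purely additive and linear: each spot adds an isotropic Gaussian with the
#' given peak value (truncated at 4 sigma, not renormalized) to every on
#' plane of its barcode. No channel gains, noise, or clipping are applied, so
#' rendering two disjoint spot sets and summing the stacks equals rendering
#' their union exactly.
#'
#' @param truth data frame with columns `row`, `col` (0-based pixel-centered),
#'   `barcode_index`, `peak`, `sigma`.
#' @param codebook a [codebook()].
#' @param shape c(H, W) in pixels.
#' @return an (H, W, 3n) array.
#' @export
render_spots <- function(truth, codebook, shape) {
  H <- as.integer(shape[1L]); W <- as.integer(shape[2L])
  C <- 3L * codebook$n
  arr <- array(0, dim = c(H, W, C))
  if (nrow(truth) > 0L) {
    on_planes <- apply(codebook$X, 2L, function(x) which(x == 1))
    planes <- t(on_planes[, truth$barcode_index, drop = FALSE])
    arr <- cpp_render_spots(arr, H, W, as.numeric(truth$row),
                            as.numeric(truth$col), as.numeric(truth$peak),
                            as.numeric(truth$sigma),
                            matrix(as.integer(planes), nrow(truth)))
    dim(arr) <- c(H, W, C)
  }
  arr
}

#' Simulate one field of view with known ground truth
#'
#' Emulates the benchmark conditions for decoder comparison: spots are placed
#' uniformly over the FOV with gene identity uniform over the non-empty
#' barcodes; each rolony is an isotropic Gaussian with peak intensity drawn
#' from `intensity_range` and sigma from `sigma_range`; per-plane channel
#' gains are drawn from `coeff_range` and multiply their planes; intensities
#' above 1 are clipped.
#'
#' @param codebook a [codebook()] with at least one non-empty barcode.
#' @param n_spots number of ground-truth rolonies.
#' @param shape c(H, W) pixels (default 1024 x 1024).
#' @param intensity_range peak intensity bounds (default c(0.25, 0.7)).
#' @param sigma_range Gaussian sigma bounds in pixels (default c(2, 2.5)).
#' @param coeff_range channel-gain bounds (default c(0.75, 1.25)).
#' @param noise_sd optional additive Gaussian pixel noise (default 0, none).
#' @param rng_seed integer seed; the simulation is fully deterministic given
#'   it.
#' @return list with `stack` (a [fov_stack()]), `truth` (data frame
#'   `spot_id,row,col,barcode_index,barcode,gene,peak,sigma`), `coefficients`
#'   (length-3n gain vector) and `rng_seed`.
#' @export
simulate_fov <- function(codebook, n_spots, shape = c(1024L, 1024L),
                         intensity_range = c(0.25, 0.7),
                         sigma_range = c(2, 2.5),
                         coeff_range = c(0.75, 1.25),
                         noise_sd = 0, rng_seed = 0L) {
  stopifnot(inherits(codebook, "codebook"))
  if (!any(!codebook$is_empty)) stop("codebook has no non-empty barcode")
  if (n_spots < 0) stop("`n_spots` must be >= 0")
  H <- as.integer(shape[1L]); W <- as.integer(shape[2L])
  genes_idx <- which(!codebook$is_empty)
  sim <- with_seed(rng_seed, {
    list(row = runif(n_spots, 0, H - 1),
         col = runif(n_spots, 0, W - 1),
         bc = if (n_spots > 0) sample(genes_idx, n_spots, replace = TRUE) else integer(0),
         peak = runif(n_spots, intensity_range[1L], intensity_range[2L]),
         sigma = runif(n_spots, sigma_range[1L], sigma_range[2L]),
         coef = runif(3L * codebook$n, coeff_range[1L], coeff_range[2L]),
         noise = if (noise_sd > 0) rnorm(H * W * 3L * codebook$n, 0, noise_sd))
  })
  truth <- data.frame(spot_id = seq_len(n_spots),
                      row = sim$row, col = sim$col,
                      barcode_index = sim$bc,
                      barcode = codebook$barcodes[sim$bc],
                      gene = codebook$genes[sim$bc],
                      peak = sim$peak, sigma = sim$sigma,
                      stringsAsFactors = FALSE)
  arr <- render_spots(truth, codebook, c(H, W))
  arr <- sweep(arr, 3L, sim$coef, "*")
  if (noise_sd > 0) arr <- arr + sim$noise
  arr[arr > 1] <- 1
  arr[arr < 0] <- 0
  list(stack = fov_stack(arr), truth = truth, coefficients = sim$coef,
       rng_seed = rng_seed)
}

#' Simulate a series of FOVs at different rolony densities
#'
#' One independent simulation per requested density, with sub-seeds derived
#' as `rng_seed + index` and recorded in each element.
#'
#' @param codebook a [codebook()].
#' @param n_spots_list integer vector of spot counts.
#' @param shape c(H, W).
#' @param rng_seed base integer seed.
#' @param ... passed to [simulate_fov()].
#' @return list of [simulate_fov()] results, one per density.
#' @export
density_grid <- function(codebook, n_spots_list, shape = c(1024L, 1024L),
                         rng_seed = 0L, ...) {
  lapply(seq_along(n_spots_list), function(i)
    simulate_fov(codebook, n_spots_list[i], shape = shape,
                 rng_seed = rng_seed + i, ...))
}

#' Benchmark codebook matching the decoder-comparison conditions
#'
#' A 6-round, 3-on codebook with 121 synthetic gene names plus 10 empty
#' barcodes, designed by the full pipeline (multicolor enumeration, seed set,
#' randomized MIS, random gene assignment).
#'
#' @param rng_seed integer seed for the design.
#' @param n_runs randomized MIS runs.
#' @return a [codebook()].
#' @export
benchmark_codebook <- function(rng_seed = 0L, n_runs = 20000L) {
  design_codebook(6L, 3L, sprintf("gene%03d", 1:121), n_empty = 10L,
                  n_runs = n_runs, rng_seed = rng_seed)
}
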