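#' Match ground-truth spots to decoded spots
#'
#' Greedy nearest-first one-to-one matching: candidate pairs share a barcode
#' and lie strictly closer than `max_dist_px`; pairs are accepted in order of
#' increasing distance (ties by truth then decoded id), each spot used at
#' most once.
#'
#' @param truth data frame with `row`, `col`, `barcode_index` (simulator
#'   truth).
#' @param decoded spot table with the same columns.
#' @param max_dist_px matching radius in pixels (default 6).
#' @return data frame `truth_id, decoded_id, barcode_index, dist` (row
#'   numbers into the inputs).
#' @export
match_spots <- function(truth, decoded, max_dist_px = 6) {
  if (max_dist_px <= 0) stop("max_dist_px must be positive")
  empty <- data.frame(truth_id = integer(0), decoded_id = integer(0),
                      barcode_index = integer(0), dist = numeric(0))
  if (nrow(truth) == 0L || nrow(decoded) == 0L) return(empty)
  cand <- list()
  for (b in intersect(unique(truth$barcode_index),
                      unique(decoded$barcode_index))) {
    ti <- which(truth$barcode_index == b)
    di <- which(decoded$barcode_index == b)
    d2 <- outer(truth$row[ti], decoded$row[di], "-")^2 +
      outer(truth$col[ti], decoded$col[di], "-")^2
    hit <- which(d2 < max_dist_px^2, arr.ind = TRUE)
    if (nrow(hit))
      cand[[length(cand) + 1L]] <-
        data.frame(truth_id = ti[hit[, 1L]], decoded_id = di[hit[, 2L]],
                   barcode_index = b, dist = sqrt(d2[hit]))
  }
  if (length(cand) == 0L) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$dist, cand$truth_id, cand$decoded_id), , drop = FALSE]
  used_t <- logical(nrow(truth)); used_d <- logical(nrow(decoded))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    t <- cand$truth_id[i]; d <- cand$decoded_id[i]
    if (!used_t[t] && !used_d[d]) {
      keep[i] <- TRUE
      used_t[t] <- TRUE; used_d[d] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benchmark metrics for one decode
#'
#' Sensitivity is the fraction of ground-truth spots matched; specificity is
#' the fraction of decoded spots that are matched; empty rate is the fraction
#' of decoded spots carrying an empty barcode. Metrics whose denominator is
#' zero are reported as NA, not 0.
#'
#' @param truth,decoded,matches as produced by [match_spots()] on the same
#'   inputs.
#' @param codebook the [codebook()].
#' @return one-row data frame `n_truth, n_decoded, n_matched, sensitivity,
#'   specificity, empty_rate`.
#' @export
compute_metrics <- function(truth, decoded, matches, codebook) {
  nt <- nrow(truth); nd <- nrow(decoded); nm <- nrow(matches)
  data.frame(
    n_truth = nt, n_decoded = nd, n_matched = nm,
    sensitivity = if (nt > 0) nm / nt else NA_real_,
    specificity = if (nd > 0) nm / nd else NA_real_,
    empty_rate = if (nd > 0) mean(codebook$is_empty[decoded$barcode_index])
                 else NA_real_)
}

#' Naive pixel-matching baseline decoder
#'
#' Each foreground pixel's intensity vector and every barcode column are
#' L2-normalized; the pixel is labeled with the nearest barcode when the
#' Euclidean distance between the unit vectors is at or below
#' `distance_threshold` (ties to the smaller barcode index). Labeled pixels
#' are grouped per barcode into 8-connected components, each yielding one
#' spot with a norm-weighted centroid. No post-hoc filtering is applied.
#'
#' @param stack a [fov_stack()].
#' @param codebook a [codebook()].
#' @param distance_threshold unit-vector distance cutoff (default 0.7).
#' @param foreground_norm background threshold on the raw pixel norm
#'   (default 0.25).
#' @param chunk pixels per distance block.
#' @return spot table with the [call_spots()] columns (`max_weight` and
#'   `mean_weight` hold pixel-norm statistics).
#' @export
naive_decode <- function(stack, codebook, distance_threshold = 0.7,
                         foreground_norm = 0.25, chunk = 100000L) {
  nm <- stack_norms(stack)
  fg <- which(nm > foreground_norm)
  Xn <- sweep(codebook$X, 2L, sqrt(colSums(codebook$X^2)), "/")
  lab_img <- matrix(0L, stack$H, stack$W)
  i <- 1L
  while (i <= length(fg)) {
    sel <- fg[i:min(i + chunk - 1L, length(fg))]
    Y <- stack_pixels(stack, sel)
    Y <- sweep(Y, 2L, sqrt(colSums(Y^2)), "/")
    sim <- crossprod(Y, Xn)                    # P x N cosine similarities
    best <- max.col(sim, ties.method = "first")
    d <- sqrt(pmax(0, 2 - 2 * sim[cbind(seq_along(best), best)]))
    ok <- d <= distance_threshold
    lab_img[sel[ok]] <- best[ok]
    i <- i + chunk
  }
  out <- list()
  for (b in sort(unique(lab_img[lab_img > 0L]))) {
    cc <- EBImage::bwlabel(lab_img == b)
    lab <- as.integer(cc)
    hit <- which(lab > 0L)
    lv <- lab[hit]
    w <- nm[hit]
    r0 <- (hit - 1L) %% stack$H
    c0 <- (hit - 1L) %/% stack$H
    area <- as.vector(rowsum(rep(1L, length(hit)), lv))
    wsum <- as.vector(rowsum(w, lv))
    out[[length(out) + 1L]] <- data.frame(
      gene = codebook$genes[b], barcode = codebook$barcodes[b],
      barcode_index = b,
      row = as.vector(rowsum(w * r0, lv)) / wsum,
      col = as.vector(rowsum(w * c0, lv)) / wsum,
      area = area, max_weight = vapply(split(w, lv), max, numeric(1L)),
      mean_weight = wsum / area, stringsAsFactors = FALSE)
  }
  spots <- if (length(out)) do.call(rbind, out) else
    data.frame(gene = character(0), barcode = character(0),
               barcode_index = integer(0), row = numeric(0), col = numeric(0),
               area = integer(0), max_weight = numeric(0),
               mean_weight = numeric(0), stringsAsFactors = FALSE)
  spots <- spots[order(spots$barcode_index, spots$row, spots$col), ,
                 drop = FALSE]
  rownames(spots) <- NULL
  cbind(spot_id = seq_len(nrow(spots)), spots,
        empty_prob = rep(NA_real_, nrow(spots)),
        cell_id = rep(NA_integer_, nrow(spots)))
}

#' Run the full decode on a simulated FOV
#'
#' Convenience wrapper used by the density sweep: estimates channel
#' coefficients, builds the alpha lookup, decodes, calls spots, and — when
#' both empty and non-empty spots exist — trains the emptiness classifier
#' and filters at `filter_threshold`.
#'
#' @param sim a [simulate_fov()] result.
#' @param codebook the [codebook()].
#' @param config an [spd_config()].
#' @param filter_threshold emptiness-probability cutoff (default 0.325).
#' @return list `spots` (kept spot table), `empty_rate`,
#'   `empty_rate_prefilter`, `coefficients`, `lookup`.
#' @export
spd_pipeline <- function(sim, codebook, config = spd_config(),
                         filter_threshold = 0.325) {
  cf <- estimate_channel_coefficients(sim$stack, codebook, config)
  lk <- build_alpha_lookup(sim$stack, codebook, cf, config)
  maps <- decode_fov(sim$stack, codebook, cf, lk, config)
  spots <- call_spots(maps)
  lab <- codebook$is_empty[spots$barcode_index]
  fl <- if (nrow(spots) && length(unique(lab)) == 2L) {
    clf <- train_empty_classifier(spots, codebook, rng_seed = config$rng_seed)
    filter_spots(spots, clf, filter_threshold, codebook)
  } else {
    filter_spots(spots, NULL, filter_threshold, codebook)
  }
  list(spots = fl$spots, empty_rate = fl$empty_rate,
       empty_rate_prefilter = fl$empty_rate_prefilter,
       coefficients = cf, lookup = lk)
}

#' Density sweep benchmarking decoders against simulated truth
#'
#' For each density, one FOV is simulated (sub-seed `rng_seed + index`) and
#' shared by all decoders; each decoder's spots are matched to the truth and
#' scored.
#'
#' @param codebook a [codebook()].
#' @param densities integer vector of spot counts per FOV.
#' @param decoders subset of c("spd", "naive").
#' @param shape FOV shape in pixels.
#' @param config an [spd_config()].
#' @param rng_seed base seed.
#' @param max_dist_px matching radius (default 6).
#' @return tidy data frame: one row per density x decoder with
#'   `density, decoder, n_truth, n_decoded, n_matched, sensitivity,
#'   specificity, empty_rate`.
#' @export
run_density_sweep <- function(codebook, densities, decoders = c("spd", "naive"),
                              shape = c(1024L, 1024L), config = spd_config(),
                              rng_seed = 0L, max_dist_px = 6) {
  if (length(densities) == 0L) stop("`densities` must be non-empty")
  decoders <- match.arg(decoders, c("spd", "naive"), several.ok = TRUE)
  rows <- list()
  for (i in seq_along(densities)) {
    sim <- simulate_fov(codebook, densities[i], shape = shape,
                        rng_seed = rng_seed + i)
    for (dec in decoders) {
      spots <- if (dec == "spd") spd_pipeline(sim, codebook, config)$spots
               else naive_decode(sim$stack, codebook,
                                 foreground_norm = config$foreground_norm)
      m <- match_spots(sim$truth, spots, max_dist_px)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(density = densities[i], decoder = dec),
              compute_metrics(sim$truth, spots, m, codebook))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
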