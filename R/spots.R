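#' Call spots from decoded weight maps
#'
#' Per barcode: the OLS weight map is Gaussian-smoothed, local maxima (within
#' a Chebyshev radius of `min_peak_distance`) are taken as markers, and the
#' positive region of the smoothed map is partitioned by marker-seeded
#' watershed-style propagation. Each segmented region becomes one spot with
#' area, weight-weighted centroid, and the maximum and mean of the
#' unsmoothed OLS weights over the region.
#'
#' @param maps a `weight_maps` object from [decode_fov()].
#' @param smoothing_sigma Gaussian sigma in pixels (default 1).
#' @param min_peak_distance minimum peak separation in pixels (default 2).
#' @return data frame with columns `spot_id, gene, barcode, barcode_index,
#'   row, col, area, max_weight, mean_weight, empty_prob, cell_id`.
#'   Coordinates are 0-based pixel-centered floats.
#' @export
call_spots <- function(maps, smoothing_sigma = 1, min_peak_distance = 2L) {
  stopifnot(inherits(maps, "weight_maps"))
  cb <- maps$codebook
  out <- list()
  margin <- as.integer(ceiling(4 * smoothing_sigma)) + min_peak_distance
  for (b in sort(unique(maps$entries$barcode))) {
    e <- maps$entries[maps$entries$barcode == b, , drop = FALSE]
    # work on the padded bounding box of the barcode's support
    rr <- range(e$row); cc <- range(e$col)
    r1 <- max(1L, rr[1L] - margin); r2 <- min(maps$dim[1L], rr[2L] + margin)
    c1 <- max(1L, cc[1L] - margin); c2 <- min(maps$dim[2L], cc[2L] + margin)
    d <- matrix(0, r2 - r1 + 1L, c2 - c1 + 1L)
    d[cbind(e$row - r1 + 1L, e$col - c1 + 1L)] <- e$weight
    sm <- EBImage::gblur(d, sigma = smoothing_sigma)
    # the FFT smoother leaves numerical ripple; floor it well below any
    # real weight so background stays exactly zero
    sm[sm < 1e-6] <- 0
    pk <- local_maxima(sm, min_peak_distance)
    if (!any(pk)) next
    markers <- EBImage::bwlabel(pk)
    seg <- EBImage::propagate(sm, seeds = markers, mask = sm > 0)
    lab <- as.integer(seg)
    hit <- which(lab > 0L)
    if (length(hit) == 0L) next
    lv <- lab[hit]
    w <- d[hit]
    r0 <- ((hit - 1L) %% nrow(d)) + (r1 - 1L)   # 0-based FOV row
    c0 <- ((hit - 1L) %/% nrow(d)) + (c1 - 1L)  # 0-based FOV col
    area <- as.vector(rowsum(rep(1L, length(hit)), lv))
    wsum <- as.vector(rowsum(w, lv))
    wr <- as.vector(rowsum(w * r0, lv))
    wc <- as.vector(rowsum(w * c0, lv))
    wmax <- vapply(split(w, lv), max, numeric(1L))
    # regions whose unsmoothed weights are all zero are smoothing artifacts
    keep <- wmax > 0
    if (!any(keep)) next
    crow <- (wr / wsum)[keep]
    ccol <- (wc / wsum)[keep]
    out[[length(out) + 1L]] <- data.frame(
      gene = cb$genes[b], barcode = cb$barcodes[b], barcode_index = b,
      row = crow, col = ccol, area = area[keep], max_weight = wmax[keep],
      mean_weight = (wsum / area)[keep], stringsAsFactors = FALSE)
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

# strict-interior local maxima by shifted comparison within Chebyshev radius r;
# plateaus of equal neighbors survive jointly and later merge into one marker
local_maxima <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  pk <- m > 0
  for (dr in -r:r) for (dc in -r:r) {
    if (dr == 0L && dc == 0L) next
    sh <- matrix(-Inf, H, W)
    rs <- max(1L, 1L + dr):min(H, H + dr)
    cs <- max(1L, 1L + dc):min(W, W + dc)
    sh[rs, cs] <- m[rs - dr, cs - dc]
    pk <- pk & (m >= sh)
  }
  pk
}

#' Train the empty-barcode spot classifier
#'
#' Fits a seeded random forest on (area, max_weight, mean_weight) to predict
#' whether a spot carries an empty barcode. Spots decoded to empty barcodes
#' are known false positives; their feature distribution (smaller, dimmer)
#' lets the forest score every spot with an emptiness probability.
#'
#' @param spots spot table from [call_spots()].
#' @param codebook the [codebook()] (provides the empty flags).
#' @param sample_fraction fraction of spots used for training (per class,
#'   default 0.5).
#' @param rng_seed integer seed.
#' @param ntree forest size (default 100).
#' @return object of class `empty_classifier`.
#' @export
train_empty_classifier <- function(spots, codebook, sample_fraction = 0.5,
                                   rng_seed = 0L, ntree = 100L) {
  lab <- codebook$is_empty[spots$barcode_index]
  if (length(unique(lab)) < 2L)
    stop("training data has a single class; skip filtering ",
         "(use filter_spots with classifier = NULL for a pass-through)")
  feats <- spots[, c("area", "max_weight", "mean_weight")]
  model <- with_seed(rng_seed, {
    take <- unlist(lapply(split(seq_len(nrow(spots)), lab), function(ix)
      sample(ix, max(1L, ceiling(sample_fraction * length(ix))))))
    randomForest::randomForest(feats[take, , drop = FALSE],
                               factor(lab[take], levels = c(FALSE, TRUE)),
                               ntree = ntree)
  })
  structure(list(model = model, threshold = 0.325,
                 sample_fraction = sample_fraction, rng_seed = rng_seed),
            class = "empty_classifier")
}

#' Emptiness probabilities for a spot table
#'
#' @param classifier an `empty_classifier`.
#' @param spots spot table.
#' @return numeric vector in \[0, 1\].
#' @export
predict_emptiness <- function(classifier, spots) {
  stopifnot(inherits(classifier, "empty_classifier"))
  unname(predict(classifier$model,
                 spots[, c("area", "max_weight", "mean_weight")],
                 type = "prob")[, "TRUE"])
}

#' Filter spots on emptiness probability
#'
#' Removes spots whose emptiness probability is at or above `threshold` and
#' reports the empty rate — the fraction of kept spots that still carry an
#' empty barcode, the observable proxy for false discoveries.
#'
#' @param spots spot table.
#' @param classifier an `empty_classifier`, or NULL to pass spots through
#'   using any existing `empty_prob` column (missing values count as 0).
#' @param threshold probability cutoff in \[0, 1\] (default 0.325, the center
#'   of the working range 0.3-0.35).
#' @param codebook the [codebook()] used for the empty flags.
#' @return list with `spots` (kept rows, `empty_prob` filled), `empty_rate`
#'   (on the kept set), and `empty_rate_prefilter` (before filtering).
#' @export
filter_spots <- function(spots, classifier = NULL, threshold = 0.325,
                         codebook = NULL) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  prob <- if (is.null(classifier)) {
    p <- spots$empty_prob
    ifelse(is.na(p), 0, p)
  } else {
    predict_emptiness(classifier, spots)
  }
  spots$empty_prob <- prob
  kept <- spots[prob < threshold, , drop = FALSE]
  is_empty <- function(df) {
    if (nrow(df) == 0L) return(logical(0))
    if (!is.null(codebook)) codebook$is_empty[df$barcode_index]
    else grepl("^Empty_", df$gene)
  }
  pre <- if (nrow(spots)) mean(is_empty(spots)) else NA_real_
  er <- if (nrow(kept) == 0L) {
    warning("no spots kept; empty rate reported as 0")
    0
  } else mean(is_empty(kept))
  list(spots = kept, empty_rate = er, empty_rate_prefilter = pre)
}
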