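#' Read a multi-page TIFF stack
#'
#' Pages follow the shared flattening convention (plane =
#' 3*(round-1)+channel), so the page count must be divisible by 3.
#'
#' @param path TIFF file.
#' @param scale "none" (values must already lie in \[0,1\]) or "percentile"
#'   (each plane divided by its 99.9th percentile, then clipped; for raw
#'   integer input).
#' @return a [fov_stack()].
#' @export
read_stack <- function(path, scale = c("none", "percentile")) {
  scale <- match.arg(scale)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (length(pages) %% 3L != 0L)
    stop(sprintf("page count %d is not divisible by 3", length(pages)))
  arr <- array(0, dim = c(nrow(pages[[1L]]), ncol(pages[[1L]]), length(pages)))
  for (p in seq_along(pages)) arr[, , p] <- pages[[p]]
  if (scale == "percentile") {
    for (p in seq_len(dim(arr)[3L])) {
      q <- stats::quantile(arr[, , p], 0.999, names = FALSE)
      if (q > 0) arr[, , p] <- arr[, , p] / q
    }
    arr[arr > 1] <- 1
  }
  fov_stack(arr)
}

#' Write a stack as a 32-bit float multi-page TIFF
#'
#' @param stack a [fov_stack()]; values must lie in \[0, 1\].
#' @param path output file.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "fov_stack"))
  pages <- lapply(seq_len(3L * stack$n_rounds), function(p) stack$data[, , p])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read a codebook CSV
#'
#' Expected columns `gene,barcode,is_empty`. Malformed barcodes (characters
#' outside 0-3, ragged lengths) and duplicates are rejected with the
#' offending line numbers.
#'
#' @param path CSV file.
#' @return a [codebook()].
#' @export
read_codebook <- function(path) {
  df <- read.csv(path, colClasses = c(gene = "character",
                                      barcode = "character"))
  if (!all(c("gene", "barcode", "is_empty") %in% names(df)))
    stop("codebook CSV must have columns gene,barcode,is_empty")
  bad <- which(!grepl("^[0-3]+$", df$barcode))
  if (length(bad))
    stop("invalid barcode digits on line(s): ", paste(bad + 1L, collapse = ", "))
  if (length(unique(nchar(df$barcode))) != 1L)
    stop("ragged barcode lengths on line(s): ",
         paste(which(nchar(df$barcode) != nchar(df$barcode[1L])) + 1L,
               collapse = ", "))
  dup <- which(duplicated(df$barcode))
  if (length(dup))
    stop("duplicate barcodes on line(s): ", paste(dup + 1L, collapse = ", "))
  dupg <- which(duplicated(df$gene) & !df$is_empty)
  if (length(dupg))
    stop("duplicate gene rows on line(s): ", paste(dupg + 1L, collapse = ", "))
  codebook(df$gene, df$barcode, as.logical(df$is_empty))
}

#' Write a codebook CSV (`gene,barcode,is_empty`)
#'
#' @param cb a [codebook()].
#' @param path output file.
#' @export
write_codebook <- function(cb, path) {
  stopifnot(inherits(cb, "codebook"))
  write.csv(data.frame(gene = cb$genes, barcode = cb$barcodes,
                       is_empty = cb$is_empty), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Write codebook JSON with design metadata
#'
#' @param cb a [codebook()].
#' @param path output file.
#' @param metadata named list (seeds, run counts) stored alongside.
#' @export
write_codebook_json <- function(cb, path, metadata = list()) {
  jsonlite::write_json(list(n = cb$n, k = cb$k, channels = 3L,
                            entries = data.frame(gene = cb$genes,
                                                 barcode = cb$barcodes,
                                                 is_empty = cb$is_empty),
                            metadata = metadata),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a spot table CSV
#'
#' Columns `spot_id,gene,barcode,row,col,area,max_weight,mean_weight,
#' empty_prob,cell_id` (plus any extras present).
#'
#' @param spots spot table.
#' @param path file.
#' @export
write_spots <- function(spots, path) {
  write.csv(spots, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spots
#' @export
read_spots <- function(path) {
  read.csv(path, colClasses = c(gene = "character", barcode = "character"))
}

#' Write / read a ground-truth spot table CSV
#'
#' Columns `spot_id,row,col,barcode,gene,peak,sigma`.
#'
#' @param truth simulator truth table.
#' @param path file.
#' @export
write_truth <- function(truth, path) {
  write.csv(truth[, c("spot_id", "row", "col", "barcode", "gene",
                      "peak", "sigma")], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  read.csv(path, colClasses = c(barcode = "character", gene = "character"))
}

#' Read / write an integer segmentation mask as 16-bit TIFF
#'
#' @param path TIFF file.
#' @return integer label matrix.
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' @rdname read_mask
#' @param mask integer matrix with labels below 65536.
#' @export
write_mask <- function(mask, path) {
  if (max(mask) > 65535L) stop("labels exceed 16-bit range")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Export decoded weight maps as sparse CSV
#'
#' One row per non-zero pixel weight: `row,col,barcode,gene,weight` (1-based
#' pixel indices). Readable back with [read_weight_maps()] given the
#' codebook and FOV shape.
#'
#' @param maps a `weight_maps`.
#' @param path file.
#' @export
write_weight_maps <- function(maps, path) {
  e <- maps$entries
  e$gene <- maps$codebook$genes[e$barcode]
  write.csv(e[, c("row", "col", "barcode", "gene", "weight")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_weight_maps
#' @param codebook the [codebook()] used for the decode.
#' @param dim c(H, W) of the FOV.
#' @export
read_weight_maps <- function(path, codebook, dim) {
  e <- read.csv(path, colClasses = c(gene = "character"))
  structure(list(entries = e[, c("row", "col", "barcode", "weight")],
                 dim = as.integer(dim), codebook = codebook,
                 coefficients = NULL, n_foreground = NA_integer_,
                 n_nonconverged = NA_integer_),
            class = "weight_maps")
}

#' Write a genes x cells count matrix in MatrixMarket format
#'
#' Writes `<path>.mtx` plus `<path>.genes.txt` and `<path>.cells.txt` row /
#' column name sidecars.
#'
#' @param counts sparse matrix from [cell_gene_counts()].
#' @param path output prefix.
#' @export
write_counts_mtx <- function(counts, path) {
  Matrix::writeMM(counts, paste0(path, ".mtx"))
  writeLines(rownames(counts), paste0(path, ".genes.txt"))
  writeLines(colnames(counts), paste0(path, ".cells.txt"))
  invisible(path)
}

#' Write / read decoder configuration
#'
#' YAML (`.yml`/`.yaml`) or JSON by extension. Unknown keys are rejected so a
#' config file round-trips losslessly onto [spd_config()].
#'
#' @param config an [spd_config()].
#' @param path file.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "spd_config"))
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(x, path, precision = 15L)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::fromJSON(path)
  known <- names(formals(spd_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(spd_config, x)
}

#' Write a provenance record for a pipeline run
#'
#' @param path JSON file.
#' @param config an [spd_config()] or NULL.
#' @param seeds named list of seeds used.
#' @param extra named list of additional fields.
#' @export
write_provenance <- function(path, config = NULL, seeds = list(),
                             extra = list()) {
  jsonlite::write_json(c(list(package = "spdecon",
                              version = as.character(utils::packageVersion("spdecon")),
                              seeds = seeds,
                              config = if (!is.null(config)) unclass(config)),
                         extra),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
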