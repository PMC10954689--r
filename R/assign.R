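#' Boundary pixels of a labeled segmentation mask
#'
#' A pixel belongs to its cell's boundary when any of its 8 neighbors (or the
#' image edge) carries a different label.
#'
#' @param mask integer matrix (H x W), 0 = background.
#' @return data frame `label, row, col` of boundary pixels; coordinates are
#'   0-based pixel-centered. Empty masks give zero rows.
#' @export
mask_boundaries <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(-1L, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- mask
  bd <- matrix(FALSE, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- pad[(2:(H + 1L)) + dr, (2:(W + 1L)) + dc]
    bd <- bd | (nb != mask)
  }
  bd <- bd & mask > 0L
  idx <- which(bd)
  out <- data.frame(label = mask[idx],
                    row = (idx - 1L) %% H,
                    col = (idx - 1L) %/% H)
  out[order(out$label, out$row, out$col), , drop = FALSE]
}

#' Assign spots to segmented cells
#'
#' A spot inside a cell gets that cell's label at distance 0. A spot outside
#' all cells is assigned to the cell owning the nearest boundary pixel,
#' provided the distance (in micrometers) is at or below the applicable
#' threshold; a per-gene override beats the global threshold, which lets
#' genes known to live outside somata (for example myelin transcripts) use a
#' stricter radius. Unassigned spots are retained with `cell_id = NA`.
#'
#' @param spots spot table with 0-based `row`, `col` and `gene`.
#' @param mask integer segmentation matrix, 0 = background.
#' @param max_dist_um global assignment radius in micrometers.
#' @param per_gene_max_dist named numeric vector of per-gene radii (um).
#' @param pixel_size_um physical pixel size (default 1).
#' @return `spots` with `cell_id` filled where assigned and a
#'   `boundary_dist_um` column. Equidistant ties go to the smaller label.
#' @export
assign_spots_to_cells <- function(spots, mask, max_dist_um,
                                  per_gene_max_dist = NULL,
                                  pixel_size_um = 1) {
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  if (nrow(spots) == 0L) {
    spots$boundary_dist_um <- numeric(0)
    return(spots)
  }
  H <- nrow(mask); W <- ncol(mask)
  pr <- pmin(pmax(as.integer(round(spots$row)), 0L), H - 1L) + 1L
  pc <- pmin(pmax(as.integer(round(spots$col)), 0L), W - 1L) + 1L
  inside <- mask[cbind(pr, pc)]
  cell <- ifelse(inside > 0L, inside, NA_integer_)
  dist_um <- ifelse(inside > 0L, 0, NA_real_)
  out_idx <- which(inside == 0L)
  bd <- mask_boundaries(mask)
  if (length(out_idx) && nrow(bd)) {
    # boundary rows are ordered by label, so which.min ties pick the
    # smallest label
    for (i in out_idx) {
      d2 <- (bd$row - spots$row[i])^2 + (bd$col - spots$col[i])^2
      j <- which.min(d2)
      dum <- sqrt(d2[j]) * pixel_size_um
      th <- max_dist_um
      g <- spots$gene[i]
      if (!is.null(per_gene_max_dist) && g %in% names(per_gene_max_dist))
        th <- per_gene_max_dist[[g]]
      dist_um[i] <- dum
      if (dum <= th) cell[i] <- bd$label[j]
    }
  }
  spots$cell_id <- cell
  spots$boundary_dist_um <- dist_um
  spots
}

#' Per-cell gene count matrix
#'
#' @param spots assigned spot table (rows with `cell_id = NA` are dropped).
#' @param codebook the [codebook()]; empty barcodes are excluded.
#' @return sparse genes x cells [Matrix::sparseMatrix()] of spot counts.
#' @export
cell_gene_counts <- function(spots, codebook) {
  keep <- !is.na(spots$cell_id) & !codebook$is_empty[spots$barcode_index]
  sp <- spots[keep, , drop = FALSE]
  genes <- sort(codebook$genes[!codebook$is_empty])
  cells <- sort(unique(sp$cell_id))
  Matrix::sparseMatrix(i = match(sp$gene, genes),
                       j = match(sp$cell_id, cells),
                       x = 1, dims = c(length(genes), length(cells)),
                       dimnames = list(genes, as.character(cells)))
}
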