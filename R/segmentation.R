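#' Threshold-based 3D instance segmentation
#'
#' Labels the 26-connected components of `channel > threshold`, discarding
#' components smaller than `min_voxels`. Labels `1..n` are assigned in
#' decreasing component size (ties by smallest voxel index), so label 1 is
#' always the largest object. This is a deliberately simple segmenter for
#' synthetic or high-contrast images; precomputed masks from dedicated
#' segmentation tools can be supplied anywhere a [label_mask()] is accepted.
#'
#' @param channel 3-D intensity array (z, y, x) or a single-channel
#'   [multichannel_image()].
#' @param threshold Intensity threshold; voxels strictly above it are
#'   foreground.
#' @param min_voxels Minimum component size kept (default 1).
#' @param voxel_size Voxel spacing for the returned mask (taken from the
#'   image when one is supplied).
#' @return A [label_mask()].
#' @export
instance_segment <- function(channel, threshold, min_voxels = 1L, voxel_size = NULL) {
  if (inherits(channel, "mc_image")) {
    if (dim(channel$data)[1] != 1L) {
      abort("`instance_segment` takes a single channel; subset the image first.")
    }
    voxel_size <- voxel_size %||% channel$voxel_size
    channel <- array(channel$data[1, , , ], dim(channel$data)[2:4])
  }
  voxel_size <- voxel_size %||% c(1, 1, 1)
  if (length(dim(channel)) != 3L) abort("`channel` must be a 3-D array.")
  fg <- channel > threshold
  labels <- label_components_26(fg)
  if (max(labels) > 0L && min_voxels > 1L) {
    sizes <- tabulate(labels[labels > 0L])
    keep <- which(sizes >= min_voxels)
    relab <- integer(length(sizes))
    relab[keep] <- seq_along(keep)
    labels[labels > 0L] <- relab[labels[labels > 0L]]
  }
  labels <- relabel_by_size(labels)
  label_mask(labels, voxel_size = voxel_size)
}

# 26-connected components of a logical 3-D array, via the voxel adjacency
# graph (igraph handles the union-find).
label_components_26 <- function(fg) {
  d <- dim(fg)
  out <- array(0L, d)
  idx <- which(fg)
  if (length(idx) == 0L) return(out)
  comp_of <- integer(length(idx))
  pos <- integer(prod(d))          # linear voxel index -> rank among foreground
  pos[idx] <- seq_along(idx)
  ai <- arrayInd(idx, d)
  # 13 forward neighbour offsets cover all 26 neighbours once
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[(offs[, 3] > 0) | (offs[, 3] == 0 & offs[, 2] > 0) |
                 (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), , drop = FALSE]
  edges_from <- integer(0); edges_to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nz <- ai[, 1] + offs[r, 1]; ny <- ai[, 2] + offs[r, 2]; nx <- ai[, 3] + offs[r, 3]
    ok <- nz >= 1 & nz <= d[1] & ny >= 1 & ny <= d[2] & nx >= 1 & nx <= d[3]
    if (!any(ok)) next
    nlin <- (nx[ok] - 1L) * d[1] * d[2] + (ny[ok] - 1L) * d[1] + nz[ok]
    tgt <- pos[nlin]
    hit <- tgt > 0L
    if (any(hit)) {
      edges_from <- c(edges_from, which(ok)[hit])
      edges_to <- c(edges_to, tgt[hit])
    }
  }
  if (length(edges_from)) {
    g <- igraph::make_graph(rbind(edges_from, edges_to), n = length(idx), directed = FALSE)
    comp_of <- igraph::components(g)$membership
  } else {
    comp_of <- seq_along(idx)
  }
  out[idx] <- as.integer(comp_of)
  out
}

# relabel so that 1..n are in decreasing size order (ties: smallest first voxel)
relabel_by_size <- function(labels) {
  mx <- max(labels)
  if (mx == 0L) return(labels)
  present <- sort(unique(labels[labels > 0L]))
  sizes <- tabulate(labels[labels > 0L], nbins = mx)[present]
  first_voxel <- vapply(present, function(l) which(labels == l)[1], integer(1))
  ord <- order(-sizes, first_voxel)
  relab <- integer(mx)
  relab[present[ord]] <- seq_along(present)
  labels[labels > 0L] <- relab[labels[labels > 0L]]
  labels
}

#' Jaccard similarity of two binary masks
#'
#' `|a intersect b| / |a union b|`; defined as 1 when both masks are empty
#' (perfect agreement on absence). Image-wise semantic segmentation
#' agreement is computed on the union of all instances of a channel.
#'
#' @param a,b Binary (or labelled; any non-zero voxel is foreground) arrays
#'   or [label_mask()]s of identical shape.
#' @return Scalar in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  if (inherits(a, "label_mask")) a <- a$labels
  if (inherits(b, "label_mask")) b <- b$labels
  check_same_shape(a, b)
  fa <- a != 0; fb <- b != 0
  uni <- sum(fa | fb)
  if (uni == 0L) return(1)
  sum(fa & fb) / uni
}

#' Extract per-instance organelle objects from a label mask
#'
#' Each labelled instance becomes one object row with its voxel list,
#' physical centroid and surface points (centres of foreground voxels
#' 6-adjacent to background), in micrometres (0-based voxel index times
#' spacing). Objects belonging to a border-touching cell are excluded when
#' the supplying record is flagged.
#'
#' @param mask A [label_mask()] (or integer array, with `voxel_size`).
#' @param record Optional [cell_record()] supplying `cell_id`, the boundary
#'   flag and the voxel size.
#' @param source Provenance tag stored per object (e.g. `"real"` or a
#'   synthetic model name).
#' @param voxel_size Voxel spacing when `mask` is a bare array.
#' @return A tibble with one row per object: `object_id`, `cell_id`,
#'   `source`, `n_voxels`, `centroid` (list of length-3 um vectors, z/y/x),
#'   `voxels` and `surface` (list of matrices).
#' @export
extract_objects <- function(mask, record = NULL, source = "real", voxel_size = NULL) {
  arr <- if (inherits(mask, "label_mask")) mask$labels else mask
  vs <- voxel_size %||% (if (inherits(mask, "label_mask")) mask$voxel_size else NULL) %||%
    (if (!is.null(record)) record$voxel_size else c(1, 1, 1))
  cell_id <- if (!is.null(record)) record$cell_id else NA_integer_
  empty <- tibble::tibble(object_id = integer(), cell_id = integer(),
                          source = character(), n_voxels = integer(),
                          centroid = list(), voxels = list(), surface = list())
  if (!is.null(record) && record$touches_boundary) return(empty)
  ids <- setdiff(sort(unique(as.vector(arr))), 0L)
  if (!length(ids)) return(empty)
  rows <- lapply(ids, function(id) {
    inst <- arr == id
    idx <- mask_indices(inst)
    coords <- voxel_coords_um(idx, vs)
    surf_idx <- boundary_voxels(inst)
    tibble::tibble(
      object_id = as.integer(id), cell_id = cell_id, source = source,
      n_voxels = nrow(idx),
      centroid = list(colMeans(coords)),
      voxels = list(idx),
      surface = list(voxel_coords_um(surf_idx, vs))
    )
  })
  dplyr::bind_rows(rows)
}

# foreground voxels 6-adjacent to background (or the array border)
boundary_voxels <- function(mask) {
  d <- dim(mask)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb_all <-
    pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] & pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] & pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] & pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  mask_indices(core & !nb_all)
}

#' Summarise object counts per cell and per population
#'
#' @param objects A tibble of objects as returned by [extract_objects()]
#'   (rows from several cells may be bound together), or a list of such
#'   tibbles.
#' @return A list with `per_cell` (tibble: `cell_id`, `source`, `n_objects`)
#'   and `summary` (tibble: `source`, `n_cells`, `n_objects`, `mean`,
#'   `median` objects per cell).
#' @export
count_objects <- function(objects) {
  if (is.list(objects) && !is.data.frame(objects)) objects <- dplyr::bind_rows(objects)
  if (nrow(objects) == 0L) {
    return(list(
      per_cell = tibble::tibble(cell_id = integer(), source = character(),
                                n_objects = integer()),
      summary = tibble::tibble(source = NA_character_, n_cells = 0L,
                               n_objects = 0L, mean = 0, median = 0)
    ))
  }
  per_cell <- objects |>
    dplyr::group_by(.data$cell_id, .data$source) |>
    dplyr::summarise(n_objects = dplyr::n(), .groups = "drop")
  summary <- per_cell |>
    dplyr::group_by(.data$source) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     mean = mean(.data$n_objects),
                     median = stats::median(.data$n_objects),
                     n_objects = sum(.data$n_objects), .groups = "drop") |>
    dplyr::relocate("n_objects", .after = "n_cells")
  list(per_cell = per_cell, summary = summary)
}
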