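#' Multi-channel 3D image container
#'
#' Holds a stack of per-organelle intensity volumes in canonical
#' `(channel, z, y, x)` order together with channel names and the physical
#' voxel spacing. All package metrics assume this layout; readers convert
#' into it.
#'
#' @param data Numeric 4-D array indexed `(channel, z, y, x)`. A 3-D array is
#'   promoted to a single channel.
#' @param channel_names Character vector naming each channel (one organelle
#'   per channel). Defaults to `"ch0" ... "ch<C-1>"`.
#' @param voxel_size Numeric length-3 vector `(dz, dy, dx)` in micrometres;
#'   strictly positive.
#'
#' @return An object of class `mc_image`.
#' @examples
#' img <- multichannel_image(array(runif(2 * 4 * 8 * 8), c(2, 4, 8, 8)),
#'                           c("mito", "golgi"), voxel_size = c(0.5, 0.25, 0.25))
#' dim(img$data)
#' @export
multichannel_image <- function(data, channel_names = NULL, voxel_size = c(1, 1, 1)) {
  if (length(dim(data)) == 3L) {
    data <- array(data, c(1L, dim(data)))
  }
  if (length(dim(data)) != 4L) {
    abort("`data` must be a 4-D (channel, z, y, x) array (or 3-D for one channel).")
  }
  if (!all(is.finite(data))) abort("all intensity values must be finite.")
  nc <- dim(data)[1]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc) - 1L)
  if (length(channel_names) != nc) {
    abort(sprintf("`channel_names` has length %d but `data` has %d channels.",
                  length(channel_names), nc))
  }
  if (anyDuplicated(channel_names)) abort("`channel_names` must be unique.")
  voxel_size <- check_voxel_size(voxel_size)
  structure(
    list(data = data, channel_names = as.character(channel_names),
         voxel_size = voxel_size),
    class = "mc_image"
  )
}

check_voxel_size <- function(voxel_size) {
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || !all(is.finite(voxel_size)) || any(voxel_size <= 0)) {
    abort("`voxel_size` must be 3 strictly positive numbers (dz, dy, dx) in um.")
  }
  voxel_size
}

#' @export
print.mc_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mc_image> %d channel(s), %d x %d x %d voxels (z,y,x), voxel %s um\n",
              d[1], d[2], d[3], d[4], paste(signif(x$voxel_size, 3), collapse = " x ")))
  cat("channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.mc_image <- function(x) dim(x$data)

#' Instance label mask
#'
#' A 3-D grid of non-negative integers; 0 is background, labels `1..n` index
#' object instances. Shares the spatial shape and voxel spacing of any paired
#' [multichannel_image()].
#'
#' @param labels 3-D array of non-negative integers.
#' @param voxel_size Physical voxel spacing `(dz, dy, dx)` in micrometres.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, voxel_size = c(1, 1, 1)) {
  if (length(dim(labels)) != 3L) abort("`labels` must be a 3-D (z, y, x) array.")
  if (any(labels < 0) || any(labels != round(labels))) {
    abort("`labels` must contain non-negative integers (0 = background).")
  }
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, voxel_size = check_voxel_size(voxel_size)),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_mask> %d x %d x %d voxels (z,y,x), %d instance(s)\n",
              d[1], d[2], d[3], max(x$labels)))
  invisible(x)
}

#' Single segmented cell with its nucleus and organelle instances
#'
#' @param cell_mask Logical/0-1 3-D array marking the cell.
#' @param nuclear_mask Logical/0-1 3-D array; must be a subset of `cell_mask`.
#' @param organelle_masks Named list of [label_mask()] (or integer arrays),
#'   one per organelle channel; every foreground voxel must lie inside
#'   `cell_mask`.
#' @param voxel_size Physical voxel spacing in micrometres.
#' @param cell_id Identifier carried through object tables.
#' @param touches_boundary If `NULL` (default), computed from `cell_mask`:
#'   `TRUE` iff the cell intersects the image border.
#'
#' @return An object of class `cell_record`.
#' @export
cell_record <- function(cell_mask, nuclear_mask, organelle_masks = list(),
                        voxel_size = c(1, 1, 1), cell_id = 1L,
                        touches_boundary = NULL) {
  cell_mask <- as_binary_mask(cell_mask, "cell_mask")
  nuclear_mask <- as_binary_mask(nuclear_mask, "nuclear_mask")
  if (!identical(dim(cell_mask), dim(nuclear_mask))) {
    abort("cell and nuclear masks must share the same spatial shape.")
  }
  if (any(nuclear_mask & !cell_mask)) {
    abort("`nuclear_mask` must be a subset of `cell_mask`.")
  }
  organelle_masks <- lapply(organelle_masks, function(m) {
    arr <- if (inherits(m, "label_mask")) m$labels else m
    if (!identical(dim(arr), dim(cell_mask))) {
      abort("organelle masks must share the cell mask's spatial shape.")
    }
    if (any(arr > 0 & !cell_mask)) {
      abort("every organelle instance voxel must lie inside `cell_mask`.")
    }
    storage.mode(arr) <- "integer"
    arr
  })
  if (is.null(touches_boundary)) touches_boundary <- mask_touches_border(cell_mask)
  structure(
    list(cell_mask = cell_mask, nuclear_mask = nuclear_mask,
         organelle_masks = organelle_masks,
         voxel_size = check_voxel_size(voxel_size),
         cell_id = cell_id, touches_boundary = isTRUE(touches_boundary)),
    class = "cell_record"
  )
}

as_binary_mask <- function(m, what) {
  if (inherits(m, "label_mask")) m <- m$labels
  if (length(dim(m)) != 3L) abort(sprintf("`%s` must be a 3-D array.", what))
  m != 0
}

mask_touches_border <- function(mask) {
  d <- dim(mask)
  any(mask[1, , ]) || any(mask[d[1], , ]) ||
    any(mask[, 1, ]) || any(mask[, d[2], ]) ||
    any(mask[, , 1]) || any(mask[, , d[3]])
}

#' @export
print.cell_record <- function(x, ...) {
  cat(sprintf("<cell_record> id %s: %d cell voxels, %d nuclear voxels, %d organelle channel(s)%s\n",
              as.character(x$cell_id), sum(x$cell_mask), sum(x$nuclear_mask),
              length(x$organelle_masks),
              if (x$touches_boundary) " [touches boundary]" else ""))
  invisible(x)
}

# physical coordinates (z, y, x) in um of voxel centers, 0-based index * spacing
voxel_coords_um <- function(idx, voxel_size) {
  sweep(idx - 1, 2, voxel_size, `*`)
}

# array indices (z,y,x) of TRUE/foreground voxels
mask_indices <- function(mask) {
  which_idx <- which(mask != 0)
  if (length(which_idx) == 0L) {
    return(matrix(numeric(0), 0, 3, dimnames = list(NULL, c("z", "y", "x"))))
  }
  ai <- arrayInd(which_idx, dim(mask))
  colnames(ai) <- c("z", "y", "x")
  ai
}
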