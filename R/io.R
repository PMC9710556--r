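#' Read a multi-channel 3D TIFF stack
#'
#' Reads a multi-page TIFF (or OME-TIFF) into the canonical
#' `(channel, z, y, x)` layout. Metadata are resolved in this order:
#' a JSON sidecar written by [write_image()] (`<path>.json`), an OME-XML
#' `ImageDescription` embedded by other tools, then the `axis_order` /
#' `n_channels` arguments. Without any of these, all pages are treated as z
#' planes of one channel.
#'
#' @param path TIFF file path.
#' @param axis_order `"zyx"` (single channel) or `"czyx"`; with `"czyx"`,
#'   `n_channels` must be given so pages can be split (channel-major page
#'   order). Ignored when a sidecar or OME metadata resolves the axes.
#' @param n_channels Number of channels when `axis_order = "czyx"`.
#' @param channel_names,voxel_size Optional overrides of the metadata.
#' @return An [multichannel_image()] object.
#' @export
read_image <- function(path, axis_order = NULL, n_channels = NULL,
                       channel_names = NULL, voxel_size = NULL) {
  if (!file.exists(path)) abort(sprintf("cannot read '%s': no such file.", path))
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1)))) {
    # collapse grayscale stored with a trailing sample dim
    pages <- lapply(pages, function(p) {
      if (length(dim(p)) == 3L && dim(p)[3] == 1L) p[, , 1] else p
    })
  }
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1)))) {
    abort("expected single-sample grayscale pages; RGB TIFFs are not supported.")
  }

  meta <- read_sidecar(path) %||% parse_ome_description(attr(pages[[1]], "description"))
  np <- length(pages)
  if (!is.null(meta)) {
    nc <- meta$n_channels
    nz <- np %/% nc
  } else if (!is.null(axis_order) && identical(axis_order, "czyx")) {
    if (is.null(n_channels)) {
      abort("axis_order 'czyx' is ambiguous without `n_channels`.")
    }
    nc <- as.integer(n_channels)
    nz <- np %/% nc
  } else if (is.null(axis_order) || identical(axis_order, "zyx")) {
    nc <- 1L
    nz <- np
  } else {
    abort(sprintf("unknown axis_order '%s' (use 'zyx' or 'czyx').", axis_order))
  }
  if (nc * nz != np) {
    abort(sprintf("%d pages cannot be split into %d channels.", np, nc))
  }
  if (nz < 2L && np == 1L) {
    abort("expected 3 spatial dimensions; file holds a single 2-D page.")
  }
  d2 <- dim(pages[[1]])
  data <- array(0, c(nc, nz, d2[1], d2[2]))
  for (ci in seq_len(nc)) {
    for (zi in seq_len(nz)) {
      data[ci, zi, , ] <- pages[[(ci - 1L) * nz + zi]]
    }
  }
  if (!is.null(meta$intensity_scale)) {
    data <- data * meta$intensity_scale + meta$intensity_offset
  }
  multichannel_image(
    data,
    channel_names = channel_names %||% meta$channel_names,
    voxel_size = voxel_size %||% meta$voxel_size %||% c(1, 1, 1)
  )
}

#' Write a multi-channel image as multi-page 32-bit float TIFF
#'
#' Pages are written channel-major (`c` outer, `z` inner). Channel names,
#' voxel size and any intensity rescaling (applied when data fall outside
#' the TIFF float range `[0, 1]`) go into a JSON sidecar `<path>.json`, which
#' [read_image()] uses for a lossless round-trip (exact for integers, 32-bit
#' float precision otherwise).
#'
#' @param img A [multichannel_image()].
#' @param path Output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "mc_image"))
  d <- dim(img$data)
  if (d[1] == 0L) abort("image has an empty channel list; nothing to write.")
  lo <- min(img$data); hi <- max(img$data)
  offset <- 0; scale <- 1
  data <- img$data
  if (lo < 0 || hi > 1) {
    offset <- lo
    scale <- max(hi - lo, .Machine$double.eps)
    data <- (data - offset) / scale
  }
  pages <- vector("list", d[1] * d[2])
  for (ci in seq_len(d[1])) {
    for (zi in seq_len(d[2])) {
      pages[[(ci - 1L) * d[2] + zi]] <- matrix(data[ci, zi, , ], d[3], d[4])
    }
  }
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 32L),
                 error = function(e) abort(sprintf("cannot write '%s': %s", path, conditionMessage(e))))
  jsonlite::write_json(
    list(format = "orgeval-image", n_channels = d[1], n_z = d[2],
         channel_names = img$channel_names, voxel_size = img$voxel_size,
         intensity_offset = offset, intensity_scale = scale),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  list(n_channels = as.integer(meta$n_channels),
       channel_names = meta$channel_names,
       voxel_size = as.numeric(meta$voxel_size),
       intensity_offset = as.numeric(meta$intensity_offset %||% 0),
       intensity_scale = as.numeric(meta$intensity_scale %||% 1))
}

# Minimal OME-XML reader: SizeC, channel names, physical voxel sizes.
parse_ome_description <- function(desc) {
  if (is.null(desc) || !nzchar(desc) || !grepl("<OME", desc, fixed = TRUE)) {
    return(NULL)
  }
  doc <- tryCatch(xml2::read_xml(desc), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  xml2::xml_ns_strip(doc)
  px <- xml2::xml_find_first(doc, ".//Pixels")
  if (inherits(px, "xml_missing")) return(NULL)
  nc <- as.integer(xml2::xml_attr(px, "SizeC") %||% "1")
  ch <- xml2::xml_find_all(doc, ".//Channel")
  nms <- xml2::xml_attr(ch, "Name")
  if (length(nms) != nc || any(is.na(nms))) nms <- paste0("ch", seq_len(nc) - 1L)
  vz <- as.numeric(xml2::xml_attr(px, "PhysicalSizeZ") %||% "1")
  vy <- as.numeric(xml2::xml_attr(px, "PhysicalSizeY") %||% "1")
  vx <- as.numeric(xml2::xml_attr(px, "PhysicalSizeX") %||% "1")
  list(n_channels = nc, channel_names = nms,
       voxel_size = c(vz, vy, vx), intensity_offset = 0, intensity_scale = 1)
}

#' Read / write an instance label mask as 16-bit TIFF
#'
#' Labels are stored losslessly in 16-bit pages (up to 65535 instances);
#' voxel size goes into the JSON sidecar.
#'
#' @param mask A [label_mask()].
#' @param path File path.
#' @return `write_mask()` returns `path` invisibly; `read_mask()` a
#'   [label_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  mx <- max(mask$labels)
  if (mx > 65535L) abort("label masks with > 65535 instances are not supported.")
  d <- dim(mask$labels)
  pages <- lapply(seq_len(d[1]), function(zi) matrix(mask$labels[zi, , ] / 65535, d[2], d[3]))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(
    list(format = "orgeval-mask", n_z = d[1], voxel_size = mask$voxel_size),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_mask
#' @param voxel_size Override for the voxel size when no sidecar is present.
#' @export
read_mask <- function(path, voxel_size = NULL) {
  if (!file.exists(path)) abort(sprintf("cannot read '%s': no such file.", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d2 <- dim(pages[[1]])
  arr <- array(0L, c(length(pages), d2[1], d2[2]))
  for (zi in seq_along(pages)) arr[zi, , ] <- pages[[zi]]
  meta <- read_sidecar(path)
  label_mask(arr, voxel_size = voxel_size %||% meta$voxel_size %||% c(1, 1, 1))
}

#' Split labelled cells into per-cell records
#'
#' Builds one [cell_record()] per cell label. Each nucleus and each organelle
#' instance is assigned to the cell containing its centroid voxel; instances
#' whose centroid falls in no cell are skipped with a warning. Cells whose
#' mask touches the image border are flagged, and dropped when
#' `drop_boundary = TRUE` (partial cells cannot yield reliable shapes or
#' positions).
#'
#' @param cell_labels,nuclear_labels [label_mask()] objects of identical shape.
#' @param organelle_labels Named list of [label_mask()], one per organelle.
#' @param drop_boundary Drop border-touching cells (default `TRUE`).
#' @return A list of [cell_record()]s, named by cell label.
#' @export
extract_cells <- function(cell_labels, nuclear_labels, organelle_labels = list(),
                          drop_boundary = TRUE) {
  stopifnot(inherits(cell_labels, "label_mask"), inherits(nuclear_labels, "label_mask"))
  cl <- cell_labels$labels
  if (!identical(dim(cl), dim(nuclear_labels$labels))) {
    abort("all masks must share the same spatial shape.")
  }
  for (om in organelle_labels) {
    arr <- if (inherits(om, "label_mask")) om$labels else om
    if (!identical(dim(arr), dim(cl))) abort("all masks must share the same spatial shape.")
  }
  vs <- cell_labels$voxel_size
  cell_ids <- setdiff(sort(unique(as.vector(cl))), 0L)

  assign_to_cell <- function(lab_arr, what) {
    ids <- setdiff(sort(unique(as.vector(lab_arr))), 0L)
    out <- setNames(integer(length(ids)), ids)
    for (i in seq_along(ids)) {
      idx <- mask_indices(lab_arr == ids[i])
      cen <- round(colMeans(idx))
      cen <- pmin(pmax(cen, 1), dim(cl))
      owner <- cl[cen[1], cen[2], cen[3]]
      if (owner == 0L) {
        warn(sprintf("%s instance %d has its centroid in no cell; skipped.", what, ids[i]))
      }
      out[i] <- owner
    }
    out
  }

  nuc_owner <- assign_to_cell(nuclear_labels$labels, "nucleus")
  org_owner <- lapply(seq_along(organelle_labels), function(j) {
    arr <- organelle_labels[[j]]
    arr <- if (inherits(arr, "label_mask")) arr$labels else arr
    assign_to_cell(arr, names(organelle_labels)[j] %||% paste0("organelle", j))
  })

  records <- list()
  for (cid in cell_ids) {
    cmask <- cl == cid
    touches <- mask_touches_border(cmask)
    if (drop_boundary && touches) next
    nuc_ids <- as.integer(names(nuc_owner)[nuc_owner == cid])
    nmask <- array(FALSE, dim(cl))
    if (length(nuc_ids)) {
      nmask <- array(nuclear_labels$labels %in% nuc_ids, dim(cl))
    }
    nmask <- nmask & cmask
    omasks <- list()
    for (j in seq_along(organelle_labels)) {
      arr <- organelle_labels[[j]]
      arr <- if (inherits(arr, "label_mask")) arr$labels else arr
      keep <- as.integer(names(org_owner[[j]])[org_owner[[j]] == cid])
      m <- array(0L, dim(cl))
      if (length(keep)) {
        sel <- arr %in% keep
        m[sel] <- arr[sel]
      }
      m[!cmask] <- 0L
      omasks[[names(organelle_labels)[j] %||% paste0("organelle", j)]] <- m
    }
    records[[as.character(cid)]] <- cell_record(
      cell_mask = cmask, nuclear_mask = nmask, organelle_masks = omasks,
      voxel_size = vs, cell_id = cid, touches_boundary = touches
    )
  }
  records
}
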