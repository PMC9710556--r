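#' Pixel-level organelle exclusivity metrics
#'
#' Exclusivity quantifies how spatially distinct the predicted organelle
#' channels are: at each pixel it is the margin between the highest and the
#' second-highest predicted intensity (in pixel-intensity units).
#'
#' * `overall_exclusivity()` averages the margin over all pixels (or a
#'   region mask).
#' * `organelle_exclusivity()` averages, for each channel, only over the
#'   pixels where that channel has the highest value; channels that are
#'   nowhere the argmax report `NA` (undefined), never 0.
#' * `pairwise_exclusivity()` gives, for each directed pair `(o, j)`, the
#'   mean of `value_o - value_j` over pixels where `o` is the argmax; it is
#'   not symmetric.
#'
#' Argmax ties are broken by the lowest channel index, so tied pixels
#' contribute a zero margin to that channel's average. No internal intensity
#' normalization is applied; channels are compared on the caller's scale.
#'
#' @param img A [multichannel_image()] with at least two channels.
#' @param region Optional logical 3-D mask restricting the pixel set.
#' @return `overall_exclusivity()`: a scalar. `organelle_exclusivity()`: a
#'   named numeric vector (with `NA` for channels that are never the argmax).
#'   `pairwise_exclusivity()`: a named `C x C` matrix with `NA` diagonal.
#' @examples
#' v <- array(c(0.9, 0.5, 0.1,  0.2, 0.7, 0.6), c(3, 1, 1, 2))
#' img <- multichannel_image(v)
#' overall_exclusivity(img)        # 0.25
#' organelle_exclusivity(img)      # 0.4, 0.1, NA
#' @export
overall_exclusivity <- function(img, region = NULL) {
  tt <- top_two(img, region)
  mean(tt$top - tt$second)
}

#' @rdname overall_exclusivity
#' @export
organelle_exclusivity <- function(img, region = NULL) {
  tt <- top_two(img, region)
  nc <- length(img$channel_names)
  out <- setNames(rep(NA_real_, nc), img$channel_names)
  for (ci in seq_len(nc)) {
    sel <- tt$amax == ci
    if (any(sel)) out[ci] <- mean(tt$top[sel] - tt$second[sel])
  }
  out
}

#' @rdname overall_exclusivity
#' @export
pairwise_exclusivity <- function(img, region = NULL) {
  tt <- top_two(img, region)
  nc <- length(img$channel_names)
  out <- matrix(NA_real_, nc, nc, dimnames = list(img$channel_names, img$channel_names))
  for (o in seq_len(nc)) {
    sel <- tt$amax == o
    if (!any(sel)) next
    for (j in seq_len(nc)) {
      if (j == o) next
      out[o, j] <- mean(tt$values[sel, o] - tt$values[sel, j])
    }
  }
  out
}

# per-pixel channel matrix, argmax (lowest-index ties) and top-two values
top_two <- function(img, region = NULL) {
  stopifnot(inherits(img, "mc_image"))
  nc <- dim(img$data)[1]
  if (nc < 2L) abort("exclusivity needs at least two channels.")
  m <- t(matrix(img$data, nrow = nc))     # npix x C, pixel-major
  if (!is.null(region)) {
    if (!identical(dim(region), dim(img$data)[2:4])) {
      abort("`region` must match the image's spatial shape.")
    }
    keep <- as.vector(region != 0)
    if (!any(keep)) abort("`region` selects no pixels.")
    m <- m[keep, , drop = FALSE]
  }
  amax <- max.col(m, ties.method = "first")
  n <- nrow(m)
  top <- m[cbind(seq_len(n), amax)]
  m2 <- m
  m2[cbind(seq_len(n), amax)] <- -Inf
  second <- m2[, 1]
  for (j in 2:nc) second <- pmax(second, m2[, j])
  list(values = m, amax = amax, top = top, second = second)
}

#' Full exclusivity report for a predicted image
#'
#' Bundles the overall, per-organelle and directed pairwise exclusivities
#' together with each channel's occupancy (the fraction of pixels where it
#' is the argmax). The overall value always equals the occupancy-weighted
#' sum of the per-organelle values.
#'
#' @inheritParams overall_exclusivity
#' @return An object of class `exclusivity_report`; see [tidy.exclusivity_report()].
#' @export
exclusivity_report <- function(img, region = NULL) {
  tt <- top_two(img, region)
  nc <- length(img$channel_names)
  occ <- setNames(tabulate(tt$amax, nc) / length(tt$amax), img$channel_names)
  structure(
    list(overall = mean(tt$top - tt$second),
         per_organelle = organelle_exclusivity(img, region),
         pairwise = pairwise_exclusivity(img, region),
         occupancy = occ,
         n_pixels = length(tt$amax),
         channel_names = img$channel_names),
    class = "exclusivity_report"
  )
}

#' @export
print.exclusivity_report <- function(x, ...) {
  cat(sprintf("<exclusivity_report> %d channels, %d pixels\n",
              length(x$channel_names), x$n_pixels))
  cat(sprintf("overall exclusivity: %.4g (pixel-intensity units)\n", x$overall))
  print(tibble::tibble(organelle = x$channel_names,
                       exclusivity = unname(x$per_organelle),
                       occupancy = unname(x$occupancy)))
  invisible(x)
}

#' Exclusivity loss term for model retraining
#'
#' The retraining objective rewards predictions that differ from the
#' strongest competing organelle at every pixel: if the current organelle is
#' brightest, pushing it further above the runner-up; if not, pushing it
#' further below the leader. Both branches maximize
#' `mean(|pred - others_max|)`, so the loss is its negative and is minimized
#' during training.
#'
#' @param pred 3-D grid of the current model's predicted intensities.
#' @param others_max 3-D grid holding, per pixel, the maximum predicted
#'   intensity over all other organelle channels.
#' @return `-mean(abs(pred - others_max))`, a scalar `<= 0`.
#' @export
exclusivity_loss <- function(pred, others_max) {
  check_same_shape(pred, others_max)
  -mean(abs(pred - others_max))
}

check_same_shape <- function(a, b) {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (!identical(da, db)) abort("grids must have matching shapes.")
  invisible(TRUE)
}

#' Mean squared / absolute reconstruction error
#'
#' @param pred,truth Numeric arrays of identical shape.
#' @return A scalar.
#' @export
mse <- function(pred, truth) {
  check_same_shape(pred, truth)
  mean((pred - truth)^2)
}

#' @rdname mse
#' @export
mae <- function(pred, truth) {
  check_same_shape(pred, truth)
  mean(abs(pred - truth))
}

#' Combined retraining loss: reconstruction plus weighted exclusivity
#'
#' `base(pred, truth) + p * exclusivity_loss(pred, others_max)`. The
#' reconstruction base is mean-squared error by default; mean-absolute (L1)
#' error is offered for membrane-like structures whose thin morphology an
#' L2 fit tends to thicken. With `p = 0` the loss degenerates to the plain
#' reconstruction error.
#'
#' @inheritParams exclusivity_loss
#' @param truth Ground-truth intensity grid.
#' @param p Non-negative exclusivity weight.
#' @param base `"mse"` or `"l1"`.
#' @return A scalar loss value.
#' @export
combined_retrain_loss <- function(pred, truth, others_max, p, base = c("mse", "l1")) {
  base <- match.arg(base)
  if (!is.numeric(p) || length(p) != 1L || p < 0) abort("`p` must be a single weight >= 0.")
  recon <- switch(base, mse = mse(pred, truth), l1 = mae(pred, truth))
  recon + p * exclusivity_loss(pred, others_max)
}

#' Select the exclusivity weight by the exclusivity/MSE ratio
#'
#' Scans candidate weights and keeps the one whose retrained model attains
#' the highest ratio of overall exclusivity to overall MSE; exact ties go to
#' the smallest weight.
#'
#' @param candidates A data frame with columns `p`, `exclusivity`, `mse`
#'   (one row per tried weight), or a list of `c(p, exclusivity, mse)`
#'   triples.
#' @return The selected weight `p` (scalar).
#' @examples
#' select_weight(data.frame(p = 0:2, exclusivity = c(1, 1.5, 1.6),
#'                          mse = c(1, 1.2, 1.6)))  # 1
#' @export
select_weight <- function(candidates) {
  if (is.list(candidates) && !is.data.frame(candidates)) {
    candidates <- as.data.frame(do.call(rbind, lapply(candidates, function(x) {
      setNames(as.numeric(x[1:3]), c("p", "exclusivity", "mse"))
    })))
  }
  if (!all(c("p", "exclusivity", "mse") %in% names(candidates))) {
    abort("`candidates` needs columns p, exclusivity, mse.")
  }
  if (nrow(candidates) == 0L) abort("`candidates` is empty.")
  if (any(candidates$mse <= 0)) abort("all MSE values must be positive.")
  ratio <- candidates$exclusivity / candidates$mse
  best <- which(ratio == max(ratio))
  candidates$p[best[which.min(candidates$p[best])]]
}

#' Order organelle models for sequential retraining
#'
#' Retraining proceeds one organelle model at a time, ordered by each
#' organelle's initial exclusivity (default: decreasing, so the most
#' exclusive models anchor the predictions the later models are pushed away
#' from). Exclusivity ties are broken alphabetically.
#'
#' @param per_organelle Named numeric vector of initial organelle
#'   exclusivities; every value must be defined (non-`NA`).
#' @param direction `"decreasing"` (default) or `"increasing"`.
#' @return Character vector of organelle names in retraining order.
#' @export
retrain_order <- function(per_organelle, direction = c("decreasing", "increasing")) {
  direction <- match.arg(direction)
  if (is.null(names(per_organelle)) || any(!nzchar(names(per_organelle)))) {
    abort("`per_organelle` must be a named vector.")
  }
  bad <- names(per_organelle)[is.na(per_organelle)]
  if (length(bad)) {
    abort(sprintf("exclusivity undefined for: %s.", paste(bad, collapse = ", ")))
  }
  ord <- order(if (direction == "decreasing") -per_organelle else per_organelle,
               names(per_organelle))
  names(per_organelle)[ord]
}
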