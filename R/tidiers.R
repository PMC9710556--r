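#' Tidy an exclusivity report
#'
#' Long tibble with one row per metric value: the overall exclusivity, each
#' per-organelle exclusivity (with its occupancy) and each defined directed
#' pairwise entry. Undefined values (channels never the argmax) appear as
#' `NA`, not 0.
#'
#' @param x An [exclusivity_report()].
#' @param ... Unused.
#' @return A tibble with columns `metric`, `organelle`, `versus`, `value`.
#' @export
tidy.exclusivity_report <- function(x, ...) {
  pw <- tibble::as_tibble(as.data.frame(as.table(x$pairwise),
                                        stringsAsFactors = FALSE))
  names(pw) <- c("organelle", "versus", "value")
  dplyr::bind_rows(
    tibble::tibble(metric = "overall", organelle = NA_character_,
                   versus = NA_character_, value = x$overall),
    tibble::tibble(metric = "organelle", organelle = x$channel_names,
                   versus = NA_character_, value = unname(x$per_organelle)),
    tibble::tibble(metric = "occupancy", organelle = x$channel_names,
                   versus = NA_character_, value = unname(x$occupancy)),
    dplyr::mutate(pw[pw$organelle != pw$versus, ], metric = "pairwise",
                  .before = 1)
  )
}

#' @rdname tidy.exclusivity_report
#' @export
glance.exclusivity_report <- function(x, ...) {
  tibble::tibble(overall = x$overall, n_channels = length(x$channel_names),
                 n_pixels = x$n_pixels,
                 n_undefined = sum(is.na(x$per_organelle)))
}

#' Tidy a purity-divergence result
#'
#' @param x A [k_sweep()] result.
#' @param ... Unused.
#' @return `tidy()`: tibble `k`, `score` (nats), `p_value`. `glance()`: one
#'   row with the population sizes, reference purity and permutation count.
#' @export
tidy.divergence_result <- function(x, ...) x$score_by_k

#' @rdname tidy.divergence_result
#' @export
glance.divergence_result <- function(x, ...) {
  tibble::tibble(m = x$m, n = x$n, q = x$q,
                 n_permutations = x$n_permutations,
                 min_score = min(x$score_by_k$score),
                 max_score = max(x$score_by_k$score))
}

#' Tidy a spherical harmonic descriptor
#'
#' @param x A [fit_spharm()] descriptor.
#' @param ... Unused.
#' @return `tidy()`: tibble with `coordinate` (z/y/x), `l`, `m`, `value`.
#'   `glance()`: one-row summary (order, residual, degree-1 energy
#'   fraction).
#' @export
tidy.spharm_descriptor <- function(x, ...) {
  L <- x$order
  deg <- spharm_degrees(L)
  ord <- unlist(lapply(0:L, function(l) -l:l))
  purrr::map_dfr(1:3, function(cc) {
    tibble::tibble(coordinate = c("z", "y", "x")[cc], l = deg, m = ord,
                   value = x$coeffs[, cc])
  })
}

#' @rdname tidy.spharm_descriptor
#' @export
glance.spharm_descriptor <- function(x, ...) {
  deg <- spharm_degrees(x$order)
  en <- rowSums(x$coeffs^2)
  tibble::tibble(order = x$order, fit_residual = x$fit_residual,
                 energy_degree1 = sum(en[deg == 1]) / sum(en),
                 n_coefficients = 3 * (x$order + 1)^2)
}

#' Tidy an evaluation report
#'
#' @param x An [run_full_evaluation()] report.
#' @param ... Unused.
#' @return The per-organelle summary tibble (`tidy`) or a one-row overall
#'   summary (`glance`).
#' @export
tidy.evaluation_report <- function(x, ...) x$per_organelle

#' @rdname tidy.evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(overall_exclusivity = x$exclusivity$overall,
                 n_images = x$provenance$n_images,
                 n_organelles = nrow(x$per_organelle),
                 median_jaccard = stats::median(x$jaccard$jaccard),
                 config_hash = x$provenance$config_hash)
}
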