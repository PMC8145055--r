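#' Registration quality metrics
#'
#' For every point of the registered (transformed) cloud, the distance to the
#' nearest point of the reference cloud is computed; the metrics are the mean
#' and maximum of these distances and, for each threshold, the fraction of
#' points whose distance is strictly below it. The defaults follow the usual
#' evaluation of femur fine registration: points below 0.5 mm are counted as
#' coincident, and the fraction below 2 mm captures gross overlap.
#'
#' The measure is asymmetric by construction: distances run from the
#' transformed cloud to the reference, not the other way round.
#'
#' @param transformed the registered cloud.
#' @param reference the fixed reference (benchmark) cloud.
#' @param thresholds numeric vector of distance thresholds in mm.
#' @return object of class `"registration_quality"`: `mean_distance_mm`,
#'   `max_distance_mm`, `fractions` (named by threshold, in \[0, 1\]),
#'   `thresholds`, `n_points`.
#' @export
registration_quality <- function(transformed, reference, thresholds = c(0.5, 2)) {
  Tm <- as_cloud_matrix(transformed)
  Rm <- as_cloud_matrix(reference)
  if (!is.numeric(thresholds) || length(thresholds) < 1L || any(thresholds <= 0))
    stop("thresholds must be positive numbers", call. = FALSE)
  thresholds <- sort(thresholds)
  d <- cpp_nearest(Rm, Tm)$distance
  fr <- vapply(thresholds, function(th) mean(d < th), numeric(1))
  names(fr) <- paste0("lt_", vapply(thresholds, format, character(1)))
  structure(list(mean_distance_mm = mean(d),
                 max_distance_mm = max(d),
                 fractions = fr,
                 thresholds = thresholds,
                 n_points = length(d)),
            class = "registration_quality")
}

#' @export
print.registration_quality <- function(x, ...) {
  cat(sprintf("  n = %d points\n", x$n_points))
  cat(sprintf("  mean distance: %.2f mm   max distance: %.2f mm\n",
              x$mean_distance_mm, x$max_distance_mm))
  for (i in seq_along(x$thresholds))
    cat(sprintf("  points < %g mm: %.2f%%\n", x$thresholds[i], 100 * x$fractions[i]))
  invisible(x)
}

quality_to_list <- function(q) {
  out <- list(mean_mm = q$mean_distance_mm, max_mm = q$max_distance_mm,
              n = q$n_points)
  for (i in seq_along(q$thresholds)) {
    nm <- paste0("pct_lt_", gsub("\\.", "_", format(q$thresholds[i], trim = TRUE)))
    out[[nm]] <- 100 * unname(q$fractions[i])
  }
  out
}
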