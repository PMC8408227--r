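# Closed-form phenotype computations: doubling time, xenograft tumor
# volume, relative transwell migration.

#' Cell doubling time
#'
#' `Td = duration * log(2) / (log(final) - log(initial))`, applied between
#' the first and last timepoint (`mode = "endpoint"`, the default) or via
#' log-linear regression over all points (`mode = "fit"`, for noisy data).
#' A curve whose final count does not exceed its initial count is flagged
#' non-growing (`Td = NA`, `growing = FALSE`) rather than raising an error.
#'
#' @param curve A `growth_curve`.
#' @param mode `"endpoint"` or `"fit"`.
#' @return List with `Td` (hours, NA when non-growing) and `growing`.
#' @export
doubling_time <- function(curve, mode = c("endpoint", "fit")) {
  mode <- match.arg(mode)
  stopifnot(inherits(curve, "growth_curve"))
  n <- nrow(curve)
  if (mode == "endpoint") {
    duration <- curve$time[n] - curve$time[1]
    num <- log(curve$count[n]) - log(curve$count[1])
    if (num <= 0) return(list(Td = NA_real_, growing = FALSE))
    list(Td = duration * log(2) / num, growing = TRUE)
  } else {
    fit <- stats::lm(log2(count) ~ time, data = curve)
    slope <- unname(stats::coef(fit)[2])
    if (slope <= 0) return(list(Td = NA_real_, growing = FALSE))
    list(Td = 1 / slope, growing = TRUE)
  }
}

#' Xenograft tumor volume
#'
#' `volume = width^2 * length / 2` (mm^3). Calipers convention requires
#' width <= length; violated inputs are swapped with a warning.
#'
#' @param width,length Caliper measurements in mm (>= 0), vectorized.
#' @return Volume(s) in mm^3.
#' @export
tumor_volume <- function(width, length) {
  if (any(width < 0) || any(length < 0)) stop("measurements must be >= 0")
  swap <- width > length
  if (any(swap)) {
    warning("width > length for ", sum(swap),
            " measurement(s); swapped to caliper convention")
    tmp <- width[swap]
    width[swap] <- length[swap]
    length[swap] <- tmp
  }
  width^2 * length / 2
}

#' Relative transwell migration
#'
#' Number of migrated cells normalized to the total number of cells.
#'
#' @param migrated_count,total_count Cell counts; `total_count` > 0.
#' @return Ratio(s).
#' @export
relative_migration <- function(migrated_count, total_count) {
  if (any(total_count <= 0)) stop("total_count must be positive")
  if (any(migrated_count < 0)) stop("migrated_count must be >= 0")
  migrated_count / total_count
}
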