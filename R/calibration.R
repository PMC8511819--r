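#' Per-rod HU statistics from a labelled calibration phantom
#'
#' Summarizes the HU histogram of each segmented calibration rod: voxel
#' count, mean, median and sample SD (n - 1 convention), alongside the known
#' equivalent mineral density of the rod.
#'
#' @param vol An [image_volume()] of HU.
#' @param labels Integer 3-D label array coded per [fracenv_labels()].
#' @param rod_densities Six strictly increasing known densities (g/cm^3).
#' @return A `rod_stats` data.frame with columns `rod`, `n_voxels`, `mean_hu`,
#'   `median_hu`, `sd_hu`, `density`.
#' @export
extract_rod_stats <- function(vol, labels, rod_densities) {
  if (length(rod_densities) < 2L) stop("need at least two rod densities")
  if (any(diff(rod_densities) <= 0)) stop("rod densities must be strictly increasing")
  codes <- fracenv_labels()
  rows <- lapply(seq_along(rod_densities), function(k) {
    code <- codes[[paste0("rod_", k)]]
    hu <- vol$data[labels == code]
    if (length(hu) == 0L)
      stop("rod label missing or empty: rod_", k, " (code ", code, ")")
    data.frame(rod = k, n_voxels = length(hu), mean_hu = mean(hu),
               median_hu = median(hu),
               sd_hu = if (length(hu) > 1L) sd(hu) else 0,
               density = rod_densities[k])
  })
  structure(do.call(rbind, rows), class = c("rod_stats", "data.frame"))
}

#' Fit the HU to equivalent-mineral-density calibration line
#'
#' Ordinary least squares of known rod density on rod median HU (the median
#' is robust to partial-volume voxels at the rod rim).
#'
#' @param stats A `rod_stats` data.frame from [extract_rod_stats()].
#' @return A `calibration_model` list with `slope` ((g/cm^3)/HU), `intercept`
#'   (g/cm^3), `r_squared` and `n_rods`. A warning is issued when R^2 falls
#'   below 0.99.
#' @export
fit_hu_to_density <- function(stats) {
  if (nrow(stats) < 2L) stop("need at least two rods to fit a calibration line")
  hu <- stats$median_hu
  if (diff(range(hu)) == 0) stop("degenerate calibration: all rod HU values equal")
  fit <- lm(density ~ median_hu, data = stats)
  # R^2 computed directly (summary.lm warns on numerically perfect fits)
  sst <- sum((stats$density - mean(stats$density))^2)
  r2 <- if (nrow(stats) == 2L || sst == 0) 1
        else 1 - sum(fit$residuals^2) / sst
  if (r2 < 0.99)
    warning(sprintf("calibration R^2 = %.4f is below 0.99; check rod segmentation", r2))
  structure(list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 r_squared = r2, n_rods = nrow(stats)),
            class = "calibration_model")
}

#' @exportS3Method base::print
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> rho_eqm = %.6g * HU + %.6g  (R^2 = %.6f, %d rods)\n",
              x$slope, x$intercept, x$r_squared, x$n_rods))
  invisible(x)
}

#' Apply a calibration model voxel-wise
#'
#' Maps HU to equivalent mineral density, `rho_eqm = slope * HU + intercept`,
#' clamped below at zero (ash density downstream must be non-negative).
#'
#' @param vol An [image_volume()] of HU.
#' @param model A `calibration_model`.
#' @return An [image_volume()] of equivalent mineral density (g/cm^3).
#' @export
apply_calibration <- function(vol, model) {
  if (!inherits(model, "calibration_model")) stop("invalid calibration model")
  rho <- model$slope * vol$data + model$intercept
  rho[rho < 0] <- 0
  image_volume(rho, spacing = vol$spacing, origin = vol$origin)
}

#' Convert a density threshold to HU under a calibration model
#' @param density g/cm^3.
#' @param model A `calibration_model`.
#' @return HU value mapping to `density`.
#' @export
density_to_hu <- function(density, model) {
  (density - model$intercept) / model$slope
}
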