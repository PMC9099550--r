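#' Construct a binned nanoparticle size distribution
#'
#' One nanoparticle-tracking measurement: particle concentration per size bin
#' over the 10-1000 nm detection range, together with the dilution factor
#' applied to the plasma before measurement.
#'
#' @param bin_centers Strictly increasing bin centers in nm, within
#'   \[10, 1000\].
#' @param concentration Non-negative particle concentrations (particles/mL)
#'   per bin; at least one positive value.
#' @param dilution_factor Dimensionless dilution factor >= 1 (default 1).
#' @return An object of class `size_distribution`.
#' @export
size_distribution <- function(bin_centers, concentration, dilution_factor = 1) {
  bin_centers <- as.numeric(bin_centers)
  concentration <- as.numeric(concentration)
  if (length(bin_centers) != length(concentration))
    stop("bin_centers and concentration must have equal length", call. = FALSE)
  if (length(bin_centers) < 3L)
    stop("need at least 3 size bins", call. = FALSE)
  if (any(diff(bin_centers) <= 0))
    stop("bin_centers must be strictly increasing", call. = FALSE)
  if (min(bin_centers) < 10 - 1e-9 || max(bin_centers) > 1000 + 1e-9)
    stop("bin centers must lie within 10-1000 nm", call. = FALSE)
  if (any(concentration < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  if (all(concentration == 0))
    stop("all-zero concentration: no particles detected", call. = FALSE)
  if (dilution_factor < 1)
    stop("dilution_factor must be >= 1", call. = FALSE)
  structure(list(bin_centers = bin_centers, concentration = concentration,
                 dilution_factor = dilution_factor),
            class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf("size_distribution: %d bins, %.0f-%.0f nm, dilution %.0fx\n",
              length(x$bin_centers), min(x$bin_centers), max(x$bin_centers),
              x$dilution_factor))
  invisible(x)
}

#' Read a binned size distribution
#'
#' CSV with header `size_nm,concentration`; an optional sidecar TSV (columns
#' `sample`, `dilution_factor`) carries per-sample metadata.
#'
#' @param path CSV path.
#' @param dilution_factor Dilution factor; overrides the sidecar.
#' @param sidecar Optional path to the metadata TSV.
#' @param sample Sample name to look up in the sidecar.
#' @return A [size_distribution()].
#' @export
read_size_distribution <- function(path, dilution_factor = NULL,
                                   sidecar = NULL, sample = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("size_nm", "concentration") %in% names(d)))
    stop("distribution CSV must have columns size_nm,concentration",
         call. = FALSE)
  if (is.null(dilution_factor)) {
    dilution_factor <- 1
    if (!is.null(sidecar)) {
      meta <- utils::read.delim(sidecar)
      i <- if (is.null(sample)) 1L else match(sample, meta$sample)
      if (is.na(i)) stop("sample not found in sidecar", call. = FALSE)
      dilution_factor <- meta$dilution_factor[i]
    }
  }
  size_distribution(d$size_nm, d$concentration, dilution_factor)
}

# trapezoidal integral of y over x
.trapz <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1]) / 2)

#' Summary features of a particle size distribution
#'
#' Area under the concentration curve (trapezoidal rule, i.e. total particle
#' concentration), concentration-weighted mean, SD and skewness of particle
#' size, the modal bin, the median size (cumulative trapezoidal integral,
#' interpolated linearly within the crossing bin), and the dilution-corrected
#' original particle volume.
#'
#' Skewness is the standardized third central weighted moment; it is defined
#' as 0 for a degenerate (zero-SD) distribution.
#'
#' @param dist A [size_distribution()].
#' @return A one-row `data.frame` with columns `auc`, `mean_size`, `sd_size`,
#'   `skewness`, `mode_size`, `median_size`, `original_particle_volume`.
#' @export
distribution_features <- function(dist) {
  stopifnot(inherits(dist, "size_distribution"))
  s <- dist$bin_centers
  c_ <- dist$concentration
  w <- c_ / sum(c_)
  mean_size <- sum(w * s)
  v <- sum(w * (s - mean_size)^2)
  sd_size <- sqrt(v)
  skew <- if (sd_size > 0) sum(w * (s - mean_size)^3) / sd_size^3 else 0
  cum <- c(0, cumsum(diff(s) * (c_[-length(c_)] + c_[-1]) / 2))
  auc <- cum[length(cum)]
  half <- auc / 2
  k <- which(cum >= half)[1]
  median_size <- if (k == 1L) s[1] else
    s[k - 1] + (half - cum[k - 1]) / (cum[k] - cum[k - 1]) * (s[k] - s[k - 1])
  data.frame(
    auc = auc,
    mean_size = mean_size,
    sd_size = sd_size,
    skewness = skew,
    mode_size = s[which.max(c_)],
    median_size = median_size,
    original_particle_volume = original_particle_volume(dist)
  )
}

#' Dilution-corrected total particle volume
#'
#' Sum over bins of concentration times the volume of a sphere with the bin's
#' diameter, multiplied by the dilution factor; units nm^3 per mL of the
#' original (undiluted) plasma.
#'
#' @param dist A [size_distribution()].
#' @return Scalar particle volume in nm^3/mL.
#' @export
original_particle_volume <- function(dist) {
  stopifnot(inherits(dist, "size_distribution"))
  sum(dist$concentration * (4 / 3) * pi * (dist$bin_centers / 2)^3) *
    dist$dilution_factor
}

#' Average distributions measured at several dilutions
#'
#' Each measurement is first corrected to original-plasma concentrations
#' (multiplied by its dilution factor); per-bin concentrations are then
#' averaged with weights proportional to each measurement's total corrected
#' particle count, so runs that traced more particles carry more weight.
#' All measurements must share the bin grid.
#'
#' @param dists List of [size_distribution()] objects on a common grid.
#' @return A [size_distribution()] with `dilution_factor = 1` (already
#'   corrected).
#' @export
average_dilutions <- function(dists) {
  stopifnot(length(dists) >= 1L,
            all(vapply(dists, inherits, logical(1), "size_distribution")))
  grid <- dists[[1]]$bin_centers
  for (d in dists)
    if (!isTRUE(all.equal(d$bin_centers, grid)))
      stop("all measurements must share the same bin grid", call. = FALSE)
  corr <- lapply(dists, function(d) d$concentration * d$dilution_factor)
  wts <- vapply(corr, sum, numeric(1))
  avg <- Reduce(`+`, Map(`*`, corr, wts / sum(wts)))
  size_distribution(grid, avg, dilution_factor = 1)
}
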