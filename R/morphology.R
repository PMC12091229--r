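#' Acute angle between a cell axis and the construct axis
#'
#' Orientation-insensitive angle in degrees, folded to \[0, 90\]:
#' `v` and `-v` (and `a` and `-a`) give identical results.
#'
#' @param cell_axis,construct_axis Non-zero 2-D vectors.
#' @return Angle in degrees in \[0, 90\].
#' @examples
#' axis_angle(c(1, 1), c(1, 0))    # 45
#' axis_angle(c(-1, 1), c(1, 0))   # 45 (acute convention)
#' @export
axis_angle <- function(cell_axis, construct_axis) {
  if (length(cell_axis) != 2 || length(construct_axis) != 2)
    stop_tenomech("invalid_parameter", "axes must be 2-D vectors")
  nv <- sqrt(sum(cell_axis^2)); na <- sqrt(sum(construct_axis^2))
  if (nv == 0 || na == 0)
    stop_tenomech("invalid_parameter", "zero-length axis vector")
  cosang <- min(abs(sum(cell_axis * construct_axis)) / (nv * na), 1)
  acos(cosang) * 180 / pi
}

#' Mean cell-axis angle of one construct
#'
#' Arithmetic mean of the per-cell acute angles of a construct at a given
#' day (the per-dot quantity of the orientation analysis, nominally 15
#' cells per construct). Fewer than 15 cells raises a warning.
#'
#' @param set Orientation table with columns `construct_id`, `day`,
#'   `angle_deg`.
#' @param construct_id,day Selection keys.
#' @return Mean angle in degrees.
#' @export
construct_mean_angle <- function(set, construct_id, day) {
  rows <- set[set$construct_id == construct_id & set$day == day, ]
  if (!nrow(rows))
    stop_tenomech("invalid_parameter", "no cells for construct %s day %s",
                  construct_id, day)
  if (nrow(rows) < 15)
    warning(sprintf("construct %s day %s: only %d cells (< 15)",
                    construct_id, day, nrow(rows)), call. = FALSE)
  mean(rows$angle_deg)
}

#' Cross-sectional area of a cylindrical construct
#'
#' @param diameter Diameter in mm (> 0).
#' @return Area in mm^2: `pi * d^2 / 4`.
#' @examples
#' cross_sectional_area(2)   # pi
#' @export
cross_sectional_area <- function(diameter) {
  if (any(!is.finite(diameter)) || any(diameter <= 0))
    stop_tenomech("invalid_parameter", "diameter must be positive")
  pi * diameter^2 / 4
}

#' Volume fold change between two diameters at fixed length
#'
#' The constructs are held between fixed anchor points, so their length is
#' constant and the volume ratio reduces to the squared diameter ratio:
#' `(d_start / d_end)^2`. With the measured Day-0 and Day-21 mean
#' diameters (2.08 and 0.55 mm) this gives ~14.3, i.e. an about 15-fold
#' volume reduction.
#'
#' @param d_start,d_end Diameters in mm (both > 0).
#' @return Dimensionless volume ratio.
#' @examples
#' volume_fold_change(2.08, 0.55)   # ~14.3
#' @export
volume_fold_change <- function(d_start, d_end) {
  if (!is.finite(d_start) || !is.finite(d_end) ||
      d_start <= 0 || d_end <= 0)
    stop_tenomech("invalid_parameter", "diameters must be positive")
  (d_start / d_end)^2
}

#' Regional cell density
#'
#' Density (cells/mm^2) of the centre and periphery regions from
#' pre-labelled counts and region areas. The centre/periphery boundary is
#' an input annotation of the count table, not computed here.
#'
#' @param rec Data frame with columns `construct_id`, `day`, `region`
#'   (`"centre"`/`"periphery"`), `cell_count`, `region_area` (mm^2).
#' @return The same data frame with a `density` column.
#' @examples
#' cell_density(data.frame(construct_id = "c1", day = 0,
#'                         region = "centre", cell_count = 40,
#'                         region_area = 0.02))$density   # 2000
#' @export
cell_density <- function(rec) {
  need <- c("construct_id", "day", "region", "cell_count", "region_area")
  if (!all(need %in% names(rec)))
    stop_tenomech("format_error", "density table must have columns %s",
                  paste(need, collapse = ", "))
  if (any(!is.finite(rec$region_area)) || any(rec$region_area <= 0))
    stop_tenomech("invalid_parameter", "region_area must be positive")
  rec$density <- rec$cell_count / rec$region_area
  rec
}

#' Centre-vs-periphery density comparison per day
#'
#' Exact Mann-Whitney comparison of centre and periphery densities within
#' each day, with star annotations.
#'
#' @param dens Output of [cell_density()].
#' @return Data frame `day`, `n_centre`, `n_periphery`, `U`, `p`, `stars`.
#' @export
compare_density <- function(dens) {
  rows <- lapply(split(dens, dens$day), function(d) {
    ce <- d$density[d$region == "centre"]
    pe <- d$density[d$region == "periphery"]
    tst <- mann_whitney_exact(ce, pe)
    data.frame(day = d$day[1], n_centre = length(ce),
               n_periphery = length(pe), U = tst$U, p = tst$p.value,
               stars = significance_stars(tst$p.value))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$day), ]
  rownames(out) <- NULL
  out
}
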