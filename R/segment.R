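#' Split an indentation record into loading / hold / unloading phases
#'
#' Phases are detected from the cantilever-base position `z` alone, so the
#' segmentation is unaffected by force noise. Loading is the first
#' monotone advance of the base, the hold is the subsequent plateau
#' (|z - median(z_plateau)| below `plateau_tol`), and unloading the first
#' monotone retreat after it. A record with no advancing phase raises a
#' `no_loading` error; a record with no plateau returns an empty hold
#' range with a warning.
#'
#' @param record A [force_record()].
#' @param plateau_tol Plateau tolerance on z in um; default 5e-3 (5 nm,
#'   piezo-resolution scale).
#' @return An object of class `segmented_curve`: the record plus integer
#'   index ranges `load`, `hold`, `unload` (empty ranges are `integer(0)`).
#' @examples
#' probe <- probe_config(rate = 500)
#' rec <- simulate_relaxation_record(sls_material(2000, 1300, 2), probe)
#' seg <- segment_phases(rec)
#' length(seg$hold)
#' @export
segment_phases <- function(record, plateau_tol = 5e-3) {
  stopifnot(inherits(record, "force_record"))
  z <- record$z
  dz <- diff(z)
  eps <- plateau_tol / 10
  dir <- ifelse(dz > eps, 1L, ifelse(dz < -eps, -1L, 0L))
  r <- rle(dir)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  # run k covers intervals starts[k]..ends[k] = samples starts[k]..ends[k]+1
  k_load <- which(r$values == 1L)[1]
  if (is.na(k_load))
    stop_tenomech("no_loading", "record has no monotone advancing phase")
  load <- starts[k_load]:(ends[k_load] + 1L)

  hold <- integer(0)
  k_hold <- which(r$values == 0L & seq_along(r$values) > k_load &
                    r$lengths >= 4L)[1]
  if (!is.na(k_hold)) {
    idx <- starts[k_hold]:(ends[k_hold] + 1L)
    if (all(abs(z[idx] - median(z[idx])) < plateau_tol))
      hold <- idx[idx > max(load)]
  }
  if (!length(hold))
    warning("no hold plateau detected; hold range is empty",
            call. = FALSE)

  unload <- integer(0)
  after <- if (length(hold)) max(hold) else max(load)
  k_un <- which(r$values == -1L & (ends + 1L) > after)[1]
  if (!is.na(k_un)) {
    idx <- starts[k_un]:(ends[k_un] + 1L)
    unload <- idx[idx > after]
  }

  structure(list(record = record, load = load, hold = hold, unload = unload),
            class = "segmented_curve")
}

#' @export
print.segmented_curve <- function(x, ...) {
  fmt <- function(i) if (length(i)) sprintf("%d..%d", min(i), max(i)) else "-"
  cat(sprintf("<segmented_curve> '%s': load %s | hold %s | unload %s\n",
              x$record$meta$label, fmt(x$load), fmt(x$hold), fmt(x$unload)))
  invisible(x)
}

as_segmented <- function(x) {
  if (inherits(x, "segmented_curve")) x
  else if (inherits(x, "force_record")) segment_phases(x)
  else stop_tenomech("invalid_parameter",
                     "expected a force_record or segmented_curve")
}
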