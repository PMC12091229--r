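#' Indentation force record
#'
#' Container for one indentation experiment: time `t` (s, strictly
#' increasing), cantilever-base position `z` (um), force `F` (uN) and a
#' metadata list that must carry at least the cantilever stiffness
#' `k_cant` (N/m), tip radius `R_tip` (um), sampling `rate` (Hz) and a
#' free-text `label`. An optional `phase` annotation
#' (`"load"`/`"hold"`/`"unload"`) may accompany simulated records.
#'
#' @param t Time in s, strictly increasing.
#' @param z Cantilever-base position in um.
#' @param F Force in uN.
#' @param meta Named list with at least `k_cant`, `R_tip`, `rate`, `label`.
#'   Extra keys (e.g. simulation ground truth) are preserved and written to
#'   file headers.
#' @param phase Optional character vector of per-sample phase annotations.
#' @return An object of class `force_record`.
#' @export
force_record <- function(t, z, F, meta, phase = NULL) {
  n <- length(t)
  if (length(z) != n || length(F) != n)
    stop_tenomech("format_error", "t, z, F must have equal length")
  if (n < 100)
    stop_tenomech("format_error",
                  "force record needs >= 100 samples, got %d", n)
  if (any(diff(t) <= 0))
    stop_tenomech("format_error", "time must be strictly increasing")
  if (!is.null(phase) && length(phase) != n)
    stop_tenomech("format_error", "phase annotation length mismatch")
  required <- c("k_cant", "R_tip", "rate", "label")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop_tenomech("format_error", "record meta lacks key(s): %s",
                  paste(missing, collapse = ", "))
  structure(list(t = as.numeric(t), z = as.numeric(z), F = as.numeric(F),
                 meta = meta, phase = phase),
            class = "force_record")
}

#' @export
print.force_record <- function(x, ...) {
  cat(sprintf(
    "<force_record> '%s': %d samples, %.3g s, z %.3g..%.3g um, F max %.4g uN\n",
    x$meta$label, length(x$t), max(x$t) - min(x$t),
    min(x$z), max(x$z), max(x$F)))
  invisible(x)
}

# Header keys coerced to numeric on read; everything else stays character.
.numeric_meta_keys <- c("k_cant", "R_tip", "rate", "z_contact", "E_true",
                        "E0", "E_inf", "tau", "alpha", "noise_sd", "speed",
                        "seed", "day")

#' Write an indentation record to the TSV interchange format
#'
#' The dialect is plain text: `# key: value` header lines carrying the
#' metadata, then a tab-separated table with columns `time_s`, `base_um`,
#' `force_uN` and, when the record carries phase annotations, `phase`.
#' Numbers are written with 17 significant digits so that a write-read
#' round trip is bit-identical.
#'
#' @param record A [force_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_force_record <- function(record, path) {
  stopifnot(inherits(record, "force_record"))
  meta <- record$meta
  hdr <- sprintf("# %s: %s", names(meta),
                 vapply(meta, function(v) {
                   if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
                 }, character(1)))
  cols <- c("time_s", "base_um", "force_uN")
  body <- paste(sprintf("%.17g", record$t),
                sprintf("%.17g", record$z),
                sprintf("%.17g", record$F), sep = "\t")
  if (!is.null(record$phase)) {
    cols <- c(cols, "phase")
    body <- paste(body, record$phase, sep = "\t")
  }
  writeLines(c(hdr, paste(cols, collapse = "\t"), body), path)
  invisible(path)
}

#' Read an indentation record from the TSV interchange format
#'
#' @param path File written by [write_force_record()] (or any file in the
#'   same dialect).
#' @return A [force_record()].
#' @export
read_force_record <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines))
    stop_tenomech("format_error", "empty record file: %s", path)
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  meta <- list()
  for (ln in hdr) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) {
      key <- trimws(m[2]); val <- trimws(m[3])
      meta[[key]] <- if (key %in% .numeric_meta_keys) as.numeric(val) else val
    }
  }
  required <- c("k_cant", "R_tip", "rate", "label")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop_tenomech("format_error", "%s: header lacks key(s): %s",
                  path, paste(missing, collapse = ", "))
  body <- lines[!is_hdr]
  body <- body[nzchar(body)]
  if (length(body) < 2)
    stop_tenomech("format_error", "%s: no data rows", path)
  tab <- tryCatch(
    read.delim(text = body, header = TRUE, sep = "\t",
               colClasses = NA, check.names = FALSE),
    error = function(e)
      stop_tenomech("format_error", "%s: malformed table (%s)",
                    path, conditionMessage(e)))
  need <- c("time_s", "base_um", "force_uN")
  if (!all(need %in% names(tab)))
    stop_tenomech("format_error", "%s: columns must include %s",
                  path, paste(need, collapse = ", "))
  if (any(!stats::complete.cases(tab[need])))
    stop_tenomech("format_error", "%s: non-numeric or missing values", path)
  if (any(diff(tab$time_s) <= 0))
    stop_tenomech("format_error", "%s: time not strictly increasing", path)
  force_record(tab$time_s, tab$base_um, tab$force_uN, meta,
               phase = if ("phase" %in% names(tab)) as.character(tab$phase))
}
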