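#' Per-sample delta-Ct against the reference gene
#'
#' For every sample, subtracts the reference-gene Ct (YWHAZ by default)
#' from each target-gene Ct: `dCt = Ct_gene - Ct_ref`. Samples lacking a
#' reference measurement are dropped with a warning. Reference-gene rows
#' themselves are not returned.
#'
#' @param ct Data frame with columns `gene`, `sample_id`, `day`, `ct` and
#'   optionally `detected` (logical; assumed `TRUE` when absent).
#' @param ref_gene Reference gene name. Default `"YWHAZ"`.
#' @return Data frame with columns `gene`, `sample_id`, `day`, `ct`,
#'   `ct_ref`, `dct`, `detected`.
#' @examples
#' ct <- data.frame(gene = c("COL1A1", "YWHAZ"), sample_id = "s1",
#'                  day = 0, ct = c(25, 20))
#' delta_ct(ct)$dct    # 5
#' @export
delta_ct <- function(ct, ref_gene = "YWHAZ") {
  need <- c("gene", "sample_id", "day", "ct")
  if (!all(need %in% names(ct)))
    stop_tenomech("format_error", "ct table must have columns %s",
                  paste(need, collapse = ", "))
  if (!ref_gene %in% ct$gene)
    stop_tenomech("configuration_error",
                  "reference gene '%s' absent from the table", ref_gene)
  if (!"detected" %in% names(ct)) ct$detected <- TRUE
  ref <- ct[ct$gene == ref_gene, ]
  ref_ct <- tapply(ref$ct, ref$sample_id, mean)
  out <- ct[ct$gene != ref_gene, ]
  has_ref <- out$sample_id %in% names(ref_ct)
  if (any(!has_ref)) {
    warning(sprintf("dropping %d row(s) from sample(s) without reference Ct: %s",
                    sum(!has_ref),
                    paste(unique(out$sample_id[!has_ref]), collapse = ", ")),
            call. = FALSE)
    out <- out[has_ref, ]
  }
  out$ct_ref <- as.numeric(ref_ct[out$sample_id])
  out$dct <- out$ct - out$ct_ref
  rownames(out) <- NULL
  out[, c("gene", "sample_id", "day", "ct", "ct_ref", "dct", "detected")]
}

#' 2^-ddCt fold changes against a control group
#'
#' For each gene, `ddCt = dCt - mean(dCt of the control group)` and
#' `fold = 2^-ddCt`. Because the control mean (not per-sample pairing)
#' defines the reference level, the control group's summary fold change
#' `2^-mean(ddCt)` is exactly 1, matching the convention "control
#' normalised to 1".
#'
#' @param dct Output of [delta_ct()] (columns `gene`, `sample_id`, `day`,
#'   `dct`, and `detected` when control is `"first_detection"`).
#' @param control_day Either a day number (default 0) used as control for
#'   every gene, or `"first_detection"` to normalise each gene to its
#'   first day of detection (see [first_detection_day()]).
#' @param detection_frac Replicate fraction required for detection when
#'   `control_day = "first_detection"`. Default 0.5.
#' @return Data frame with columns `gene`, `sample_id`, `day`, `dct`,
#'   `ddct`, `fold`, `control_day`, `ctrl_mean_dct` (the control-group
#'   mean dCt used as the per-gene reference level).
#' @seealso [fold_change_summary()] for gene-by-day group summaries.
#' @export
fold_change_ddct <- function(dct, control_day = 0, detection_frac = 0.5) {
  out <- NULL
  for (g in unique(dct$gene)) {
    rows <- dct[dct$gene == g, ]
    cd <- if (identical(control_day, "first_detection")) {
      first_detection_day(rows, g, min_frac = detection_frac)
    } else control_day
    ctrl <- rows$dct[rows$day == cd]
    if (is.na(cd) || !length(ctrl))
      stop_tenomech("configuration_error",
                    "gene %s: empty control group (day %s)", g,
                    if (is.na(cd)) "undetected" else cd)
    ctrl_mean <- mean(ctrl)
    rows$ddct <- rows$dct - ctrl_mean
    rows$fold <- 2^(-rows$ddct)
    rows$control_day <- cd
    rows$ctrl_mean_dct <- ctrl_mean
    out <- rbind(out, rows)
  }
  rownames(out) <- NULL
  out
}

#' Gene-by-day fold-change summary
#'
#' Group summary of a [fold_change_ddct()] table: per gene and day, the
#' number of samples, mean ddCt and the group fold change
#' `2^-mean(ddCt)` (exactly 1 for the control group).
#'
#' @param fc Output of [fold_change_ddct()].
#' @return Data frame `gene`, `day`, `n`, `mean_ddct`, `fold`,
#'   `control_day`.
#' @export
fold_change_summary <- function(fc) {
  key <- interaction(fc$gene, fc$day, drop = TRUE)
  rows <- lapply(split(fc, key), function(d) {
    # group mean dCt minus the control mean: bitwise zero for the control
    # group itself, so its fold is exactly 1
    mean_ddct <- mean(d$dct) - d$ctrl_mean_dct[1]
    data.frame(gene = d$gene[1], day = d$day[1], n = nrow(d),
               mean_ddct = mean_ddct, fold = 2^(-mean_ddct),
               control_day = d$control_day[1])
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene, out$day), ]
  rownames(out) <- NULL
  out
}

#' Single-pass 2-SD outlier exclusion
#'
#' Drops values lying more than two sample standard deviations above or
#' below the mean. The rule is applied once (mean and SD are not
#' recomputed after exclusion). Groups of fewer than three values are
#' returned unchanged with a warning; a zero-SD group excludes nothing.
#'
#' @param values Numeric vector.
#' @return The filtered vector; the integer indices of the dropped values
#'   are attached as attribute `"excluded"`.
#' @examples
#' exclude_outliers_2sd(c(rep(0, 9), 10))   # drops the 10
#' @export
exclude_outliers_2sd <- function(values) {
  n <- length(values)
  if (n < 3) {
    warning("fewer than 3 values; no outlier exclusion applied",
            call. = FALSE)
    return(structure(values, excluded = integer(0)))
  }
  m <- mean(values); s <- sd(values)
  drop <- if (s > 0) abs(values - m) > 2 * s else rep(FALSE, n)
  structure(values[!drop], excluded = which(drop))
}

#' First day a gene is called detected
#'
#' Walks the design days in order and returns the earliest day on which
#' the gene is detected (Ct below the cutoff, i.e. `detected` flag true)
#' in at least `min_frac` of the replicates. Returns `NA` when the gene is
#' never detected.
#'
#' @param ct Ct (or dCt) table with columns `gene`, `day`, `detected`.
#' @param gene Gene name.
#' @param min_frac Minimum detected fraction per day. Default 0.5.
#' @return The day (numeric), or `NA_real_` for a never-detected gene.
#' @export
first_detection_day <- function(ct, gene, min_frac = 0.5) {
  rows <- ct[ct$gene == gene, ]
  if (!nrow(rows))
    stop_tenomech("configuration_error", "gene %s absent from table", gene)
  if (!"detected" %in% names(rows))
    stop_tenomech("format_error", "table has no 'detected' column")
  for (d in sort(unique(rows$day))) {
    det <- rows$detected[rows$day == d]
    if (mean(det) >= min_frac) return(as.numeric(d))
  }
  NA_real_
}

#' Exact Mann-Whitney U test
#'
#' Two-sided rank-sum test reporting `U = min(U_A, U_B)`. With no ties
#' and `min(n_A, n_B) <= 8` the p-value is exact, evaluated from the full
#' null distribution of U; otherwise the normal approximation with tie
#' correction (and continuity correction) is used. Degenerate cases where
#' the null variance is zero return p = 1.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @return List of class `mw_test`: `U`, `p.value`, `method`.
#' @examples
#' mann_whitney_exact(c(1, 2), c(3, 4))$p.value   # 1/3
#' @export
mann_whitney_exact <- function(a, b) {
  if (!length(a) || !length(b))
    stop_tenomech("invalid_parameter", "both groups must be non-empty")
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  U_b <- na * nb - U_a
  U <- min(U_a, U_b)
  ties <- any(duplicated(pooled))
  if (!ties && min(na, nb) <= 8) {
    # exact: P(U <= u) + P(U >= n_a n_b - u) over all C(N, n_a) labelings
    p <- pwilcox(U, na, nb) +
      (1 - pwilcox(na * nb - U - 1, na, nb))
    p <- min(1, p)
    method <- "exact"
  } else {
    N <- na + nb
    tie_tab <- table(pooled)
    sigma2 <- na * nb / 12 *
      ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      mu <- na * nb / 2
      zstat <- (abs(U - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(zstat, 0)))
    }
    method <- "normal approximation with tie correction"
  }
  structure(list(U = U, p.value = p, method = method), class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("<mw_test> U = %g, p = %.4g (%s)\n", x$U, x$p.value, x$method))
  invisible(x)
}

#' Significance stars
#'
#' Conventional significance tiers: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001,
#' `****` p < 0.0001; `ns` otherwise. No multiple-testing correction is
#' applied anywhere in the pipeline.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star annotations.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) NA_character_
    else if (pp < 1e-4) "****"
    else if (pp < 1e-3) "***"
    else if (pp < 1e-2) "**"
    else if (pp < 0.05) "*"
    else "ns"
  }, character(1))
}
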