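# Default qPCR design: culture days and per-day replicate counts of the
# expression experiments (Day 0 n=29, Day 2 n=19, Day 4 n=18, Day 7 n=25,
# Day 14 n=17, Day 21 n=16).
.design_days <- c(0, 2, 4, 7, 14, 21)
.design_n <- c(`0` = 29, `2` = 19, `4` = 18, `7` = 25, `14` = 17, `21` = 16)

#' Simulate a qPCR Ct table
#'
#' Generates per-sample cycle thresholds with prescribed per-gene log2
#' fold-change trajectories: `Ct(gene, sample) = ct_base(gene) -
#' log2fc(gene, day) + noise`, with the reference gene centred at
#' `ct_ref`. A trajectory value of `NA` encodes an undetected gene-day:
#' its wells are written at the detection cutoff with `detected = FALSE`.
#'
#' @param day_effects Data frame with columns `gene`, `day`, `log2fc`
#'   (`NA` = undetected at that day). Days absent from a gene's rows get
#'   effect 0.
#' @param n_reps Replicates per day: a single count or a vector named by
#'   day. Default: the per-day design counts (29/19/18/25/17/16 for days
#'   0/2/4/7/14/21). Must be >= 3.
#' @param ct_ref Reference-gene Ct level in cycles. Default 18.
#' @param noise_sd Gaussian Ct noise sd in cycles (applied to every well,
#'   reference included). Default 0.
#' @param seed Integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @param ct_base Baseline Ct per gene: single value or vector named by
#'   gene. Default 25.
#' @param cutoff Detection cutoff in cycles. Default 35.
#' @param ref_gene Reference gene name. Default `"YWHAZ"`.
#' @return Data frame `gene`, `sample_id`, `day`, `ct`, `detected`.
#' @examples
#' eff <- data.frame(gene = "COL1A1", day = c(0, 7), log2fc = c(0, 1))
#' ct <- simulate_ct_table(eff, n_reps = 4, seed = 1)
#' @export
simulate_ct_table <- function(day_effects, n_reps = .design_n, ct_ref = 18,
                              noise_sd = 0, seed = NULL, ct_base = 25,
                              cutoff = 35, ref_gene = "YWHAZ") {
  need <- c("gene", "day", "log2fc")
  if (!all(need %in% names(day_effects)))
    stop_tenomech("configuration_error",
                  "day_effects must have columns %s",
                  paste(need, collapse = ", "))
  if (ref_gene %in% day_effects$gene)
    stop_tenomech("configuration_error",
                  "reference gene '%s' is generated from ct_ref; remove it from day_effects",
                  ref_gene)
  days <- sort(unique(day_effects$day))
  genes <- unique(day_effects$gene)
  reps_of <- function(d) {
    n <- if (length(n_reps) == 1L && is.null(names(n_reps))) n_reps
         else if (as.character(d) %in% names(n_reps)) n_reps[[as.character(d)]]
         else stop_tenomech("configuration_error",
                            "n_reps has no entry for day %s", d)
    if (n < 3)
      stop_tenomech("configuration_error", "n_reps must be >= 3")
    n
  }
  base_of <- function(g) {
    if (length(ct_base) == 1L && is.null(names(ct_base))) ct_base
    else if (g %in% names(ct_base)) ct_base[[g]]
    else 25
  }
  with_seed(seed, {
    out <- NULL
    for (d in days) {
      n <- reps_of(d)
      samples <- sprintf("D%g_r%02d", d, seq_len(n))
      # reference gene once per sample
      ref_ct <- ct_ref + if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
      out <- rbind(out, data.frame(gene = ref_gene, sample_id = samples,
                                   day = d, ct = ref_ct, detected = TRUE))
      for (g in genes) {
        fc_rows <- day_effects[day_effects$gene == g & day_effects$day == d, ]
        fc <- if (nrow(fc_rows)) fc_rows$log2fc[1] else 0
        if (is.na(fc)) {
          ct <- rep(cutoff, n); det <- rep(FALSE, n)
        } else {
          ct <- base_of(g) - fc +
            if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
          det <- ct < cutoff
          ct <- pmin(ct, cutoff)
        }
        out <- rbind(out, data.frame(gene = g, sample_id = samples,
                                     day = d, ct = ct, detected = det))
      }
    }
    rownames(out) <- NULL
    out
  })
}

#' Simulate cell-axis orientation tables
#'
#' Draws per-cell acute angles to the construct axis from a zero-centred
#' normal distribution of per-day standard deviation (degrees), folded to
#' \[0, 90\]. A dispersion of 0 yields perfect alignment (all angles 0);
#' `Inf` yields the uniform distribution on \[0, 90\] (mean 45).
#' Dispersion decreasing with day emulates cells progressively aligning
#' along the tension axis.
#'
#' @param dispersion_per_day Named numeric vector: day -> angular sd in
#'   degrees. Default: 55/45/35/25/18/12 over days 0/2/4/7/14/21.
#' @param n_cells Cells measured per construct (>= 15 by design; smaller
#'   values raise an error). Default 15.
#' @param n_constructs Constructs per day. Default 3.
#' @param seed Integer seed.
#' @return Data frame `construct_id`, `day`, `cell_id`, `angle_deg`.
#' @export
simulate_orientations <- function(dispersion_per_day = c(`0` = 55, `2` = 45,
                                                         `4` = 35, `7` = 25,
                                                         `14` = 18, `21` = 12),
                                  n_cells = 15, n_constructs = 3,
                                  seed = NULL) {
  if (n_cells < 15)
    stop_tenomech("invalid_parameter", "n_cells must be >= 15 per construct")
  if (any(dispersion_per_day < 0))
    stop_tenomech("invalid_parameter", "dispersion must be >= 0")
  fold90 <- function(x) {
    a <- abs(x) %% 180
    ifelse(a > 90, 180 - a, a)
  }
  with_seed(seed, {
    out <- NULL
    for (d in names(dispersion_per_day)) {
      sdv <- dispersion_per_day[[d]]
      for (ci in seq_len(n_constructs)) {
        ang <- if (sdv == 0) rep(0, n_cells)
               else if (is.infinite(sdv)) stats::runif(n_cells, 0, 90)
               else fold90(rnorm(n_cells, 0, sdv))
        out <- rbind(out, data.frame(
          construct_id = sprintf("D%s_c%d", d, ci),
          day = as.numeric(d), cell_id = seq_len(n_cells),
          angle_deg = ang))
      }
    }
    rownames(out) <- NULL
    out
  })
}

#' Simulate construct diameter series
#'
#' Gaussian draws truncated at zero around per-day mean diameters. The
#' defaults are the measured series for cell-seeded constructs:
#' 2.08 +/- 0.08 mm (Day 0, n=11), 0.67 +/- 0.02 (Day 7, n=15),
#' 0.59 +/- 0.02 (Day 14, n=14), 0.55 +/- 0.04 mm (Day 21, n=19).
#'
#' @param day_means Named vector day -> mean diameter (mm).
#' @param day_sds Named vector day -> sd (mm), same days.
#' @param n_per_day Constructs per day: single count or vector named by
#'   day.
#' @param seed Integer seed.
#' @return Data frame `construct_id`, `day`, `diameter_mm`.
#' @export
simulate_diameters <- function(day_means = c(`0` = 2.08, `7` = 0.67,
                                             `14` = 0.59, `21` = 0.55),
                               day_sds = c(`0` = 0.08, `7` = 0.02,
                                           `14` = 0.02, `21` = 0.04),
                               n_per_day = c(`0` = 11, `7` = 15,
                                             `14` = 14, `21` = 19),
                               seed = NULL) {
  if (any(day_means <= 0) || any(day_sds < 0))
    stop_tenomech("invalid_parameter",
                  "means must be positive and sds non-negative")
  if (!identical(sort(names(day_means)), sort(names(day_sds))))
    stop_tenomech("configuration_error", "day_means/day_sds days differ")
  with_seed(seed, {
    out <- NULL
    for (d in names(day_means)) {
      n <- if (length(n_per_day) == 1L && is.null(names(n_per_day))) n_per_day
           else n_per_day[[d]]
      x <- rnorm(n, day_means[[d]], day_sds[[d]])
      while (any(x <= 0))   # truncation at 0; essentially never triggers
        x[x <= 0] <- rnorm(sum(x <= 0), day_means[[d]], day_sds[[d]])
      out <- rbind(out, data.frame(
        construct_id = sprintf("D%s_c%02d", d, seq_len(n)),
        day = as.numeric(d), diameter_mm = x))
    }
    rownames(out) <- NULL
    out
  })
}

#' Simulate regional cell-count tables
#'
#' Poisson cell counts for centre and periphery regions of fixed area,
#' with the periphery denser than the centre (the constructs form a dense
#' surface layer three to four cells deep). Defaults: centre
#' 1500 cells/mm^2, periphery 3000 cells/mm^2, region area 0.02 mm^2.
#'
#' @param days Days to simulate. Default `c(0, 2, 4, 7, 14, 21)`.
#' @param n_constructs Constructs per day. Default 10.
#' @param centre_density,periphery_density Mean densities in cells/mm^2.
#' @param region_area Region area in mm^2. Default 0.02.
#' @param seed Integer seed.
#' @return Data frame `construct_id`, `day`, `region`, `cell_count`,
#'   `region_area`.
#' @export
simulate_density <- function(days = c(0, 2, 4, 7, 14, 21), n_constructs = 10,
                             centre_density = 1500, periphery_density = 3000,
                             region_area = 0.02, seed = NULL) {
  if (region_area <= 0)
    stop_tenomech("invalid_parameter", "region_area must be positive")
  with_seed(seed, {
    out <- NULL
    for (d in days) {
      for (ci in seq_len(n_constructs)) {
        out <- rbind(out, data.frame(
          construct_id = rep(sprintf("D%g_c%02d", d, ci), 2),
          day = d, region = c("centre", "periphery"),
          cell_count = c(rpois(1, centre_density * region_area),
                         rpois(1, periphery_density * region_area)),
          region_area = region_area))
      }
    }
    rownames(out) <- NULL
    out
  })
}
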