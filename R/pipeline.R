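# Per-day fixture defaults. Median effective moduli double every 7 days
# from 1.3 kPa (Day 0) to 9.2 kPa (Day 21) for the cell-seeded arm; the
# no-cell arm stays at 0.4 kPa. Relaxation percentages run 35 -> 24 %
# (cells) and 23 -> 15 % (no-cell) with tau = 2 s.
.fixture_days <- c(0, 7, 14, 21)
.fixture_E_kPa <- list(cell = c(`0` = 1.3, `7` = 2.6, `14` = 5.2, `21` = 9.2),
                       nocell = c(`0` = 0.4, `7` = 0.4, `14` = 0.4, `21` = 0.4))
.fixture_r_pct <- list(cell = c(`0` = 35, `7` = 31, `14` = 27, `21` = 24),
                       nocell = c(`0` = 23, `7` = 15, `14` = 15, `21` = 15))

#' Pipeline configuration
#'
#' Single declarative configuration for [make_fixture()] and [run_all()].
#' Every tunable of the analysis surfaces here with its module default, so
#' each choice is user-visible and overridable.
#'
#' @param out_dir Output directory for reports.
#' @param seed Master seed; every stage derives its randomness from it.
#' @param curves_glob Glob for indentation record TSV files.
#' @param ct_csv,angles_csv,geometry_csv,density_csv Input CSV paths.
#' @param probe Default [probe_config()] for simulation.
#' @param n_constructs,n_sites Fixture sizing: constructs per day/arm and
#'   indentation sites per construct.
#' @param detection_cutoff qPCR detection cutoff in cycles. Default 35.
#' @param ref_gene Reference gene. Default `"YWHAZ"`.
#' @param control_day qPCR control group: a day or `"first_detection"`.
#' @param exclude_outliers Apply single-pass 2-SD exclusion to dCt values
#'   per gene-by-day group before testing. Default TRUE.
#' @param h_max Hertz fit window in um. Default 1.
#' @param t_eval Relaxation evaluation time in s. Default 10.
#' @param hold_s Simulated hold duration in s. Default 10.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "tenomech-out", seed = 1,
                            curves_glob = NULL, ct_csv = NULL,
                            angles_csv = NULL, geometry_csv = NULL,
                            density_csv = NULL, probe = probe_config(),
                            n_constructs = 3, n_sites = 5,
                            detection_cutoff = 35, ref_gene = "YWHAZ",
                            control_day = 0, exclude_outliers = TRUE,
                            h_max = 1, t_eval = 10, hold_s = 10) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 curves_glob = curves_glob, ct_csv = ct_csv,
                 angles_csv = angles_csv, geometry_csv = geometry_csv,
                 density_csv = density_csv, probe = probe,
                 n_constructs = n_constructs, n_sites = n_sites,
                 detection_cutoff = detection_cutoff, ref_gene = ref_gene,
                 control_day = control_day,
                 exclude_outliers = exclude_outliers,
                 h_max = h_max, t_eval = t_eval, hold_s = hold_s),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config A [pipeline_config()].
#' @return `read_pipeline_config()` returns a `pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  probe <- if (!is.null(raw$probe)) do.call(probe_config, raw$probe)
           else probe_config()
  raw$probe <- NULL
  cfg <- do.call(pipeline_config, raw)
  cfg$probe <- probe
  cfg
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  lst <- unclass(config)
  lst$probe <- unclass(lst$probe)
  lst <- lst[!vapply(lst, is.null, logical(1))]
  lst$probe <- lst$probe[!vapply(lst$probe, is.null, logical(1))]
  yaml::write_yaml(lst, path)
  invisible(path)
}

# deterministic small sub-seed from the master seed and a counter
# (double arithmetic: the product overflows 32-bit integers)
sub_seed <- function(seed, k)
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483629)

#' Write a complete synthetic input bundle
#'
#' Generates a seeded, self-consistent dataset for every pipeline stage:
#' relaxation indentation records (TSV) for the cell-seeded and no-cell
#' arms at days 0/7/14/21, a qPCR Ct table, orientation, diameter and
#' density CSVs, plus the configuration itself as `config.yaml`. Per-day
#' median moduli double every 7 days from 1.3 to 9.2 kPa (no-cell arm
#' constant at 0.4 kPa) and per-day relaxation percentages run 35 to 24%
#' (no-cell 23 to 15%), with lognormal construct-to-construct scatter.
#'
#' @param dir Directory to create the bundle in.
#' @param config A [pipeline_config()]; sizing and seed are taken from it.
#' @return The configuration actually written (with input paths pointing
#'   into `dir`), invisibly.
#' @export
make_fixture <- function(dir, config = pipeline_config()) {
  dir.create(file.path(dir, "curves"), recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  k <- 0L
  for (arm in c("cell", "nocell")) {
    for (d in .fixture_days) {
      E_med <- .fixture_E_kPa[[arm]][[as.character(d)]] * 1000
      r_med <- .fixture_r_pct[[arm]][[as.character(d)]]
      for (ci in seq_len(config$n_constructs)) {
        k <- k + 1L
        scatter <- with_seed(sub_seed(seed, k),
                             c(exp(rnorm(1, 0, 0.25)), rnorm(1, 0, 1.5)))
        E_c <- E_med * scatter[1]
        r_c <- max(min(r_med + scatter[2], 95), 2)
        for (si in seq_len(config$n_sites)) {
          k <- k + 1L
          probe <- config$probe
          probe$seed <- sub_seed(seed, k)
          mat <- sls_for_relaxation(r_c, tau = 2, E0 = E_c,
                                    t_eval = config$t_eval)
          label <- sprintf("%s_D%g_c%02d_s%d", arm, d, ci, si)
          rec <- simulate_relaxation_record(mat, probe,
                                            hold_s = config$hold_s,
                                            label = label)
          rec$meta$arm <- arm
          rec$meta$day <- d
          rec$meta$construct <- sprintf("%s_D%g_c%02d", arm, d, ci)
          rec$meta$site <- as.character(si)
          write_force_record(rec, file.path(dir, "curves",
                                            paste0(label, ".tsv")))
        }
      }
    }
  }

  genes <- data.frame(
    gene = rep(c("COL1A1", "SCX", "MKX", "THBS2", "DPT", "LOX"), each = 6),
    day = rep(.design_days, 6),
    log2fc = c(0, 0.5, 1, 1.5, 2.5, 3,            # COL1A1: steady increase
               0, 0.5, 1, 1.2, 1.2, 0.5,          # SCX: bell shape
               NA, NA, 0, 0.8, 1.5, 2,            # MKX: detected from Day 4
               0, 0.4, 0.8, 1.5, 2, 2.5,          # THBS2
               0, 0.3, 0.8, 1.5, 2.2, 2.8,        # DPT
               0, 0.2, 0.6, 1.2, 1.8, 2.2))       # LOX
  ct <- simulate_ct_table(genes, n_reps = .design_n, noise_sd = 0.3,
                          seed = sub_seed(seed, 90001L),
                          cutoff = config$detection_cutoff,
                          ref_gene = config$ref_gene)
  write.csv(ct, file.path(dir, "ct.csv"), row.names = FALSE)

  ang <- simulate_orientations(seed = sub_seed(seed, 90002L))
  write.csv(ang, file.path(dir, "angles.csv"), row.names = FALSE)
  geo <- simulate_diameters(seed = sub_seed(seed, 90003L))
  write.csv(geo, file.path(dir, "geometry.csv"), row.names = FALSE)
  den <- simulate_density(seed = sub_seed(seed, 90004L))
  write.csv(den, file.path(dir, "density.csv"), row.names = FALSE)

  out_cfg <- config
  out_cfg$curves_glob <- file.path(dir, "curves", "*.tsv")
  out_cfg$ct_csv <- file.path(dir, "ct.csv")
  out_cfg$angles_csv <- file.path(dir, "angles.csv")
  out_cfg$geometry_csv <- file.path(dir, "geometry.csv")
  out_cfg$density_csv <- file.path(dir, "density.csv")
  write_pipeline_config(out_cfg, file.path(dir, "config.yaml"))
  invisible(out_cfg)
}

write_table <- function(df, staging, name) {
  write.csv(df, file.path(staging, name), row.names = FALSE)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes the mechanics, relaxation, qPCR and morphology stages declared
#' in the configuration and writes per-day report tables (diameters and
#' derived geometry, cell angles, moduli with their empirical CDF,
#' relaxation percentages, fold changes with significance stars, regional
#' densities) plus a machine-readable `manifest.json`. Outputs are staged
#' in a temporary directory and moved into `config$out_dir` only on
#' success, so a failing stage leaves no partial outputs. Reruns with the
#' same configuration and seed are byte-identical.
#'
#' @param config A [pipeline_config()] with input paths set (see
#'   [make_fixture()]).
#' @param stages Character subset of
#'   `c("mechanics", "relax", "qpcr", "morpho")`; default all.
#' @return Named list of the output tables, invisibly.
#' @export
run_all <- function(config,
                    stages = c("mechanics", "relax", "qpcr", "morpho")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  staging <- tempfile("tenomech-staging-")
  dir.create(staging)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)
  outputs <- list()
  inputs <- list()

  needs_curves <- any(c("mechanics", "relax") %in% stages)
  segs <- NULL
  if (needs_curves) {
    files <- run_stage("curves", {
      if (is.null(config$curves_glob)) stop("no curves_glob configured")
      f <- Sys.glob(config$curves_glob)
      if (!length(f))
        stop(sprintf("no curve files match '%s'", config$curves_glob))
      sort(f)
    })
    inputs$curves <- files
    segs <- run_stage("curves", lapply(files, function(f)
      segment_phases(read_force_record(f))))
  }
  curve_meta <- function(s) {
    m <- s$record$meta
    data.frame(label = m$label, arm = m$arm %||% NA_character_,
               day = as.numeric(m$day %||% NA_real_),
               construct = m$construct %||% m$label,
               site = m$site %||% NA_character_)
  }

  if ("mechanics" %in% stages) {
    run_stage("mechanics", {
      per <- do.call(rbind, lapply(segs, function(s) {
        fit <- analyze_indent(s, h_max = config$h_max)
        cbind(curve_meta(s),
              data.frame(z_contact_um = fit$z_contact, E_eff_Pa = fit$E_eff,
                         rmse_uN = fit$rmse, n_points = fit$n_points))
      }))
      outputs$moduli_per_indent <- per
      byc <- do.call(rbind, lapply(split(per, per$construct), function(d) {
        cm <- withCallingHandlers(
          construct_modulus(d$E_eff_Pa, d$construct[1], d$day[1]),
          warning = function(w) invokeRestart("muffleWarning"))
        data.frame(construct = d$construct[1], arm = d$arm[1],
                   day = d$day[1], n_sites = length(cm$site_values),
                   mean_E_Pa = cm$mean_E)
      }))
      byc <- byc[order(byc$arm, byc$day, byc$construct), ]
      outputs$moduli_by_construct <- byc
      byd <- do.call(rbind, lapply(split(byc, interaction(byc$arm, byc$day,
                                                          drop = TRUE)),
        function(d) data.frame(arm = d$arm[1], day = d$day[1], n = nrow(d),
                               median_E_Pa = modulus_cdf(d$mean_E_Pa)$median,
                               mean_E_Pa = mean(d$mean_E_Pa),
                               sd_E_Pa = sd(d$mean_E_Pa))))
      byd <- byd[order(byd$arm, byd$day), ]
      outputs$moduli_by_day <- byd
      cdf <- do.call(rbind, lapply(split(byc, interaction(byc$arm, byc$day,
                                                          drop = TRUE)),
        function(d) {
          cc <- modulus_cdf(d$mean_E_Pa)
          data.frame(arm = d$arm[1], day = d$day[1],
                     E_Pa = cc$value, cdf = cc$p)
        }))
      outputs$moduli_cdf <- cdf
    })
  }

  if ("relax" %in% stages) {
    run_stage("relax", {
      per <- do.call(rbind, lapply(segs, function(s) {
        st <- relaxation_percentage(s, t_eval = config$t_eval)
        cbind(curve_meta(s),
              data.frame(F_max_uN = st$F_max, F_t_uN = st$F_10s,
                         r_relax_pct = st$r_relax,
                         hold_s = st$hold_duration))
      }))
      outputs$relaxation_per_indent <- per
      byc <- do.call(rbind, lapply(split(per, per$construct), function(d) {
        cr <- withCallingHandlers(
          construct_relaxation(d$r_relax_pct, d$construct[1], d$day[1]),
          warning = function(w) invokeRestart("muffleWarning"))
        data.frame(construct = d$construct[1], arm = d$arm[1],
                   day = d$day[1], mean_r_pct = cr$mean_r)
      }))
      byc <- byc[order(byc$arm, byc$day, byc$construct), ]
      outputs$relaxation_by_construct <- byc
      byd <- do.call(rbind, lapply(split(byc, interaction(byc$arm, byc$day,
                                                          drop = TRUE)),
        function(d) data.frame(arm = d$arm[1], day = d$day[1], n = nrow(d),
                               median_r_pct = modulus_cdf(d$mean_r_pct)$median,
                               mean_r_pct = mean(d$mean_r_pct),
                               sd_r_pct = sd(d$mean_r_pct))))
      byd <- byd[order(byd$arm, byd$day), ]
      outputs$relaxation_by_day <- byd
    })
  }

  if ("qpcr" %in% stages) {
    run_stage("qpcr", {
      if (is.null(config$ct_csv)) stop("no ct_csv configured")
      ct <- utils::read.csv(config$ct_csv)
      inputs$ct <- config$ct_csv
      dct <- delta_ct(ct, ref_gene = config$ref_gene)
      if (isTRUE(config$exclude_outliers)) {
        keep <- unsplit(lapply(split(dct$dct,
                                     interaction(dct$gene, dct$day,
                                                 drop = TRUE)),
          function(v) {
            f <- suppressWarnings(exclude_outliers_2sd(v))
            out <- rep(TRUE, length(v))
            out[attr(f, "excluded")] <- FALSE
            out
          }), interaction(dct$gene, dct$day, drop = TRUE))
        dct <- dct[keep, ]
      }
      fc <- fold_change_ddct(dct, control_day = config$control_day)
      outputs$qpcr_fold_changes <- fc
      outputs$qpcr_summary <- fold_change_summary(fc)
      tests <- do.call(rbind, lapply(split(fc, fc$gene), function(d) {
        cd <- d$control_day[1]
        ctrl <- d$dct[d$day == cd]
        days <- setdiff(sort(unique(d$day)), cd)
        do.call(rbind, lapply(days, function(dd) {
          tst <- mann_whitney_exact(ctrl, d$dct[d$day == dd])
          data.frame(gene = d$gene[1], control_day = cd, day = dd,
                     n_control = length(ctrl),
                     n_day = sum(d$day == dd), U = tst$U, p = tst$p.value,
                     stars = significance_stars(tst$p.value))
        }))
      }))
      rownames(tests) <- NULL
      outputs$qpcr_tests <- tests
    })
  }

  if ("morpho" %in% stages) {
    run_stage("morpho", {
      if (!is.null(config$geometry_csv)) {
        geo <- utils::read.csv(config$geometry_csv)
        inputs$geometry <- config$geometry_csv
        byd <- do.call(rbind, lapply(split(geo, geo$day), function(d)
          data.frame(day = d$day[1], n = nrow(d),
                     mean_diameter_mm = mean(d$diameter_mm),
                     sd_diameter_mm = sd(d$diameter_mm),
                     mean_area_mm2 = mean(cross_sectional_area(d$diameter_mm)))))
        byd <- byd[order(byd$day), ]
        outputs$geometry_by_day <- byd
        d0 <- byd$mean_diameter_mm[which.min(byd$day)]
        d1 <- byd$mean_diameter_mm[which.max(byd$day)]
        outputs$geometry_summary <- data.frame(
          day_start = min(byd$day), day_end = max(byd$day),
          d_start_mm = d0, d_end_mm = d1,
          volume_fold_change = volume_fold_change(d0, d1))
      }
      if (!is.null(config$angles_csv)) {
        ang <- utils::read.csv(config$angles_csv)
        inputs$angles <- config$angles_csv
        byc <- do.call(rbind, lapply(
          split(ang, interaction(ang$construct_id, ang$day, drop = TRUE)),
          function(d) data.frame(construct_id = d$construct_id[1],
                                 day = d$day[1], n_cells = nrow(d),
                                 mean_angle_deg = mean(d$angle_deg))))
        byc <- byc[order(byc$day, byc$construct_id), ]
        outputs$angles_by_construct <- byc
        byd <- do.call(rbind, lapply(split(byc, byc$day), function(d)
          data.frame(day = d$day[1], n_constructs = nrow(d),
                     mean_angle_deg = mean(d$mean_angle_deg),
                     sd_angle_deg = sd(d$mean_angle_deg))))
        byd <- byd[order(byd$day), ]
        outputs$angles_by_day <- byd
      }
      if (!is.null(config$density_csv)) {
        den <- cell_density(utils::read.csv(config$density_csv))
        inputs$density <- config$density_csv
        byd <- do.call(rbind, lapply(
          split(den, interaction(den$day, den$region, drop = TRUE)),
          function(d) data.frame(day = d$day[1], region = d$region[1],
                                 n = nrow(d),
                                 mean_density = mean(d$density),
                                 sd_density = sd(d$density))))
        byd <- byd[order(byd$day, byd$region), ]
        outputs$density_by_day <- byd
        outputs$density_tests <- compare_density(den)
      }
    })
  }

  for (nm in names(outputs))
    write_table(outputs[[nm]], staging, paste0(nm, ".csv"))
  manifest <- list(package = "tenomech",
                   version = as.character(utils::packageVersion("tenomech")),
                   seed = config$seed, stages = stages,
                   config = {
                     lst <- unclass(config); lst$probe <- unclass(lst$probe)
                     lst[!vapply(lst, is.null, logical(1))]
                   },
                   inputs = inputs,
                   outputs = paste0(names(outputs), ".csv"))
  jsonlite::write_json(manifest, file.path(staging, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(staging, full.names = TRUE))
    file.copy(f, file.path(config$out_dir, basename(f)), overwrite = TRUE)
  invisible(outputs)
}
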