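#' Study-condition trajectory templates
#'
#' The four dish conditions of the wettability study, encoded as trajectory
#' templates with the group-mean diameters as defaults:
#' \itemize{
#'   \item `ps_initial` — bare polystyrene: two-step squeezing, 5 mm
#'     shoulder at 0.2 s spreading to a 17 mm plateau, no recovery.
#'   \item `vgp_initial` — plasma-treated polystyrene: ~6 Hz oscillation
#'     about a 6.8 mm mean, partial recovery to a 5.0 mm residual.
#'   \item `ps_14d`, `vgp_14d` — 14-day biofilm-covered dishes: fast rise to
#'     6.0 / 5.6 mm and full recovery within 0.1 s.
#' }
#'
#' @param condition one of the four names above.
#' @param seed integer seed for the rendered video's noise.
#' @param jitter_sd multiplicative between-replicate variability of the
#'   plateau (and residual) diameters; drawn from the same seed.
#' @return a [squeeze_trajectory_spec()].
#' @export
condition_spec <- function(condition = c("ps_initial", "vgp_initial",
                                         "ps_14d", "vgp_14d"),
                           seed = 1L, jitter_sd = 0.03) {
  condition <- match.arg(condition)
  j <- if (jitter_sd > 0)
    with_seed(seed + 90000L, stats::rnorm(2, mean = 1, sd = jitter_sd))
  else c(1, 1)
  switch(condition,
    ps_initial = squeeze_trajectory_spec(
      "two_step_no_recovery", plateau_diameter_mm = 17 * j[1],
      first_step_diameter_mm = 5, step_time_s = 0.2, seed = seed),
    vgp_initial = squeeze_trajectory_spec(
      "oscillatory_partial_recovery", plateau_diameter_mm = 6.8 * j[1],
      osc_freq_hz = 6, osc_amplitude_mm = 1,
      residual_diameter_mm = 5.0 * j[2], seed = seed),
    ps_14d = squeeze_trajectory_spec(
      "fast_rise_full_recovery", plateau_diameter_mm = 6.0 * j[1],
      seed = seed),
    vgp_14d = squeeze_trajectory_spec(
      "fast_rise_full_recovery", plateau_diameter_mm = 5.6 * j[1],
      seed = seed))
}

#' Generate a complete synthetic study fixture tree
#'
#' Writes, under `out_dir`:
#' \itemize{
#'   \item `squeeze/<condition>_r<k>/` — numbered PNG frames,
#'     `manifest.yaml` and ground-truth `truth.csv` for each replicate of
#'     the four study conditions;
#'   \item `stain/` — stained-dish phantom PNGs, a `dishes.csv` manifest
#'     (dish geometry, condition, day, true coverage), a `calibration.csv`
#'     ND-standards table and a `config.yaml` (gamma, bit depth);
#'   \item `bubble/` — captive-bubble phantom PNGs and `bubble_config.yaml`.
#' }
#' Identical seeds produce byte-identical trees.
#'
#' @param out_dir output directory.
#' @param seed integer master seed; per-replicate seeds derive from it.
#' @param n_replicates named integer vector of squeeze replicates per
#'   condition; the defaults are the study's group sizes.
#' @param stain_coverages stained-area fractions for the incubated stain
#'   phantoms (one dish per value and dish type).
#' @param dish_radius_px stain-phantom dish radius, px.
#' @return `out_dir`, invisibly.
#' @export
run_simulate <- function(out_dir, seed = 1L,
                         n_replicates = c(ps_initial = 3L, ps_14d = 9L,
                                          vgp_initial = 3L, vgp_14d = 6L),
                         stain_coverages = c(0.95, 0.3),
                         dish_radius_px = 60) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  # --- squeeze videos -------------------------------------------------
  sq_dir <- file.path(out_dir, "squeeze")
  k <- 0L
  for (cond in names(n_replicates)) {
    for (r in seq_len(n_replicates[[cond]])) {
      k <- k + 1L
      spec <- condition_spec(cond, seed = seed * 1000L + k)
      video <- make_squeeze_video(spec)
      write_squeeze_video(video, file.path(sq_dir,
                                           sprintf("%s_r%d", cond, r)),
                          experiment_id = sprintf("%s_r%d", cond, r),
                          condition = cond)
    }
  }
  # --- stained dishes -------------------------------------------------
  st_dir <- file.path(out_dir, "stain")
  dir.create(st_dir, showWarnings = FALSE)
  dim <- c(2 * dish_radius_px + 20, 2 * dish_radius_px + 20)
  center <- (dim + 1) / 2
  gamma <- 1.8; bit_depth <- 8L
  dishes <- list(); di <- 0L
  add_dish <- function(type, day, field, true_cov, dseed) {
    di <<- di + 1L
    spec <- stain_phantom_spec(dim, center, dish_radius_px, field,
                               gamma = gamma, bit_depth = bit_depth,
                               noise_sd = 2, seed = dseed)
    ph <- make_stained_dish_image(spec)
    id <- sprintf("%s_d%02d_%d", type, day, di)
    write_gray_image(ph$image, file.path(st_dir, paste0(id, ".png")))
    dishes[[di]] <<- data.frame(
      dish_id = id, condition = type, day = day,
      file = paste0(id, ".png"), center_row = center[1],
      center_col = center[2], dish_radius_px = dish_radius_px,
      true_coverage_pct = true_cov)
  }
  for (type in c("PS", "VGP")) {
    base_od <- if (type == "PS") 0.08 else 0.12  # substrate tint
    add_dish(type, 0L, matrix(base_od, dim[1], dim[2]), 0,
             seed * 100L + di)
    for (cv in stain_coverages) {
      fld <- make_coverage_field(dim, center, dish_radius_px, cv,
                                 od_background = base_od, od_stained = 1.0,
                                 seed = seed * 100L + di + 1L)
      add_dish(type, 14L, fld$field, fld$true_coverage_pct,
               seed * 100L + di + 1L)
    }
  }
  utils::write.csv(do.call(rbind, dishes), file.path(st_dir, "dishes.csv"),
                   row.names = FALSE)
  # ND-standard calibration table measured off uniform filter phantoms
  standards <- data.frame(standard_id = c("ND4", "ND8", "ND16"),
                          od = c(0.6, 0.9, 1.2))
  standards$mean_i_prime <- vapply(standards$od, function(od) {
    sp <- stain_phantom_spec(c(40, 40), c(20.5, 20.5), 15,
                             matrix(od, 40, 40), gamma = gamma,
                             noise_sd = 0, seed = 1L)
    ph <- make_stained_dish_image(sp)
    odm <- decompensate(ph$image, gamma = gamma)
    mean(odm$i_prime[ph$dish_mask])
  }, numeric(1))
  utils::write.csv(standards, file.path(st_dir, "calibration.csv"),
                   row.names = FALSE)
  yaml::write_yaml(list(gamma = gamma, bit_depth = bit_depth),
                   file.path(st_dir, "config.yaml"))
  # --- captive bubbles ------------------------------------------------
  bu_dir <- file.path(out_dir, "bubble")
  dir.create(bu_dir, showWarnings = FALSE)
  bubbles <- data.frame(image_id = c("ps_initial", "vgp_initial"),
                        true_angle_deg = c(103, 126))
  baseline_row <- 30L
  for (i in seq_len(nrow(bubbles))) {
    sp <- bubble_phantom_spec(bubbles$true_angle_deg[i],
                              bubble_radius_px = 60,
                              baseline_row = baseline_row, noise_sd = 5,
                              seed = seed * 10L + i)
    bi <- make_bubble_image(sp)
    write_gray_image(bi$image,
                     file.path(bu_dir, paste0(bubbles$image_id[i], ".png")))
  }
  yaml::write_yaml(list(baseline_row = baseline_row),
                   file.path(bu_dir, "bubble_config.yaml"))
  utils::write.csv(bubbles, file.path(bu_dir, "bubbles.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

#' Quantify staining over a directory of dish images
#'
#' Expects the layout written by [run_simulate()]: dish PNGs, a
#' `dishes.csv` manifest with per-dish geometry and labels, a
#' `calibration.csv` ND-standards table and a `config.yaml` with `gamma`
#' and `bit_depth`. For each dish the centre-half-radius ROI is extracted,
#' the image decompensated, the calibration applied and the mean density
#' computed; the stained/unstained threshold is then set per dish type
#' (midpoint between initial-state and incubated group averages) and the
#' percent stained area computed.
#'
#' @param in_dir input directory.
#' @param out_csv optional path for the results CSV.
#' @return data.frame with columns `dish_id`, `condition`, `day`,
#'   `mean_density`, `threshold`, `area_ratio_pct` (plus
#'   `true_coverage_pct` when the manifest carries ground truth).
#' @export
run_stain <- function(in_dir, out_csv = NULL) {
  man_path <- file.path(in_dir, "dishes.csv")
  cal_path <- file.path(in_dir, "calibration.csv")
  if (!file.exists(man_path) || !file.exists(cal_path))
    stop("stain input requires dishes.csv and calibration.csv in ", in_dir,
         call. = FALSE)
  cfg_path <- file.path(in_dir, "config.yaml")
  cfg <- if (file.exists(cfg_path)) yaml::read_yaml(cfg_path)
         else list(gamma = 1.8, bit_depth = 8L)
  man <- utils::read.csv(man_path)
  if (nrow(man) == 0L) stop("empty dish manifest", call. = FALSE)
  cal <- utils::read.csv(cal_path)
  fit <- fit_calibration(cal$mean_i_prime, cal$od)
  results <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    img <- read_gray_image(file.path(in_dir, man$file[i]),
                           bit_depth = cfg$bit_depth)
    roi <- extract_roi(img, c(man$center_row[i], man$center_col[i]),
                       man$dish_radius_px[i])
    od <- decompensate(img, gamma = cfg$gamma)
    results[[i]] <- stain_density(od, fit, roi_mask = roi,
                                  dish_id = man$dish_id[i],
                                  condition = man$condition[i],
                                  day = man$day[i])
  }
  mean_d <- vapply(results, `[[`, numeric(1), "mean_density")
  out <- data.frame(dish_id = man$dish_id, condition = man$condition,
                    day = man$day, mean_density = mean_d,
                    threshold = NA_real_, area_ratio_pct = NA_real_)
  for (type in unique(out$condition)) {
    ini <- out$condition == type & out$day == 0
    inc <- out$condition == type & out$day > 0
    if (!any(ini) || !any(inc))
      stop("dish type ", type, " needs both initial and incubated dishes ",
           "to set the threshold", call. = FALSE)
    thr <- compute_threshold(out$mean_density[ini], out$mean_density[inc])
    for (i in which(out$condition == type)) {
      out$threshold[i] <- thr
      out$area_ratio_pct[i] <- area_ratio(results[[i]]$od, thr)
    }
  }
  if ("true_coverage_pct" %in% names(man))
    out$true_coverage_pct <- man$true_coverage_pct
  if (!is.null(out_csv))
    utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Analyse a directory of liquid-squeezing experiments
#'
#' Each subdirectory of `in_dir` holding a `manifest.yaml` is treated as
#' one experiment: the frames are read, the diameter series extracted and
#' both wettability indexes computed. Per-experiment series CSVs
#' (`series_<id>.csv`) and a combined `indexes.csv` are written when
#' `out_dir` is given.
#'
#' @param in_dir directory of experiment subdirectories.
#' @param out_dir optional output directory.
#' @param windows an [analysis_windows()].
#' @return data.frame with one row per experiment: `experiment_id`,
#'   `condition`, `mean_squeezed_diameter_mm`, `residual_diameter_mm`,
#'   `oscillation_freq_hz`.
#' @export
run_squeeze <- function(in_dir, out_dir = NULL,
                        windows = analysis_windows()) {
  subs <- list.dirs(in_dir, recursive = FALSE)
  subs <- subs[file.exists(file.path(subs, "manifest.yaml"))]
  if (length(subs) == 0L)
    stop("no experiment directories with manifest.yaml under ", in_dir,
         call. = FALSE)
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  failures <- character()
  rows <- list()
  for (sub in subs) {
    id <- basename(sub)
    res <- tryCatch({
      video <- read_squeeze_video(sub)
      series <- diameter_series(video)
      idx <- wettability_indexes(series, windows)
      if (!is.null(out_dir))
        utils::write.csv(series$samples,
                         file.path(out_dir, paste0("series_", id, ".csv")),
                         row.names = FALSE)
      data.frame(
        experiment_id = if (!is.null(video$experiment_id))
          video$experiment_id else id,
        condition = if (!is.null(video$condition)) video$condition
          else NA_character_,
        mean_squeezed_diameter_mm = idx$mean_squeezed_diameter_mm,
        residual_diameter_mm = idx$residual_diameter_mm,
        oscillation_freq_hz = idx$oscillation_freq_hz)
    }, error = function(e) e)
    if (inherits(res, "error")) failures[id] <- conditionMessage(res)
    else rows[[id]] <- res
  }
  if (length(failures) > 0L)
    stop("analysis failed for ", length(failures), " experiment(s): ",
         paste(names(failures), failures, sep = ": ", collapse = "; "),
         call. = FALSE)
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(out_dir))
    utils::write.csv(out, file.path(out_dir, "indexes.csv"),
                     row.names = FALSE)
  out
}

#' Measure contact angles over a directory of bubble images
#'
#' Expects PNG/TIFF stills plus a `bubble_config.yaml` with `baseline_row`
#' (and optional `threshold`).
#'
#' @param in_dir input directory.
#' @param out_csv optional results CSV path.
#' @return data.frame with `image_id`, `angle_deg`, `fit_residual`.
#' @export
run_bubble <- function(in_dir, out_csv = NULL) {
  cfg_path <- file.path(in_dir, "bubble_config.yaml")
  if (!file.exists(cfg_path))
    stop("bubble_config.yaml not found in ", in_dir, call. = FALSE)
  cfg <- yaml::read_yaml(cfg_path)
  if (is.null(cfg$baseline_row))
    stop("bubble config must supply baseline_row", call. = FALSE)
  files <- list.files(in_dir, pattern = "\\.(png|tif|tiff)$",
                      full.names = TRUE)
  if (length(files) == 0L)
    stop("no bubble images in ", in_dir, call. = FALSE)
  rows <- lapply(files, function(p) {
    img <- read_gray_image(p)
    r <- measure_contact_angle(img, cfg$baseline_row,
                               threshold = cfg$threshold)
    data.frame(image_id = tools::file_path_sans_ext(basename(p)),
               angle_deg = r$angle_deg, fit_residual = r$fit_residual)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Gated group comparisons from a tidy CSV or data.frame
#'
#' @param data a data.frame with `group` and `value` columns, or a CSV path.
#' @param pairings,alpha_gate,bonferroni see [compare_groups()].
#' @param out_csv optional results CSV path.
#' @return the comparison data.frame (see [compare_groups()]).
#' @export
run_compare <- function(data, pairings = NULL, alpha_gate = 0.05,
                        bonferroni = FALSE, out_csv = NULL) {
  if (is.character(data)) data <- utils::read.csv(data)
  out <- compare_groups(data, pairings = pairings, alpha_gate = alpha_gate,
                        bonferroni = bonferroni)
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}
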