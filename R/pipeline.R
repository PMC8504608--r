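#' Sweep configuration
#'
#' Defines the coupled setup-error sweep: each point applies `mm`
#' millimetres and `deg` degrees of error.  In `"six_dof"` mode (the
#' simulated-plan convention) every translational axis gets `mm` and
#' every rotational axis `deg`, with signs all positive or drawn per
#' replicate.  In `"translation_norm"` mode the point is a single pure
#' translation of Euclidean norm `mm` — the convention under which the
#' calibrated phantom's covering dose declines by exactly the kernel
#' fall-off per millimetre of error.
#'
#' @param error_magnitudes two-column matrix or data.frame (`mm`, `deg`);
#'   default `(0,0), (0.5,0.5), (1,1), (2,2)`.  Magnitudes must be
#'   non-negative and strictly increasing.
#' @param sign_mode `"all_positive"` (one replicate) or `"random"`
#'   (`n_replicates` sign patterns drawn from `seed`).
#' @param n_replicates replicates for `sign_mode = "random"` (default 8).
#' @param seed integer run seed.
#' @param dof_mode `"six_dof"` (default) or `"translation_norm"`.
#' @param rx prescription dose in Gy (default 20).
#' @param ick_threshold indirect cell-kill dose threshold in Gy
#'   (default 15; must be < `rx`).
#' @param covering_step covering-dose search step in Gy (default 0.1).
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(error_magnitudes = cbind(mm = c(0, 0.5, 1, 2),
                                                  deg = c(0, 0.5, 1, 2)),
                         sign_mode = c("all_positive", "random"),
                         n_replicates = 8, seed = 1L,
                         dof_mode = c("six_dof", "translation_norm"),
                         rx = 20, ick_threshold = 15, covering_step = 0.1) {
  sign_mode <- match.arg(sign_mode)
  dof_mode <- match.arg(dof_mode)
  m <- as.data.frame(error_magnitudes)
  names(m) <- c("mm", "deg")
  if (any(m$mm < 0) || any(m$deg < 0)) {
    stop("error magnitudes must be non-negative")
  }
  if (nrow(m) > 1 && any(diff(m$mm) <= 0 & diff(m$deg) <= 0)) {
    stop("error magnitudes must be strictly increasing")
  }
  if (ick_threshold >= rx) stop("ick_threshold must be below rx")
  structure(
    list(error_magnitudes = m, sign_mode = sign_mode,
         n_replicates = if (sign_mode == "random") n_replicates else 1L,
         seed = as.integer(seed), dof_mode = dof_mode, rx = rx,
         ick_threshold = ick_threshold, covering_step = covering_step),
    class = "sweep_config"
  )
}

# transform for one sweep point / replicate
.sweep_transform <- function(cfg, mm, deg, replicate, pivot) {
  if (cfg$dof_mode == "translation_norm") {
    # pure translation of norm `mm`; direction fixed along +x for
    # all_positive, drawn from the replicate seed otherwise
    dir <- c(1, 0, 0)
    if (cfg$sign_mode == "random") {
      dir <- with_seed(cfg$seed + 7919L * replicate, {
        u <- stats::rnorm(3)
        u / sqrt(sum(u^2))
      })
    }
    transform6dof(dx = mm * dir[1], dy = mm * dir[2], dz = mm * dir[3],
                  pivot = pivot)
  } else {
    signs <- if (cfg$sign_mode == "all_positive") "all_positive" else "random"
    error_vector(mm, deg, signs = signs,
                 seed = cfg$seed + 7919L * replicate, pivot = pivot)
  }
}

#' Run the setup-error sweep over a phantom cohort
#'
#' For every patient, error magnitude and sign replicate: builds the
#' error transform about the patient's isocenter, perturbs the dose by
#' rigid resampling, and computes per-target coverage records (direct /
#' indirect cell-kill fractions and minimum covering dose) plus the
#' whole-brain V14Gy NTCP change.  Aggregation weights every lesion
#' equally; the headline threshold interpolates the per-magnitude mean
#' covering-dose curve at the indirect cell-kill threshold.
#'
#' @param cohort non-empty list of [build_phantom()] objects.
#' @param cfg a [sweep_config()].
#' @param ntcp_pars an [ntcp_params()].
#' @return An object of class `sweep_result`: `records` (one row per
#'   patient x target x magnitude x replicate), `summary` (per-magnitude
#'   mean and sample SD of covering dose and coverage fractions), `ntcp`
#'   (per patient x magnitude x replicate), `threshold` (see
#'   [interpolate_threshold()]), `config`.
#' @export
run_sweep <- function(cohort, cfg = sweep_config(),
                      ntcp_pars = ntcp_params()) {
  if (inherits(cohort, "patient_phantom")) cohort <- list(cohort)
  stopifnot(length(cohort) >= 1, inherits(cfg, "sweep_config"))
  records <- list()
  ntcp_rows <- list()
  for (p in seq_along(cohort)) {
    ph <- cohort[[p]]
    for (m in seq_len(nrow(cfg$error_magnitudes))) {
      mm <- cfg$error_magnitudes$mm[m]
      deg <- cfg$error_magnitudes$deg[m]
      for (rep_i in seq_len(cfg$n_replicates)) {
        tr <- .sweep_transform(cfg, mm, deg, (m - 1L) * cfg$n_replicates +
                                 rep_i, pivot = ph$grid$isocenter)
        pert <- tryCatch(
          apply_setup_error(ph$dose, tr, within = ph$brain_mask),
          error = function(e) {
            stop(sprintf("patient %d, magnitude %g mm/%g deg: %s",
                         p, mm, deg, conditionMessage(e)))
          })
        for (k in seq_along(ph$ptv_masks)) {
          part <- dck_ick_partition(pert, ph$ptv_masks[[k]], rx = cfg$rx,
                                    ick_level = cfg$ick_threshold)
          mcd <- min_covering_dose(pert, ph$ptv_masks[[k]],
                                   step = cfg$covering_step)
          records[[length(records) + 1L]] <- data.frame(
            patient = p, target = k, magnitude_mm = mm, magnitude_deg = deg,
            replicate = rep_i,
            dck_fraction = part$dck_fraction,
            ick_fraction = part$ick_fraction,
            v15_fraction = part$v15_fraction,
            min_covering_dose = mcd,
            clipped_fraction = attr(pert, "clipped_fraction"))
        }
        if (is.null(ph$brain_mask)) next  # imported plans without a brain contour
        nd <- ntcp_delta(ph$dose, pert, ph$brain_mask, ntcp_pars)
        ntcp_rows[[length(ntcp_rows) + 1L]] <- data.frame(
          patient = p, magnitude_mm = mm, magnitude_deg = deg,
          replicate = rep_i, vx_ref = nd$vx_ref,
          vx_perturbed = nd$vx_perturbed, ntcp_ref = nd$ntcp_ref,
          ntcp_perturbed = nd$ntcp_perturbed,
          abs_diff_pct = nd$abs_diff_pct, rel_diff_pct = nd$rel_diff_pct)
      }
    }
  }
  records <- do.call(rbind, records)
  ntcp_tab <- do.call(rbind, ntcp_rows)
  key <- interaction(records$magnitude_mm, records$magnitude_deg, drop = TRUE)
  lev <- levels(key)[order(tapply(records$magnitude_mm, key, `[`, 1),
                           tapply(records$magnitude_deg, key, `[`, 1))]
  summary <- data.frame(
    magnitude_mm = tapply(records$magnitude_mm, key, `[`, 1)[lev],
    magnitude_deg = tapply(records$magnitude_deg, key, `[`, 1)[lev],
    n = as.integer(table(key)[lev]),
    mcd_mean = tapply(records$min_covering_dose, key, mean)[lev],
    mcd_sd = tapply(records$min_covering_dose, key, stats::sd)[lev],
    dck_mean = tapply(records$dck_fraction, key, mean)[lev],
    dck_sd = tapply(records$dck_fraction, key, stats::sd)[lev],
    ick_mean = tapply(records$ick_fraction, key, mean)[lev],
    ick_sd = tapply(records$ick_fraction, key, stats::sd)[lev],
    row.names = NULL)
  thr <- interpolate_threshold(summary$magnitude_mm, summary$mcd_mean,
                               level = cfg$ick_threshold, strict = FALSE)
  structure(
    list(records = records, summary = summary, ntcp = ntcp_tab,
         threshold = thr, config = cfg),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d coverage records over %d magnitudes\n",
              nrow(x$records), nrow(x$summary)))
  print(x$summary, digits = 4)
  if (isTRUE(x$threshold$in_range)) {
    cat(sprintf("15 Gy-threshold crossing at %.1f mm/deg (unrounded %.3f)\n",
                x$threshold$magnitude_rounded, x$threshold$magnitude))
  } else {
    cat("15 Gy-threshold crossing outside the swept range\n")
  }
  invisible(x)
}

#' Interpolate the setup-error magnitude at a covering-dose level
#'
#' Piecewise-linear interpolation of the (magnitude, mean covering dose)
#' curve at the crossing `dose = level`.  No extrapolation: a level
#' outside the observed dose range is reported as out-of-range.
#'
#' @param magnitudes strictly increasing error magnitudes (mm-and-degrees
#'   sweep settings).
#' @param mean_covering_doses strictly decreasing mean covering doses in
#'   Gy, one per magnitude.
#' @param level crossing level in Gy (default 15, the indirect
#'   cell-kill threshold).
#' @param strict error (TRUE, default) or downgrade to the out-of-range
#'   marker (FALSE) when monotonicity fails.
#' @return List with `magnitude` (unrounded crossing), `magnitude_rounded`
#'   (one decimal, the headline value), `in_range`, and `level`.
#' @export
#' @examples
#' interpolate_threshold(c(0, 0.5, 1, 2), c(19.2, 17.8, 15.9, 12.6), 15)
interpolate_threshold <- function(magnitudes, mean_covering_doses,
                                  level = 15, strict = TRUE) {
  m <- as.numeric(magnitudes)
  d <- as.numeric(mean_covering_doses)
  stopifnot(length(m) == length(d), length(m) >= 2)
  bad <- any(diff(m) <= 0) || any(diff(d) >= 0)
  if (bad) {
    if (strict) stop("magnitudes must be strictly increasing and mean covering doses strictly decreasing")
    return(list(magnitude = NA_real_, magnitude_rounded = NA_real_,
                in_range = FALSE, level = level))
  }
  if (level > d[1] || level < d[length(d)]) {
    return(list(magnitude = NA_real_, magnitude_rounded = NA_real_,
                in_range = FALSE, level = level))
  }
  i <- max(which(d >= level))
  mag <- if (d[i] == level || i == length(d)) {
    m[i]
  } else {
    m[i] + (d[i] - level) / (d[i] - d[i + 1]) * (m[i + 1] - m[i])
  }
  list(magnitude = mag, magnitude_rounded = round(mag, 1),
       in_range = TRUE, level = level)
}

#' Aggregate a cohort manifest into a summary row
#'
#' @param manifest `data.frame` with one row per patient and columns
#'   `n_lesions`, `avg_distance_cm` (per-patient mean distance to
#'   isocenter), and optionally `gtv_cc`, `ptv_cc` (per-patient mean
#'   lesion volumes).
#' @return One-row `data.frame`: `n_patients`, `n_lesions` (sum),
#'   `mean_distance_cm` (mean of the per-patient averages),
#'   `mean_gtv_cc`, `mean_ptv_cc` (lesion-count-weighted means, i.e.
#'   averages across lesions).
#' @export
#' @examples
#' aggregate_cohort_table(table1_cohort())
aggregate_cohort_table <- function(manifest) {
  stopifnot(is.data.frame(manifest), nrow(manifest) >= 1,
            all(c("n_lesions", "avg_distance_cm") %in% names(manifest)))
  out <- data.frame(
    n_patients = nrow(manifest),
    n_lesions = sum(manifest$n_lesions),
    mean_distance_cm = mean(manifest$avg_distance_cm))
  for (col in c("gtv_cc", "ptv_cc")) {
    if (col %in% names(manifest)) {
      out[[paste0("mean_", col)]] <-
        sum(manifest[[col]] * manifest$n_lesions) / sum(manifest$n_lesions)
    }
  }
  out
}

#' Published per-patient tumor characteristics of the study cohort
#'
#' The printed nine-patient summary table shipped with the package:
#' lesion counts, per-patient average distance to isocenter, per-lesion
#' mean and SD of GTV and PTV volumes, and adjacent OARs.
#'
#' @return A `data.frame` with one row per patient.
#' @export
table1_cohort <- function() {
  utils::read.csv(system.file("extdata", "table1_cohort.csv",
                              package = "icksim"),
                  stringsAsFactors = FALSE)
}

#' Build a cohort manifest from phantoms
#'
#' @param cohort list of [build_phantom()] objects.
#' @return Per-patient manifest `data.frame` usable with
#'   [aggregate_cohort_table()].
#' @export
cohort_manifest <- function(cohort) {
  if (inherits(cohort, "patient_phantom")) cohort <- list(cohort)
  stopifnot(length(cohort) >= 1)
  do.call(rbind, lapply(seq_along(cohort), function(p) {
    ph <- cohort[[p]]
    dists <- vapply(ph$targets, function(t) {
      sqrt(sum((t$center - ph$grid$isocenter)^2))
    }, numeric(1))
    data.frame(
      patient = p, n_lesions = length(ph$targets),
      avg_distance_cm = mean(dists) / 10,
      gtv_cc = mean(vapply(ph$gtv_masks, volume_cc, numeric(1))),
      ptv_cc = mean(vapply(ph$ptv_masks, volume_cc, numeric(1))))
  }))
}

#' Write sweep reports
#'
#' Writes `records.csv` (one row per patient, target, magnitude,
#' replicate), `summary.csv` (per-magnitude means and SDs), `ntcp.csv`,
#' a `headline.json` block (threshold, per-magnitude means, NTCP deltas,
#' config echo with seed), and three figures: covering dose versus error
#' magnitude with the indirect cell-kill threshold line, stacked
#' direct/indirect coverage fractions per magnitude, and NTCP versus
#' brain V14Gy per magnitude.  CSV and JSON output is byte-stable across
#' reruns with the same seed; figures are not guaranteed byte-identical.
#'
#' @param result a [run_sweep()] result with at least one record.
#' @param outdir output directory (created if missing; must be writable).
#' @return Character vector of written file paths, invisibly.
#' @export
report <- function(result, outdir) {
  stopifnot(inherits(result, "sweep_result"))
  if (is.null(result$records) || nrow(result$records) == 0) {
    stop("empty sweep result: nothing to report")
  }
  ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop(sprintf("cannot create '%s'", outdir))
  paths <- file.path(outdir, c("records.csv", "summary.csv", "ntcp.csv",
                               "headline.json", "fig_covering_dose.pdf",
                               "fig_dck_ick.pdf", "fig_ntcp.pdf"))
  has_ntcp <- !is.null(result$ntcp) && nrow(result$ntcp) > 0
  utils::write.csv(result$records, paths[1], row.names = FALSE)
  utils::write.csv(result$summary, paths[2], row.names = FALSE)
  utils::write.csv(if (has_ntcp) result$ntcp else data.frame(), paths[3],
                   row.names = FALSE)
  cfg <- result$config
  headline <- list(
    threshold = result$threshold,
    sign_assumption = if (cfg$sign_mode == "all_positive")
      "all six error components positive (assumption)" else "random signs",
    dof_mode = cfg$dof_mode,
    per_magnitude = result$summary,
    ntcp_abs_diff_pct = if (has_ntcp) stats::aggregate(
      abs_diff_pct ~ magnitude_mm, data = result$ntcp, FUN = mean) else NULL,
    config = list(
      error_magnitudes = cfg$error_magnitudes, sign_mode = cfg$sign_mode,
      n_replicates = cfg$n_replicates, seed = cfg$seed, rx = cfg$rx,
      ick_threshold = cfg$ick_threshold, covering_step = cfg$covering_step),
    max_clipped_fraction = max(result$records$clipped_fraction))
  jsonlite::write_json(headline, paths[4], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  .report_figures(result, paths[5:7])
  invisible(paths)
}

.report_figures <- function(result, paths) {
  s <- result$summary
  thr <- result$threshold
  p1 <- ggplot2::ggplot(s, ggplot2::aes(x = magnitude_mm,
                                        y = mcd_mean)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(color = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mcd_mean - mcd_sd,
                                        ymax = mcd_mean + mcd_sd),
                           width = 0.05, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = result$config$ick_threshold,
                        linetype = "dashed", color = "red") +
    ggplot2::labs(x = "setup error magnitude (mm and degrees)",
                  y = "mean minimum covering dose (Gy)",
                  title = "Covering dose vs setup-error magnitude") +
    ggplot2::theme_minimal()
  if (isTRUE(thr$in_range)) {
    p1 <- p1 + ggplot2::geom_vline(xintercept = thr$magnitude,
                                   linetype = "dotted")
  }
  ggplot2::ggsave(paths[1], p1, width = 6, height = 4)

  stacked <- rbind(
    data.frame(magnitude_mm = s$magnitude_mm, component = "DCK (>= Rx)",
               fraction = s$dck_mean),
    data.frame(magnitude_mm = s$magnitude_mm, component = "ICK (15 Gy band)",
               fraction = s$ick_mean))
  p2 <- ggplot2::ggplot(stacked, ggplot2::aes(
    x = factor(magnitude_mm), y = fraction,
    fill = component)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "setup error magnitude (mm and degrees)",
                  y = "% of PTV volume",
                  title = "Direct vs indirect cell-kill coverage") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(paths[2], p2, width = 6, height = 4)

  nt <- result$ntcp
  if (is.null(nt) || nrow(nt) == 0) return(invisible(paths))
  p3 <- ggplot2::ggplot(nt, ggplot2::aes(
    x = vx_perturbed, y = 100 * ntcp_perturbed,
    color = factor(magnitude_mm))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "whole-brain V14Gy (cc)", y = "NTCP (%)",
                  color = "error (mm/deg)",
                  title = "Radionecrosis NTCP vs brain V14Gy") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(paths[3], p3, width = 6, height = 4)
  invisible(paths)
}
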