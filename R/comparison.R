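# MRI-versus-CFD comparison assembly: per-level peak-velocity tables,
# cohort aggregates (mean +/- SD), stroke-volume profiles along the spine,
# anterior/posterior asymmetry descriptors and the discrepancy report.

#' Cohort aggregates of peak velocities
#'
#' Sample mean and SD (n-1 denominator) of the peak systolic and diastolic
#' velocities per (group, level, method, direction) cell.
#'
#' @param table Data frame with columns `subject_id`, `level_label`,
#'   `method` (mri/cfd), `peak_systolic`, `peak_diastolic`.
#' @param groups Named character vector mapping every subject id to a group
#'   (`healthy_like` / `cm_like`).
#' @return Data frame with `group`, `level_label`, `method`, `direction`,
#'   `mean`, `sd`, `n` and `single_subject` flag (`sd` reported as 0 when
#'   `n = 1`).
#' @export
aggregate_cohort <- function(table, groups) {
  need <- c("subject_id", "level_label", "method",
            "peak_systolic", "peak_diastolic")
  stopifnot(all(need %in% names(table)))
  if (!all(table$subject_id %in% names(groups))) {
    stop("every subject must have a group assignment")
  }
  long <- rbind(
    data.frame(table[c("subject_id", "level_label", "method")],
               direction = "systolic", value = table$peak_systolic),
    data.frame(table[c("subject_id", "level_label", "method")],
               direction = "diastolic", value = table$peak_diastolic))
  long$group <- unname(groups[long$subject_id])
  agg <- stats::aggregate(
    value ~ group + level_label + method + direction, data = long,
    FUN = function(v) c(mean = mean(v),
                        sd = if (length(v) > 1L) stats::sd(v) else 0,
                        n = length(v)))
  out <- cbind(agg[, 1:4], as.data.frame(agg$value))
  names(out)[5:7] <- c("mean", "sd", "n")
  out$single_subject <- out$n == 1
  out
}

#' Anterior/posterior asymmetry of a thru-plane velocity map
#'
#' Splits lumen pixels at the horizontal line through the cord centroid
#' (anterior is +y) and compares mean peak velocity magnitudes.
#'
#' @param map 2D thru-plane velocity matrix (cm/s; `NA` outside the lumen).
#' @param section The `sss_section` defining the cord centroid.
#' @param x,y Map axes (mm).
#' @return An `asymmetry_index`: anterior and posterior mean |v|, their
#'   ratio, and flags for empty or all-zero halves.
#' @export
anterior_posterior_split <- function(map, section, x, y) {
  stopifnot(length(x) == nrow(map), length(y) == ncol(map))
  c0 <- polygon_centroid(section$inner_contour)
  ymat <- matrix(rep(y, each = nrow(map)), nrow(map))
  lum <- !is.na(map)
  ant <- lum & ymat > c0[2L]
  pos <- lum & ymat <= c0[2L]
  flag <- NULL
  if (!any(ant) || !any(pos)) flag <- "empty_half"
  a_mean <- if (any(ant)) mean(abs(map[ant])) else NA_real_
  p_mean <- if (any(pos)) mean(abs(map[pos])) else NA_real_
  ratio <- NA_real_
  if (is.null(flag)) {
    if (p_mean == 0) flag <- "zero_posterior" else ratio <- a_mean / p_mean
  }
  structure(list(level_label = section$level_label,
                 anterior_mean_peak = a_mean, posterior_mean_peak = p_mean,
                 ratio = ratio, flag = flag),
            class = "asymmetry_index")
}

#' MRI-versus-CFD discrepancy report
#'
#' Joins the two arms at the nine comparison levels and emits per-level
#' differences and ratios of peak velocity magnitudes, the per-subject
#' consistency count (levels where |MRI| > |CFD| peak systolic velocity),
#' stroke-volume profiles along the spine for both arms, and group
#' contrasts of the FM-level MRI-CFD gap.
#'
#' @param mri_metrics,cfd_metrics Data frames with columns `subject_id`,
#'   `level_label`, `peak_systolic`, `peak_diastolic`, `stroke_volume`;
#'   both arms must cover the same levels per subject.
#' @param groups Named character vector of subject groups.
#' @param motion_summaries Optional data frame with `subject_id`,
#'   `moving_fraction`.
#' @return A `comparison_report` (list of data frames + summary scalars).
#' @export
discrepancy_report <- function(mri_metrics, cfd_metrics, groups,
                               motion_summaries = NULL) {
  key <- c("subject_id", "level_label")
  m <- merge(mri_metrics, cfd_metrics, by = key, suffixes = c("_mri", "_cfd"))
  per_subj_levels <- table(mri_metrics$subject_id)
  if (nrow(m) != nrow(mri_metrics) || nrow(m) != nrow(cfd_metrics)) {
    stop("MRI and CFD metrics must be evaluated at the same levels")
  }
  m$sys_diff <- abs(m$peak_systolic_mri) - abs(m$peak_systolic_cfd)
  m$dia_diff <- abs(m$peak_diastolic_mri) - abs(m$peak_diastolic_cfd)
  m$sys_ratio <- ifelse(m$peak_systolic_cfd != 0,
                        abs(m$peak_systolic_mri) / abs(m$peak_systolic_cfd),
                        NA_real_)
  m$group <- unname(groups[m$subject_id])

  cons <- stats::aggregate(sys_diff ~ subject_id, data = m,
                           FUN = function(v) sum(v > 0))
  names(cons)[2L] <- "n_levels_mri_greater"
  cons$n_levels <- as.integer(per_subj_levels[cons$subject_id])

  fm <- m[m$level_label == "FM", ]
  fm_gap <- stats::aggregate(sys_diff ~ group, data = fm, FUN = mean)
  names(fm_gap)[2L] <- "mean_fm_sys_gap"

  sv <- rbind(
    data.frame(m[key], group = m$group, method = "mri",
               stroke_volume = m$stroke_volume_mri),
    data.frame(m[key], group = m$group, method = "cfd",
               stroke_volume = m$stroke_volume_cfd))

  cfd_sv_spread <- stats::aggregate(
    stroke_volume ~ subject_id, data = sv[sv$method == "cfd", ],
    FUN = function(v) (max(v) - min(v)) / max(mean(v), 1e-300))
  names(cfd_sv_spread)[2L] <- "sv_rel_spread"

  summary <- list(
    min_consistency_count = min(cons$n_levels_mri_greater),
    mean_fm_gap = stats::setNames(fm_gap$mean_fm_sys_gap, fm_gap$group),
    cm_gap_exceeds_healthy =
      ("cm_like" %in% fm_gap$group && "healthy_like" %in% fm_gap$group) &&
      fm_gap$mean_fm_sys_gap[fm_gap$group == "cm_like"] >
        fm_gap$mean_fm_sys_gap[fm_gap$group == "healthy_like"],
    max_cfd_sv_rel_spread = max(cfd_sv_spread$sv_rel_spread))

  structure(list(per_level = m, consistency = cons, fm_gap = fm_gap,
                 sv_profiles = sv, cfd_sv_spread = cfd_sv_spread,
                 motion = motion_summaries, summary = summary),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  cat(sprintf("  %d subjects x %d levels\n",
              nrow(x$consistency),
              length(unique(x$per_level$level_label))))
  cat(sprintf("  |MRI| > |CFD| peak systolic at >= %d levels per subject\n",
              x$summary$min_consistency_count))
  for (g in names(x$summary$mean_fm_gap)) {
    cat(sprintf("  mean FM systolic gap (|MRI|-|CFD|), %s: %.2f cm/s\n",
                g, x$summary$mean_fm_gap[[g]]))
  }
  invisible(x)
}

#' Write a comparison report to disk
#'
#' CSV tables, a JSON summary, figure panels (stroke-volume profiles,
#' per-level peak-velocity comparison) and a small HTML index.
#'
#' @param report A `comparison_report`.
#' @param out_dir Output directory (created if needed).
#' @param maps Optional named list (subject) of lists with `mri` and `cfd`
#'   velocity-map panels as produced by the cohort runner; plotted when
#'   given.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir, maps = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$per_level,
                   file.path(out_dir, "per_level_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$consistency,
                   file.path(out_dir, "consistency_counts.csv"),
                   row.names = FALSE)
  utils::write.csv(report$sv_profiles,
                   file.path(out_dir, "stroke_volume_profiles.csv"),
                   row.names = FALSE)
  if (!is.null(report$motion)) {
    utils::write.csv(report$motion, file.path(out_dir, "motion_summary.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(report$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)

  figs <- character(0)
  lvl <- factor(report$sv_profiles$level_label,
                levels = c("INLET", rev(SSS_LEVELS)))
  d <- report$sv_profiles; d$level <- lvl
  p <- ggplot2::ggplot(d, ggplot2::aes(x = level, y = stroke_volume,
                                       colour = method,
                                       group = interaction(subject_id, method))) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = NULL, y = "stroke volume (mL)",
                  title = "Stroke volume along the cervical spine") +
    ggplot2::theme_minimal(base_size = 9)
  f <- file.path(out_dir, "stroke_volume_profiles.png")
  ggplot2::ggsave(f, p, width = 7, height = 3.2, dpi = 120)
  figs <- c(figs, f)

  pl <- report$per_level
  pl$level <- factor(pl$level_label, levels = rev(SSS_LEVELS))
  d2 <- rbind(data.frame(pl[c("subject_id", "group", "level")], method = "mri",
                         peak = pl$peak_systolic_mri),
              data.frame(pl[c("subject_id", "group", "level")], method = "cfd",
                         peak = pl$peak_systolic_cfd))
  p2 <- ggplot2::ggplot(d2, ggplot2::aes(x = level, y = peak, colour = method,
                                         group = interaction(subject_id, method))) +
    ggplot2::geom_line(alpha = 0.7) + ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = NULL, y = "peak systolic velocity (cm/s)",
                  title = "Peak systolic velocities: MRI vs CFD") +
    ggplot2::theme_minimal(base_size = 9)
  f2 <- file.path(out_dir, "peak_systolic_velocities.png")
  ggplot2::ggsave(f2, p2, width = 7, height = 3.2, dpi = 120)
  figs <- c(figs, f2)

  if (!is.null(maps)) {
    for (sid in names(maps)) {
      f3 <- file.path(out_dir, sprintf("velocity_maps_%s.png", sid))
      plot_velocity_maps(maps[[sid]], f3)
      figs <- c(figs, f3)
    }
  }

  html <- c("<html><head><title>MRI vs CFD comparison</title></head><body>",
            "<h1>MRI vs CFD comparison report</h1>",
            sprintf("<p>|MRI| &gt; |CFD| peak systolic at &ge; %d of the levels for every subject.</p>",
                    report$summary$min_consistency_count),
            paste(sprintf('<img src="%s" width="900"><br>', basename(figs)),
                  collapse = "\n"),
            '<p>Tables: <a href="per_level_metrics.csv">per-level metrics</a>,',
            '<a href="consistency_counts.csv">consistency counts</a>,',
            '<a href="stroke_volume_profiles.csv">stroke volumes</a>.</p>',
            "</body></html>")
  writeLines(html, file.path(out_dir, "index.html"))
  invisible(out_dir)
}

# side-by-side thru-plane velocity colour maps (MRI | CFD) per level
plot_velocity_maps <- function(subject_maps, path) {
  df <- do.call(rbind, lapply(subject_maps, function(lm) {
    rbind(map_to_df(lm$mri$map, lm$mri$x, lm$mri$y, lm$level, "mri"),
          map_to_df(lm$cfd$map, lm$cfd$x, lm$cfd$y, lm$level, "cfd"))
  }))
  df$level <- factor(df$level, levels = rev(SSS_LEVELS))
  p <- ggplot2::ggplot(df, ggplot2::aes(x, y, fill = v)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "transparent",
                                  name = "w (cm/s)") +
    ggplot2::facet_grid(method ~ level) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Peak-systolic thru-plane velocity", x = NULL, y = NULL) +
    ggplot2::theme_void(base_size = 8)
  ggplot2::ggsave(path, p, width = 10, height = 2.8, dpi = 120)
  invisible(path)
}

map_to_df <- function(map, x, y, level, method) {
  data.frame(x = rep(x, times = length(y)), y = rep(y, each = length(x)),
             v = as.vector(map), level = level, method = method)
}
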