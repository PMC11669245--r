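#' Pipeline configuration
#'
#' Single home for every stage parameter, round-trippable through YAML.
#' Defaults mirror the reference processing chain: probability smoothing at
#' sigma 1 voxel, Otsu thresholding, vasculature exclusion at probability
#' 0.5, watershed markers from the smoothed distance transform, a 100 um^3
#' size filter, CD68 positivity at two voxels of signal, and a 0.05
#' normality gate for the statistics.
#'
#' @param sigmas Feature-bank scales (voxel units).
#' @param n_trees Random-forest size.
#' @param seed Master seed for training and simulation.
#' @param smooth_sigma Probability-map smoothing sigma (voxels).
#' @param v_threshold Vasculature exclusion probability cutoff.
#' @param marker_smooth_sigma,marker_min_separation_um,marker_min_distance_um
#'   Watershed marker construction (see [separate_instances()]).
#' @param min_volume_um3 Size-filter threshold.
#' @param positivity_min_um3 CD68 positivity threshold (`NULL` = 2 voxels).
#' @param normality_alpha Shapiro-Wilk gate level.
#' @param default_spacing Fallback voxel spacing for metadata-less input.
#' @param output_dir Where [run_pipeline()] writes its bundle.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sigmas = c(0.3, 0.7, 1.0, 1.6, 3.5, 5.0, 10),
                            n_trees = 100L,
                            seed = 1L,
                            smooth_sigma = 1,
                            v_threshold = 0.5,
                            marker_smooth_sigma = 2,
                            marker_min_separation_um = 5,
                            marker_min_distance_um = 2.5,
                            min_volume_um3 = 100,
                            positivity_min_um3 = NULL,
                            normality_alpha = 0.05,
                            default_spacing = c(319.45 / 2048,
                                                319.45 / 2048, 1),
                            output_dir = "microglia3d-results") {
  structure(
    list(sigmas = sigmas, n_trees = as.integer(n_trees),
         seed = as.integer(seed), smooth_sigma = smooth_sigma,
         v_threshold = v_threshold,
         marker_smooth_sigma = marker_smooth_sigma,
         marker_min_separation_um = marker_min_separation_um,
         marker_min_distance_um = marker_min_distance_um,
         min_volume_um3 = min_volume_um3,
         positivity_min_um3 = positivity_min_um3,
         normality_alpha = normality_alpha,
         default_spacing = default_spacing,
         output_dir = output_dir),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)))
  })
}

#' Run the full quantification pipeline
#'
#' Executes, per stack: classify, smooth, Otsu-threshold, exclude
#' vasculature, watershed, size-filter, (optional QC decisions), morphometry
#' and CD68 colocalization; then runs the group statistics over all stacks.
#' All tabular outputs are written as CSV, labels as 16-bit TIFF, and a JSON
#' manifest records inputs, parameters and timings. Re-running with
#' identical inputs, config and seeds reproduces the CSVs byte for byte.
#'
#' @param inputs A data frame with columns `stack` (list of [mg_stack()]
#'   objects or TIFF paths), `group` (`control` / `AD`), optional
#'   `stack_id`.
#' @param config A [pipeline_config()].
#' @param classifier A trained [train_voxel_classifier()]; if `NULL`,
#'   `train_labels` must provide sparse labels for the first stack.
#' @param train_labels Optional [sparse_labels()] for on-the-fly training.
#' @param qc_decisions Optional named list (by stack id) of QC decision
#'   frames passed to [qc_review()].
#' @param write_outputs Write the result bundle to `config$output_dir`?
#' @return A result bundle: `cells` (per-cell morphometry + CD68 + group),
#'   `densities`, `coloc_summaries`, `stats` (list of test objects),
#'   `labels` (list of label volumes), `manifest`.
#' @export
run_pipeline <- function(inputs, config = pipeline_config(),
                         classifier = NULL, train_labels = NULL,
                         qc_decisions = NULL, write_outputs = TRUE) {
  t0 <- Sys.time()
  inputs <- as.data.frame(inputs)
  stopifnot(all(c("stack", "group") %in% names(inputs)))
  n_stacks <- nrow(inputs)
  if (!"stack_id" %in% names(inputs)) {
    inputs$stack_id <- sprintf("stack%02d", seq_len(n_stacks))
  }
  bank <- feature_bank(sigmas = config$sigmas)
  timings <- list()

  get_stack <- function(i) {
    s <- inputs$stack[[i]]
    if (inherits(s, "mg_stack")) return(s)
    stage("read_stack",
          read_stack(s, default_spacing = config$default_spacing))
  }

  if (is.null(classifier)) {
    if (is.null(train_labels)) {
      abort("supply a trained classifier or sparse training labels")
    }
    t1 <- Sys.time()
    s1 <- get_stack(1L)
    classifier <- stage("train_classifier", train_voxel_classifier(
      stack_channel(s1, 1L), train_labels, bank,
      n_trees = config$n_trees, seed = config$seed))
    timings$train <- as.numeric(Sys.time() - t1, units = "secs")
  }

  cells_all <- list()
  dens_all <- list()
  coloc_sum_all <- list()
  coloc_all <- list()
  labels_all <- list()
  for (i in seq_len(n_stacks)) {
    t1 <- Sys.time()
    id <- inputs$stack_id[i]
    st <- get_stack(i)
    vol <- stack_channel(st, 1L)
    pmap <- stage("classify", predict_probabilities(classifier, vol))
    sm <- stage("smooth", smooth_probability(pmap, config$smooth_sigma))
    ot <- stage("threshold", otsu_threshold(sm))
    mask <- stage("exclude_vasculature",
                  exclude_vasculature(ot$mask, pmap, config$v_threshold))
    labels <- stage("watershed", separate_instances(
      mask, spacing = st$spacing,
      marker_smooth_sigma = config$marker_smooth_sigma,
      marker_min_separation_um = config$marker_min_separation_um,
      marker_min_distance_um = config$marker_min_distance_um))
    labels <- stage("size_filter",
                    size_filter(labels, config$min_volume_um3))
    if (!is.null(qc_decisions) && !is.null(qc_decisions[[id]])) {
      labels <- stage("qc_review", qc_review(labels, qc_decisions[[id]]))
    }
    cells <- stage("morphometry",
                   measure_cells(labels, st$spacing, stack_id = id))
    cells$group <- inputs$group[i]
    d <- dim(vol)
    geom <- acquisition_geometry(nx = d[2], ny = d[1], nz = d[3],
                                 dx = st$spacing[["x"]],
                                 dy = st$spacing[["y"]],
                                 dz = st$spacing[["z"]])
    dens <- stage("count_density", count_density(labels, geom))
    dens$stack_id <- id
    dens$group <- inputs$group[i]

    has_cd68 <- dim(st$data)[4] >= 2L
    if (has_cd68) {
      cd <- stage("coloc", {
        seg <- segment_cd68(stack_channel(st, 2L), labels)
        coloc_per_cell(seg$mask, labels, st$spacing,
                       config$positivity_min_um3)
      })
      cd$stack_id <- id
      cs <- coloc_summary(cd)
      cs$stack_id <- id
      cs$group <- inputs$group[i]
      coloc_all[[i]] <- cd
      coloc_sum_all[[i]] <- cs
      cells <- dplyr::left_join(
        cells, cd[, c("stack_id", "label", "cd68_volume_um3", "cd68_ratio",
                      "cd68_positive")],
        by = c("stack_id", "label"))
    }
    cells_all[[i]] <- cells
    dens_all[[i]] <- dens
    labels_all[[id]] <- labels
    timings[[id]] <- as.numeric(Sys.time() - t1, units = "secs")
  }

  cells <- dplyr::bind_rows(cells_all)
  densities <- dplyr::bind_rows(dens_all)
  coloc_summaries <- dplyr::bind_rows(coloc_sum_all)
  coloc_records <- dplyr::bind_rows(coloc_all)

  stats <- stage("stats", pipeline_stats(cells, densities, coloc_summaries,
                                         config$normality_alpha))

  manifest <- list(
    package_version = as.character(utils::packageVersion("microglia3d")),
    n_stacks = n_stacks,
    stack_ids = inputs$stack_id,
    groups = inputs$group,
    config = unclass(config),
    timings_sec = timings,
    finished = format(t0, tz = "UTC")
  )

  bundle <- list(cells = cells, densities = densities,
                 coloc = coloc_records, coloc_summaries = coloc_summaries,
                 stats = stats, labels = labels_all, manifest = manifest,
                 config = config)
  if (write_outputs) write_bundle(bundle, config$output_dir)
  bundle
}

# group statistics over the pipeline tables; per-cell metrics use cells as
# the unit of analysis, densities and CD68 proportions use stacks (subjects)
pipeline_stats <- function(cells, densities, coloc_summaries,
                           normality_alpha = 0.05) {
  out <- list()
  groups <- unique(cells$group)
  if (length(groups) == 2L) {
    split_by <- function(df, col) {
      split(df[[col]], df$group)[groups]
    }
    try_test <- function(samples) {
      if (any(vapply(samples, length, 1L) < 3)) return(NULL)
      tryCatch(
        two_sample_test(samples[[1]], samples[[2]],
                        normality_alpha = normality_alpha),
        error = function(e) NULL)
    }
    for (metric in c("volume_um3", "solidity_3d", "convexity",
                     "circularity", "axis_ratio")) {
      out[[metric]] <- try_test(split_by(cells, metric))
    }
    if (nrow(densities) > 0) {
      out$density_3d_mm3 <- try_test(split_by(densities, "density_3d_mm3"))
    }
    if (!is.null(coloc_summaries) && nrow(coloc_summaries) > 0) {
      out$proportion_cd68_positive <-
        try_test(split_by(coloc_summaries, "proportion_cd68_positive"))
    }
    if ("cd68_positive" %in% names(cells) &&
          !anyNA(cells$cd68_positive)) {
      strat <- cells
      strat$cd68_status <- factor(
        ifelse(strat$cd68_positive, "CD68+", "CD68-"),
        levels = c("CD68+", "CD68-"))
      counts <- table(strat$group, strat$cd68_status)
      if (all(counts >= 2)) {
        out$volume_by_group_cd68 <- two_way_anova_bonferroni(
          strat, "volume_um3", "group", "cd68_status")
      }
    }
  }
  out
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(bundle$cells, file.path(dir, "cells.csv"), row.names = FALSE)
  write.csv(bundle$densities, file.path(dir, "densities.csv"),
            row.names = FALSE)
  if (nrow(bundle$coloc) > 0) {
    write.csv(bundle$coloc, file.path(dir, "coloc.csv"), row.names = FALSE)
    write.csv(bundle$coloc_summaries,
              file.path(dir, "coloc_summaries.csv"), row.names = FALSE)
  }
  for (id in names(bundle$labels)) {
    write_labels(bundle$labels[[id]],
                 file.path(dir, paste0("labels_", id, ".tif")))
  }
  stats_rows <- purrr::imap(bundle$stats, function(s, nm) {
    if (inherits(s, "mg_test")) {
      dplyr::mutate(tidy(s), metric = nm, .before = 1)
    } else if (inherits(s, "mg_anova")) {
      dplyr::mutate(tidy(s), metric = nm, .before = 1)
    } else {
      NULL
    }
  })
  stats_tbl <- dplyr::bind_rows(stats_rows)
  if (nrow(stats_tbl) > 0) {
    write.csv(stats_tbl, file.path(dir, "stats.csv"), row.names = FALSE)
  }
  writeLines(render_stats_report(bundle), file.path(dir, "report.txt"))
  write_config(bundle$config, file.path(dir, "config.yaml"))
  manifest <- bundle$manifest
  manifest$config_md5 <-
    unname(tools::md5sum(file.path(dir, "config.yaml")))
  manifest$outputs <- setdiff(list.files(dir), "manifest.json")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

render_stats_report <- function(bundle) {
  lines <- c("microglia3d group comparison report",
             strrep("=", 40), "")
  sg <- summarize_groups(bundle$cells, "volume_um3", "group")
  lines <- c(lines, "Cell volume (um^3), mean ± SEM per group:",
             sprintf("  %s: %s (n = %d cells)", sg$group, sg$label, sg$n), "")
  for (nm in names(bundle$stats)) {
    s <- bundle$stats[[nm]]
    if (inherits(s, "mg_test")) {
      lines <- c(lines, sprintf(
        "%-28s %-16s p = %-10.4g %s", nm, s$method, s$p_value, s$stars))
    }
  }
  aov_ <- bundle$stats$volume_by_group_cd68
  if (!is.null(aov_)) {
    lines <- c(lines, "", "Two-way ANOVA (volume ~ group x CD68 status):")
    an <- aov_$anova
    lines <- c(lines, sprintf("  %-24s F = %-8.4g p = %.4g",
                              an$term[1:3], an$statistic[1:3],
                              an$p_value[1:3]))
    ct <- aov_$contrasts
    lines <- c(lines, "  Bonferroni contrasts:",
               sprintf("    %-28s p = %-10.4g %s", ct$contrast,
                       ct$p_bonferroni, ct$stars))
  }
  lines
}
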