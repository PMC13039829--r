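## File interfaces: multi-page TIFF for image stacks, CSV/JSON for results,
## YAML for configs. All writers are deterministic: identical inputs give
## byte-identical files.

#' Write a named list of channel matrices as a multi-page TIFF
#'
#' @param channels named list of matrices on the `[0, 1]` scale (one page
#'   per channel).
#' @param path output path.
#' @export
write_tiff_stack <- function(channels, path) {
  imgs <- lapply(channels, function(m) {
    m <- pmin(pmax(m, 0), 1)
    storage.mode(m) <- "double"
    m
  })
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF as a list of matrices
#'
#' @param path TIFF path.
#' @param channel_names optional names for the pages.
#' @export
read_tiff_stack <- function(path, channel_names = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  if (!is.null(channel_names)) names(pages) <- channel_names
  pages
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

write_csv_file <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    yaml::read_yaml(config)
  } else if (is.list(config)) {
    config
  } else {
    stop("'config' must be a list or a YAML file path", call. = FALSE)
  }
}

#' Run the phantom sprouting study end to end
#'
#' Generates `n_images` seeded retina phantoms, segments their layers,
#' quantifies sprouting, TUNEL counts and ONL thickness, and writes one CSV
#' row per image plus a JSON summary. Re-running with the same config and
#' seed reproduces byte-identical outputs.
#'
#' @param config list (or YAML path) with optional `n_images` (default 5),
#'   `sprout_range` (default `c(1, 10)`), `phantom` (overrides for
#'   [retina_phantom_spec()]) and `sprouting` (params for
#'   [quantify_sprouting()]).
#' @param seed integer master seed.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the per-image results data frame.
#' @export
run_sprouting_study <- function(config = list(), seed = 1L, out_dir) {
  cfg <- read_config(config)
  n_images <- cfg$n_images %||% 5L
  sprout_range <- cfg$sprout_range %||% c(1L, 10L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  rows <- list()
  for (i in seq_len(n_images)) {
    s_img <- child_seed(seed, i)
    base <- do.call(retina_phantom_spec,
                    utils::modifyList(cfg$phantom %||% list(),
                                      list(seed = s_img)))
    n_spr <- withr::with_seed(child_seed(seed, 1000L + i),
                              sample(sprout_range[1]:sprout_range[2], 1L))
    spec <- do.call(retina_phantom_spec, utils::modifyList(
      cfg$phantom %||% list(),
      list(sprouts = random_sprouts(n_spr, base,
                                    seed = child_seed(seed, 2000L + i)),
           tunel_positive_count =
             withr::with_seed(child_seed(seed, 3000L + i), sample(0:12, 1L)),
           seed = s_img)))
    ph <- make_retina_phantom(spec)
    masks <- segment_layers(ph$channels$nuclei, ph$channels$opl_marker,
                            spec$pixel_size_um,
                            is_marker_channel = ph$channels$is_marker)
    spr <- quantify_sprouting(ph$channels$bipolar, masks,
                              params = cfg$sprouting %||% list())
    tun <- count_tunel(ph$channels$tunel, masks$onl_mask, spec$pixel_size_um)
    th <- measure_onl_thickness(masks, seed = child_seed(seed, 4000L + i))
    rows[[i]] <- data.frame(
      image_id = sprintf("phantom_%03d", i),
      n_sprouts = spr$n_sprouts,
      total_length_um = spr$total_length_um,
      density_pct = spr$density_pct,
      tunel_count = tun,
      onl_thickness_um = th$mean_um,
      truth_total_length_um = ph$truth$total_sprout_length_um,
      truth_density_pct = ph$truth$sprouted_area_fraction_pct,
      truth_tunel_count = ph$truth$tunel_count)
  }
  res <- do.call(rbind, rows)
  write_csv_file(res, file.path(out_dir, "sprouting_per_image.csv"))
  write_json_file(list(
    n_images = n_images,
    seed = seed,
    median_abs_rel_error_length_pct = 100 * stats::median(
      abs(res$total_length_um - res$truth_total_length_um) /
        pmax(res$truth_total_length_um, 1e-9)),
    mean_abs_density_error_pp = mean(abs(res$density_pct -
                                           res$truth_density_pct))
  ), file.path(out_dir, "sprouting_summary.json"))
  invisible(res)
}

#' Run the differential-expression study end to end
#'
#' Generates a two-group spectral-count matrix with planted fold changes,
#' normalizes it, calibrates the fold-change window on a control split,
#' calls DEPs with the triple filter and writes the DEP table (TSV), the
#' calibration (JSON) and a run log. Byte-identical under identical config
#' and seed.
#'
#' @param config list (or YAML path) with optional `counts` (overrides for
#'   [count_table_spec()]), `thresholds` (`w_cut`, `p_cut`, `fc_cut`) and
#'   `denominator_mode`.
#' @param seed integer master seed.
#' @param out_dir output directory.
#' @return invisibly, the `dep_table`.
#' @export
run_dep_study <- function(config = list(), seed = 1L, out_dir) {
  cfg <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- do.call(count_table_spec,
                  utils::modifyList(cfg$counts %||% list(),
                                    list(seed = child_seed(seed, 1L))))
  sim <- make_count_table(spec)
  normd <- normalize_counts(sim$matrix)

  ## control split: a null matrix of the same design
  ctrl_spec <- do.call(count_table_spec,
                       utils::modifyList(cfg$counts %||% list(),
                                         list(planted_effects = numeric(0),
                                              seed = child_seed(seed, 2L))))
  ctrl <- normalize_counts(make_count_table(ctrl_spec)$matrix)
  calib <- calibrate_fc_threshold(ctrl)

  th <- cfg$thresholds %||% list()
  deps <- call_deps(normd,
                    w_cut = th$w_cut %||% 0.8,
                    p_cut = th$p_cut %||% 0.05,
                    fc_cut = th$fc_cut %||% calib$threshold,
                    denominator_mode = cfg$denominator_mode %||% "sum")

  utils::write.table(deps, file.path(out_dir, "dep_table.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_json_file(list(threshold = calib$threshold,
                       threshold_raw = calib$threshold_raw,
                       lnln_r = calib$lnln_r,
                       fraction_within = calib$fraction_within,
                       n_used = calib$n_used),
                  file.path(out_dir, "fc_calibration.json"))
  write_json_file(list(seed = seed,
                       n_proteins = spec$n_proteins,
                       group_sizes = spec$group_sizes,
                       thresholds = attr(deps, "thresholds"),
                       denominator_mode = attr(deps, "denominator_mode"),
                       n_dep = sum(deps$is_dep)),
                  file.path(out_dir, "run_log.json"))
  invisible(deps)
}
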