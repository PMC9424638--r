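#' Run a configured pipeline step
#'
#' Single programmatic entry point wiring the simulator, video analysis,
#' kinetics and photochemistry modules, mirroring a command-line workflow:
#' a config (YAML path or list) names a subcommand and its parameters; the
#' artifacts are written under an output directory together with a JSON
#' manifest recording the seed, package version, parameters and MD5 hashes
#' of every output, so a run is reproducible from its manifest alone.
#'
#' Subcommands and their config fields:
#' * `simulate` — fields of [crystal_spec()]; writes `stack.tif`,
#'   `truth.csv`, `spec.json`.
#' * `analyze` — `stack` (TIFF path), `frame_interval_s`, `mode`
#'   (`"positions"` with `rois` = list of `(top_row, left_col, side_px)`,
#'   or `"sizes"` with `center`, optional `sizes_px`), optional `window`,
#'   `bin_px`; writes `events.csv` and `summary.csv`.
#' * `kinetics` — `B0_mM`, `k_op`, `k_on`, `k_f`, optional `R0_mM`,
#'   `t_end_s`; writes `trajectory.csv` and `t1.json`.
#' * `photo` — `standards` (data frame/list with `nmol`, `area`),
#'   `yields_percent`, `beam` (`power_mW`, `beam_diameter_mm`,
#'   `drop_diameter_mm`), `c0_mM`; writes `photo.json`.
#'
#' @param config YAML file path or named list with at least `subcommand`.
#' @param seed Integer seed overriding `config$seed` (default 1).
#' @param out_dir Output directory (created if missing); overrides
#'   `config$out_dir`.
#' @return Invisibly, a list with `manifest` (path) and `outputs` (paths).
#' @export
run_config <- function(config, seed = NULL, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config) || is.null(config$subcommand))
    stop("config must be a list (or YAML file) with a `subcommand` field")
  sub <- config$subcommand
  if (!sub %in% c("simulate", "analyze", "kinetics", "photo"))
    stop("unknown subcommand: ", sub,
         " (expected simulate/analyze/kinetics/photo)")
  seed <- as.integer(if (!is.null(seed)) seed else
    if (!is.null(config$seed)) config$seed else 1L)
  if (is.na(seed) || seed < 0) stop("seed must be a non-negative integer")
  out_dir <- if (!is.null(out_dir)) out_dir else
    if (!is.null(config$out_dir)) config$out_dir else "."
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)

  outputs <- switch(sub,
    simulate = run_simulate(config, seed, out_dir),
    analyze = run_analyze(config, out_dir),
    kinetics = run_kinetics(config, out_dir),
    photo = run_photo(config, out_dir))

  manifest <- list(subcommand = sub, seed = seed,
                   package = "sspt",
                   version = as.character(utils::packageVersion("sspt")),
                   parameters = config[setdiff(names(config),
                                               c("subcommand", "out_dir"))],
                   outputs = lapply(outputs, function(p)
                     list(path = basename(p),
                          md5 = unname(tools::md5sum(p)))))
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(list(manifest = mpath, outputs = outputs))
}

run_simulate <- function(config, seed, out_dir) {
  keep <- intersect(names(config), names(formals(crystal_spec)))
  args <- config[keep]
  if (!is.null(args$crystal_polygon))
    args$crystal_polygon <- do.call(rbind, lapply(args$crystal_polygon,
                                                  as.numeric))
  args$seed <- seed
  spec <- do.call(crystal_spec, args)
  sim <- render_video(spec)
  p1 <- file.path(out_dir, "stack.tif")
  p2 <- file.path(out_dir, "truth.csv")
  p3 <- file.path(out_dir, "spec.json")
  write_stack_tiff(sim$stack, p1)
  write_t1_csv(sim$truth, p2)
  sjson <- spec
  sjson$crystal_polygon <- apply(spec$crystal_polygon, 1, as.list)
  jsonlite::write_json(unclass(sjson), p3, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  list(p1, p2, p3)
}

run_analyze <- function(config, out_dir) {
  if (is.null(config$stack)) stop("analyze config needs a `stack` TIFF path")
  if (is.null(config$frame_interval_s))
    stop("analyze config needs `frame_interval_s`")
  stack <- read_stack_tiff(config$stack, config$frame_interval_s,
                           config$pixel_size_um %||% (1 / 14))
  mode <- config$mode %||% "positions"
  p1 <- file.path(out_dir, "events.csv")
  p2 <- file.path(out_dir, "summary.csv")
  if (mode == "positions") {
    rois <- lapply(seq_along(config$rois), function(i) {
      r <- config$rois[[i]]
      roi(r$top_row, r$left_col, r$side_px,
          r$label %||% sprintf("ROI%d", i))
    })
    res <- analyze_positions(stack, rois, window = config$window %||% 65)
    utils::write.csv(res$events, p1, row.names = FALSE)
    utils::write.csv(res$summary, p2, row.names = FALSE)
  } else if (mode == "sizes") {
    res <- roi_size_sweep(stack, center = as.numeric(config$center),
                          sizes_px = config$sizes_px %||% c(2, 4, 8, 14, 28, 42),
                          window = config$window %||% 39,
                          bin_px = config$bin_px %||% 1L)
    utils::write.csv(res$events, p1, row.names = FALSE)
    utils::write.csv(res$stats, p2, row.names = FALSE)
  } else stop("unknown analyze mode: ", mode)
  list(p1, p2)
}

run_kinetics <- function(config, out_dir) {
  p <- kinetic_params(B0_mM = config$B0_mM, k_op = config$k_op,
                      k_on = config$k_on %||% 3e-2, k_f = config$k_f,
                      R0_mM = config$R0_mM %||% 16)
  traj <- simulate_four_state(p, t_end_s = config$t_end_s %||% 400)
  p1 <- file.path(out_dir, "trajectory.csv")
  p2 <- file.path(out_dir, "t1.json")
  utils::write.csv(traj$species, p1, row.names = FALSE)
  t1 <- tryCatch(inflection_time(traj), error = function(e) NA_real_)
  jsonlite::write_json(list(t1_s = t1), p2, auto_unbox = TRUE, digits = NA)
  list(p1, p2)
}

run_photo <- function(config, out_dir) {
  out <- list()
  if (!is.null(config$standards)) {
    curve <- fit_standard_curve(as.data.frame(config$standards))
    out$standard_curve <- list(slope = curve$slope,
                               intercept = curve$intercept,
                               r_squared = curve$r_squared)
  }
  if (!is.null(config$yields_percent))
    out$yield <- summarize_replicates(as.numeric(config$yields_percent))
  if (!is.null(config$beam)) {
    b <- config$beam
    out$beam <- list(
      power_density_W_cm2 = power_density(b$power_mW, b$beam_diameter_mm),
      illuminated_fraction = illuminated_fraction(b$beam_diameter_mm,
                                                  b$drop_diameter_mm))
    if (!is.null(config$c0_mM) && !is.null(out$yield))
      out$nominal_mM <- nominal_uncaged_concentration(config$c0_mM,
                                                      out$yield$mean)
  }
  p1 <- file.path(out_dir, "photo.json")
  jsonlite::write_json(out, p1, auto_unbox = TRUE, digits = NA)
  list(p1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
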