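#' Write a display to JSON
#'
#' One JSON object per display: seed, arrangement, mode, percent_pairs,
#' polarity_scheme, field (w, h), disc_radius, zone factors, and the disc
#' table (id, role, parent_id, x, y, polarity). Positions are serialized at
#' full precision so a round-trip is bit-exact.
#'
#' @param d a `na_display`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_display <- function(d, path) {
  obj <- list(seed = d$seed, arrangement = d$arrangement, mode = d$mode,
              percent_pairs = d$percent_pairs,
              polarity_scheme = d$polarity_scheme,
              field = list(w = d$field[["w"]], h = d$field[["h"]]),
              disc_radius = d$disc_radius,
              zone_major_factor = d$zone_major_factor,
              zone_minor_factor = d$zone_minor_factor,
              fixation_exclusion_radius = d$fixation_exclusion_radius,
              base_count = d$base_count, numerosity = d$numerosity,
              demotions = d$demotions,
              discs = d$discs)
  # 17 significant digits guarantee a bit-exact double round-trip
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a display from JSON
#'
#' @param path file written by [write_display()].
#' @return a `na_display`.
#' @export
read_display <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("seed", "arrangement", "mode", "polarity_scheme", "field",
                "disc_radius", "discs")
  missing <- setdiff(required, names(obj))
  if (length(missing)) {
    stop("display JSON is missing required key(s): ",
         paste(missing, collapse = ", "))
  }
  discs <- as.data.frame(obj$discs)
  structure(list(discs = discs,
                 arrangement = obj$arrangement, mode = obj$mode,
                 percent_pairs = if (is.null(obj$percent_pairs)) NA
                                 else obj$percent_pairs,
                 polarity_scheme = obj$polarity_scheme,
                 field = c(w = obj$field$w, h = obj$field$h),
                 disc_radius = obj$disc_radius,
                 zone_major_factor = obj$zone_major_factor,
                 zone_minor_factor = obj$zone_minor_factor,
                 fixation_exclusion_radius = obj$fixation_exclusion_radius,
                 base_count = obj$base_count,
                 numerosity = obj$numerosity,
                 demotions = obj$demotions,
                 seed = obj$seed),
            class = "na_display")
}

#' Rasterize a display
#'
#' Renders a display into a matrix of hex colors: gray `#B6B6B6`
#' background, dark discs `#000000`, light discs `#FFFFFF`, fixation at the
#' image center, no anti-aliasing (a pixel is a disc color iff its center
#' falls inside a disc), default scale 0.04 degrees per pixel. Use
#' [write_ppm()] to store it as a plain-text image.
#'
#' @param d a `na_display`.
#' @param scale degrees per pixel (default 0.04).
#' @return character matrix (rows = image rows, top row first) of hex
#'   colors, with attribute `scale`.
#' @export
render_display <- function(d, scale = 0.04) {
  stopifnot(scale > 0)
  w_px <- ceiling(d$field[["w"]] / scale)
  h_px <- ceiling(d$field[["h"]] / scale)
  # pixel-center coordinates in degrees, y decreasing down the rows
  px <- (seq_len(w_px) - (w_px + 1) / 2) * scale
  py <- ((h_px + 1) / 2 - seq_len(h_px)) * scale
  img <- matrix("#B6B6B6", nrow = h_px, ncol = w_px)
  r2 <- d$disc_radius^2
  for (i in seq_len(nrow(d$discs))) {
    cx <- d$discs$x[i]; cy <- d$discs$y[i]
    ix <- which(abs(px - cx) <= d$disc_radius)
    iy <- which(abs(py - cy) <= d$disc_radius)
    if (!length(ix) || !length(iy)) next
    hit <- outer((py[iy] - cy)^2, (px[ix] - cx)^2, "+") <= r2
    col <- if (d$discs$polarity[i] == "dark") "#000000" else "#FFFFFF"
    img[iy, ix][hit] <- col
  }
  attr(img, "scale") <- scale
  img
}

#' Write a rendered display as plain-text PPM (P3)
#'
#' @param img matrix from [render_display()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ppm <- function(img, path) {
  rgb <- grDevices::col2rgb(t(img))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(ncol(img), nrow(img)), "255"), con)
  writeLines(paste(rgb[1, ], rgb[2, ], rgb[3, ]), con)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes generate, properties, match, simulate, analyze and (optionally)
#' power from one configuration, writing every artifact plus a
#' `manifest.json` (seeds, stage file hashes, package version) under
#' `out_dir`. Every stochastic stage receives a seed derived
#' deterministically from the global seed, so the run is a pure function of
#' the configuration.
#'
#' @param config list with components `seed` (global seed), `out_dir`,
#'   and optional overrides: `generator` (arguments to
#'   [generator_config()]), `n_per_arrangement` (default 20),
#'   `experiment_tag` (default "1a"), `n_participants` (default 8),
#'   `observer` (arguments to [observer_params()]), `power_reps`
#'   (default 0 = skip the power stage), `max_smd` (default 0.2).
#' @return list of stage outputs (invisibly): pool, match report, trials,
#'   screening, fit, power, manifest path.
#' @export
run_pipeline <- function(config) {
  stopifnot(!is.null(config$seed), !is.null(config$out_dir))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  gen_args <- config$generator
  if (is.null(gen_args)) gen_args <- list()
  gcfg <- do.call(generator_config, gen_args)
  n_arr <- if (is.null(config$n_per_arrangement)) 20L
           else config$n_per_arrangement
  tag <- if (is.null(config$experiment_tag)) "1a" else config$experiment_tag
  n_part <- if (is.null(config$n_participants)) 8L else config$n_participants
  obs_args <- config$observer
  if (is.null(obs_args)) obs_args <- list()
  params <- do.call(observer_params, obs_args)
  max_smd <- if (is.null(config$max_smd)) 0.2 else config$max_smd

  # stage 1-2: pool + properties
  pool <- generate_pool(gcfg, n_arr, seed = derive_seed(config$seed, 1))
  utils::write.csv(pool$table, file.path(out, "pool_properties.csv"),
                   row.names = FALSE)
  # stage 3: match
  report <- match_displays(pool$table, max_smd = max_smd)
  jsonlite::write_json(report[c("pairs", "unmatched", "smd_summary",
                                "pool_sizes", "max_smd")],
                       file.path(out, "match_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  # stage 4: simulate
  plan <- design_session(tag, seed = derive_seed(config$seed, 2))
  trials <- simulate_trials(plan, params, n_part,
                            seed = derive_seed(config$seed, 3))
  utils::write.csv(trials, file.path(out, "trials.csv"), row.names = FALSE)
  # stage 5: analyze
  screening <- screen_participants(trials)
  jsonlite::write_json(list(kept = screening$kept,
                            excluded = screening$excluded),
                       file.path(out, "screening.json"),
                       auto_unbox = TRUE, dataframe = "rows")
  tab <- prepare_trials(trials)
  fit <- fit_lmm(tab, "arrangement", outcome = "dv", method = "reml")
  utils::write.csv(fit$terms, file.path(out, "fit_terms.csv"),
                   row.names = FALSE)
  # stage 6: power (optional)
  power <- NULL
  if (!is.null(config$power_reps) && config$power_reps > 0) {
    power <- power_simulation(params, n_part, plan, config$power_reps,
                              seed = derive_seed(config$seed, 4))
    jsonlite::write_json(power[c("power", "ci", "n_sig", "n_reps", "alpha")],
                         file.path(out, "power.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  files <- c("pool_properties.csv", "match_report.json", "trials.csv",
             "screening.json", "fit_terms.csv",
             if (!is.null(power)) "power.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("numaniso")),
    global_seed = config$seed,
    stage_seeds = list(pool = derive_seed(config$seed, 1),
                       plan = derive_seed(config$seed, 2),
                       trials = derive_seed(config$seed, 3),
                       power = derive_seed(config$seed, 4)),
    df_method = fit$df_method,
    converged = fit$converged,
    hashes = as.list(tools::md5sum(file.path(out, files))))
  names(manifest$hashes) <- files
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(pool = pool, match = report, trials = trials,
                 screening = screening, fit = fit, power = power,
                 manifest = file.path(out, "manifest.json")))
}
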