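.prop_names <- c("mean_eccentricity", "mean_spacing", "convex_hull_area",
                 "occupancy_area", "density")

#' Derive a child seed deterministically from a parent seed
#'
#' Keeps every derived seed a positive 32-bit integer so all stochastic
#' stages of a run are a pure function of one global seed.
#'
#' @param seed parent integer seed.
#' @param i child index (>= 0).
#' @return integer seed.
#' @export
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i)) %% 2147483629) + 1L
}

#' Generate a pool of displays for matching
#'
#' Generates `n_per_arrangement` radial and `n_per_arrangement` tangential
#' displays from a base configuration, each from a seed derived
#' deterministically from `seed`, and computes the property vector of each.
#'
#' @param config a [generator_config()]; its `arrangement` and `seed` fields
#'   are overridden per display.
#' @param n_per_arrangement displays per arrangement.
#' @param seed pool seed.
#' @param occ_radius,grid_step occupancy parameters (see [occupancy_area()]).
#' @return list with `displays` (list, indexed by display id) and `table`
#'   (data.frame: id, arrangement, seed, numerosity, the five properties).
#' @export
generate_pool <- function(config, n_per_arrangement, seed = config$seed,
                          occ_radius = 1, grid_step = 0.02) {
  stopifnot(n_per_arrangement >= 1)
  displays <- list()
  rows <- vector("list", 2 * n_per_arrangement)
  k <- 0L
  for (arr in c("radial", "tangential")) {
    for (i in seq_len(n_per_arrangement)) {
      k <- k + 1L
      cfg <- config
      cfg$arrangement <- arr
      cfg$seed <- derive_seed(seed, k)
      d <- generate_display(cfg)
      displays[[k]] <- d
      rows[[k]] <- cbind(data.frame(id = k, arrangement = arr, seed = cfg$seed),
                         display_properties(d, occ_radius, grid_step))
    }
  }
  list(displays = displays, table = do.call(rbind, rows))
}

#' Match radial with tangential displays on numerosity and properties
#'
#' For each target numerosity, pairs each radial display greedily (in id
#' order) with the unused tangential display of the same numerosity that
#' minimizes Euclidean distance in z-scored property space (z-scores from
#' the pooled distribution; ties broken by lower id). A candidate pair
#' whose standardized mean difference exceeds `max_smd` in absolute value on
#' any single property is rejected and the radial display is reported
#' unmatched. Displays are never altered; the report references ids only.
#'
#' @param pool a pool table from [generate_pool()] (or any data.frame with
#'   columns id, arrangement, numerosity and the five properties).
#' @param target_numerosities numerosities to match (default: all
#'   numerosities present in both arrangements).
#' @param max_smd per-property cap on the absolute standardized mean
#'   difference of an accepted pair (default 0.2, a conventional
#'   balance tolerance; reported in the output).
#' @return a `na_match_report`: list with `pairs` (data.frame radial_id,
#'   tangential_id, numerosity, zdist and per-property smd_*), `unmatched`
#'   (data.frame id, numerosity, reason), `smd_summary` (mean and max |SMD|
#'   per property over accepted pairs), `pool_sizes`, `max_smd`.
#' @export
match_displays <- function(pool, target_numerosities = NULL, max_smd = 0.2) {
  if (is.list(pool) && !is.data.frame(pool) && !is.null(pool$table)) {
    pool <- pool$table
  }
  stopifnot(all(c("id", "arrangement", "numerosity", .prop_names) %in%
                  names(pool)))
  rad <- pool[pool$arrangement == "radial", ]
  tan <- pool[pool$arrangement == "tangential", ]
  if (!nrow(rad) || !nrow(tan)) stop("pool must contain both arrangements")
  if (is.null(target_numerosities)) {
    target_numerosities <- sort(intersect(rad$numerosity, tan$numerosity))
  }
  sds <- vapply(.prop_names, function(p) stats::sd(pool[[p]]), numeric(1))
  sds[!is.finite(sds) | sds == 0] <- 1  # constant property: raw differences
  z <- function(df) sweep(as.matrix(df[, .prop_names, drop = FALSE]), 2, sds, "/")
  zr <- z(rad); zt <- z(tan)
  pairs <- list(); unmatched <- list()
  used_t <- logical(nrow(tan))
  for (num in sort(unique(c(target_numerosities, numeric(0))))) {
    ri <- which(rad$numerosity == num)
    ri <- ri[order(rad$id[ri])]
    if (!length(ri)) next
    for (i in ri) {
      cand <- which(!used_t & tan$numerosity == num)
      if (!length(cand)) {
        unmatched[[length(unmatched) + 1L]] <-
          data.frame(id = rad$id[i], numerosity = num,
                     reason = "no_same_numerosity_candidate")
        next
      }
      dz <- sqrt(colSums((t(zt[cand, , drop = FALSE]) - zr[i, ])^2))
      best <- cand[order(dz, tan$id[cand])][1]
      smd <- (zr[i, ] - zt[best, ])  # already scaled by pooled sd
      if (any(abs(smd) > max_smd)) {
        unmatched[[length(unmatched) + 1L]] <-
          data.frame(id = rad$id[i], numerosity = num, reason = "smd_cap")
        next
      }
      used_t[best] <- TRUE
      row <- data.frame(radial_id = rad$id[i], tangential_id = tan$id[best],
                        numerosity = num, zdist = min(dz))
      for (p in .prop_names) row[[paste0("smd_", p)]] <- smd[[p]]
      pairs[[length(pairs) + 1L]] <- row
    }
  }
  numerosities_absent <- setdiff(target_numerosities,
                                 intersect(rad$numerosity, tan$numerosity))
  pairs <- if (length(pairs)) do.call(rbind, pairs) else NULL
  unmatched <- if (length(unmatched)) do.call(rbind, unmatched) else NULL
  smd_summary <- NULL
  if (!is.null(pairs)) {
    sm <- abs(as.matrix(pairs[, paste0("smd_", .prop_names), drop = FALSE]))
    smd_summary <- data.frame(property = .prop_names,
                              mean_abs_smd = colMeans(sm),
                              max_abs_smd = apply(sm, 2, max),
                              row.names = NULL)
  }
  structure(list(pairs = pairs, unmatched = unmatched,
                 unmatched_numerosities = numerosities_absent,
                 smd_summary = smd_summary,
                 pool_sizes = c(radial = nrow(rad), tangential = nrow(tan)),
                 max_smd = max_smd),
            class = "na_match_report")
}

#' @export
print.na_match_report <- function(x, ...) {
  np <- if (is.null(x$pairs)) 0L else nrow(x$pairs)
  cat(sprintf("<na_match_report> %d pairs (pool %d radial / %d tangential), |SMD| cap %.2f\n",
              np, x$pool_sizes[["radial"]], x$pool_sizes[["tangential"]],
              x$max_smd))
  if (!is.null(x$smd_summary)) {
    print(x$smd_summary, digits = 3)
  }
  invisible(x)
}
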