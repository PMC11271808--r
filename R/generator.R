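#' Field sizes used by the display generator
#'
#' The small field (21.5 x 13.5 degrees) hosts the small numerosity ranges,
#' the large field (27.0 x 18.5 degrees) the large ranges.
#' @keywords internal
.fields <- list(small = c(w = 21.5, h = 13.5), large = c(w = 27.0, h = 18.5))

round_half_up <- function(x) floor(x + 0.5)

#' Generator configuration
#'
#' Bundles every parameter of display construction. Defaults are the display
#' parameters of the study design this package models: 0.36 degree disc
#' radius, interference-zone semi-axes 0.25 x and 0.1 x eccentricity, a 4
#' degree fixation exclusion circle, and the two field sizes.
#'
#' @param arrangement `"radial"` or `"tangential"`: which zone receives the
#'   flanking discs.
#' @param mode `"mixture"` (singles/pairs/triplets in controlled
#'   proportions; numerosity = 2 x base count) or `"all_triplets"` (every
#'   base flanked on both sides; numerosity = 3 x base count).
#' @param percent_pairs percentage of base discs that form pairs, one of
#'   0, 25, 50, 75, 100 (mixture mode only).
#' @param polarity_scheme `"uniform_dark"`, `"uniform_light"`, or `"mixed"`
#'   (dark bases, light flankers).
#' @param field `"small"`, `"large"`, or a numeric `c(w, h)` in degrees.
#' @param disc_radius disc radius, degrees.
#' @param zone_major_factor,zone_minor_factor eccentricity scaling of the
#'   zone semi-axes.
#' @param fixation_exclusion_radius no part of any disc may come closer to
#'   fixation than this radius (degrees).
#' @param seed integer seed; the display is a pure function of the config.
#' @param max_consecutive_failures rejection-sampling saturation proxy:
#'   packing (and each flanker placement) stops after this many consecutive
#'   rejected candidates.
#' @param n_bases optional target base count: packing stops early once this
#'   many bases are placed (`NULL` packs to saturation). Used to hit the
#'   fixed numerosity grids of the study design.
#' @param n_poly_vertices vertex count of the polygonal ellipse
#'   approximation used in overlap tests.
#' @param require_flanker_room if `TRUE` (default), packing only accepts
#'   base positions whose designated zone admits an on-axis flanker on both
#'   sides (inside the field, outside the fixation exclusion circle). This
#'   is what makes the exact numerosity identities (2 x and 3 x base count)
#'   attainable for every base; without it, bases near the field edge or
#'   the exclusion ring cannot host their flankers and are demoted.
#' @return a `na_config` list.
#' @export
generator_config <- function(arrangement = c("radial", "tangential"),
                             mode = c("mixture", "all_triplets"),
                             percent_pairs = 50,
                             polarity_scheme = c("uniform_dark",
                                                 "uniform_light", "mixed"),
                             field = "small",
                             disc_radius = 0.36,
                             zone_major_factor = 0.25,
                             zone_minor_factor = 0.1,
                             fixation_exclusion_radius = 4,
                             seed = 1L,
                             max_consecutive_failures = 3000L,
                             n_bases = NULL,
                             n_poly_vertices = 64L,
                             require_flanker_room = TRUE) {
  arrangement <- match.arg(arrangement)
  mode <- match.arg(mode)
  polarity_scheme <- match.arg(polarity_scheme)
  if (is.character(field)) {
    field <- match.arg(field, names(.fields))
    fdim <- .fields[[field]]
  } else {
    stopifnot(is.numeric(field), length(field) == 2, all(field > 0))
    fdim <- c(w = field[[1]], h = field[[2]])
  }
  if (mode == "mixture" && !percent_pairs %in% c(0, 25, 50, 75, 100)) {
    stop("percent_pairs must be one of 0, 25, 50, 75, 100")
  }
  stopifnot(disc_radius > 0,
            zone_minor_factor > 0, zone_minor_factor <= zone_major_factor,
            zone_major_factor < 1, fixation_exclusion_radius >= 0)
  structure(list(arrangement = arrangement, mode = mode,
                 percent_pairs = if (mode == "mixture") percent_pairs else NA,
                 polarity_scheme = polarity_scheme,
                 field = fdim, disc_radius = disc_radius,
                 zone_major_factor = zone_major_factor,
                 zone_minor_factor = zone_minor_factor,
                 fixation_exclusion_radius = fixation_exclusion_radius,
                 seed = as.integer(seed),
                 max_consecutive_failures = as.integer(max_consecutive_failures),
                 n_bases = if (is.null(n_bases)) NULL else as.integer(n_bases),
                 n_poly_vertices = as.integer(n_poly_vertices),
                 require_flanker_room = isTRUE(require_flanker_room)),
            class = "na_config")
}

#' Pack base discs under the zone non-overlap constraint
#'
#' Base discs are placed by uniform rejection sampling: a candidate is
#' accepted iff its whole disc lies inside the field, wholly outside the
#' fixation exclusion circle, and neither of its interference zones overlaps
#' any zone (of either kind) of an already accepted base. Placement stops
#' when `max_consecutive_failures` successive candidates were rejected (the
#' saturation proxy) or when `n_bases` bases have been accepted.
#'
#' Consumes the R RNG stream; call [set.seed()] (or use [generate_display()],
#' which seeds from the config) for reproducibility.
#'
#' @param config a [generator_config()].
#' @return data.frame of base discs (id, role, parent_id, x, y).
#' @export
pack_base_discs <- function(config) {
  target <- if (is.null(config$n_bases)) -1L else config$n_bases
  xy <- .pack_bases(config$field[["w"]], config$field[["h"]],
                    config$disc_radius, config$fixation_exclusion_radius,
                    config$zone_major_factor, config$zone_minor_factor,
                    config$max_consecutive_failures, config$n_poly_vertices,
                    target, as.integer(config$arrangement == "radial"),
                    as.integer(config$require_flanker_room))
  n <- nrow(xy)
  data.frame(id = seq_len(n),
             role = rep("base", n),
             parent_id = seq_len(n),
             x = xy[, 1], y = xy[, 2],
             stringsAsFactors = FALSE)
}

#' Allocate single/pair/triplet configurations to base discs
#'
#' `percent_pairs` percent of bases are paired with one flanker; the
#' remainder is split exactly in half between triplets (two flankers) and
#' singles (none), so the implied flanker total equals the base count and
#' the display numerosity is exactly twice the base count. When the rounded
#' pair count leaves an odd remainder it is adjusted by one step (upward for
#' percent_pairs >= 50, downward otherwise) to restore an even split.
#'
#' @param base_count number of base discs (>= 1).
#' @param percent_pairs one of 0, 25, 50, 75, 100.
#' @return list with counts `n_pair`, `n_triplet`, `n_single` and `roles`, a
#'   character vector (one of "pair"/"triplet"/"single" per base, assigned
#'   uniformly at random from the current RNG stream).
#' @export
allocate_configurations <- function(base_count, percent_pairs) {
  if (!percent_pairs %in% c(0, 25, 50, 75, 100)) {
    stop("percent_pairs must be one of 0, 25, 50, 75, 100")
  }
  stopifnot(base_count >= 1)
  n_pair <- round_half_up(percent_pairs * base_count / 100)
  if ((base_count - n_pair) %% 2 == 1) {
    step <- if (percent_pairs >= 50) 1L else -1L
    if (n_pair + step < 0L || n_pair + step > base_count) step <- -step
    n_pair <- n_pair + step
  }
  n_triplet <- (base_count - n_pair) %/% 2L
  n_single <- base_count - n_pair - n_triplet
  roles <- sample(rep(c("pair", "triplet", "single"),
                      c(n_pair, n_triplet, n_single)))
  list(n_pair = as.integer(n_pair), n_triplet = as.integer(n_triplet),
       n_single = as.integer(n_single), roles = roles)
}

# sample one flanker center in the designated half-zone of one base;
# uniform rejection sampling over the half-zone first, then (if the legal
# sliver is too small to hit by chance) jittered sampling around the same
# probe grid the packer used to certify flanker room; returns c(x, y) or
# NULL if even that fails (the caller then demotes the base)
.sample_flanker <- function(bx, by, side, zones, arrangement, config,
                            placed_x, placed_y) {
  zin <- if (arrangement == "radial") zones$radial else zones$tangential
  zout <- if (arrangement == "radial") zones$tangential else zones$radial
  ct <- cos(zin$theta); st <- sin(zin$theta)
  r <- config$disc_radius
  w2 <- config$field[["w"]] / 2; h2 <- config$field[["h"]] / 2
  min_ecc <- config$fixation_exclusion_radius + r
  legal <- function(u, v) {
    if ((u / zin$a)^2 + (v / zin$b)^2 > 1) return(NULL)
    if ((v / zin$a)^2 + (u / zin$b)^2 <= 1) return(NULL)  # lens off-limits
    if (u^2 + v^2 < (2 * r)^2) return(NULL)
    x <- bx + u * ct - v * st
    y <- by + u * st + v * ct
    if (abs(x) + r > w2 || abs(y) + r > h2) return(NULL)
    if (eccentricity(x, y) < min_ecc) return(NULL)
    if (length(placed_x) &&
        min((placed_x - x)^2 + (placed_y - y)^2) < (2 * r)^2) return(NULL)
    c(x, y)
  }
  for (i in seq_len(config$max_consecutive_failures)) {
    u <- stats::runif(1, 0, zin$a) * side
    v <- stats::runif(1, -zin$b, zin$b)
    p <- legal(u, v)
    if (!is.null(p)) return(p)
  }
  # probe-grid fallback (same grid as the packer's room certificate)
  ug <- zin$a * (0.02 + 0.978 * (0:9) / 9)
  grid <- do.call(rbind, lapply(ug, function(u) {
    vmax <- zin$b * sqrt(max(0, 1 - (u / zin$a)^2)) * 0.999
    cbind(u, vmax * (2 * (0:8) / 8 - 1))
  }))
  grid <- grid[sample(nrow(grid)), , drop = FALSE]
  for (pass in 1:40) {
    jit <- (pass - 1) / 39 * 0.02
    for (k in seq_len(nrow(grid))) {
      u <- grid[k, 1] + stats::rnorm(1, 0, jit * zin$a)
      v <- grid[k, 2] + stats::rnorm(1, 0, jit * zin$b)
      p <- legal(side * u, v)
      if (!is.null(p)) return(p)
    }
  }
  NULL
}

#' Place flanking discs into the designated interference zones
#'
#' Pairs receive one flanker on a uniformly chosen side of the base along
#' the designated zone's major axis; triplets receive one flanker on each
#' side. Every flanker center lies inside its parent's designated zone
#' (radial zone in radial displays, tangential zone in tangential displays),
#' outside the lens where the two zones overlap, wholly inside the field,
#' wholly outside the fixation exclusion circle, and at center distance of
#' at least one disc diameter from every other disc. A base whose flanker
#' cannot be placed within `max_consecutive_failures` samples is demoted
#' (triplet to pair to single); demotions are counted in the result.
#'
#' @param bases base-disc data.frame from [pack_base_discs()].
#' @param roles character vector from [allocate_configurations()].
#' @param config a [generator_config()].
#' @return list with `flankers` (data.frame) and `demotions` (integer).
#' @export
place_flankers <- function(bases, roles, config) {
  stopifnot(nrow(bases) == length(roles))
  fx <- numeric(0); fy <- numeric(0); fparent <- integer(0)
  all_x <- bases$x; all_y <- bases$y
  demotions <- 0L
  for (i in seq_len(nrow(bases))) {
    role <- roles[i]
    if (role == "single") next
    zones <- make_zones(bases$x[i], bases$y[i],
                        config$zone_major_factor, config$zone_minor_factor)
    sides <- if (role == "triplet") c(-1, 1) else sample(c(-1, 1), 1)
    placed <- 0L
    for (s in sides) {
      p <- .sample_flanker(bases$x[i], bases$y[i], s, zones,
                           config$arrangement, config, all_x, all_y)
      if (is.null(p)) {
        demotions <- demotions + 1L
      } else {
        fx <- c(fx, p[1]); fy <- c(fy, p[2]); fparent <- c(fparent, bases$id[i])
        all_x <- c(all_x, p[1]); all_y <- c(all_y, p[2])
        placed <- placed + 1L
      }
    }
  }
  n <- length(fx)
  list(flankers = data.frame(id = max(bases$id, 0L) + seq_len(n),
                             role = rep("flanker", n),
                             parent_id = fparent, x = fx, y = fy,
                             stringsAsFactors = FALSE),
       demotions = demotions)
}

#' Assign contrast polarity
#'
#' `uniform_dark` paints every disc dark, `uniform_light` light, and
#' `mixed` paints base discs dark and flanking discs light. Positions are
#' untouched.
#'
#' @param discs disc data.frame with a `role` column.
#' @param scheme polarity scheme.
#' @return the data.frame with a `polarity` column ("dark"/"light").
#' @export
assign_polarity <- function(discs, scheme = c("uniform_dark", "uniform_light",
                                              "mixed")) {
  scheme <- match.arg(scheme)
  discs$polarity <- switch(scheme,
    uniform_dark = rep("dark", nrow(discs)),
    uniform_light = rep("light", nrow(discs)),
    mixed = ifelse(discs$role == "base", "dark", "light"))
  discs
}

#' Generate one complete display
#'
#' Composes packing, configuration allocation (all bases become triplets in
#' `all_triplets` mode), flanker placement, and polarity assignment. The
#' result is a pure function of the configuration (including its seed):
#' mixture displays have numerosity 2 x base count and all-triplet displays
#' 3 x base count, minus any logged demotions.
#'
#' @param config a [generator_config()].
#' @return a `na_display` object: list with `discs` (data.frame id, role,
#'   parent_id, x, y, polarity), arrangement/mode/percent_pairs/
#'   polarity_scheme metadata, `field`, `disc_radius`, `base_count`,
#'   `numerosity`, `demotions`, `seed`.
#' @export
generate_display <- function(config) {
  stopifnot(inherits(config, "na_config"))
  set.seed(config$seed)
  bases <- pack_base_discs(config)
  if (nrow(bases) == 0) {
    roles <- character(0)
    fl <- list(flankers = bases[0, ], demotions = 0L)
  } else if (config$mode == "all_triplets") {
    roles <- rep("triplet", nrow(bases))
    fl <- place_flankers(bases, roles, config)
  } else {
    roles <- allocate_configurations(nrow(bases), config$percent_pairs)$roles
    fl <- place_flankers(bases, roles, config)
  }
  discs <- rbind(bases, fl$flankers)
  discs <- assign_polarity(discs, config$polarity_scheme)
  structure(list(discs = discs,
                 arrangement = config$arrangement,
                 mode = config$mode,
                 percent_pairs = config$percent_pairs,
                 polarity_scheme = config$polarity_scheme,
                 field = config$field,
                 disc_radius = config$disc_radius,
                 zone_major_factor = config$zone_major_factor,
                 zone_minor_factor = config$zone_minor_factor,
                 fixation_exclusion_radius = config$fixation_exclusion_radius,
                 base_count = nrow(bases),
                 numerosity = nrow(discs),
                 demotions = fl$demotions,
                 seed = config$seed),
            class = "na_display")
}

#' @export
print.na_display <- function(x, ...) {
  cat(sprintf(
    "<na_display> %s/%s, %d discs (%d bases), field %.1fx%.1f deg, seed %d\n",
    x$arrangement, x$mode, x$numerosity, x$base_count,
    x$field[["w"]], x$field[["h"]], x$seed))
  invisible(x)
}

#' Check the geometric legality of a display
#'
#' Re-checks every construction constraint with the package's predicates:
#' whole-disc field containment, whole-disc fixation exclusion, pairwise
#' disc non-overlap, base-zone pairwise non-overlap (all four
#' radial/tangential pairings), and for every flanker membership in its
#' parent's designated zone but not in the central lens.
#'
#' @param d a `na_display`.
#' @return list with logical `ok` and a character vector `violations`.
#' @export
validate_display <- function(d) {
  v <- character(0)
  discs <- d$discs
  r <- d$disc_radius
  w2 <- d$field[["w"]] / 2; h2 <- d$field[["h"]] / 2
  if (any(abs(discs$x) + r > w2 + 1e-9 | abs(discs$y) + r > h2 + 1e-9)) {
    v <- c(v, "disc outside field")
  }
  ecc <- eccentricity(discs$x, discs$y)
  if (any(ecc < d$fixation_exclusion_radius + r - 1e-9)) {
    v <- c(v, "disc inside fixation exclusion circle")
  }
  if (nrow(discs) >= 2) {
    dd <- as.matrix(stats::dist(discs[, c("x", "y")]))
    diag(dd) <- Inf
    if (min(dd) < 2 * r - 1e-9) v <- c(v, "disc-disc overlap")
  }
  bases <- discs[discs$role == "base", ]
  if (nrow(bases) >= 1) {
    zs <- lapply(seq_len(nrow(bases)), function(i)
      make_zones(bases$x[i], bases$y[i], d$zone_major_factor,
                 d$zone_minor_factor))
    if (nrow(bases) >= 2) {
      for (i in seq_len(nrow(bases) - 1)) {
        for (j in (i + 1):nrow(bases)) {
          if (ellipses_overlap(zs[[i]]$radial, zs[[j]]$radial) ||
              ellipses_overlap(zs[[i]]$radial, zs[[j]]$tangential) ||
              ellipses_overlap(zs[[i]]$tangential, zs[[j]]$radial) ||
              ellipses_overlap(zs[[i]]$tangential, zs[[j]]$tangential)) {
            v <- c(v, sprintf("zone overlap between bases %d and %d",
                              bases$id[i], bases$id[j]))
          }
        }
      }
    }
    fl <- discs[discs$role == "flanker", ]
    if (nrow(fl)) {
      idx <- match(fl$parent_id, bases$id)
      for (k in seq_len(nrow(fl))) {
        z <- zs[[idx[k]]]
        zin <- if (d$arrangement == "radial") z$radial else z$tangential
        if (!point_in_ellipse(fl$x[k], fl$y[k], zin)) {
          v <- c(v, sprintf("flanker %d outside designated zone", fl$id[k]))
        }
        if (in_zone_overlap(fl$x[k], fl$y[k], z$radial, z$tangential)) {
          v <- c(v, sprintf("flanker %d inside zone lens", fl$id[k]))
        }
      }
    }
  }
  list(ok = length(v) == 0, violations = v)
}
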