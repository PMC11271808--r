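# Independent oracles. Everything here is written from first principles
# (plain coordinate algebra, rasterization, exhaustive search) and must not
# call the package's geometry predicates, so that implementation and oracle
# stay two separate routes to the same answer.

# membership of grid points in an ellipse, by direct quadratic form
.oracle_in_ellipse <- function(px, py, cx, cy, a, b, theta) {
  dx <- px - cx; dy <- py - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# rasterization overlap oracle: any shared cell on a `step`-spaced grid
# over the intersection of the two bounding boxes
oracle_ellipses_overlap <- function(z1, z2, step = 0.005) {
  xr <- c(max(z1$cx - z1$a, z2$cx - z2$a), min(z1$cx + z1$a, z2$cx + z2$a))
  yr <- c(max(z1$cy - z1$a, z2$cy - z2$a), min(z1$cy + z1$a, z2$cy + z2$a))
  if (xr[1] > xr[2] || yr[1] > yr[2]) return(FALSE)
  gx <- seq(xr[1], xr[2], by = step)
  gy <- seq(yr[1], yr[2], by = step)
  g <- expand.grid(x = gx, y = gy)
  any(.oracle_in_ellipse(g$x, g$y, z1$cx, z1$cy, z1$a, z1$b, z1$theta) &
        .oracle_in_ellipse(g$x, g$y, z2$cx, z2$cy, z2$a, z2$b, z2$theta))
}

# closed-form area of the union of two equal circles at center distance d
oracle_two_circle_union <- function(d, r) {
  if (d >= 2 * r) return(2 * pi * r^2)
  lens <- 2 * r^2 * acos(d / (2 * r)) - d / 2 * sqrt(4 * r^2 - d^2)
  2 * pi * r^2 - lens
}

# brute-force display legality, from raw coordinates only
oracle_validate_display <- function(d, raster_step = 0.02) {
  discs <- d$discs
  r <- d$disc_radius
  probs <- character(0)
  if (any(abs(discs$x) + r > d$field[["w"]] / 2 + 1e-9 |
            abs(discs$y) + r > d$field[["h"]] / 2 + 1e-9)) {
    probs <- c(probs, "field")
  }
  if (any(sqrt(discs$x^2 + discs$y^2) <
            d$fixation_exclusion_radius + r - 1e-9)) {
    probs <- c(probs, "exclusion")
  }
  n <- nrow(discs)
  for (i in seq_len(max(0, n - 1))) {
    dd <- sqrt((discs$x[(i + 1):n] - discs$x[i])^2 +
                 (discs$y[(i + 1):n] - discs$y[i])^2)
    if (any(dd < 2 * r - 1e-9)) probs <- c(probs, "disc_overlap")
  }
  bases <- discs[discs$role == "base", ]
  mf <- d$zone_major_factor; nf <- d$zone_minor_factor
  zone_of <- function(i, kind) {
    e <- sqrt(bases$x[i]^2 + bases$y[i]^2)
    th <- atan2(bases$y[i], bases$x[i])
    list(cx = bases$x[i], cy = bases$y[i], a = mf * e, b = nf * e,
         theta = if (kind == "radial") th else th + pi / 2)
  }
  nb <- nrow(bases)
  if (nb >= 2) {
    for (i in 1:(nb - 1)) for (j in (i + 1):nb) {
      for (ki in c("radial", "tangential")) for (kj in c("radial",
                                                         "tangential")) {
        if (oracle_ellipses_overlap(zone_of(i, ki), zone_of(j, kj),
                                    step = raster_step)) {
          probs <- c(probs, "zone_overlap")
        }
      }
    }
  }
  fl <- discs[discs$role == "flanker", ]
  if (nrow(fl)) {
    idx <- match(fl$parent_id, bases$id)
    for (k in seq_len(nrow(fl))) {
      zin <- zone_of(idx[k],
                     if (d$arrangement == "radial") "radial" else "tangential")
      zout <- zone_of(idx[k],
                      if (d$arrangement == "radial") "tangential" else "radial")
      inz <- .oracle_in_ellipse(fl$x[k], fl$y[k], zin$cx, zin$cy, zin$a,
                                zin$b, zin$theta)
      lens <- inz && .oracle_in_ellipse(fl$x[k], fl$y[k], zout$cx, zout$cy,
                                        zout$a, zout$b, zout$theta)
      if (!inz) probs <- c(probs, "flanker_outside_zone")
      if (lens) probs <- c(probs, "flanker_in_lens")
    }
  }
  unique(probs)
}

# exhaustive optimal same-numerosity matching: minimize total z-distance
# over all radial-to-tangential assignments (small pools only)
oracle_match_exhaustive <- function(pool, max_smd = 0.2) {
  props <- c("mean_eccentricity", "mean_spacing", "convex_hull_area",
             "occupancy_area", "density")
  sds <- vapply(props, function(p) stats::sd(pool[[p]]), numeric(1))
  sds[!is.finite(sds) | sds == 0] <- 1
  rad <- pool[pool$arrangement == "radial", ]
  tan <- pool[pool$arrangement == "tangential", ]
  best <- NULL; best_cost <- Inf
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  stopifnot(nrow(rad) == nrow(tan), nrow(rad) <= 4)
  for (p in perms(seq_len(nrow(tan)))) {
    ok <- TRUE; cost <- 0
    pairs <- list()
    for (i in seq_len(nrow(rad))) {
      j <- p[i]
      if (rad$numerosity[i] != tan$numerosity[j]) { ok <- FALSE; break }
      zr <- as.numeric(rad[i, props]) / sds
      zt <- as.numeric(tan[j, props]) / sds
      if (any(abs(zr - zt) > max_smd)) { ok <- FALSE; break }
      cost <- cost + sqrt(sum((zr - zt)^2))
      pairs[[i]] <- c(rad$id[i], tan$id[j])
    }
    if (ok && cost < best_cost) { best_cost <- cost; best <- pairs }
  }
  list(pairs = best, cost = best_cost)
}

# quick random ellipse for property tests
random_zone <- function(kind = "radial") {
  e <- runif(1, 4.5, 9)
  th <- runif(1, 0, 2 * pi)
  make_zones(e * cos(th), e * sin(th))[[kind]]
}

# compact session plan for statistically scaled-down tests: balanced
# arrangement x numerosity, one block, n_reps trials per cell, no controls
mini_plan <- function(nums = c(36, 42), n_reps = 10,
                      polarity = "uniform_dark", range = "small") {
  g <- expand.grid(true_numerosity = nums,
                   arrangement = c("radial", "tangential"),
                   rep = seq_len(n_reps), stringsAsFactors = FALSE)
  data.frame(block = 1L, trial = seq_len(nrow(g)),
             arrangement = g$arrangement, polarity_scheme = polarity,
             numerosity_range = range, percent_pairs = 50,
             true_numerosity = g$true_numerosity,
             block_mean = mean(nums), is_control = FALSE)
}

# plan with both polarities, for interaction / polarity-effect tests
mini_plan_pol <- function(nums = c(36, 42), n_reps = 6) {
  g <- expand.grid(true_numerosity = nums,
                   arrangement = c("radial", "tangential"),
                   polarity_scheme = c("uniform_dark", "mixed"),
                   rep = seq_len(n_reps), stringsAsFactors = FALSE)
  data.frame(block = 1L, trial = seq_len(nrow(g)),
             arrangement = g$arrangement, polarity_scheme = g$polarity_scheme,
             numerosity_range = "small", percent_pairs = 50,
             true_numerosity = g$true_numerosity,
             block_mean = mean(nums), is_control = FALSE)
}

# synthetic trial table for screening boundary tests
make_screening_table <- function(n_main = 300, n_ctrl = 30, n_invalid = 0,
                                 n_ctrl_wrong = 0, participant = "P1") {
  tn <- c(rep(40L, n_main), rep(3L, n_ctrl))
  resp <- tn
  is_ctrl <- c(rep(FALSE, n_main), rep(TRUE, n_ctrl))
  if (n_ctrl_wrong > 0) resp[n_main + seq_len(n_ctrl_wrong)] <- 2L
  invalid <- rep(FALSE, n_main + n_ctrl)
  if (n_invalid > 0) invalid[seq_len(n_invalid)] <- TRUE
  resp[invalid] <- NA_integer_
  data.frame(participant = participant, experiment = "1a", block = 1L,
             trial = seq_along(tn), arrangement = "radial",
             polarity_scheme = "uniform_dark",
             numerosity_range = ifelse(is_ctrl, "control", "small"),
             percent_pairs = 50, true_numerosity = tn, block_mean = 39,
             is_control = is_ctrl, response = resp, invalid = invalid)
}
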