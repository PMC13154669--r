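#' Configuration for the synthetic pellet-field generator
#'
#' Describes a rendered stereo-microscopy scene of a two-species pellet
#' suspension: a bluish background with a smooth illumination gradient,
#' large single-dark-core fungal pellets with a bright hyphal corona, small
#' single-core bacterial pellets, irregular multi-core bacterial
#' aggregates, one-sided bright lateral shadows, and additive sensor
#' noise. All randomness is fixed by `seed`.
#'
#' @param width_px,height_px Image size in pixels.
#' @param pixel_size_um Micrometres per pixel.
#' @param n_an,n_sc,n_agg Number of fungal pellets, single bacterial
#'   pellets, and bacterial aggregates.
#' @param an_diameter_um,sc_diameter_um Diameter ranges (um) for the two
#'   species.
#' @param an_core_frac,sc_core_frac Core-area fraction ranges.
#' @param agg_subunits Range of subunit counts per aggregate.
#' @param agg_diameter_um Range of the total equivalent diameter of an
#'   aggregate (um); subunit sizes are derived from it so that fused
#'   aggregates stay within the bacterial size regime.
#' @param background_rgb Background colour (8-bit RGB, bluish).
#' @param halo_brightness Peak additive brightness of the hyphal corona.
#' @param illumination_amplitude Relative amplitude of the smooth
#'   multiplicative illumination gradient.
#' @param shadow_direction_deg,shadow_strength Direction and peak additive
#'   brightness of the one-sided lateral shadow crescents.
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (8-bit units).
#' @param overlap_prob Probability that a bacterial pellet is placed
#'   touching an already-placed pellet.
#' @param seed Integer seed fixing all randomness.
#' @return A `synth_config` list.
#' @export
synth_config <- function(width_px = 1200, height_px = 1200,
                         pixel_size_um = 5,
                         n_an = 5, n_sc = 20, n_agg = 3,
                         an_diameter_um = c(600, 1500),
                         an_core_frac = c(0.05, 0.2),
                         sc_diameter_um = c(150, 350),
                         sc_core_frac = c(0.3, 0.6),
                         agg_subunits = c(2, 6),
                         agg_diameter_um = c(250, 380),
                         background_rgb = c(140, 150, 210),
                         halo_brightness = 70,
                         illumination_amplitude = 0.12,
                         shadow_direction_deg = 35,
                         shadow_strength = 55,
                         noise_sd = 3,
                         overlap_prob = 0.15,
                         seed = 1) {
  ordered_range <- function(r) length(r) == 2 && r[1] <= r[2] && r[1] > 0
  if (!ordered_range(an_diameter_um) || !ordered_range(sc_diameter_um) ||
      !ordered_range(agg_diameter_um))
    stopf("diameter ranges must be ordered positive pairs")
  if (any(c(n_an, n_sc, n_agg) < 0)) stopf("counts must be >= 0")
  structure(as.list(environment())[
    c("width_px", "height_px", "pixel_size_um", "n_an", "n_sc", "n_agg",
      "an_diameter_um", "an_core_frac", "sc_diameter_um", "sc_core_frac",
      "agg_subunits", "agg_diameter_um", "background_rgb",
      "halo_brightness", "illumination_amplitude", "shadow_direction_deg",
      "shadow_strength", "noise_sd", "overlap_prob", "seed")],
    class = "synth_config")
}

#' Named generator presets
#'
#' `"well_separated"` uses the default, late-cultivation morphology where
#' the two species differ clearly in size (fungal pellets 600-1500 um vs
#' bacterial 150-350 um). `"overlapping"` narrows the gap to probe the
#' early-cultivation regime where the species are morphologically similar
#' and classification is expected to degrade.
#'
#' @param preset Preset name.
#' @param ... Overrides passed to [synth_config()].
#' @return A `synth_config`.
#' @export
synth_preset <- function(preset = c("well_separated", "overlapping"), ...) {
  preset <- match.arg(preset)
  args <- list(...)
  if (preset == "overlapping") {
    defaults <- list(an_diameter_um = c(350, 700),
                     sc_diameter_um = c(200, 420),
                     an_core_frac = c(0.1, 0.3),
                     sc_core_frac = c(0.2, 0.5))
    args <- utils::modifyList(defaults, args)
  }
  do.call(synth_config, args)
}

# Species appearance (8-bit RGB). Bodies and cores are jointly dark in the
# red channel against the bluish background (so the whole pellet forms one
# dark layer for the red-channel thresholding), while the core/body
# contrast lives mainly in green/blue, i.e. in the luma used for core
# detection. The fungal body is brighter in luma than the bacterial body
# (lower hyphal density); cores are darkest.
SYNTH_COLORS <- list(
  an_body = c(70, 130, 165), an_core = c(60, 45, 60),
  sc_body = c(62, 95, 125), sc_core = c(52, 40, 55)
)

#' Render one synthetic pellet field with full ground truth
#'
#' @param config A [synth_config()].
#' @return List with `image` (a [calibrated_image()]) and `truth`: list
#'   holding `labels` (integer instance raster), `cores` (logical core
#'   raster), and `info` (tibble: `instance`, `class`, `diameter_um`,
#'   `n_subunits`, `row`, `col`). Ground truth reflects the geometry
#'   before noise is added.
#' @export
generate_field <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_local_seed(config$seed, render_field(config))
}

render_field <- function(cfg) {
  H <- cfg$height_px; W <- cfg$width_px; ps <- cfg$pixel_size_um

  R <- matrix(cfg$background_rgb[1], H, W)
  G <- matrix(cfg$background_rgb[2], H, W)
  B <- matrix(cfg$background_rgb[3], H, W)
  labels <- matrix(0L, H, W)
  cores <- matrix(FALSE, H, W)
  claim <- matrix(Inf, H, W)   # radial coordinate r/R of the owning pellet

  # --- plan particle geometry -------------------------------------------
  specs <- list()
  add_spec <- function(s) specs[[length(specs) + 1L]] <<- s
  for (i in seq_len(cfg$n_an)) {
    d <- runif(1, cfg$an_diameter_um[1], cfg$an_diameter_um[2])
    add_spec(list(class = "AN_pellet", diam_um = d, r_px = d / 2 / ps,
                  core_frac = runif(1, cfg$an_core_frac[1],
                                    cfg$an_core_frac[2])))
  }
  for (i in seq_len(cfg$n_agg)) {
    k <- sample(seq(cfg$agg_subunits[1], cfg$agg_subunits[2]), 1)
    d_agg <- runif(1, cfg$agg_diameter_um[1], cfg$agg_diameter_um[2])
    # subunit radius such that the fused chain has ~the target total area
    r_sub <- d_agg / (2 * sqrt(0.95 * k))
    ds <- r_sub * 2 * runif(k, 0.85, 1.15)
    add_spec(list(class = "SC_aggregate", subunit_r_px = ds / 2 / ps,
                  core_frac = runif(k, cfg$sc_core_frac[1],
                                    cfg$sc_core_frac[2])))
  }
  for (i in seq_len(cfg$n_sc)) {
    d <- runif(1, cfg$sc_diameter_um[1], cfg$sc_diameter_um[2])
    add_spec(list(class = "SC_pellet", diam_um = d, r_px = d / 2 / ps,
                  core_frac = runif(1, cfg$sc_core_frac[1],
                                    cfg$sc_core_frac[2])))
  }

  # --- place particles (bounded rejection sampling) ---------------------
  placed <- data.frame(row = numeric(), col = numeric(), r = numeric())
  eff_radius <- function(s) {
    if (s$class == "SC_aggregate")
      max(s$subunit_r_px) * (1 + 0.8 * (length(s$subunit_r_px) - 1)) / 1.4
    else s$r_px
  }
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    re <- eff_radius(s) * 1.45   # corona + shadow margin
    if (2 * re >= min(H, W))
      stopf("placement error: particle %d (effective radius %.0f px) does not fit the %d x %d field",
            i, re, H, W)
    ok <- FALSE
    touch <- s$class == "SC_pellet" && nrow(placed) > 0 &&
      runif(1) < cfg$overlap_prob
    for (try in 1:300) {
      if (touch) {
        j <- sample(nrow(placed), 1)
        ang <- runif(1, 0, 2 * pi)
        dist <- 0.95 * (placed$r[j] + s$r_px)
        cr <- placed$row[j] + dist * sin(ang)
        cc <- placed$col[j] + dist * cos(ang)
        if (cr < re || cr > H - re || cc < re || cc > W - re) next
        others <- placed[-j, , drop = FALSE]
        if (nrow(others) && any(sqrt((others$row - cr)^2 +
                                     (others$col - cc)^2) <
                                1.05 * (others$r + s$r_px))) next
        ok <- TRUE; break
      } else {
        cr <- runif(1, re, H - re)
        cc <- runif(1, re, W - re)
        if (nrow(placed) && any(sqrt((placed$row - cr)^2 +
                                     (placed$col - cc)^2) <
                                1.1 * (placed$r + eff_radius(s)))) next
        ok <- TRUE; break
      }
    }
    if (!ok)
      stopf("placement error: could not place particle %d of %d after bounded retries (field too crowded)",
            i, length(specs))
    specs[[i]]$row <- cr; specs[[i]]$col <- cc
    placed <- rbind(placed,
                    data.frame(row = cr, col = cc, r = eff_radius(s)))
  }

  # --- rasterise ---------------------------------------------------------
  state <- list(R = R, G = G, B = B, labels = labels, cores = cores,
                claim = claim)
  info <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    if (s$class == "SC_aggregate") {
      sub <- plan_aggregate(s)
      for (u in seq_along(sub$r)) {
        state <- draw_pellet(state, sub$row[u], sub$col[u], sub$r[u],
                             sub$core_frac[u], s$class, i, cfg,
                             center_core = TRUE,
                             aspect = runif(1, 1.2, 1.7),
                             orient = runif(1, 0, pi),
                             roughness = 0.08)
      }
      # fuse the subunit cores with dark hyphal-dense necks so the
      # aggregate centre images as one connected dark region
      if (length(sub$r) > 1) for (u in 2:length(sub$r)) {
        w <- 0.45 * min(sub$r[u - 1], sub$r[u]) *
          sqrt(min(sub$core_frac[(u - 1):u]))
        state <- draw_core_bridge(state,
                                  c(sub$row[u - 1], sub$col[u - 1]),
                                  c(sub$row[u], sub$col[u]), w, i)
      }
      area_px <- sum(state$labels == i)
      info[[i]] <- tibble::tibble(
        instance = i, class = s$class,
        diameter_um = 2 * sqrt(area_px * ps^2 / pi),
        n_subunits = length(sub$r),
        row = mean(sub$row), col = mean(sub$col))
    } else {
      state <- draw_pellet(state, s$row, s$col, s$r_px, s$core_frac,
                           s$class, i, cfg)
      info[[i]] <- tibble::tibble(
        instance = i, class = s$class, diameter_um = s$diam_um,
        n_subunits = 1L, row = s$row, col = s$col)
    }
  }
  R <- state$R; G <- state$G; B <- state$B
  labels <- state$labels; cores <- state$cores

  # --- illumination gradient, noise -------------------------------------
  ang <- runif(1, 0, 2 * pi)
  gr <- outer((seq_len(H) - H / 2) / H, rep(1, W)) * sin(ang) +
    outer(rep(1, H), (seq_len(W) - W / 2) / W) * cos(ang)
  shade <- 1 + cfg$illumination_amplitude * gr
  R <- R * shade; G <- G * shade; B <- B * shade
  if (cfg$noise_sd > 0) {
    R <- R + rnorm(H * W, 0, cfg$noise_sd)
    G <- G + rnorm(H * W, 0, cfg$noise_sd)
    B <- B + rnorm(H * W, 0, cfg$noise_sd)
  }
  px <- array(0, dim = c(H, W, 3L))
  px[, , 1] <- round(pmin(255, pmax(0, R)))
  px[, , 2] <- round(pmin(255, pmax(0, G)))
  px[, , 3] <- round(pmin(255, pmax(0, B)))

  list(
    image = calibrated_image(px, ps,
                             source_id = sprintf("synth_seed%d", cfg$seed)),
    truth = list(labels = labels, cores = cores,
                 info = dplyr::bind_rows(info))
  )
}

# Bent-chain layout for an aggregate: consecutive subunits overlap (centre
# distance 0.8 of the radius sum) along an extended, wiggly path (moderate
# alternating turns so the chain neither folds onto itself nor stays
# straight), giving the irregular multi-lobed outline of fused bacterial
# pellets.
plan_aggregate <- function(s) {
  r <- s$subunit_r_px
  k <- length(r)
  rows <- cols <- numeric(k)
  rows[1] <- s$row; cols[1] <- s$col
  theta <- runif(1, 0, 2 * pi)
  bend <- sample(c(-1, 1), 1)
  if (k > 1) for (u in 2:k) {
    theta <- theta + bend * runif(1, 0.6, 1.3)
    bend <- -bend
    step <- 0.8 * (r[u - 1] + r[u])
    rows[u] <- rows[u - 1] + step * sin(theta)
    cols[u] <- cols[u - 1] + step * cos(theta)
  }
  rows <- rows - mean(rows) + s$row
  cols <- cols - mean(cols) + s$col
  list(row = rows, col = cols, r = r, core_frac = s$core_frac)
}

# Rasterise a single circular pellet body with dark elliptical core,
# radially decaying bright corona with angular hyphal texture, and a
# one-sided bright shadow crescent, into the running scene state. Body
# pixels are claimed by relative radial distance r/R, so overlapping
# pellets partition deterministically along the weighted bisector; corona
# and shadow are additive and only fall on unclaimed (background) pixels.
draw_pellet <- function(state, cr, cc, r_px, core_frac, class, inst, cfg,
                        center_core = FALSE, aspect = 1, orient = 0,
                        roughness = 0) {
  H <- nrow(state$labels); W <- ncol(state$labels)
  pad <- ceiling(r_px * max(1.6, 1.2 * sqrt(aspect) + 0.4)) + 2
  r0 <- max(1, floor(cr - pad)); r1 <- min(H, ceiling(cr + pad))
  c0 <- max(1, floor(cc - pad)); c1 <- min(W, ceiling(cc + pad))
  ys <- r0:r1; xs <- c0:c1
  dy <- outer(ys - cr, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cc)
  theta <- atan2(dy, dx)
  # elliptical body metric (area-preserving); rel = 1 on the outline
  sa <- sqrt(aspect)
  uy <- dy * cos(orient) + dx * sin(orient)
  ux <- -dy * sin(orient) + dx * cos(orient)
  rel <- sqrt((uy / sa)^2 + (ux * sa)^2) / r_px
  if (roughness > 0) {
    nh_b <- sample(3:6, 1)
    amp_b <- runif(nh_b, 0, 1)
    ph_b <- runif(nh_b, 0, 2 * pi)
    bump <- Reduce(`+`, lapply(seq_len(nh_b), function(h)
      amp_b[h] * sin((h + 1) * theta + ph_b[h]))) / max(sum(amp_b), 1e-9)
    rel <- rel / (1 + roughness * bump)
  }
  rr <- rel * r_px

  body <- rel <= 1
  colset <- if (class == "AN_pellet")
    list(body = SYNTH_COLORS$an_body, core = SYNTH_COLORS$an_core)
  else
    list(body = SYNTH_COLORS$sc_body, core = SYNTH_COLORS$sc_core)

  if (center_core) {
    # core concentric with the body, same metric (aggregate subunits)
    core <- rel <= sqrt(core_frac)
  } else {
    # elliptical core, slightly offset and rotated
    q <- runif(1, 0.7, 1)
    rot <- runif(1, 0, pi)
    a <- r_px * sqrt(core_frac / q); b <- r_px * sqrt(core_frac * q)
    off <- runif(2, -0.15, 0.15) * r_px
    u <- (dy - off[1]) * cos(rot) + (dx - off[2]) * sin(rot)
    v <- -(dy - off[1]) * sin(rot) + (dx - off[2]) * cos(rot)
    core <- body & ((u / b)^2 + (v / a)^2 <= 1)
  }

  # angular hyphal texture of the corona (band-limited)
  nh <- sample(4:7, 1)
  amp <- runif(nh, 0, 1) / seq_len(nh)
  phase <- runif(nh, 0, 2 * pi)
  tex <- 0.75 + 0.25 * Reduce(`+`, lapply(seq_len(nh), function(h)
    amp[h] * sin(h * theta + phase[h]))) / max(sum(amp), 1e-9)

  corona_zone <- rel > 1 & rel <= 1.45
  halo <- cfg$halo_brightness * exp(-(rr - r_px) / (0.12 * r_px)) * tex
  dir <- cfg$shadow_direction_deg * pi / 180
  shadow <- cfg$shadow_strength * exp(-(rr - r_px) / (0.18 * r_px)) *
    pmax(0, cos(theta - dir))^2
  add <- matrix(0, length(ys), length(xs))
  add[corona_zone] <- halo[corona_zone] + shadow[corona_zone]

  # mild radial brightening of the body toward its rim
  body_gain <- 1 + 0.10 * rel^2

  claim_win <- state$claim[ys, xs]
  take <- body & rel < claim_win      # pixels this pellet now owns
  free <- add > 0 & !body & claim_win > 1   # background-only additive zone

  lab <- state$labels[ys, xs]; lab[take] <- inst
  state$labels[ys, xs] <- lab
  co <- state$cores[ys, xs]
  co[take] <- core[take]
  state$cores[ys, xs] <- co
  cl <- state$claim[ys, xs]; cl[take] <- rel[take]
  state$claim[ys, xs] <- cl
  for (idx in 1:3) {
    nm <- c("R", "G", "B")[idx]
    win <- state[[nm]][ys, xs]
    val <- colset$body[idx] * body_gain
    val[core] <- colset$core[idx]
    win[take] <- val[take]
    win[free] <- win[free] + add[free]
    state[[nm]][ys, xs] <- win
  }
  state
}

# Paint a dark capsule (segment of half-width w) between two subunit
# centres of aggregate `inst`, marking it as core; restricted to pixels
# already owned by that instance.
draw_core_bridge <- function(state, p1, p2, w, inst) {
  r0 <- max(1, floor(min(p1[1], p2[1]) - w - 1))
  r1 <- min(nrow(state$labels), ceiling(max(p1[1], p2[1]) + w + 1))
  c0 <- max(1, floor(min(p1[2], p2[2]) - w - 1))
  c1 <- min(ncol(state$labels), ceiling(max(p1[2], p2[2]) + w + 1))
  ys <- r0:r1; xs <- c0:c1
  dy <- outer(ys - p1[1], rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - p1[2])
  vy <- p2[1] - p1[1]; vx <- p2[2] - p1[2]
  len2 <- max(vy^2 + vx^2, 1e-9)
  t <- pmin(1, pmax(0, (dy * vy + dx * vx) / len2))
  dist <- sqrt((dy - t * vy)^2 + (dx - t * vx)^2)
  lab <- state$labels[ys, xs]
  sel <- dist <= w & lab == inst
  if (any(sel)) {
    co <- state$cores[ys, xs]; co[sel] <- TRUE
    state$cores[ys, xs] <- co
    for (idx in 1:3) {
      nm <- c("R", "G", "B")[idx]
      win <- state[[nm]][ys, xs]
      win[sel] <- SYNTH_COLORS$sc_core[idx]
      state[[nm]][ys, xs] <- win
    }
  }
  state
}

#' Generate a deterministic series of fields with a diameter schedule
#'
#' Emulates pellet growth over cultivation time: each timepoint scales the
#' configured diameter ranges by the schedule factor. Every timepoint uses
#' the base seed, so the same underlying population is re-rendered at the
#' scheduled sizes (paired growth of one population rather than fresh
#' populations per timepoint).
#'
#' @param config A [synth_config()].
#' @param schedule Numeric vector of non-decreasing diameter scale factors,
#'   one per timepoint.
#' @return List of [generate_field()] results, one per timepoint.
#' @export
generate_series <- function(config, schedule) {
  stopifnot(inherits(config, "synth_config"))
  if (is.unsorted(schedule))
    stopf("diameter schedule must be non-decreasing")
  lapply(seq_along(schedule), function(i) {
    cfg <- config
    cfg$an_diameter_um <- config$an_diameter_um * schedule[i]
    cfg$sc_diameter_um <- config$sc_diameter_um * schedule[i]
    cfg$agg_diameter_um <- config$agg_diameter_um * schedule[i]
    generate_field(cfg)
  })
}

#' Write a synthetic field to disk (image + 16-bit label TIFF + truth CSV)
#' @param field Result of [generate_field()].
#' @param image_path,labels_path,truth_csv_path Output paths.
#' @return `field`, invisibly.
#' @export
write_field <- function(field, image_path, labels_path, truth_csv_path) {
  save_image(field$image, image_path)
  write_label_mask(field$truth$labels, labels_path)
  write.csv(field$truth$info, truth_csv_path, row.names = FALSE)
  invisible(field)
}
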