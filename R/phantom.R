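# Seed-deterministic synthetic stroke phantoms.
#
# Each phantom slice emulates the structure of the acute-stroke perfusion
# benchmark this package targets: an elliptical "brain" region containing a
# dark infarct core surrounded by a penumbra ring (the segmentation target),
# rendered into several MRI-like channels with modality-dependent contrast,
# isotropic spacing and additive Gaussian noise, normalised to [-1, 1].

#' Configuration for the stroke-phantom generator
#'
#' @param n_cases number of phantom cases; the default 30 mirrors the size of
#'   the training cohort the method was designed around.
#' @param height,width slice size in pixels (at least 16).
#' @param n_channels number of modality channels; the default 6 emulates the
#'   DWI / CBV / Tmax / CBF / T2 / TTP input stack.
#' @param spacing_mm isotropic pixel spacing in millimetres (default 2).
#' @param core_radius_range min/max semi-axis of the elliptical infarct core,
#'   in pixels.
#' @param ring_width_range min/max width of the penumbra ring, in pixels.
#' @param noise_sd standard deviation of additive Gaussian intensity noise.
#' @param seed integer seed; together with the case index it fully determines
#'   every mask and intensity.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(n_cases = 30, height = 64, width = 64,
                           n_channels = 6, spacing_mm = 2.0,
                           core_radius_range = c(3, 7),
                           ring_width_range = c(2, 5),
                           noise_sd = 0.05, seed = 1) {
  stopifnot(n_cases >= 1, height >= 16, width >= 16, n_channels >= 1,
            spacing_mm > 0, noise_sd >= 0,
            length(core_radius_range) == 2, length(ring_width_range) == 2)
  if (core_radius_range[1] < 1 || ring_width_range[1] < 1) {
    stop("core_radius_range and ring_width_range minima must be >= 1")
  }
  if (core_radius_range[1] > core_radius_range[2] ||
      ring_width_range[1] > ring_width_range[2]) {
    stop("ranges must be (min, max) with min <= max")
  }
  structure(list(
    n_cases = as.integer(n_cases), height = as.integer(height),
    width = as.integer(width), n_channels = as.integer(n_channels),
    spacing_mm = spacing_mm, core_radius_range = core_radius_range,
    ring_width_range = ring_width_range, noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "phantom_config")
}

# Per-case seeds: distinct deterministic streams for geometry and rendering,
# kept below 2^31.
case_seed <- function(seed, case_index, what = c("geometry", "render")) {
  what <- match.arg(what)
  offset <- if (what == "geometry") 0L else 104729L
  as.integer((abs(as.numeric(seed)) %% 65521 * 20011 +
                case_index * 7919 + offset) %% 2147483647)
}

ellipse_mask <- function(H, W, cx, cy, a, b) {
  # (row - cx)^2/a^2 + (col - cy)^2/b^2 <= 1, vectorised on the pixel grid
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  ((rows - cx) / a)^2 + ((cols - cy) / b)^2 <= 1
}

dilate8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  padded <- matrix(0, H + 2, W + 2)
  padded[2:(H + 1), 2:(W + 1)] <- mask
  out <- matrix(0, H, W)
  for (di in -1:1) for (dj in -1:1) {
    out <- pmax(out, padded[(2 + di):(H + 1 + di), (2 + dj):(W + 1 + dj)])
  }
  out
}

#' Draw the core / penumbra / brain geometry for one phantom case
#'
#' The infarct core is a filled ellipse; the penumbra is the surrounding
#' annulus between the core ellipse and the same ellipse expanded by the ring
#' width, augmented with the core's immediate 8-neighbourhood so the penumbra
#' always fully encloses the core. Both lie strictly inside an elliptical
#' brain mask. Deterministic given `(config$seed, case_index)`.
#'
#' @param config a [phantom_config()].
#' @param case_index 0-based case index, `< config$n_cases`.
#' @return List with binary matrices `core_mask`, `penumbra_mask`,
#'   `brain_mask` and a `params` attribute carrying the sampled ellipse
#'   parameters (centre, semi-axes, ring width).
#' @export
make_lesion_geometry <- function(config, case_index) {
  stopifnot(inherits(config, "phantom_config"),
            case_index >= 0, case_index < config$n_cases)
  H <- config$height; W <- config$width
  ab <- H / 2 - 2   # brain semi-axis along rows
  bb <- W / 2 - 2   # brain semi-axis along cols
  max_outer <- config$core_radius_range[2] + config$ring_width_range[2]
  if (max_outer + 2 >= min(ab, bb)) {
    stop("configured core radius + ring width (", max_outer,
         " px) cannot fit inside the ", H, "x", W,
         " image with a 2-pixel margin")
  }
  set.seed(case_seed(config$seed, case_index, "geometry"))
  a_c <- stats::runif(1, config$core_radius_range[1], config$core_radius_range[2])
  b_c <- stats::runif(1, config$core_radius_range[1], config$core_radius_range[2])
  w <- stats::runif(1, config$ring_width_range[1], config$ring_width_range[2])
  a_o <- a_c + w
  b_o <- b_c + w
  ctr_r <- (H + 1) / 2
  ctr_c <- (W + 1) / 2
  # sample the lesion centre so the outer ellipse stays >= 2 px inside brain
  slack_r <- ab - a_o - 2
  slack_c <- bb - b_o - 2
  theta <- stats::runif(1, 0, 2 * pi)
  rad <- sqrt(stats::runif(1))
  cx <- ctr_r + rad * slack_r * cos(theta)
  cy <- ctr_c + rad * slack_c * sin(theta)

  brain <- ellipse_mask(H, W, ctr_r, ctr_c, ab, bb) * 1
  core <- ellipse_mask(H, W, cx, cy, a_c, b_c) * brain
  outer <- ellipse_mask(H, W, cx, cy, a_o, b_o) * 1
  penumbra <- pmax(outer, dilate8(core)) * (1 - core) * brain
  geom <- list(core_mask = core, penumbra_mask = penumbra, brain_mask = brain)
  attr(geom, "params") <- list(cx = cx, cy = cy, a_core = a_c, b_core = b_c,
                               ring_width = w, a_brain = ab, b_brain = bb,
                               ctr_r = ctr_r, ctr_c = ctr_c)
  geom
}

# Region mean intensities per channel. Channel 1 plays the diffusion role
# (darkest core); the "perfusion" channel (3rd, or last if fewer) carries the
# strongest penumbra contrast. All means sit inside [-1, 1] so that with zero
# noise no clipping occurs.
region_means <- function(n_channels) {
  perf <- min(3L, n_channels)
  t(vapply(seq_len(n_channels), function(ch) {
    brain <- -0.1 + 0.05 * ((ch - 1) %% 3)
    if (ch == 1) {
      c(bg = -0.95, brain = brain, core = -0.75, pen = -0.30)
    } else if (ch == perf) {
      c(bg = -0.95, brain = brain, core = 0.40, pen = 0.80)
    } else {
      c(bg = -0.95, brain = brain, core = -0.40 + 0.1 * sin(ch),
        pen = 0.25 + 0.1 * cos(ch))
    }
  }, numeric(4)))
}

#' Render a multi-modal intensity slice from a lesion geometry
#'
#' Assigns each channel distinct mean intensities to background, brain, core
#' and penumbra (core darkest in channel 1; penumbra contrast strongest in
#' the perfusion channel), adds Gaussian noise with `config$noise_sd` and
#' clips to `[-1, 1]` — the output range of the reconstruction branch's Tanh.
#' Deterministic given `(config$seed, case_index)`.
#'
#' @inheritParams make_lesion_geometry
#' @param geometry result of [make_lesion_geometry()] with matching dims.
#' @return A `multimodal_slice`: list with `values` (C x H x W array),
#'   `spacing_mm`, `case_id`.
#' @export
render_modalities <- function(geometry, config, case_index) {
  H <- config$height; W <- config$width; C <- config$n_channels
  stopifnot(all(dim(geometry$core_mask) == c(H, W)))
  mu <- region_means(C)
  core <- geometry$core_mask
  pen <- geometry$penumbra_mask
  brain <- geometry$brain_mask * (1 - core) * (1 - pen)
  bg <- 1 - geometry$brain_mask
  set.seed(case_seed(config$seed, case_index, "render"))
  vals <- array(0, c(C, H, W))
  for (ch in seq_len(C)) {
    plane <- mu[ch, "bg"] * bg + mu[ch, "brain"] * brain +
      mu[ch, "core"] * core + mu[ch, "pen"] * pen
    if (config$noise_sd > 0) {
      plane <- plane + stats::rnorm(H * W, sd = config$noise_sd)
    }
    vals[ch, , ] <- pmin(pmax(plane, -1), 1)
  }
  new_multimodal_slice(vals, config$spacing_mm,
                       sprintf("case_%03d", case_index))
}

new_multimodal_slice <- function(values, spacing_mm, case_id) {
  stopifnot(length(dim(values)) == 3, all(is.finite(values)), spacing_mm > 0)
  structure(list(values = values, spacing_mm = spacing_mm, case_id = case_id),
            class = "multimodal_slice")
}

#' Generate a full phantom dataset
#'
#' One record per case: the rendered multi-modal slice plus the binary
#' penumbra mask (the segmentation target). Roles are unset (`NA`) until
#' [split_dataset()] assigns them. Calling twice with the same config yields
#' identical datasets.
#'
#' @param config a [phantom_config()].
#' @return List of `sample_record`s: each has `case_id`, `image`
#'   (`multimodal_slice`), `mask` (binary H x W matrix), `role`, `spacing_mm`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  lapply(seq_len(config$n_cases) - 1L, function(i) {
    geom <- make_lesion_geometry(config, i)
    img <- render_modalities(geom, config, i)
    structure(list(case_id = img$case_id, image = img,
                   mask = geom$penumbra_mask, role = NA_character_,
                   spacing_mm = config$spacing_mm),
              class = "sample_record")
  })
}

round_half_up <- function(x) floor(x + 0.5)

#' Partition records into labeled / validation / pseudo-unlabeled sets
#'
#' The labeled count is `round_half_up(label_fraction * n)`, so with 30
#' records the fractions 0.1 / 0.2 / 0.5 / 0.8 / 1.0 yield exactly
#' 3 / 6 / 15 / 24 / 30 labeled samples. A fraction `validation_split` of the
#' labeled set is carved out for validation. Every training record — labeled
#' or not, but excluding validation — also appears in the pseudo-unlabeled
#' pool feeding the reconstruction branch: each labeled sample is reused with
#' its label withheld. Selection is a seeded sample-level permutation.
#'
#' @param records list of `sample_record`s (the training pool).
#' @param label_fraction fraction in `[0, 1]` of records whose labels are used.
#' @param validation_split fraction in `[0, 1)` of the labeled set reassigned
#'   to validation.
#' @param seed integer seed for the permutation.
#' @return A `dataset_split`: list with `labeled`, `validation`,
#'   `pseudo_unlabeled` record lists.
#' @export
split_dataset <- function(records, label_fraction, validation_split = 0,
                          seed = 1) {
  n <- length(records)
  stopifnot(n >= 1, label_fraction >= 0, label_fraction <= 1,
            validation_split >= 0, validation_split < 1)
  n_lab <- round_half_up(label_fraction * n)
  if (label_fraction > 0 && n_lab == 0) {
    stop("label_fraction ", label_fraction, " of ", n,
         " records yields 0 labeled samples; provide more records")
  }
  set.seed(as.integer(seed) %% 2147483647L)
  perm <- sample.int(n)
  lab_idx <- perm[seq_len(n_lab)]
  n_val <- round_half_up(validation_split * n_lab)
  val_idx <- lab_idx[seq_len(n_val)]
  lab_idx <- setdiff(lab_idx, val_idx)
  set_role <- function(idx, role) {
    lapply(records[idx], function(r) { r$role <- role; r })
  }
  pseudo_idx <- setdiff(seq_len(n), val_idx)
  structure(list(
    labeled = set_role(lab_idx, "labeled"),
    validation = set_role(val_idx, "validation"),
    pseudo_unlabeled = set_role(pseudo_idx, "pseudo_unlabeled"),
    n_records = n, label_fraction = label_fraction,
    validation_split = validation_split, seed = as.integer(seed)
  ), class = "dataset_split")
}
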