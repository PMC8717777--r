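test_that("lesion geometry is seed-deterministic and well-formed", {
  cfg <- tiny_phantom_config(seed = 7)
  g1 <- make_lesion_geometry(cfg, 0)
  g2 <- make_lesion_geometry(cfg, 0)
  expect_identical(g1$core_mask, g2$core_mask)
  expect_identical(g1$penumbra_mask, g2$penumbra_mask)
  # disjointness by construction
  expect_equal(sum(g1$core_mask * g1$penumbra_mask), 0)
  # lesion inside brain
  expect_true(all(g1$core_mask + g1$penumbra_mask <= g1$brain_mask + 1e-12))
})

test_that("penumbra pixel count matches a brute-force rasterization oracle", {
  cfg <- tiny_phantom_config(seed = 7)
  g <- make_lesion_geometry(cfg, 0)
  p <- attr(g, "params")
  H <- cfg$height; W <- cfg$width
  in_ellipse <- function(i, j, a, b) {
    ((i - p$cx) / a)^2 + ((j - p$cy) / b)^2 <= 1
  }
  core <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (in_ellipse(i, j, p$a_core, p$b_core)) core[i, j] <- 1
  }
  count <- 0
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      if (core[i, j] == 1) next
      outer_hit <- in_ellipse(i, j, p$a_core + p$ring_width,
                              p$b_core + p$ring_width)
      near_core <- FALSE
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W && core[ii, jj] == 1) {
          near_core <- TRUE
        }
      }
      if (outer_hit || near_core) count <- count + 1
    }
  }
  expect_equal(sum(g$penumbra_mask), count)
})

test_that("geometry invariants hold across many random configurations", {
  set.seed(99)
  for (k in 1:100) {
    cr <- sort(runif(2, 1.5, 6))
    rw <- sort(runif(2, 1, 4))
    cfg <- phantom_config(n_cases = 3, height = 32, width = 32, n_channels = 2,
                          core_radius_range = cr, ring_width_range = rw,
                          noise_sd = 0, seed = k)
    g <- make_lesion_geometry(cfg, k %% 3)
    core <- g$core_mask; pen <- g$penumbra_mask
    expect_equal(sum(core * pen), 0)
    expect_true(all(core + pen <= g$brain_mask + 1e-12))
    # every core boundary pixel touches penumbra (8-adjacency)
    surf <- extract_surface(core)$points
    for (r in seq_len(nrow(surf))) {
      i <- surf[r, 1]; j <- surf[r, 2]
      nb <- pen[max(1, i - 1):min(32, i + 1), max(1, j - 1):min(32, j + 1)]
      expect_gt(sum(nb), 0)
    }
  }
})

test_that("oversized lesions are rejected with a margin error", {
  cfg <- phantom_config(n_cases = 2, height = 32, width = 32,
                        core_radius_range = c(10, 12),
                        ring_width_range = c(4, 6), seed = 1)
  expect_error(make_lesion_geometry(cfg, 0), "margin")
})

test_that("rendered modalities honour region contrast and value range", {
  cfg <- tiny_phantom_config(noise_sd = 0)
  g <- make_lesion_geometry(cfg, 1)
  img <- render_modalities(g, cfg, 1)
  expect_equal(dim(img$values), c(3, 32, 32))
  core_idx <- which(g$core_mask == 1)
  brain_only <- which(g$brain_mask == 1 & g$core_mask == 0 &
                        g$penumbra_mask == 0)
  for (ch in 1:3) {
    plane <- img$values[ch, , ]
    # zero noise -> exactly constant within each region
    expect_equal(stats::var(plane[core_idx]), 0)
    expect_equal(stats::var(plane[brain_only]), 0)
  }
  # diffusion-like channel: core darker than surrounding brain tissue
  expect_lt(mean(img$values[1, , ][core_idx]),
            mean(img$values[1, , ][brain_only]))
  # normalization contract holds even for large noise
  cfg_noisy <- tiny_phantom_config(noise_sd = 2)
  img_noisy <- render_modalities(make_lesion_geometry(cfg_noisy, 1),
                                 cfg_noisy, 1)
  expect_gte(min(img_noisy$values), -1)
  expect_lte(max(img_noisy$values), 1)
})

test_that("generate_dataset yields unique, reproducible, lesion-bearing records", {
  cfg <- tiny_phantom_config(n_cases = 6)
  ds1 <- generate_dataset(cfg)
  ds2 <- generate_dataset(cfg)
  expect_length(ds1, 6)
  ids <- vapply(ds1, function(r) r$case_id, character(1))
  expect_equal(anyDuplicated(ids), 0L)
  expect_identical(ds1, ds2)
  for (r in ds1) {
    expect_gte(sum(r$mask), 1)
    expect_gte(min(r$image$values), -1)
    expect_lte(max(r$image$values), 1)
  }
})

test_that("split arithmetic reproduces the 30-sample fraction counts", {
  ds <- tiny_dataset(n_cases = 30)
  expected <- c("0.1" = 3, "0.2" = 6, "0.5" = 15, "0.8" = 24, "1" = 30)
  for (f in names(expected)) {
    sp <- split_dataset(ds, as.numeric(f), validation_split = 0, seed = 1)
    expect_length(sp$labeled, expected[[f]])
  }
})

test_that("split partitions are disjoint and pseudo-unlabeled covers training", {
  ds <- tiny_dataset(n_cases = 30)
  sp <- split_dataset(ds, 0.8, validation_split = 0.2, seed = 3)
  ids <- function(x) vapply(x, function(r) r$case_id, character(1))
  expect_length(sp$validation, 5)          # round-half-up of 0.2 * 24
  expect_length(sp$labeled, 19)
  expect_length(intersect(ids(sp$labeled), ids(sp$validation)), 0)
  # pseudo-unlabeled = everything except validation, including labeled images
  expect_setequal(ids(sp$pseudo_unlabeled),
                  setdiff(ids(ds), ids(sp$validation)))
  expect_true(all(ids(sp$labeled) %in% ids(sp$pseudo_unlabeled)))
  # boundary: all labeled, no validation
  sp_full <- split_dataset(ds, 1.0, validation_split = 0, seed = 1)
  expect_length(sp_full$labeled, 30)
  expect_length(sp_full$pseudo_unlabeled, 30)
  # identical seeds give identical splits
  sp2 <- split_dataset(ds, 0.8, validation_split = 0.2, seed = 3)
  expect_identical(ids(sp$labeled), ids(sp2$labeled))
  # degenerate request
  expect_error(split_dataset(ds[1:2], 0.1, seed = 1), "0 labeled")
})
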