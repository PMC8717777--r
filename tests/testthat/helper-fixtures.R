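# Shared fixtures: tiny configurations that keep unit tests fast while still
# exercising every code path.

tiny_phantom_config <- function(n_cases = 6, seed = 7, noise_sd = 0.05) {
  phantom_config(n_cases = n_cases, height = 32, width = 32, n_channels = 3,
                 spacing_mm = 2, core_radius_range = c(2, 4),
                 ring_width_range = c(2, 3), noise_sd = noise_sd, seed = seed)
}

tiny_net_config <- function(...) {
  args <- list(in_channels = 3, height = 32, width = 32, base_width = 4,
               n_stages = 3, blocks_per_stage = 1, fc_width = 16)
  args[names(list(...))] <- list(...)
  do.call(network_config, args)
}

tiny_train_config <- function(seed = 1, lam = 0.2, seg_epochs = 3,
                              recon_epochs = 1, ...) {
  train_config(
    recon = list(epochs = recon_epochs, lr = 1e-3, batch = 3),
    seg = list(epochs = seg_epochs, lr = 1e-3, batch = 3),
    network = list(base_width = 4, n_stages = 3, blocks_per_stage = 1,
                   fc_width = 16),
    lam = lam, validation_split = 0.25, seed = seed, ...)
}

tiny_dataset <- function(n_cases = 12, seed = 7) {
  generate_dataset(tiny_phantom_config(n_cases = n_cases, seed = seed))
}

# A random blob mask guaranteed non-empty: filled ellipse plus salt pixels.
random_blob_mask <- function(H = 32, W = 32) {
  cx <- runif(1, 8, H - 8)
  cy <- runif(1, 8, W - 8)
  a <- runif(1, 2, 6)
  b <- runif(1, 2, 6)
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  m <- (((rows - cx) / a)^2 + ((cols - cy) / b)^2 <= 1) * 1
  salt <- matrix(runif(H * W) < 0.01, H, W)
  m <- pmax(m, salt * 1)
  if (sum(m) == 0) m[H %/% 2, W %/% 2] <- 1
  m
}

# Brute-force surface-distance oracle: plain double loops over the same
# 8-connectivity boundary definition (border = background).
oracle_surface_points <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pts <- NULL
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      if (mask[i, j] != 1) next
      boundary <- i == 1 || i == H || j == 1 || j == W
      if (!boundary) {
        for (di in -1:1) for (dj in -1:1) {
          if (di == 0 && dj == 0) next
          if (mask[i + di, j + dj] == 0) boundary <- TRUE
        }
      }
      if (boundary) pts <- rbind(pts, c(i, j))
    }
  }
  pts
}

oracle_surface_metrics <- function(pred, truth, spacing = 1) {
  a <- oracle_surface_points(pred)
  b <- oracle_surface_points(truth)
  mins_ab <- apply(a, 1, function(p) {
    min(sqrt((b[, 1] - p[1])^2 + (b[, 2] - p[2])^2))
  })
  mins_ba <- apply(b, 1, function(p) {
    min(sqrt((a[, 1] - p[1])^2 + (a[, 2] - p[2])^2))
  })
  list(hd = max(max(mins_ab), max(mins_ba)) * spacing,
       assd = 0.5 * (mean(mins_ab) + mean(mins_ba)) * spacing)
}

# Set every convolution weight and bias of a parameter structure to zero.
zero_conv_weights <- function(block) {
  for (p in coseg:::collect_params(block)) {
    if (length(dim(p$value)) == 4 || is.matrix(p$value)) p$value[] <- 0
    # biases are plain vectors; zero those too, but keep BN gamma = 1
  }
  for (nm in c("conv1", "conv2", "conv3", "proj")) {
    if (!is.null(block[[nm]])) {
      block[[nm]]$w$value[] <- 0
      block[[nm]]$b$value[] <- 0
    }
  }
  if (!is.null(block$shortcut)) {
    block$shortcut$conv$w$value[] <- 0
    block$shortcut$conv$b$value[] <- 0
  }
  block
}

# Brute-force 2D convolution of a (c, h, w) feature with a (kh, kw, c, cout)
# kernel, stride 1, zero padding to preserve dims: independent of the
# package's im2col path.
oracle_conv <- function(feature, kernel) {
  ch <- dim(feature)[1]; H <- dim(feature)[2]; W <- dim(feature)[3]
  kh <- dim(kernel)[1]; kw <- dim(kernel)[2]; cout <- dim(kernel)[4]
  ph <- (kh - 1) %/% 2
  out <- array(0, c(cout, H, W))
  padded <- array(0, c(ch, H + 2 * ph, W + 2 * ph))
  padded[, ph + seq_len(H), ph + seq_len(W)] <- feature
  for (o in seq_len(cout)) {
    for (i in seq_len(H)) {
      for (j in seq_len(W)) {
        acc <- 0
        for (c in seq_len(ch)) {
          for (di in seq_len(kh)) {
            for (dj in seq_len(kw)) {
              acc <- acc + padded[c, i + di - 1, j + dj - 1] *
                kernel[di, dj, c, o]
            }
          }
        }
        out[o, i, j] <- acc
      }
    }
  }
  out
}
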