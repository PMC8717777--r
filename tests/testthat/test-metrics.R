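test_that("dice coefficient matches pixel-count cases", {
  m <- function(...) {
    out <- matrix(0, 4, 4)
    for (ij in list(...)) out[ij[1], ij[2]] <- 1
    out
  }
  a <- m(c(1, 1), c(2, 2))
  b <- m(c(1, 1), c(3, 3))
  expect_equal(dice_coefficient(a, a), 1.0)
  expect_equal(dice_coefficient(a, m(c(3, 3), c(4, 4))), 0.0)
  expect_equal(dice_coefficient(a, b), 0.5)      # overlap 1 of 2 vs 2
  both_empty <- dice_coefficient(matrix(0, 4, 4), matrix(0, 4, 4))
  expect_equal(as.numeric(both_empty), 1)
  expect_true(attr(both_empty, "both_empty"))
  expect_error(dice_coefficient(a, matrix(0, 3, 3)), "shapes differ")
  expect_error(dice_coefficient(a * 2, a), "binary")
})

test_that("surface extraction follows the 8-connectivity border convention", {
  one <- matrix(0, 8, 8)
  one[3, 5] <- 1
  s <- extract_surface(one)$points
  expect_equal(nrow(s), 1)
  expect_equal(as.numeric(s[1, ]), c(3, 5))
  # filled 4x4 square inside a larger image: the 12 perimeter pixels
  sq <- matrix(0, 10, 10)
  sq[4:7, 4:7] <- 1
  s2 <- extract_surface(sq)$points
  expect_equal(nrow(s2), 12)
  interior <- s2[, 1] %in% 5:6 & s2[, 2] %in% 5:6
  expect_false(any(interior))
  # full-image mask: only the border ring is surface
  full <- matrix(1, 6, 6)
  s3 <- extract_surface(full)$points
  expect_equal(nrow(s3), 20)
  expect_equal(nrow(extract_surface(matrix(0, 5, 5))$points), 0)
})

test_that("hausdorff distance is Euclidean and scales with spacing", {
  a <- matrix(0, 8, 8); a[1, 1] <- 1
  b <- matrix(0, 8, 8); b[4, 5] <- 1     # displacement (3, 4)
  expect_equal(hausdorff_distance(a, b, 1), 5)
  expect_equal(hausdorff_distance(a, b, 2), 10)
  expect_equal(hausdorff_distance(a, a, 2), 0)
  expect_warning(hd <- hausdorff_distance(matrix(0, 8, 8), b), "empty mask")
  expect_true(is.na(hd))
})

test_that("assd matches one-point and identical-mask cases", {
  a <- matrix(0, 8, 8); a[1, 1] <- 1
  b <- matrix(0, 8, 8); b[4, 5] <- 1
  expect_equal(assd(a, b, 1), 5)
  expect_equal(assd(a, a, 3), 0)
})

test_that("surface metrics agree with a brute-force pairwise oracle", {
  set.seed(11)
  for (k in 1:25) {
    p <- random_blob_mask()
    q <- random_blob_mask()
    o <- oracle_surface_metrics(p, q, spacing = 2)
    expect_equal(hausdorff_distance(p, q, 2), o$hd, tolerance = 1e-9)
    expect_equal(assd(p, q, 2), o$assd, tolerance = 1e-9)
  }
})

test_that("surface metrics are symmetric and translation equivariant", {
  set.seed(12)
  for (k in 1:20) {
    p <- random_blob_mask()
    q <- random_blob_mask()
    expect_equal(hausdorff_distance(p, q, 2), hausdorff_distance(q, p, 2))
    expect_equal(assd(p, q, 2), assd(q, p, 2))
  }
  # translate both masks by the same offset inside a larger canvas
  embed <- function(m, di, dj) {
    out <- matrix(0, 48, 48)
    out[di + seq_len(nrow(m)), dj + seq_len(ncol(m))] <- m
    out
  }
  p <- random_blob_mask(); q <- random_blob_mask()
  expect_equal(hausdorff_distance(embed(p, 2, 3), embed(q, 2, 3), 1),
               hausdorff_distance(embed(p, 9, 7), embed(q, 9, 7), 1))
  expect_equal(assd(embed(p, 2, 3), embed(q, 2, 3), 1),
               assd(embed(p, 9, 7), embed(q, 9, 7), 1))
})

test_that("evaluate_cases aggregates with empty-mask flagging", {
  set.seed(13)
  truths <- list(a = random_blob_mask(), b = random_blob_mask(),
                 c = random_blob_mask())
  # perfect predictions
  perfect <- evaluate_cases(truths, truths, 2)
  expect_equal(perfect$summary$mean, c(1, 0, 0))
  expect_equal(perfect$summary$sd, c(0, 0, 0))
  # one empty prediction: excluded from HD/ASSD, counted in DC
  preds <- truths
  preds$b <- matrix(0, 32, 32)
  rep <- evaluate_cases(preds, truths, 2)
  expect_true(rep$per_case$empty_flag[rep$per_case$case_id == "b"])
  expect_equal(rep$summary$n[rep$summary$metric == "hd_mm"], 2)
  expect_equal(rep$summary$n[rep$summary$metric == "dc"], 3)
  # sd equals an independent two-pass computation
  dcs <- rep$per_case$dc
  expect_equal(rep$summary$sd[1],
               sqrt(sum((dcs - mean(dcs))^2) / (length(dcs) - 1)))
  expect_error(evaluate_cases(preds[1:2], truths), "unmatched")
  # CSV export includes MEAN/SD rows
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(rep, path)
  tab <- read.csv(path)
  expect_equal(tail(tab$case_id, 2), c("MEAN", "SD"))
})
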