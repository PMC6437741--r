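test_that("superpixels split a two-tone image along the contrast edge", {
  img <- matrix(0, 20, 20); img[, 11:20] <- 255
  p <- compute_superpixels(img, 2)
  expect_gte(p$n_segments, 2)
  # every pixel at least 1 px away from the midline is grouped with its
  # own half (half-plane oracle, 1 px slack)
  left <- unique(as.vector(p$labels[, 1:9]))
  right <- unique(as.vector(p$labels[, 12:20]))
  expect_length(intersect(left, right), 0)
})

test_that("superpixel partitions satisfy their structural invariants", {
  set.seed(31)
  img <- matrix(runif(40 * 40, 0, 255), 40, 40)
  p <- compute_superpixels(img, 25)
  # full coverage with contiguous ids
  expect_true(all(sort(unique(as.vector(p$labels))) == seq_len(p$n_segments)))
  # adjacency symmetric and irreflexive
  expect_true(isSymmetric(p$adjacency))
  expect_false(any(diag(p$adjacency)))
  # every segment 4-connected
  for (l in seq_len(p$n_segments)) {
    comp <- EBImage::bwlabel((p$labels == l) + 0)
    expect_equal(max(comp), 1)
  }
  # centroids normalised
  expect_true(all(p$centroid >= 0 & p$centroid <= 1))
  # constant image: mean colours identical across segments
  pc <- compute_superpixels(matrix(100, 20, 20), 4)
  expect_lt(max(apply(pc$mean_color, 2, function(x) diff(range(x)))), 1e-9)
  expect_error(compute_superpixels(img, 1), "n_segments")
})

test_that("cellular-automata saliency ranks a bright compact segment highest", {
  # hand-built partition: 5x5 blocks on a 40x40 grid, one bright block
  labels <- matrix(0L, 40, 40)
  k <- 0L
  for (bi in 1:5) for (bj in 1:5) {
    k <- k + 1L
    labels[((bi - 1) * 8 + 1):(bi * 8), ((bj - 1) * 8 + 1):(bj * 8)] <- k
  }
  img <- matrix(30, 40, 40)
  img[17:24, 17:24] <- 220  # block id 13 (centre)
  g <- pmin(pmax(as.vector(img) / 255, 0), 1)
  lab <- lifoseg:::srgb_to_lab(cbind(g, g, g))
  part <- lifoseg:::build_partition(labels, lab, 40, 40)
  sal <- cellular_automata_saliency(part, n_steps = 20)
  expect_true(all(sal >= 0 & sal <= 1))
  seg_sal <- sapply(seq_len(part$n_segments),
                    function(l) sal[which(part$labels == l)[1]])
  expect_true(all(seg_sal[13] > seg_sal[-13]))
  # min-max normalisation hits both ends for a non-constant map
  expect_equal(min(sal), 0)
  expect_equal(max(sal), 1)
})

test_that("mirror-symmetric bright blobs receive equal saliency", {
  labels <- matrix(0L, 24, 48)
  k <- 0L
  for (bj in 1:8) for (bi in 1:4) {
    k <- k + 1L
    labels[((bi - 1) * 6 + 1):(bi * 6), ((bj - 1) * 6 + 1):(bj * 6)] <- k
  }
  img <- matrix(40, 24, 48)
  img[7:12, 7:12] <- 230    # blob A
  img[7:12, 37:42] <- 230   # mirrored blob B
  g <- pmin(pmax(as.vector(img) / 255, 0), 1)
  lab <- lifoseg:::srgb_to_lab(cbind(g, g, g))
  part <- lifoseg:::build_partition(labels, lab, 24, 48)
  sal <- cellular_automata_saliency(part)
  expect_equal(sal[9, 9], sal[9, 39], tolerance = 1e-9)
  # degenerate single-segment partition is rejected
  one <- lifoseg:::build_partition(matrix(1L, 24, 48), lab, 24, 48)
  expect_error(cellular_automata_saliency(one), "two superpixels")
})

test_that("the mean filter matches a windowed-mean loop oracle", {
  set.seed(41)
  m <- matrix(runif(25), 5, 5)
  expect_identical(smooth_saliency(m, 1), m)
  expect_equal(smooth_saliency(matrix(0.4, 6, 6), 3), matrix(0.4, 6, 6))
  expect_equal(smooth_saliency(m, 3), loop_box_sum(m, 3) / 9,
               tolerance = 1e-12)
  expect_error(smooth_saliency(m, 2), "odd")
})

test_that("Otsu threshold maximises between-class variance over 256 bins", {
  # perfectly bimodal map
  bi <- matrix(c(rep(0.1, 50), rep(0.9, 50)), 10, 10)
  th <- otsu_threshold(bi)
  expect_gt(th, 0.1); expect_lt(th, 0.9)
  expect_true(all((bi > th) == (bi > 0.5)))
  # exhaustive scan oracle on a random 64-pixel map
  set.seed(43)
  m <- matrix(runif(64), 8, 8)
  v <- as.vector(m)
  bins <- pmin(floor(v * 256) + 1, 256)          # 256-bin assignment
  mid <- (bins - 0.5) / 256                      # bin-midpoint values
  best <- -Inf; best_k <- NA
  for (k in 1:255) {
    lo <- bins <= k
    if (!any(lo) || all(lo)) next
    w0 <- mean(lo); w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(mid[lo]) - mean(mid[!lo]))^2
    if (bcv > best + 1e-15) { best <- bcv; best_k <- k }
  }
  expect_equal(otsu_threshold(m), best_k / 256)
  # independent cross-check: achieved objective matches EBImage's Otsu
  th_eb <- EBImage::otsu(EBImage::Image(t(m)), range = c(0, 1), levels = 256)
  split_var <- function(t) {
    lo <- v[v <= t]; hi <- v[v > t]
    length(lo) * length(hi) / 64^2 * (mean(lo) - mean(hi))^2
  }
  expect_equal(split_var(otsu_threshold(m)), split_var(th_eb),
               tolerance = 1e-3)
  # alternating two-level map splits exactly into its populations
  alt <- matrix(rep(c(0.2, 0.8), 32), 8, 8)
  ta <- otsu_threshold(alt)
  expect_identical((alt > ta) + 0, (alt > 0.5) + 0)
  expect_error(otsu_threshold(matrix(0.3, 5, 5)), "constant")
})

test_that("Otsu binarisation is invariant to min-max rescaling of the map", {
  set.seed(47)
  m <- matrix(runif(100, 0.2, 0.7), 10, 10)
  r <- (m - min(m)) / diff(range(m))
  expect_identical((m > otsu_threshold(m)) + 0, (r > otsu_threshold(r)) + 0)
})

test_that("largest connected object uses 8-connectivity and raster tie-break", {
  m <- matrix(0, 8, 8); m[2:4, 2:4] <- 1
  expect_identical(largest_connected_object(m), m + 0)
  # diagonal chain counts as one component under 8-connectivity
  dg <- matrix(0, 6, 6); dg[cbind(1:4, 1:4)] <- 1; dg[6, 1] <- 1
  keep <- largest_connected_object(dg)
  expect_equal(sum(keep), 4)
  expect_equal(keep[1, 1], 1)
  # 10-pixel blob beats a 3-pixel blob
  two <- matrix(0, 10, 10); two[2:6, 2:3] <- 1; two[9, 7:9] <- 1
  expect_equal(sum(largest_connected_object(two)), 10)
  # equal sizes: first blob in row-major raster order wins
  tie <- matrix(0, 9, 9)
  tie[5:6, 7:8] <- 1   # earlier row span? rows 5-6
  tie[7:8, 1:2] <- 1   # rows 7-8
  got <- largest_connected_object(tie)
  expect_equal(got[5, 7], 1)
  expect_equal(got[7, 1], 0)
  expect_error(largest_connected_object(matrix(0, 5, 5)), "foreground")
})

test_that("adaptive initial contour captures a synthetic bright disc", {
  fx <- generate_fixture(fixture_spec(
    shape = c(100, 100), disc = ellipse_params(49.5, 49.5, 0, 30, 24),
    blur_sigma = 1, noise_sigma = 2, inhomogeneity_amplitude = 0.1,
    seed = 5))
  init <- make_initial_contour(fx$image)
  expect_gte(overlap_ratio(fx$mask, init$mask), 0.75)
  # phi0 is positive exactly on the mask interior
  expect_identical((init$phi > 0) + 0, init$mask + 0)
  # centroid of the initial mask lies inside the true disc
  idx <- which(init$mask == 1, arr.ind = TRUE)
  cy <- mean(idx[, 1]) - 1; cx <- mean(idx[, 2]) - 1
  expect_gt(ellipse_levelset(fx$ellipse, dim(fx$image))[round(cy) + 1,
                                                        round(cx) + 1], 0)
})

test_that("degenerate images fall back to a centred circle with a message", {
  flat <- matrix(128, 64, 64)
  expect_message(init <- make_initial_contour(flat), "falling back")
  expect_equal(sum(init$mask), sum(lifoseg:::fallback_circle(c(64, 64))))
  idx <- which(init$mask == 1, arr.ind = TRUE)
  expect_equal(mean(idx[, 1]), 32.5, tolerance = 1)
})

test_that("initialisation is deterministic", {
  fx <- generate_fixture(fixture_spec(seed = 8))
  a <- make_initial_contour(fx$image)
  b <- make_initial_contour(fx$image)
  expect_identical(a$mask, b$mask)
  expect_identical(a$phi, b$phi)
})
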