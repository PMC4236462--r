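test_that("calibration region buffers occurrences and honours exclusions", {
  tpl <- mr_raster(matrix(0, 40, 40), xmin = 0, ymin = 25, cellsize = 0.5)
  occ <- data.frame(lat = 34.75, lon = 9.75)
  mask <- build_calibration_region(occ, tpl, buffer_km = 350)
  # area of a 350 km disc, allowing generous rasterization error at 0.5 deg
  lats <- raster_lats(mask)
  cell_km2 <- (111.32 * 0.5)^2 * cos(lats * pi / 180)
  area <- sum((mask$values == 1) * matrix(cell_km2, 40, 40), na.rm = TRUE)
  expect_lt(abs(area - pi * 350^2) / (pi * 350^2), 0.15)
  # containment: every occurrence cell is inside its own mask
  set.seed(2)
  occ2 <- data.frame(lat = runif(8, 27, 43), lon = runif(8, 1, 19))
  mask2 <- build_calibration_region(occ2, tpl, buffer_km = 300)
  rc <- raster_cell_of(mask2, occ2$lat, occ2$lon)
  expect_true(all(mask2$values[rc] == 1))
  # exclusion rectangle swallowing the buffer: refused
  expect_error(build_calibration_region(
    occ, tpl, buffer_km = 200,
    exclusions = list(list(lonmin = 0, lonmax = 20, latmin = 25,
                           latmax = 45))), "empty")
})

test_that("occurrence thinning is maximal and respects the minimum distance", {
  far <- data.frame(lat = c(30, 35, 40), lon = c(0, 10, 20))
  reps <- thin_occurrences(far, min_km = 50, n_replicates = 4, seed = 1)
  for (r in reps) expect_equal(nrow(r), 3)
  near <- data.frame(lat = c(35, 35.05), lon = c(10, 10.05))
  reps2 <- thin_occurrences(near, min_km = 50, n_replicates = 5, seed = 2)
  for (r in reps2) expect_equal(nrow(r), 1)
  # property: pairwise distances >= min_km and maximality
  set.seed(3)
  occ <- data.frame(lat = runif(40, 30, 36), lon = runif(40, 0, 8))
  reps3 <- thin_occurrences(occ, min_km = 80, n_replicates = 6, seed = 4)
  sizes <- sapply(reps3, nrow)
  for (r in reps3) {
    D <- great_circle_matrix(r)
    expect_true(all(D[upper.tri(D)] >= 80))
    kept <- as.integer(rownames(r))
    left <- setdiff(seq_len(40), kept)
    Dfull <- great_circle_matrix(occ)
    for (i in left) expect_true(any(Dfull[i, kept] < 80))
  }
  expect_gt(length(unique(sizes)) + sd(sizes), 0) # varies only via seed
  expect_error(thin_occurrences(occ, min_km = 0), "positive")
})

test_that("maxent satisfies its entropy-maximum and normalization laws", {
  set.seed(10)
  bg <- matrix(rnorm(400 * 2), 400, 2)
  # presences drawn uniformly from the background: coefficients -> 0
  pres <- bg[sample(400, 120), ]
  fit <- fit_maxent(pres, bg, n_boot_reps = 1, seed = 1)
  expect_lt(max(abs(fit$models[[1]]$eta)), 0.2)
  # raw output sums to one over the background
  raw <- maxent_predict(fit, bg, type = "raw")
  expect_lt(abs(sum(raw) - 1), 1e-8)
  # uniform prediction across background under the null fit
  expect_lt(diff(range(raw)) / mean(raw), 1.1)
})

test_that("constrained maxent matches the closed-form uniform solution", {
  # single binary feature; all presences at z = 1, half the background at 1
  bg <- matrix(c(rep(1, 50), rep(0, 50)), ncol = 1)
  pres <- matrix(rep(1, 20), ncol = 1)
  fit <- suppressWarnings(fit_maxent(pres, bg, reg_multiplier = 0,
                                     n_boot_reps = 1, seed = 1))
  raw <- as.vector(maxent_predict(fit, bg, type = "raw"))
  # limit: uniform over the constrained set, 2/|bg| per z=1 cell
  expect_equal(raw[1:50], rep(2 / 100, 50), tolerance = 1e-4)
  expect_lt(max(raw[51:100]), 1e-4)
})

test_that("maxent solution matches an independent convex optimizer", {
  set.seed(20)
  bg <- matrix(rnorm(60), 30, 2) # 30-cell toy problem
  pres <- bg[c(1:5, 11:15), ]
  fit <- fit_maxent(pres, bg, reg_multiplier = 0, n_boot_reps = 1, seed = 1)
  fb <- medrefugia:::build_features(bg)
  fp <- medrefugia:::build_features(pres, fb$means, fb$sds)
  negobj <- function(eta)
    -(mean(fp$Z %*% eta) - log(sum(exp(fb$Z %*% eta))))
  oracle <- optim(rep(0, 4), negobj, method = "BFGS",
                  control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(fit$models[[1]]$eta, oracle$par, tolerance = 1e-3)
  expect_error(fit_maxent(pres[1:3, ], bg), "at least 5")
})

test_that("aggregation follows the median - x1000 - floor - median recipe", {
  tpl <- mr_raster(matrix(0, 2, 2), 0, 30, 0.5)
  m <- c(0.1, 0.2, 0.3, 0.4)
  same <- predict_and_aggregate(list(cbind(m, m, m)), tpl)
  expect_equal(as.vector(same$values), floor(m * 1000))
  tri <- predict_and_aggregate(list(cbind(c(0.001, 0, 0, 0),
                                          c(0.002, 0, 0, 0),
                                          c(0.009, 0, 0, 0))), tpl)
  expect_equal(tri$values[1, 1], 2) # median of 1, 2, 9
  # random stack against a per-cell sort oracle
  set.seed(5)
  subsets <- lapply(1:3, function(i) matrix(runif(4 * 7), 4, 7))
  agg <- predict_and_aggregate(subsets, tpl)
  oracle <- apply(sapply(subsets, function(P)
    floor(apply(P, 1, median) * 1000)), 1, median)
  expect_equal(as.vector(agg$values), oracle)
})

test_that("minimum-training-presence thresholds give zero omission", {
  suit <- toy_raster(matrix(c(10, 40, 20, 90, 70, 30, 60, 50, 80), 3, 3))
  lat <- raster_lats(suit); lon <- raster_lons(suit)
  # occurrences at the three highest-suitability cells (90, 80, 70)
  ix <- arrayInd(order(suit$values, decreasing = TRUE)[1:3],
                 dim(suit$values))
  occ <- data.frame(lat = lat[ix[, 1]], lon = lon[ix[, 2]])
  bin <- mtp_binarize(suit, occ)
  expect_equal(attr(bin, "tau"), 70) # third-highest value
  expect_equal(bin$values, (suit$values >= 70) + 0)
  # training omission is zero by construction, over random configurations
  set.seed(4)
  for (i in 1:5) {
    s2 <- toy_raster(matrix(runif(25), 5, 5))
    occ2 <- data.frame(lat = sample(raster_lats(s2), 4, TRUE),
                       lon = sample(raster_lons(s2), 4, TRUE))
    b2 <- mtp_binarize(s2, occ2)
    rc <- raster_cell_of(b2, occ2$lat, occ2$lon)
    expect_true(all(b2$values[rc] == 1))
  }
  # fixed-threshold variant and nodata handling
  suit$values[1, 1] <- NA
  expect_error(mtp_binarize(suit, data.frame(lat = lat[1], lon = lon[1])),
               "nodata")
  tb <- threshold_binarize(suit, 55)
  expect_equal(tb$values[2, 2], 1)
  expect_equal(attr(tb, "tau"), 55)
})

test_that("partial ROC matches hand-computed trapezoid areas", {
  suit <- mr_raster(matrix(c(10, 20, 30, 40), 1, 4), 0, 39.5, 0.5)
  lon <- raster_lons(suit)
  tp <- data.frame(lat = rep(39.75, 6), lon = lon[c(4, 4, 3, 2, 4, 3)])
  pr <- partial_roc(suit, tp, E = 0.25, n_boot = 50, seed = 1)
  # hand computation: kept curve points (x, sens) with sens >= 0.75:
  # (0.5, 5/6), (0.75, 1), (1, 1); model area = 0.479167, null = 0.375
  expect_equal(pr$auc_ratio_obs, 0.4791666667 / 0.375, tolerance = 1e-9)
  expect_error(partial_roc(mr_raster(matrix(1, 2, 3), 0, 30, 0.5),
                           tp[1:5, ]), "constant")
  expect_error(partial_roc(suit, tp[1:3, ]), "at least 5")
})

test_that("partial ROC separates signal from noise", {
  set.seed(30)
  suit <- toy_raster(matrix(runif(400), 20, 20))
  lats <- raster_lats(suit); lons <- raster_lons(suit)
  best <- arrayInd(order(suit$values, decreasing = TRUE)[1:12],
                   dim(suit$values))
  good <- data.frame(lat = lats[best[, 1]], lon = lons[best[, 2]])
  pg <- partial_roc(suit, good, E = 0.05, n_boot = 300, seed = 2)
  expect_gt(pg$auc_ratio, 1)
  expect_lt(pg$p, 0.05)
  # uniform-random test points: ratio near 1 and p diffuse rather than
  # concentrated at zero (the ratio has a small positive bias from the
  # sensitivity >= 1 - E conditioning, so this is a bounded check)
  ratios <- ps <- numeric(60)
  for (i in 1:60) {
    rnd <- data.frame(lat = sample(lats, 80, TRUE),
                      lon = sample(lons, 80, TRUE))
    r <- partial_roc(suit, rnd, E = 0.05, n_boot = 100, seed = i)
    ratios[i] <- r$auc_ratio; ps[i] <- r$p
  }
  expect_lt(abs(mean(ratios) - 1), 0.1)
  expect_gt(median(ps), 0.05)
  expect_lt(mean(ps < 0.05), 0.5)
})

test_that("MOP flags strict extrapolation and matches a brute-force oracle", {
  set.seed(40)
  C <- matrix(rnorm(20 * 3), 20, 3)
  # projection point identical to a calibration point: zero distance to its
  # nearest reference point, hence similarity 1 (alpha chosen so k = 1)
  P <- rbind(C[7, ], C + 0.1, c(100, 0, 0))
  mop1 <- mop_mask(C, P, alpha = 0.05)
  expect_equal(mop1$similarity[1], 1)
  mop <- mop_mask(C, P, alpha = 0.25)
  expect_true(mop$strict[nrow(P)])
  expect_equal(mop$similarity[nrow(P)], 0)
  # oracle: mean distance to the nearest k calibration points via dist()
  k <- ceiling(0.25 * nrow(C))
  md <- apply(P, 1, function(p) {
    d <- sqrt(colSums((t(C) - p)^2))
    mean(sort(d)[1:k])
  })
  lo <- apply(C, 2, min); hi <- apply(C, 2, max)
  strict <- apply(P, 1, function(p) any(p < lo | p > hi))
  md[strict] <- NA
  sim_oracle <- 1 - md / max(md, na.rm = TRUE)
  sim_oracle[strict] <- 0
  expect_equal(mop$similarity, sim_oracle, tolerance = 1e-12)
  # masking removes suitable-and-novel cells, never adds
  bin <- mr_raster(matrix(1, 2, 11), 0, 30, 0.5)
  mop2 <- mop_mask(C, P, alpha = 0.25, binary = bin)
  expect_true(all(mop2$masked$values <= bin$values))
  expect_equal(sum(mop2$masked$values == 0), sum(strict))
  expect_error(mop_mask(C, P[, 1:2], alpha = 0.25), "dimensionalities")
  expect_error(mop_mask(C, P, alpha = 0.001), "at least 1")
})
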