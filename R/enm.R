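#' Calibration region from buffered occurrences
#'
#' Rasterizes the union of great-circle buffers around the occurrence
#' records (the area plausibly accessible to the species), minus optional
#' exclusion rectangles. Errors if the mask comes out empty or if any
#' occurrence falls outside it after exclusion.
#'
#' @param occ data.frame with lat, lon.
#' @param template `mr_raster` defining the working grid.
#' @param buffer_km buffer radius in km (default 350).
#' @param exclusions optional list of rectangles
#'   `list(lonmin=, lonmax=, latmin=, latmax=)`.
#' @return an `mr_raster` mask (1 inside, NA outside).
#' @export
build_calibration_region <- function(occ, template, buffer_km = 350,
                                     exclusions = NULL) {
  if (nrow(occ) < 1) stop("need at least one occurrence")
  lats <- raster_lats(template); lons <- raster_lons(template)
  nr <- length(lats); nc <- length(lons)
  inside <- matrix(FALSE, nr, nc)
  latm <- matrix(lats, nr, nc); lonm <- matrix(lons, nr, nc, byrow = TRUE)
  for (i in seq_len(nrow(occ))) {
    d <- haversine_km(occ$lat[i], occ$lon[i], latm, lonm)
    inside <- inside | d <= buffer_km
  }
  for (ex in exclusions %||% list()) {
    inside[latm >= ex$latmin & latm <= ex$latmax &
             lonm >= ex$lonmin & lonm <= ex$lonmax] <- FALSE
  }
  if (!any(inside)) stop("calibration region is empty after exclusion")
  mask <- mr_raster(ifelse(inside, 1, NA_real_), template$xmin,
                    template$ymin, template$cellsize)
  rc <- raster_cell_of(mask, occ$lat, occ$lon)
  on_mask <- !is.na(rc[, 1]) & !is.na(mask$values[rc])
  if (!all(on_mask))
    stop("occurrence(s) outside the calibration region after exclusion: ",
         paste(which(!on_mask), collapse = ", "))
  mask
}

#' Spatially thin occurrence records
#'
#' Greedy thinning per replicate: records are visited in a random order and
#' accepted when at least `min_km` from every record already accepted. The
#' result is maximal (every rejected record is within `min_km` of an
#' accepted one); replicate sets differ only through the permutation.
#'
#' @param occ data.frame with lat, lon (and any id columns, preserved).
#' @param min_km minimum pairwise distance in km (default 50).
#' @param n_replicates number of replicate datasets (default 10).
#' @param seed optional integer seed.
#' @return list of data.frames (one per replicate).
#' @export
thin_occurrences <- function(occ, min_km = 50, n_replicates = 10,
                             seed = NULL) {
  if (min_km <= 0) stop("min_km must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(occ)
  D <- matrix(0, n, n)
  for (i in seq_len(n))
    D[i, ] <- haversine_km(occ$lat[i], occ$lon[i], occ$lat, occ$lon)
  lapply(seq_len(n_replicates), function(b) {
    ord <- sample.int(n)
    kept <- integer(0)
    for (i in ord) if (!length(kept) || all(D[i, kept] >= min_km))
      kept <- c(kept, i)
    occ[sort(kept), , drop = FALSE]
  })
}

# linear + quadratic features on score columns, standardized over background
build_features <- function(scores, means = NULL, sds = NULL) {
  Z <- cbind(scores, scores^2)
  colnames(Z) <- c(paste0("l", seq_len(ncol(scores))),
                   paste0("q", seq_len(ncol(scores))))
  if (is.null(means)) {
    means <- colMeans(Z); sds <- apply(Z, 2, stats::sd)
    sds[sds == 0] <- 1
  }
  list(Z = sweep(sweep(Z, 2, means), 2, sds, "/"), means = means, sds = sds)
}

# L1-regularized maxent by cyclic coordinate descent with soft thresholding.
# Maximizes mean_pres(eta.z) - log Z_bg(eta) - sum beta|eta|.
maxent_core <- function(Zp, Zb, beta, tol = 1e-6, max_cycles = 500) {
  nf <- ncol(Zb)
  eta <- rep(0, nf)
  logw <- rep(0, nrow(Zb))
  zbar <- colMeans(Zp)
  for (cycle in seq_len(max_cycles)) {
    delta_max <- 0
    for (j in seq_len(nf)) {
      w <- exp(logw - max(logw)); w <- w / sum(w)
      ez <- sum(w * Zb[, j])
      vz <- sum(w * Zb[, j]^2) - ez^2
      if (vz < 1e-12) next
      g <- zbar[j] - ez
      a <- eta[j] + g / vz
      new <- sign(a) * max(abs(a) - beta[j] / vz, 0)
      d <- new - eta[j]
      if (abs(d) > 0) {
        eta[j] <- new
        logw <- logw + d * Zb[, j]
        delta_max <- max(delta_max, abs(d))
      }
    }
    # KKT check on the exact subgradient
    w <- exp(logw - max(logw)); w <- w / sum(w)
    g <- zbar - as.vector(crossprod(Zb, w))
    viol <- ifelse(eta == 0, pmax(abs(g) - beta, 0), abs(g - beta * sign(eta)))
    if (max(viol) < tol) break
  }
  if (max(viol) >= tol && delta_max > 1e-8)
    warning(sprintf("maxent solver stopped at KKT violation %.2e", max(viol)))
  logZ <- max(logw) + log(sum(exp(logw - max(logw)))) # over background cells
  p <- exp(logw - logZ)
  list(eta = eta, logZ = logZ, p_bg = p, entropy = -sum(p * log(p)))
}

#' Fit maximum-entropy suitability models
#'
#' Minimizes the relative entropy between the presence density and the
#' background density in feature space (linear + quadratic functions of the
#' environmental scores, standardized over the background), with L1
#' regularization beta_j = reg_multiplier * s_j / sqrt(m) where s_j is the
#' feature's standard deviation over the presences and m their number. One
#' model is fitted per bootstrap replicate (presences resampled with
#' replacement, background fixed). The raw output of each model sums to one
#' over the background cells.
#'
#' @param presences matrix of environmental scores at presence points.
#' @param background matrix of scores over the calibration-region cells.
#' @param reg_multiplier regularization multiplier (default 1).
#' @param n_boot_reps bootstrap replicates (default 100).
#' @param seed optional integer seed.
#' @param tol solver gradient tolerance (default 1e-6).
#' @return list of class `maxent_fit`: `models` (list; each with eta, logZ,
#'   entropy), feature standardization, `beta`, and the background scores'
#'   column count.
#' @export
fit_maxent <- function(presences, background, reg_multiplier = 1,
                       n_boot_reps = 100, seed = NULL, tol = 1e-6) {
  presences <- as.matrix(presences); background <- as.matrix(background)
  if (nrow(presences) < 5) stop("need at least 5 presences")
  if (nrow(background) < 10 * 1) stop("background too small")
  if (!is.null(seed)) set.seed(seed)
  fb <- build_features(background)
  m <- nrow(presences)
  models <- vector("list", n_boot_reps)
  for (b in seq_len(n_boot_reps)) {
    ix <- if (n_boot_reps == 1) seq_len(m) else sample.int(m, m, replace = TRUE)
    fp <- build_features(presences[ix, , drop = FALSE], fb$means, fb$sds)
    s_pres <- apply(fp$Z, 2, stats::sd)
    beta <- reg_multiplier * pmax(s_pres, 1e-3) / sqrt(m)
    fit <- maxent_core(fp$Z, fb$Z, beta, tol = tol)
    models[[b]] <- list(eta = fit$eta, logZ = fit$logZ, entropy = fit$entropy,
                        beta = beta)
  }
  structure(list(models = models, feat_means = fb$means, feat_sds = fb$sds,
                 n_features = ncol(fb$Z), n_background = nrow(background)),
            class = "maxent_fit")
}

#' Predict suitability from a fitted maxent model
#'
#' Raw output exp(eta.z)/Z with Z from the training background; the
#' `"logistic"` type rescales with the model entropy so typical presence
#' cells score near 0.5 and values live in (0, 1).
#'
#' @param fit a `maxent_fit`.
#' @param scores matrix of environmental scores to predict at.
#' @param model_index which bootstrap model (default all; returns a matrix
#'   cells x models).
#' @param type "logistic" (default) or "raw".
#' @return matrix (cells x models) of suitabilities.
#' @export
maxent_predict <- function(fit, scores, model_index = NULL,
                           type = c("logistic", "raw")) {
  type <- match.arg(type)
  f <- build_features(as.matrix(scores), fit$feat_means, fit$feat_sds)
  ix <- model_index %||% seq_along(fit$models)
  out <- sapply(ix, function(b) {
    mod <- fit$models[[b]]
    raw <- exp(f$Z %*% mod$eta - mod$logZ)
    if (type == "raw") as.vector(raw)
    else { q <- raw * exp(mod$entropy); as.vector(q / (1 + q)) }
  })
  matrix(out, nrow = nrow(scores))
}

#' Aggregate replicate predictions into one integer suitability grid
#'
#' Cell-wise median over bootstrap replicates, multiplied by 1000 and
#' floored to integers, then cell-wise median over occurrence subsets.
#'
#' @param subset_preds list over subsets; each element a matrix
#'   (cells x bootstrap replicates) of suitabilities in [0, 1].
#' @param template `mr_raster` georeference for the output.
#' @return an `mr_raster` with integer values in 0..1000.
#' @export
predict_and_aggregate <- function(subset_preds, template) {
  per_subset <- lapply(subset_preds, function(P) {
    if (is.null(dim(P))) P <- matrix(P, ncol = 1)
    floor(apply(P, 1, stats::median) * 1000)
  })
  ncell <- length(per_subset[[1]])
  if (!all(lengths(per_subset) == ncell)) stop("grids are not conformable")
  agg <- apply(do.call(cbind, per_subset), 1, stats::median)
  mr_raster(matrix(agg, nrow(template$values), ncol(template$values)),
            template$xmin, template$ymin, template$cellsize)
}

#' Minimum-training-presence binarization
#'
#' The threshold tau is the lowest suitability at any training occurrence;
#' cells at or above tau are suitable, so training omission is zero by
#' construction.
#'
#' @param suit suitability `mr_raster`.
#' @param occ data.frame with lat, lon of the training occurrences.
#' @return an `mr_raster` with values in 0/1 (NA preserved); attributes
#'   `tau` and `rule`.
#' @export
mtp_binarize <- function(suit, occ) {
  rc <- raster_cell_of(suit, occ$lat, occ$lon)
  vals <- suit$values[rc]
  bad <- is.na(rc[, 1]) | is.na(vals)
  if (any(bad))
    stop("occurrence(s) on nodata cells: ", paste(which(bad), collapse = ", "))
  tau <- min(vals)
  out <- mr_raster((suit$values >= tau) + 0, suit$xmin, suit$ymin,
                   suit$cellsize)
  attr(out, "tau") <- tau
  attr(out, "rule") <- "minimum training presence"
  out
}

#' Binarize a suitability map at a fixed threshold
#'
#' Applies a threshold derived elsewhere (typically the minimum-training-
#' presence value of the present-day map) to another suitability surface,
#' e.g. a paleoclimate projection.
#'
#' @param suit suitability `mr_raster`.
#' @param tau threshold; cells at or above are suitable.
#' @return a binary `mr_raster` with attribute `tau`.
#' @export
threshold_binarize <- function(suit, tau) {
  out <- mr_raster((suit$values >= tau) + 0, suit$xmin, suit$ymin,
                   suit$cellsize)
  attr(out, "tau") <- tau
  attr(out, "rule") <- "fixed threshold"
  out
}

partial_roc_ratio <- function(suit_vals, test_vals, E) {
  th <- sort(unique(suit_vals))
  # proportion of area predicted present and sensitivity at each threshold
  x <- vapply(th, function(t) mean(suit_vals >= t), numeric(1))
  y <- vapply(th, function(t) mean(test_vals >= t), numeric(1))
  ord <- order(x)
  x <- c(0, x[ord], 1); y <- c(0, y[ord], 1)
  keep <- y >= 1 - E
  if (sum(keep) < 2) return(NA_real_)
  xs <- x[keep]; ys <- y[keep]
  trap <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  auc_model <- trap(xs, ys)
  auc_null <- trap(xs, xs)
  if (auc_null <= 0) return(NA_real_)
  auc_model / auc_null
}

#' Partial ROC evaluation
#'
#' AUC ratio restricted to the low-omission region: the area under the
#' sensitivity vs proportional-predicted-area curve where sensitivity is at
#' least 1 - E, divided by the corresponding area under the null
#' (uninformative) line. Significance comes from bootstrap resampling of
#' the test points; p is the proportion of bootstrap ratios at or below 1.
#'
#' @param suit suitability `mr_raster`.
#' @param test_points data.frame with lat, lon of independent test records.
#' @param E allowed omission rate (default 0.01).
#' @param n_boot bootstrap iterations (default 1000).
#' @param resample_frac fraction of test points resampled with replacement
#'   per iteration (default 0.5).
#' @param seed optional integer seed.
#' @return list of class `partial_roc_result` with E, auc_ratio (mean over
#'   bootstrap), p, n_boot, resample_frac.
#' @export
partial_roc <- function(suit, test_points, E = 0.01, n_boot = 1000,
                        resample_frac = 0.5, seed = NULL) {
  if (nrow(test_points) < 5) stop("need at least 5 test points")
  if (!is.null(seed)) set.seed(seed)
  sv <- as.vector(suit$values)
  sv <- sv[!is.na(sv)]
  if (length(unique(sv)) < 2) stop("constant suitability: partial ROC undefined")
  rc <- raster_cell_of(suit, test_points$lat, test_points$lon)
  tv <- suit$values[rc]
  if (any(is.na(tv))) stop("test point(s) on nodata cells")
  obs <- partial_roc_ratio(sv, tv, E)
  k <- max(2, round(resample_frac * length(tv)))
  ratios <- vapply(seq_len(n_boot), function(b)
    partial_roc_ratio(sv, tv[sample.int(length(tv), k, replace = TRUE)], E),
    numeric(1))
  ratios <- ratios[!is.na(ratios)]
  structure(list(E = E, auc_ratio = mean(ratios), auc_ratio_obs = obs,
                 p = mean(ratios <= 1), n_boot = n_boot,
                 resample_frac = resample_frac),
            class = "partial_roc_result")
}

#' @export
print.partial_roc_result <- function(x, ...) {
  cat(sprintf("partial ROC (E = %.2g): AUC ratio %.3f, p = %.4g (%d boots)\n",
              x$E, x$auc_ratio, x$p, x$n_boot))
  invisible(x)
}

#' Mobility-oriented parity (MOP) extrapolation analysis
#'
#' Flags strict extrapolation (any environmental dimension outside the
#' calibration min-max) and scores the remaining projection cells by their
#' similarity to the calibration cloud: one minus the mean Euclidean
#' distance to the nearest ceil(alpha * n) calibration points, normalized by
#' the maximum such mean over the projection cells. Suitable cells in strict
#' extrapolation are removed from the binary map.
#'
#' @param calibration_scores matrix (points x dims) of calibration-region
#'   environments.
#' @param projection_scores matrix (cells x dims) of projection
#'   environments, in raster cell order.
#' @param alpha reference fraction of calibration points (default 0.1).
#' @param binary optional binary `mr_raster` to mask.
#' @return list of class `mop_map`: `similarity` (mr_raster when `binary`
#'   given, else vector), `strict` (logical vector), `masked` (mr_raster or
#'   NULL).
#' @export
mop_mask <- function(calibration_scores, projection_scores, alpha = 0.1,
                     binary = NULL) {
  C <- as.matrix(calibration_scores); P <- as.matrix(projection_scores)
  if (ncol(C) != ncol(P)) stop("score dimensionalities differ")
  if (alpha * nrow(C) < 1) stop("alpha * n must be at least 1")
  kn <- ceiling(alpha * nrow(C))
  lo <- apply(C, 2, min); hi <- apply(C, 2, max)
  strict <- rowSums(sweep(P, 2, lo, "<") | sweep(P, 2, hi, ">")) > 0
  mdist <- rep(NA_real_, nrow(P))
  inb <- which(!strict)
  if (length(inb)) {
    c2 <- rowSums(C^2)
    block <- 2000
    for (s in seq(1, length(inb), by = block)) {
      ix <- inb[s:min(s + block - 1, length(inb))]
      Pi <- P[ix, , drop = FALSE]
      d2 <- outer(rowSums(Pi^2), c2, "+") - 2 * Pi %*% t(C)
      d2[d2 < 0] <- 0
      d <- sqrt(d2)
      mdist[ix] <- apply(d, 1, function(v) mean(sort.int(v, partial = kn)[1:kn]))
    }
  }
  dmax <- max(mdist, na.rm = TRUE)
  sim <- 1 - mdist / max(dmax, 1e-12)
  sim[strict] <- 0
  masked <- NULL
  if (!is.null(binary)) {
    simr <- mr_raster(matrix(sim, nrow(binary$values), ncol(binary$values)),
                      binary$xmin, binary$ymin, binary$cellsize)
    bm <- binary$values
    bm[matrix(strict, nrow(bm), ncol(bm))] <- 0
    masked <- mr_raster(bm, binary$xmin, binary$ymin, binary$cellsize)
    sim <- simr
  }
  structure(list(similarity = sim, strict = strict, alpha = alpha,
                 masked = masked),
            class = "mop_map")
}
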