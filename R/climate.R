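#' Monthly climatology stack
#'
#' Twelve monthly layers each of mean, maximum and minimum temperature
#' (degC) and precipitation (mm), on one shared grid. The physical
#' orderings tmax >= tmean >= tmin and prec >= 0 are validated cell-wise.
#'
#' @param fields list with arrays tmean, tmax, tmin, prec of dim
#'   c(rows, cols, 12).
#' @param template an `mr_raster` carrying the georeference.
#' @param check validate orderings (default TRUE).
#' @return object of class `monthly_climatology`.
#' @export
monthly_climatology <- function(fields, template, check = TRUE) {
  need <- c("tmean", "tmax", "tmin", "prec")
  if (!all(need %in% names(fields))) stop("missing climate variable(s)")
  dims <- dim(fields$tmean)
  if (length(dims) != 3 || dims[3] != 12) stop("need 12 monthly layers")
  for (v in need) if (!all(dim(fields[[v]]) == dims))
    stop("climate arrays differ in shape")
  if (check) {
    if (any(fields$tmax < fields$tmean - 1e-9, na.rm = TRUE) ||
        any(fields$tmean < fields$tmin - 1e-9, na.rm = TRUE))
      warning("temperature ordering violated (tmax >= tmean >= tmin)")
    if (any(fields$prec < 0, na.rm = TRUE)) stop("negative precipitation")
  }
  structure(list(tmean = fields$tmean, tmax = fields$tmax,
                 tmin = fields$tmin, prec = fields$prec,
                 template = template),
            class = "monthly_climatology")
}

#' The 19 bioclimatic variables
#'
#' Computes BIO1-BIO19 from a monthly climatology. Quarters are all twelve
#' wrap-around three-month windows; quarterly temperature is the mean of the
#' three monthly means and quarterly precipitation their sum. BIO4 is
#' 100 x SD of monthly mean temperature and BIO15 is
#' 100 x SD(monthly prec)/(1 + mean(monthly prec)). BIO8, BIO9, BIO18 and
#' BIO19 (temperature of the wettest/driest quarters, precipitation of the
#' warmest/coldest quarters) are computed but marked excluded, because of
#' the spatial artifacts these four variables develop; 15 layers remain for
#' modeling.
#'
#' @param clim a [monthly_climatology()].
#' @return list of class `bioclim_stack`: `layers` (named list of 19
#'   matrices BIO01..BIO19), `excluded` (names), `retained` (names),
#'   `template`.
#' @export
compute_bioclim <- function(clim) {
  stopifnot(inherits(clim, "monthly_climatology"))
  dims <- dim(clim$tmean)
  nr <- dims[1]; nc <- dims[2]
  tm <- clim$tmean; tx <- clim$tmax; tn <- clim$tmin; pr <- clim$prec
  qwin <- lapply(1:12, function(w) ((w - 1):(w + 1)) %% 12 + 1)
  qt <- array(0, c(nr, nc, 12)); qp <- array(0, c(nr, nc, 12))
  for (w in 1:12) {
    qt[, , w] <- (tm[, , qwin[[w]][1]] + tm[, , qwin[[w]][2]] +
                    tm[, , qwin[[w]][3]]) / 3
    qp[, , w] <- pr[, , qwin[[w]][1]] + pr[, , qwin[[w]][2]] +
      pr[, , qwin[[w]][3]]
  }
  amax <- function(a) apply(a, c(1, 2), max)
  amin <- function(a) apply(a, c(1, 2), min)
  amean <- function(a) apply(a, c(1, 2), mean)
  asd <- function(a) apply(a, c(1, 2), stats::sd)
  pick <- function(a, idx) { # value of a at the per-cell window index
    out <- matrix(NA_real_, nr, nc)
    for (w in 1:12) { sel <- idx == w; out[sel] <- a[, , w][sel] }
    out
  }
  wix <- function(a, fun) apply(a, c(1, 2), fun) # index of extreme window
  b <- list()
  b$BIO01 <- amean(tm)
  b$BIO02 <- amean(tx - tn)
  b$BIO05 <- amax(tx)
  b$BIO06 <- amin(tn)
  b$BIO07 <- b$BIO05 - b$BIO06
  b$BIO03 <- ifelse(b$BIO07 > 0, 100 * b$BIO02 / b$BIO07, NA_real_)
  b$BIO04 <- 100 * asd(tm)
  iwarm <- wix(qt, which.max); icold <- wix(qt, which.min)
  iwet <- wix(qp, which.max); idry <- wix(qp, which.min)
  b$BIO08 <- pick(qt, iwet)
  b$BIO09 <- pick(qt, idry)
  b$BIO10 <- pick(qt, iwarm)
  b$BIO11 <- pick(qt, icold)
  b$BIO12 <- apply(pr, c(1, 2), sum)
  b$BIO13 <- amax(pr)
  b$BIO14 <- amin(pr)
  b$BIO15 <- 100 * asd(pr) / (1 + amean(pr))
  b$BIO16 <- pick(qp, iwet)
  b$BIO17 <- pick(qp, idry)
  b$BIO18 <- pick(qp, iwarm)
  b$BIO19 <- pick(qp, icold)
  b <- b[order(names(b))]
  excluded <- c("BIO08", "BIO09", "BIO18", "BIO19")
  structure(list(layers = b, excluded = excluded,
                 retained = setdiff(names(b), excluded),
                 template = clim$template),
            class = "bioclim_stack")
}

#' @export
print.bioclim_stack <- function(x, ...) {
  cat(sprintf("bioclim_stack: 19 layers (%d retained for modeling)\n",
              length(x$retained)))
  invisible(x)
}

#' Change-factor downscaling of a paleoclimate simulation
#'
#' Interpolates the coarse anomaly (past minus current) and adds it to the
#' fine current climatology: absolute differences for temperatures, relative
#' differences for precipitation (with a small additive guard against
#' division by near-zero arid-cell values). This preserves fine-scale
#' structure while imposing the coarse model's climate-change trend; when
#' the past equals the current coarse field the output is exactly the fine
#' current climatology.
#'
#' @param past_coarse,current_coarse coarse-grid [monthly_climatology()]
#'   objects on one grid.
#' @param current_fine fine-grid [monthly_climatology()] (the target grid).
#' @param eps precipitation ratio guard in mm (default 0.01).
#' @return a [monthly_climatology()] on the fine grid.
#' @export
downscale_change_factor <- function(past_coarse, current_coarse, current_fine,
                                    eps = 0.01) {
  if (!same_grid(past_coarse$template, current_coarse$template))
    stop("coarse grids do not match")
  if (current_fine$template$cellsize > past_coarse$template$cellsize)
    stop("target grid must be finer than the source grid")
  tpl_c <- past_coarse$template; tpl_f <- current_fine$template
  interp <- function(m) bilinear_resample(
    mr_raster(m, tpl_c$xmin, tpl_c$ymin, tpl_c$cellsize), tpl_f)$values
  out <- list()
  for (v in c("tmean", "tmax", "tmin")) {
    a <- array(0, dim(current_fine[[v]]))
    for (m in 1:12)
      a[, , m] <- current_fine[[v]][, , m] +
        interp(past_coarse[[v]][, , m] - current_coarse[[v]][, , m])
    out[[v]] <- a
  }
  a <- array(0, dim(current_fine$prec))
  for (m in 1:12) {
    ratio <- interp((past_coarse$prec[, , m] + eps) /
                      (current_coarse$prec[, , m] + eps))
    a[, , m] <- pmax(current_fine$prec[, , m] * ratio, 0)
  }
  out$prec <- a
  monthly_climatology(out, tpl_f, check = FALSE)
}

#' Principal-component environmental space
#'
#' PCA of the retained bioclim layers over the calibration-region cells,
#' on the correlation matrix (the variables mix units). Components are
#' retained up to the smallest cumulative explained-variance fraction at or
#' above `variance_target`. Zero-variance variables are dropped with a
#' warning. Loadings follow a deterministic sign convention: the
#' largest-magnitude loading of each component is positive.
#'
#' @param bioclim a [compute_bioclim()] stack.
#' @param region_mask logical/0-1 matrix (or `mr_raster`) selecting
#'   calibration cells; NULL = all complete cells.
#' @param variance_target cumulative variance fraction (default 0.99).
#' @return list of class `env_pca`: variables, means, sds, loadings (all
#'   components), var_frac, k.
#' @export
fit_env_pca <- function(bioclim, region_mask = NULL, variance_target = 0.99) {
  stopifnot(inherits(bioclim, "bioclim_stack"))
  mask <- if (is.null(region_mask)) NULL
          else if (inherits(region_mask, "mr_raster")) region_mask$values
          else region_mask
  X <- sapply(bioclim$retained, function(nm) as.vector(bioclim$layers[[nm]]))
  keep <- stats::complete.cases(X)
  if (!is.null(mask)) {
    mv <- as.vector(mask)
    keep <- keep & !is.na(mv) & mv == 1
  }
  X <- X[keep, , drop = FALSE]
  if (nrow(X) < ncol(X)) stop("fewer calibration cells than variables")
  sds <- apply(X, 2, stats::sd)
  # treat numerically constant layers as zero-variance
  degenerate <- sds <= 1e-10 * pmax(1, abs(colMeans(X)))
  if (any(degenerate)) {
    warning("dropping zero-variance variable(s): ",
            paste(colnames(X)[degenerate], collapse = ", "))
    X <- X[, !degenerate, drop = FALSE]
  }
  mu <- colMeans(X); sdv <- apply(X, 2, stats::sd)
  eg <- eigen(stats::cor(X), symmetric = TRUE)
  var_frac <- eg$values / sum(eg$values)
  k <- which(cumsum(var_frac) >= variance_target)[1]
  W <- eg$vectors
  for (j in seq_len(ncol(W))) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  dimnames(W) <- list(colnames(X), paste0("PC", seq_len(ncol(W))))
  structure(list(variables = colnames(X), means = mu, sds = sdv,
                 loadings = W, sdev = sqrt(pmax(eg$values, 1e-12)),
                 var_frac = var_frac, k = k,
                 variance_target = variance_target),
            class = "env_pca")
}

#' @export
print.env_pca <- function(x, ...) {
  cat(sprintf("env_pca: %d variables, %d components retained (%.2f%% variance)\n",
              length(x$variables), x$k, 100 * sum(x$var_frac[seq_len(x$k)])))
  invisible(x)
}

#' Project a bioclim stack into a fitted environmental space
#'
#' Layers are centered and scaled with the calibration means and standard
#' deviations and multiplied by the stored loadings; the PCA is never refit,
#' so past conditions live in the present-day component space. Scores are
#' whitened (each axis divided by its calibration standard deviation), so
#' projecting the calibration stack yields axes with zero mean and unit
#' variance over the calibration cells.
#'
#' @param pca an [fit_env_pca()] object.
#' @param bioclim a [compute_bioclim()] stack with the same variables.
#' @return matrix of scores (cells x k) with attribute `dim_grid`
#'   c(rows, cols); cells in raster column-major order of the stacked
#'   matrices.
#' @export
project_env <- function(pca, bioclim) {
  stopifnot(inherits(pca, "env_pca"), inherits(bioclim, "bioclim_stack"))
  miss <- setdiff(pca$variables, names(bioclim$layers))
  if (length(miss)) stop("missing variable(s): ", paste(miss, collapse = ", "))
  X <- sapply(pca$variables, function(nm) as.vector(bioclim$layers[[nm]]))
  Z <- scale(X, pca$means, pca$sds)
  k <- seq_len(pca$k)
  S <- sweep(Z %*% pca$loadings[, k, drop = FALSE], 2, pca$sdev[k], "/")
  attr(S, "dim_grid") <- dim(bioclim$layers[[1]])
  S
}

#' Serialize / restore an environmental PCA as JSON
#' @param pca an `env_pca`.
#' @param path file path.
#' @export
write_env_pca <- function(pca, path) {
  jsonlite::write_json(list(variables = pca$variables, means = pca$means,
                            sds = pca$sds, loadings = pca$loadings,
                            sdev = pca$sdev, var_frac = pca$var_frac,
                            k = pca$k),
                       path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_env_pca
#' @export
read_env_pca <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- j$loadings
  dimnames(W) <- list(j$variables, paste0("PC", seq_len(ncol(W))))
  structure(list(variables = j$variables,
                 means = stats::setNames(j$means, j$variables),
                 sds = stats::setNames(j$sds, j$variables),
                 loadings = W, sdev = j$sdev, var_frac = j$var_frac,
                 k = j$k),
            class = "env_pca")
}
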