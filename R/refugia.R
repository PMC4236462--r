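#' Consensus of binary suitability maps
#'
#' A cell is suitable when at least `k` of the maps mark it suitable; cells
#' where fewer than `k` maps carry data become nodata.
#'
#' @param maps list of binary `mr_raster`s on one grid.
#' @param k agreement threshold (count, 1..length(maps)).
#' @return a binary `mr_raster`.
#' @export
consensus_map <- function(maps, k) {
  G <- length(maps)
  if (k < 1 || k > G) stop("k must lie in 1..", G)
  for (m in maps[-1]) if (!same_grid(maps[[1]], m))
    stop("maps are not conformable")
  vals <- lapply(maps, `[[`, "values")
  navail <- Reduce(`+`, lapply(vals, function(v) !is.na(v) + 0))
  count <- Reduce(`+`, lapply(vals, function(v) { v[is.na(v)] <- 0; v }))
  out <- (count >= k) + 0
  out[navail < k] <- NA_real_
  mr_raster(out, maps[[1]]$xmin, maps[[1]]$ymin, maps[[1]]$cellsize)
}

#' Refugium delimitation across GCMs and time slices
#'
#' A refugium is an area continuously suitable across all time slices. Two
#' orders of operations are provided. M1 takes, per time slice, the
#' consensus of the GCMs at agreement threshold k, then intersects the
#' slices. M2 first intersects the slices within each GCM (its available
#' slices), then takes the consensus of the per-GCM refugium maps at
#' threshold k. Thresholds may be given as a count `k` or a `fraction` of
#' the available models, rounded up, so fractions {1/G, 1/2, 3/4, 1}
#' reproduce counts {1, G/2, 3G/4, G}. M2(k) is always nested within M1(k).
#'
#' @param ens list of class `binary_ensemble` or a plain nested list
#'   `ens[[gcm]][[slice]]` of binary `mr_raster`s; a GCM may miss a slice.
#' @param method "M1" or "M2".
#' @param k agreement threshold as a model count.
#' @param fraction agreement threshold as a fraction (used when `k` NULL);
#'   per-slice counts are ceiling(fraction x available models).
#' @param adjacency "queen" (default) or "rook" for component labeling.
#' @return list of class `refugia_scenario`: method, k (or fraction),
#'   `result` (binary mr_raster), `components` (data.frame label,
#'   n_cells, area_km2, centroid_lat, centroid_lon).
#' @export
delimit_refugia <- function(ens, method = c("M1", "M2"), k = NULL,
                            fraction = NULL, adjacency = "queen") {
  method <- match.arg(method)
  gcms <- ens$gcms %||% ens
  slices <- unique(unlist(lapply(gcms, names)))
  G <- length(gcms)
  avail <- vapply(slices, function(s)
    sum(vapply(gcms, function(g) s %in% names(g), logical(1))), integer(1))
  if (is.null(k) && is.null(fraction)) stop("give k or fraction")
  k_slice <- if (!is.null(k)) {
    bad <- slices[avail < k]
    if (length(bad))
      stop("k = ", k, " exceeds available models in slice(s): ",
           paste(bad, collapse = ", "))
    stats::setNames(rep(k, length(slices)), slices)
  } else stats::setNames(pmax(ceiling(fraction * avail), 1L), slices)
  if (method == "M1") {
    per_slice <- lapply(slices, function(s) {
      maps <- lapply(gcms[vapply(gcms, function(g) s %in% names(g),
                                 logical(1))], `[[`, s)
      consensus_map(maps, k_slice[[s]])
    })
    res <- intersect_maps(per_slice)
  } else {
    per_gcm <- lapply(gcms, function(g) intersect_maps(unname(g)))
    kk <- if (!is.null(k)) k else max(ceiling(fraction * G), 1L)
    res <- consensus_map(per_gcm, kk)
  }
  comps <- label_components(res, adjacency = adjacency)
  structure(list(method = method, k = k, fraction = fraction,
                 k_slice = k_slice, result = res, components = comps,
                 adjacency = adjacency),
            class = "refugia_scenario")
}

# cell-wise AND over binary maps; NA propagates
intersect_maps <- function(maps) {
  vals <- Reduce(function(a, b) a * b, lapply(maps, `[[`, "values"))
  mr_raster(vals, maps[[1]]$xmin, maps[[1]]$ymin, maps[[1]]$cellsize)
}

#' @export
print.refugia_scenario <- function(x, ...) {
  cat(sprintf("refugia %s (k = %s): %d suitable cells in %d component(s)\n",
              x$method, x$k %||% sprintf("%.2f of models", x$fraction),
              sum(x$result$values == 1, na.rm = TRUE), nrow(x$components)))
  invisible(x)
}

#' Label connected refugium components
#'
#' Flood-fill connected-component labeling of a binary map, with queen
#' (8-neighbour, default) or rook (4-neighbour) adjacency. Component areas
#' use latitude-corrected cell areas.
#'
#' @param binary a binary `mr_raster`.
#' @param adjacency "queen" or "rook".
#' @return data.frame with label, n_cells, area_km2, centroid_lat,
#'   centroid_lon; attribute `labels` holds the label matrix.
#' @export
label_components <- function(binary, adjacency = c("queen", "rook")) {
  adjacency <- match.arg(adjacency)
  v <- binary$values
  nr <- nrow(v); nc <- ncol(v)
  lab <- matrix(0L, nr, nc)
  nbr <- if (adjacency == "queen")
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  cur <- 0L
  suitable <- which(!is.na(v) & v == 1)
  for (s in suitable) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      cell <- queue[1]; queue <- queue[-1]
      r <- (cell - 1) %% nr + 1; c <- (cell - 1) %/% nr + 1
      for (t in seq_len(nrow(nbr))) {
        rr <- r + nbr[t, 1]; cc <- c + nbr[t, 2]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        id <- (cc - 1) * nr + rr
        if (lab[id] == 0L && !is.na(v[id]) && v[id] == 1) {
          lab[id] <- cur
          queue <- c(queue, id)
        }
      }
    }
  }
  lats <- raster_lats(binary); lons <- raster_lons(binary)
  cell_km <- (111.32 * binary$cellsize)^2 * cos(lats * pi / 180) # per row
  rows <- lapply(seq_len(cur), function(l) {
    ix <- which(lab == l)
    r <- (ix - 1) %% nr + 1; c <- (ix - 1) %/% nr + 1
    data.frame(label = l, n_cells = length(ix),
               area_km2 = sum(cell_km[r]),
               centroid_lat = mean(lats[r]), centroid_lon = mean(lons[c]))
  })
  out <- if (cur > 0) do.call(rbind, rows)
         else data.frame(label = integer(), n_cells = integer(),
                         area_km2 = numeric(), centroid_lat = numeric(),
                         centroid_lon = numeric())
  attr(out, "labels") <- lab
  attr(out, "adjacency") <- adjacency
  out
}

#' Jaccard overlap of two binary maps
#'
#' Intersection over union of the suitable cells; a convenience for truth
#' recovery checks.
#'
#' @param a,b binary `mr_raster`s (or 0/1 matrices).
#' @return numeric in [0, 1] (NaN when both maps are empty).
#' @export
jaccard_overlap <- function(a, b) {
  va <- if (inherits(a, "mr_raster")) a$values else a
  vb <- if (inherits(b, "mr_raster")) b$values else b
  A <- !is.na(va) & va == 1
  B <- !is.na(vb) & vb == 1
  sum(A & B) / sum(A | B)
}
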