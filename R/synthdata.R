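#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults are the study
#' conditions used throughout the test suite: a cox1-like locus of 1016 sites,
#' a Mediterranean-like lon/lat box, three time slices (LGM, mid-Holocene,
#' present), four pseudo-GCMs with coherent 1 degC perturbations, and a 60x60
#' half-degree grid.
#'
#' @param seed integer root seed.
#' @param n_samples total number of sequenced individuals.
#' @param seq_length alignment length in sites.
#' @param theta scaled mutation rate per locus (ignored when `S_fixed` given).
#' @param S_fixed optional fixed segregating-site count per lineage.
#' @param n_localities number of sampling localities.
#' @param n_lineages number of independently simulated lineages.
#' @param ibd_scale spatial scale (km) of shared ancestry: the per-unit-time
#'   standard deviation of the Brownian dispersal used to place haplotypes.
#' @param bbox locality bounding box c(lonmin, lonmax, latmin, latmax).
#' @param mixing_fraction proportion in [0,1] of samples whose locality is
#'   reassigned uniformly at random (human-transport emulation).
#' @param grid_shape integer c(rows, cols) of the climate grid.
#' @param n_gcms number of pseudo-GCMs.
#' @param slices ordered time-slice labels.
#' @param gcm_noise_sd scale (degC) of the per-GCM coherent climate
#'   perturbation; precipitation is perturbed proportionally.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_samples = 60L, seq_length = 1016L,
                       theta = 8, S_fixed = NULL, n_localities = 25L,
                       n_lineages = 3L, ibd_scale = 300, mixing_fraction = 0,
                       bbox = c(-5, 25, 30, 44),
                       grid_shape = c(60L, 60L), n_gcms = 4L,
                       slices = c("LGM", "midHolocene", "present"),
                       gcm_noise_sd = 0.5) {
  if (mixing_fraction < 0 || mixing_fraction > 1)
    stop("mixing_fraction must lie in [0, 1]")
  if (seq_length <= 0) stop("seq_length must be positive")
  if (n_samples < 2) stop("n_samples must be at least 2")
  if (!is.null(S_fixed) && S_fixed > seq_length)
    stop("S_fixed cannot exceed seq_length")
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 seq_length = as.integer(seq_length), theta = theta,
                 S_fixed = S_fixed, n_localities = as.integer(n_localities),
                 n_lineages = as.integer(n_lineages), ibd_scale = ibd_scale,
                 bbox = bbox, mixing_fraction = mixing_fraction,
                 grid_shape = as.integer(grid_shape),
                 n_gcms = as.integer(n_gcms), slices = slices,
                 gcm_noise_sd = gcm_noise_sd),
            class = "sim_config")
}

#' Simulate a standard n-coalescent genealogy
#'
#' Binary ultrametric tree with exchangeable topology and inter-coalescent
#' intervals distributed Exponential(k(k-1)/2) while k lineages remain, in
#' coalescent time units (tips at age zero).
#'
#' @param n number of tips (>= 2).
#' @param seed optional integer seed.
#' @return an `ape::phylo` ultrametric tree with tips "t1".."tn".
#' @export
simulate_genealogy <- function(n, seed = NULL) {
  if (n < 2) stop("a genealogy needs at least 2 samples")
  if (!is.null(seed)) set.seed(seed)
  ape::rcoal(n)
}

#' Drop infinite-sites mutations on a genealogy
#'
#' Mutations are placed on branches either as a Poisson process with rate
#' theta/2 per unit branch length, or as exactly `S_fixed` mutations placed
#' multinomially proportional to branch length (the fixed-S conditioning that
#' also serves as the null simulator for neutrality-test significance). Each
#' mutation occupies a distinct alignment site; the derived base differs from
#' the ancestral one.
#'
#' @param tree ultrametric `phylo` genealogy.
#' @param theta scaled mutation rate per locus.
#' @param S_fixed optional exact segregating-site count (overrides `theta`).
#' @param L alignment length in sites.
#' @param seed optional integer seed.
#' @param ancestral optional ancestral sequence (character vector of length
#'   L); random when omitted.
#' @return character matrix (tips x sites) over A/C/G/T with tip labels as
#'   row names; attribute `mutation_sites` lists the mutated columns.
#' @export
simulate_alignment <- function(tree, theta = NULL, S_fixed = NULL, L = 1016,
                               seed = NULL, ancestral = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(theta) && is.null(S_fixed)) stop("give theta or S_fixed")
  if (!is.null(S_fixed) && S_fixed > L)
    stop("S_fixed cannot exceed the alignment length")
  ntip <- ape::Ntip(tree)
  len <- tree$edge.length
  nmut <- if (!is.null(S_fixed)) as.integer(S_fixed)
          else stats::rpois(1, theta / 2 * sum(len))
  if (nmut > L) stop("more mutations than sites; increase L or lower theta")
  bases <- c("A", "C", "G", "T")
  anc <- ancestral %||% sample(bases, L, replace = TRUE)
  if (length(anc) != L) stop("ancestral sequence must have length L")
  aln <- matrix(rep(anc, each = ntip), nrow = ntip,
                dimnames = list(tree$tip.label, NULL))
  if (nmut > 0) {
    edge_of <- sample.int(nrow(tree$edge), nmut, replace = TRUE, prob = len)
    sites <- sample.int(L, nmut) # distinct: infinite sites
    tips_below <- edge_tip_sets(tree)
    for (k in seq_len(nmut)) {
      carriers <- tips_below[[edge_of[k]]]
      derived <- sample(setdiff(bases, anc[sites[k]]), 1)
      aln[carriers, sites[k]] <- derived
    }
    attr(aln, "mutation_sites") <- sort(sites)
  } else attr(aln, "mutation_sites") <- integer(0)
  aln
}

# tip indices descending from each edge (index = row of tree$edge)
edge_tip_sets <- function(tree) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  kids <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) kids[[i]] <- i
  # postorder over edges: children before parents
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; c <- po$edge[e, 2]
    kids[[p]] <- c(kids[[p]], kids[[c]])
  }
  lapply(seq_len(nrow(tree$edge)), function(e) kids[[tree$edge[e, 2]]])
}

#' Simulate a geo-referenced haplotype dataset with known truth
#'
#' Lineages are simulated independently on coalescent genealogies; sample
#' coordinates evolve by Brownian dispersal along each genealogy (scale
#' `ibd_scale` km per unit coalescent time) and are snapped to the nearest
#' locality, so closely related haplotypes sit at spatially proximate
#' localities (isolation by distance). A fraction `mixing_fraction` of
#' samples then has its locality resampled uniformly, emulating
#' human-mediated transport; at 1 the dataset carries no spatial signal.
#'
#' @param config a [sim_config()].
#' @return list with `geo` (a [geo_alignment()]) and `truth` (genealogies,
#'   lineage of each sample, locality table, mixed sample ids).
#' @export
simulate_geo_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nloc <- config$n_localities
  bb <- config$bbox
  loc <- data.frame(locality = seq_len(nloc),
                    lon = stats::runif(nloc, bb[1], bb[2]),
                    lat = stats::runif(nloc, bb[3], bb[4]))
  nl <- config$n_lineages
  sizes <- diff(round(seq(0, config$n_samples, length.out = nl + 1)))
  L <- config$seq_length
  bases <- c("A", "C", "G", "T")
  backbone <- sample(bases, L, replace = TRUE)
  seqs <- NULL; samples <- NULL
  genealogies <- vector("list", nl)
  id0 <- 0
  for (g in seq_len(nl)) {
    n <- sizes[g]
    tree <- ape::rcoal(n)
    genealogies[[g]] <- tree
    # lineage ancestor: the shared backbone with ~3% diagnostic divergence
    anc <- backbone
    flip <- sample.int(L, max(1L, round(0.03 * L)))
    for (s in flip) anc[s] <- sample(setdiff(bases, backbone[s]), 1)
    aln <- simulate_alignment(tree, theta = config$theta,
                              S_fixed = config$S_fixed, L = L,
                              ancestral = anc)
    xy <- brownian_tip_positions(tree, loc, config$ibd_scale)
    locality <- snap_to_locality(xy, loc)
    ids <- paste0("s", id0 + seq_len(n))
    rownames(aln) <- ids
    samples <- rbind(samples, data.frame(
      id = ids, locality = locality, lat = loc$lat[locality],
      lon = loc$lon[locality], lineage = paste0("L", g)))
    seqs <- rbind(seqs, aln)
    id0 <- id0 + n
  }
  n_mix <- round(config$mixing_fraction * nrow(samples))
  mixed <- if (n_mix > 0) sample(nrow(samples), n_mix) else integer(0)
  if (n_mix > 0) {
    newloc <- sample.int(nloc, n_mix, replace = TRUE)
    samples$locality[mixed] <- newloc
    samples$lat[mixed] <- loc$lat[newloc]
    samples$lon[mixed] <- loc$lon[newloc]
  }
  geo <- geo_alignment(seqs, samples)
  truth <- list(genealogies = genealogies,
                lineage_of_sample = stats::setNames(samples$lineage, samples$id),
                localities = loc, mixed_samples = samples$id[mixed])
  list(geo = geo, truth = truth)
}

# Brownian dispersal along the tree, started at a random locality.
brownian_tip_positions <- function(tree, loc, ibd_scale) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1
  start <- loc[sample.int(nrow(loc), 1), ]
  sd_deg <- ibd_scale / 111.32 # km -> degrees, per sqrt(coalescent unit)
  pos <- matrix(NA_real_, ntip + tree$Nnode, 2)
  pos[root, ] <- c(start$lon, start$lat)
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(pre$edge))) {
    p <- pre$edge[e, 1]; c <- pre$edge[e, 2]
    step <- stats::rnorm(2, 0, sd_deg * sqrt(pre$edge.length[e]))
    pos[c, ] <- pos[p, ] + step
  }
  pos[seq_len(ntip), , drop = FALSE]
}

snap_to_locality <- function(xy, loc) {
  vapply(seq_len(nrow(xy)), function(i) {
    d <- haversine_km(xy[i, 2], xy[i, 1], loc$lat, loc$lon)
    which.min(d)
  }, integer(1))
}

#' Simulate a multi-GCM monthly climate suite with known suitability truth
#'
#' Smooth monthly temperature and precipitation fields on a half-degree grid:
#' temperature follows a latitudinal gradient plus seasonal cycle and fixed
#' orographic bumps; precipitation follows a longitudinal gradient. Past
#' slices cool the whole domain (mid-Holocene mildly, LGM strongly), so the
#' climatically suitable band shifts southward at the LGM. Each pseudo-GCM
#' receives a coherent smooth perturbation of scale `gcm_noise_sd`, identical
#' across slices and months for that GCM. The true suitability is a steep
#' logistic band in annual mean temperature (BIO1) with a mild annual
#' precipitation (BIO12) term, evaluated on the unperturbed fields; true
#' refugia are the cells suitable (>= cutoff 0.5) in every slice.
#'
#' @param config a [sim_config()].
#' @return list with `suite` (per-GCM, per-slice monthly climatologies) and
#'   `truth` (per-slice suitability rasters, the refugium raster, cutoff).
#' @export
simulate_climate_suite <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (any(config$grid_shape < 10)) stop("grid must be at least 10 x 10")
  set.seed(config$seed + 1000L)
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  cs <- 0.5
  template <- mr_raster(matrix(0, nr, nc), xmin = -15, ymin = 20, cellsize = cs)
  lat <- raster_lats(template); lon <- raster_lons(template)
  latm <- matrix(lat, nr, nc); lonm <- matrix(lon, nr, nc, byrow = TRUE)
  bump <- 1.5 * exp(-((latm - 38)^2 + (lonm - 0)^2) / 30) -
    1.5 * exp(-((latm - 30)^2 + (lonm + 8)^2) / 40)
  slice_dT <- stats::setNames(rep(0, length(config$slices)), config$slices)
  if ("midHolocene" %in% config$slices) slice_dT[["midHolocene"]] <- -0.5
  if ("LGM" %in% config$slices) slice_dT[["LGM"]] <- -4.5
  slice_prec_fac <- ifelse(names(slice_dT) == "LGM", 0.9, 1)
  names(slice_prec_fac) <- names(slice_dT)

  month_clim <- function(dT, prec_fac, t_pert, p_fac) {
    tmean <- array(0, c(nr, nc, 12)); prec <- array(0, c(nr, nc, 12))
    for (m in 1:12) {
      seas <- 6 * cos(2 * pi * (m - 7) / 12)
      tmean[, , m] <- 24 - 0.9 * (latm - 20) + seas + bump + dT + t_pert
      prec[, , m] <- pmax((50 + 1.2 * (lonm + 15) +
                             15 * cos(2 * pi * (m - 1) / 12)) *
                            prec_fac * p_fac, 0)
    }
    drange <- 5 + 0.03 * (lonm + 15) # diurnal range widens with continentality
    tmax <- tmean; tmin <- tmean
    for (m in 1:12) {
      tmax[, , m] <- tmean[, , m] + drange
      tmin[, , m] <- tmean[, , m] - drange
    }
    list(tmean = tmean, tmax = tmax, tmin = tmin, prec = prec)
  }

  gcms <- vector("list", config$n_gcms)
  names(gcms) <- paste0("GCM", seq_len(config$n_gcms))
  for (g in seq_len(config$n_gcms)) {
    t_pert <- matrix(0, nr, nc); p_fac <- matrix(1, nr, nc)
    if (config$gcm_noise_sd > 0) {
      f <- smooth_field(latm, lonm)
      t_pert <- config$gcm_noise_sd * f
      p_fac <- pmax(1 + 0.05 * config$gcm_noise_sd * smooth_field(latm, lonm), 0.2)
    }
    sl <- lapply(config$slices, function(s)
      monthly_climatology(month_clim(slice_dT[[s]], slice_prec_fac[[s]],
                                     t_pert, p_fac), template))
    names(sl) <- config$slices
    gcms[[g]] <- sl
  }

  truth_suit <- lapply(config$slices, function(s) {
    clim <- monthly_climatology(month_clim(slice_dT[[s]], slice_prec_fac[[s]],
                                           matrix(0, nr, nc), matrix(1, nr, nc)),
                                template)
    bio <- compute_bioclim(clim)
    suit <- stats::plogis(50 * (1 - ((bio$layers$BIO01 - 12) / 4)^2 -
                                  ((bio$layers$BIO12 - 816) / 1200)^2))
    mr_raster(suit, template$xmin, template$ymin, cs)
  })
  names(truth_suit) <- config$slices
  cutoff <- 0.5
  ref <- Reduce(`&`, lapply(truth_suit, function(r) r$values >= cutoff))
  truth <- list(true_suitability = truth_suit,
                true_refugia = mr_raster(ref + 0, template$xmin,
                                         template$ymin, cs),
                cutoff = cutoff)
  list(suite = structure(list(gcms = gcms, slices = config$slices,
                              template = template), class = "climate_suite"),
       truth = truth)
}

# standardized smooth random field: a few random Gaussian bumps, unit sd
smooth_field <- function(latm, lonm) {
  f <- matrix(0, nrow(latm), ncol(latm))
  for (b in 1:4) {
    c_lat <- stats::runif(1, min(latm), max(latm))
    c_lon <- stats::runif(1, min(lonm), max(lonm))
    amp <- stats::rnorm(1)
    f <- f + amp * exp(-((latm - c_lat)^2 + (lonm - c_lon)^2) / 80)
  }
  s <- stats::sd(f)
  if (s > 0) f <- f / s
  f - mean(f)
}

#' Sample occurrence records from a suitability surface
#'
#' Cells are drawn with probability proportional to suitability and
#' coordinates jittered uniformly within the drawn cell.
#'
#' @param suitability an `mr_raster` with non-negative values.
#' @param n number of records (>= 1).
#' @param seed optional integer seed.
#' @return data.frame with columns id, lat, lon.
#' @export
sample_occurrences <- function(suitability, n, seed = NULL) {
  if (n < 1) stop("n must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  w <- suitability$values
  w[is.na(w)] <- 0
  if (all(w <= 0)) stop("suitability is zero everywhere; cannot sample")
  idx <- sample.int(length(w), n, replace = TRUE, prob = as.vector(w))
  rc <- arrayInd(idx, dim(w))
  lat <- raster_lats(suitability)[rc[, 1]] +
    stats::runif(n, -0.5, 0.5) * suitability$cellsize
  lon <- raster_lons(suitability)[rc[, 2]] +
    stats::runif(n, -0.5, 0.5) * suitability$cellsize
  data.frame(id = paste0("occ", seq_len(n)), lat = lat, lon = lon)
}
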