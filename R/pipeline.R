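#' Pipeline configuration
#'
#' Collects every stage parameter with its study default: grid spacing
#' 100 km and pools of m = 5 with B = 1000 bootstraps for the diversity
#' grid, 50 km occurrence thinning, E = 0.01 partial ROC with 1000
#' bootstraps, 99% PCA variance target, 350 km calibration buffer, and
#' consensus fractions {1/G, 1/2, 3/4, 1}. Analysis sizes that only control
#' compute (occurrence subsets, maxent bootstrap replicates, permutation and
#' simulation counts) default to desk scale and can be raised to the full
#' protocol (10 subsets x 100 replicates, 999 permutations, 1000
#' simulations) through this object. Unknown keys are rejected.
#'
#' @param seed root seed; every stage derives its own substream from it.
#' @param sim a [sim_config()] for the synthetic stage.
#' @param out_dir artifact directory (NULL = no files written).
#' @param ... overrides of the defaults listed above.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, sim = NULL, out_dir = NULL, ...) {
  cfg <- list(
    seed = as.integer(seed),
    sim = sim %||% sim_config(seed = seed),
    out_dir = out_dir,
    spacing_km = 100, grid_m = 5, grid_B = 200,
    n_perm = 999, n_sims = 500,
    min_km = 50, n_subsets = 2, n_boot_reps = 3,
    buffer_km = 350, variance_target = 0.99,
    E = 0.01, roc_boot = 200, mop_alpha = 0.1,
    n_occurrences = 150,
    use_mop_mask = FALSE,
    fractions = c(0.25, 0.5, 0.75, 1))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

stage_seed <- function(cfg, stage) {
  offsets <- c(simulate = 11L, popgen = 23L, delimit = 37L, climate = 53L,
               enm = 71L, refugia = 89L)
  (cfg$seed * 1009L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order
#' (simulate -> popgen/delimit and simulate -> climate -> enm -> refugia) on
#' synthetic inputs, returning all intermediate objects plus a manifest that
#' echoes the resolved configuration and per-stage seeds. Identical
#' config + seed gives identical results. A stage whose inputs were not
#' produced earlier in the same call raises an error naming the stage to run
#' first.
#'
#' @param config a [pipeline_config()].
#' @param stages character vector among "simulate", "popgen", "delimit",
#'   "climate", "enm", "refugia"; order is normalized internally.
#' @return list of class `pipeline_run` with one element per executed stage
#'   and a `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "popgen", "delimit",
                                    "climate", "enm", "refugia")) {
  stopifnot(inherits(config, "pipeline_config"))
  order_all <- c("simulate", "popgen", "delimit", "climate", "enm", "refugia")
  stages <- order_all[order_all %in% match.arg(stages, order_all,
                                               several.ok = TRUE)]
  st <- list(manifest = list(seed = config$seed, stages = stages,
                             config = config[setdiff(names(config), "sim")],
                             timing = list()))
  need <- function(dep, stage) {
    if (is.null(st[[dep]]))
      stop(sprintf("stage '%s' needs artifacts from '%s'; run it first",
                   stage, dep))
  }
  for (stage in stages) {
    t0 <- proc.time()[["elapsed"]]
    sd <- stage_seed(config, stage)
    st[[stage]] <- switch(stage,
      simulate = {
        set.seed(sd)
        cfgs <- config$sim
        geo <- simulate_geo_dataset(cfgs)
        clim <- simulate_climate_suite(cfgs)
        occ <- sample_occurrences(clim$truth$true_suitability$present,
                                  config$n_occurrences)
        list(geo = geo$geo, truth = geo$truth, suite = clim$suite,
             climate_truth = clim$truth, occurrences = occ)
      },
      popgen = {
        need("simulate", "popgen")
        set.seed(sd)
        geo <- st$simulate$geo
        stats <- alignment_summary(geo)
        neut <- if (stats$S >= 1) list(
          Fs = neutrality_significance(fu_fs(stats), "Fs", stats$n, stats$S,
                                       n_sims = config$n_sims),
          R2 = neutrality_significance(r2_stat(stats), "R2", stats$n,
                                       stats$S, n_sims = config$n_sims))
          else NULL
        gen <- locality_distance_matrices(geo)
        mant <- tryCatch(
          mantel_ibd(gen, attr(gen, "geographic"), n_perm = config$n_perm),
          error = function(e) e)
        grid <- diversity_grid(geo, spacing = config$spacing_km,
                               m = config$grid_m, B = config$grid_B)
        list(summary = stats, neutrality = neut, mantel = mant,
             diversity = grid)
      },
      delimit = {
        need("simulate", "delimit")
        set.seed(sd)
        geo <- st$simulate$geo
        haps <- suppressWarnings(collapse_haplotypes(geo))
        lim95 <- connection_limit(geo$L, 0.95)
        lim99 <- connection_limit(geo$L, 0.99)
        tree <- st$simulate$truth$genealogies[[1]]
        gm <- tryCatch(gmyc_single_threshold(tree, fix_exponents = TRUE),
                       error = function(e) e)
        list(haplotypes = haps,
             networks95 = parsimony_networks(haps, lim95),
             networks99 = parsimony_networks(haps, lim99),
             gmyc = gm)
      },
      climate = {
        need("simulate", "climate")
        suite <- st$simulate$suite
        occ <- st$simulate$occurrences
        mask <- build_calibration_region(occ, suite$template,
                                         buffer_km = config$buffer_km)
        env <- lapply(suite$gcms, function(g) {
          bio <- lapply(g, compute_bioclim)
          pca <- fit_env_pca(bio$present, mask,
                             variance_target = config$variance_target)
          scores <- lapply(bio, function(b) project_env(pca, b))
          list(bioclim = bio, pca = pca, scores = scores)
        })
        list(mask = mask, env = env)
      },
      enm = {
        need("climate", "enm")
        set.seed(sd)
        suite <- st$simulate$suite
        occ <- st$simulate$occurrences
        mask <- st$climate$mask
        subsets <- thin_occurrences(occ, min_km = config$min_km,
                                    n_replicates = config$n_subsets)
        bg_cells <- which(as.vector(mask$values) == 1)
        out <- lapply(names(suite$gcms), function(gname) {
          env <- st$climate$env[[gname]]
          bg <- env$scores$present[bg_cells, , drop = FALSE]
          fits <- lapply(subsets, function(ss) {
            rc <- raster_cell_of(mask, ss$lat, ss$lon)
            pres <- env$scores$present[(rc[, 2] - 1) *
                                         nrow(mask$values) + rc[, 1], ,
                                       drop = FALSE]
            fit_maxent(pres, bg, n_boot_reps = config$n_boot_reps)
          })
          suits <- lapply(suite$slices, function(s) predict_and_aggregate(
            lapply(fits, function(f) maxent_predict(f, env$scores[[s]])),
            suite$template))
          names(suits) <- suite$slices
          # threshold from the present-day (training) surface, applied to
          # every slice
          tau <- attr(mtp_binarize(suits$present, occ), "tau")
          per_slice <- lapply(suite$slices, function(s) {
            bin <- threshold_binarize(suits[[s]], tau)
            mop <- mop_mask(bg, env$scores[[s]], alpha = config$mop_alpha,
                            binary = bin)
            list(suitability = suits[[s]], binary = bin,
                 masked = mop$masked, mop = mop)
          })
          names(per_slice) <- suite$slices
          # paper-style evaluation: half of the first subset calibrates a
          # model, the other half tests it by partial ROC
          ss <- subsets[[1]]
          half <- sample.int(nrow(ss), nrow(ss) %/% 2)
          rc <- raster_cell_of(mask, ss$lat[half], ss$lon[half])
          tr_sc <- env$scores$present[(rc[, 2] - 1) * nrow(mask$values) +
                                        rc[, 1], , drop = FALSE]
          evfit <- fit_maxent(tr_sc, bg, n_boot_reps = 1)
          evsuit <- predict_and_aggregate(
            list(maxent_predict(evfit, env$scores$present)), suite$template)
          proc <- tryCatch(
            partial_roc(evsuit, ss[-half, , drop = FALSE], E = config$E,
                        n_boot = config$roc_boot),
            error = function(e) e)
          list(fits = fits, slices = per_slice, tau = tau,
               partial_roc = proc)
        })
        names(out) <- names(suite$gcms)
        list(subsets = subsets, gcms = out)
      },
      refugia = {
        need("enm", "refugia")
        layer <- if (config$use_mop_mask) "masked" else "binary"
        ens <- lapply(st$enm$gcms, function(g)
          lapply(g$slices, `[[`, layer))
        scen <- list()
        for (m in c("M1", "M2")) for (f in config$fractions)
          scen[[sprintf("%s_f%.2f", m, f)]] <-
            delimit_refugia(ens, method = m, fraction = f)
        list(ensemble = ens, scenarios = scen)
      })
    st$manifest$timing[[stage]] <- proc.time()[["elapsed"]] - t0
    st$manifest$seeds[[stage]] <- sd
  }
  if (!is.null(config$out_dir)) write_pipeline_artifacts(st, config)
  class(st) <- "pipeline_run"
  st
}

write_pipeline_artifacts <- function(st, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(config$out_dir, ...)
  if (!is.null(st$simulate)) {
    write_geo_alignment(st$simulate$geo, p("alignment.fasta"),
                        p("samples.csv"))
    ape::write.tree(st$simulate$truth$genealogies[[1]], p("genealogy.nwk"))
    utils::write.csv(st$simulate$occurrences, p("occurrences.csv"),
                     row.names = FALSE)
    write_ascii_grid(st$simulate$climate_truth$true_refugia,
                     p("true_refugia.asc"))
  }
  if (!is.null(st$popgen)) {
    s <- st$popgen$summary
    utils::write.csv(data.frame(n = s$n, sites = s$L_eff, S = s$S, H = s$H,
                                Hd = s$Hd, pi = s$pi, kbar = s$kbar),
                     p("summary_stats.csv"), row.names = FALSE)
    utils::write.csv(st$popgen$diversity, p("diversity_grid.csv"),
                     row.names = FALSE)
  }
  if (!is.null(st$delimit) && !inherits(st$delimit$gmyc, "error")) {
    g <- st$delimit$gmyc
    jsonlite::write_json(list(threshold_age = g$threshold_age,
                              entities = g$entities, clusters = g$clusters,
                              LR = g$LR, p = g$p,
                              ci_entities = g$ci_entities),
                         p("gmyc.json"), digits = NA, auto_unbox = TRUE)
    write_network(st$delimit$networks95, p("network95_edges.csv"))
  }
  if (!is.null(st$refugia)) {
    for (nm in names(st$refugia$scenarios)) {
      sc <- st$refugia$scenarios[[nm]]
      write_ascii_grid(sc$result, p(paste0("refugia_", nm, ".asc")))
      utils::write.csv(sc$components, p(paste0("refugia_", nm, ".csv")),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(st$manifest, file.path(config$out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE)
  invisible(config$out_dir)
}
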