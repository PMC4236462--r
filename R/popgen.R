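#' Geo-referenced alignment
#'
#' Joins an alignment to its sample table; the universal input of the
#' molecular arm. Sequences are IUPAC characters; anything other than
#' A/C/G/T (case-insensitive) is treated as unresolved (missing) by the
#' downstream statistics.
#'
#' @param seqs character matrix (samples x sites), row names = sample ids,
#'   or a named character vector of equal-length sequence strings.
#' @param samples data.frame with columns id, locality, lat, lon and an
#'   optional lineage column; one row per sequence.
#' @return an object of class `geo_alignment` with fields `seq`, `samples`,
#'   `L`.
#' @export
geo_alignment <- function(seqs, samples) {
  if (is.character(seqs) && is.null(dim(seqs)))
    seqs <- do.call(rbind, lapply(strsplit(toupper(seqs), ""), identity))
  stopifnot(is.matrix(seqs), nrow(seqs) >= 1)
  if (is.null(rownames(seqs))) stop("sequences must carry sample ids")
  if (!all(c("id", "locality", "lat", "lon") %in% names(samples)))
    stop("samples needs columns id, locality, lat, lon")
  if (!setequal(rownames(seqs), samples$id))
    stop("sequence ids and sample ids do not match")
  if (any(samples$lat < -90 | samples$lat > 90) ||
      any(samples$lon < -180 | samples$lon > 180))
    stop("coordinates out of range")
  samples <- samples[match(rownames(seqs), samples$id), , drop = FALSE]
  structure(list(seq = toupper(seqs), samples = samples, L = ncol(seqs)),
            class = "geo_alignment")
}

#' @export
print.geo_alignment <- function(x, ...) {
  cat(sprintf("geo_alignment: %d samples x %d sites, %d localities\n",
              nrow(x$seq), x$L, length(unique(x$samples$locality))))
  invisible(x)
}

seq_matrix <- function(x) {
  if (inherits(x, "geo_alignment")) x$seq
  else if (is.matrix(x)) toupper(x)
  else stop("expected a geo_alignment or character matrix")
}

# integer codes 1..4 for A,C,G,T; NA for gaps/N/ambiguity codes
code_matrix <- function(m) {
  cm <- matrix(match(m, c("A", "C", "G", "T")), nrow(m), ncol(m),
               dimnames = dimnames(m))
  cm
}

#' Collapse identical sequences into haplotypes
#'
#' Samples are grouped into identical-sequence classes. Sites that are not
#' A/C/G/T (gaps, N, ambiguity codes) are unresolved; two sequences are
#' compatible when they agree at all mutually resolved sites. Fully resolved
#' sequences collapse exactly; a partially resolved sequence joins the unique
#' compatible class, becomes its own class when none is compatible, and under
#' the default strict policy is excluded with a warning when several classes
#' are compatible (the merge would be ambiguous). Under `"lenient"` it joins
#' the largest compatible class. Sequences with no resolved site at all are
#' always unassignable.
#'
#' @param aln a [geo_alignment()] or character matrix.
#' @param ambiguous_policy "strict" (default) or "lenient".
#' @return list of class `haplotype_table`: `haplotypes` (data.frame with
#'   representative sequence and count), `members` (list of sample-id
#'   vectors), `hap_of` (named vector sample -> haplotype index), `excluded`
#'   (unassignable sample ids), `n`, `H`.
#' @export
collapse_haplotypes <- function(aln, ambiguous_policy = c("strict", "lenient")) {
  ambiguous_policy <- match.arg(ambiguous_policy)
  m <- seq_matrix(aln)
  if (nrow(m) == 0) stop("empty alignment")
  cm <- code_matrix(m)
  resolved <- !is.na(cm)
  full <- rowSums(resolved) == ncol(cm)
  reps <- list(); members <- list()
  key <- unname(apply(m, 1, paste, collapse = ""))
  for (i in which(full)) {
    hit <- which(vapply(reps, function(r) key[r] == key[i], logical(1)))
    if (length(hit) == 1) members[[hit]] <- c(members[[hit]], i)
    else { reps[[length(reps) + 1]] <- i; members[[length(members) + 1]] <- i }
  }
  excluded <- integer(0)
  for (i in which(!full)) {
    if (!any(resolved[i, ])) { excluded <- c(excluded, i); next }
    compat <- which(vapply(reps, function(r) {
      both <- resolved[i, ] & resolved[r, ]
      all(cm[i, both] == cm[r, both])
    }, logical(1)))
    if (length(compat) == 1) {
      members[[compat]] <- c(members[[compat]], i)
    } else if (length(compat) == 0) {
      reps[[length(reps) + 1]] <- i
      members[[length(members) + 1]] <- i
    } else if (ambiguous_policy == "lenient") {
      big <- compat[which.max(lengths(members)[compat])]
      members[[big]] <- c(members[[big]], i)
    } else excluded <- c(excluded, i)
  }
  if (length(excluded))
    warning(sprintf("%d sequence(s) unassignable under the strict policy: %s",
                    length(excluded),
                    paste(rownames(m)[excluded], collapse = ", ")))
  ids <- rownames(m)
  hap_of <- stats::setNames(rep(NA_integer_, nrow(m)), ids)
  for (h in seq_along(members)) hap_of[members[[h]]] <- h
  structure(list(
    haplotypes = data.frame(haplotype = seq_along(reps),
                            sequence = key[unlist(reps)],
                            count = lengths(members)),
    members = lapply(members, function(ix) ids[ix]),
    hap_of = hap_of[!is.na(hap_of)],
    excluded = ids[excluded],
    n = nrow(m) - length(excluded), H = length(reps)),
    class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("haplotype_table: %d haplotypes among %d samples", x$H, x$n))
  if (length(x$excluded)) cat(sprintf(" (%d excluded)", length(x$excluded)))
  cat("\n"); invisible(x)
}

#' Pairwise p-distances with pairwise deletion
#'
#' Proportion of differing sites over the sites resolved in both sequences
#' of a pair (MEGA-style pairwise deletion). Pairs without any comparable
#' site get `NA`. With `groups`, mean between- and within-group distances
#' are attached (arithmetic means of the relevant pairwise entries).
#'
#' @param aln a [geo_alignment()] or character matrix.
#' @param groups optional factor/character vector, one label per sequence.
#' @return symmetric matrix of proportions; attributes `between` and
#'   `within` when `groups` is given.
#' @export
p_distance_matrix <- function(aln, groups = NULL) {
  cm <- code_matrix(seq_matrix(aln))
  n <- nrow(cm)
  if (n < 2) stop("need at least two sequences")
  D <- matrix(0, n, n, dimnames = list(rownames(cm), rownames(cm)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    both <- !is.na(cm[i, ]) & !is.na(cm[j, ])
    nc <- sum(both)
    D[i, j] <- D[j, i] <- if (nc == 0) NA_real_
      else sum(cm[i, both] != cm[j, both]) / nc
  }
  if (!is.null(groups)) {
    g <- as.character(groups)
    lv <- unique(g)
    B <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
    for (a in seq_along(lv)) for (b in seq_len(a)) {
      sub <- D[g == lv[a], g == lv[b], drop = FALSE]
      vals <- if (a == b) sub[lower.tri(sub)] else as.vector(sub)
      B[a, b] <- B[b, a] <- mean(vals, na.rm = TRUE)
    }
    attr(D, "between") <- B
    attr(D, "within") <- diag(B)
  }
  D
}

#' Diversity summary of an alignment
#'
#' DnaSP-style summary under complete deletion (default): sites with any
#' unresolved base are removed before computing segregating sites, haplotype
#' and nucleotide diversity. Hd uses the small-sample correction
#' n(1 - sum p_i^2)/(n - 1); pi is the mean per-site pairwise difference on
#' the retained sites; kbar = pi * L_eff is the mean pairwise difference per
#' locus; U_i counts singleton mutations (alleles of count one) carried by
#' sequence i.
#'
#' @param aln a [geo_alignment()] or character matrix.
#' @param deletion "complete" (default) or "none" (use all sites; unresolved
#'   bases simply never count as differences or alleles).
#' @return list of class `summary_stats` with n, L_eff, S, H, Hd, pi, kbar, U.
#' @export
alignment_summary <- function(aln, deletion = c("complete", "none")) {
  deletion <- match.arg(deletion)
  cm <- code_matrix(seq_matrix(aln))
  n <- nrow(cm)
  if (n < 2) stop("need at least two sequences")
  if (deletion == "complete") cm <- cm[, colSums(is.na(cm)) == 0, drop = FALSE]
  L_eff <- ncol(cm)
  if (L_eff == 0) stop("no sites left after complete deletion")
  nalle <- apply(cm, 2, function(col) length(unique(col[!is.na(col)])))
  S <- sum(nalle > 1)
  key <- apply(cm, 1, paste, collapse = ".")
  counts <- table(key)
  H <- length(counts)
  p <- as.numeric(counts) / n
  Hd <- n * (1 - sum(p^2)) / (n - 1)
  # pairwise differences per site from allele counts: (n^2 - sum c_a^2)/2
  diffs <- apply(cm, 2, function(col) {
    col <- col[!is.na(col)]
    (length(col)^2 - sum(table(col)^2)) / 2
  })
  npair <- n * (n - 1) / 2
  kbar <- sum(diffs) / npair
  U <- rep(0, n); names(U) <- rownames(cm)
  for (s in which(nalle > 1)) {
    tab <- table(cm[, s])
    singles <- as.integer(names(tab)[tab == 1])
    for (a in singles) U[which(cm[, s] == a)] <- U[which(cm[, s] == a)] + 1
  }
  structure(list(n = n, L_eff = L_eff, S = S, H = H, Hd = Hd,
                 pi = kbar / L_eff, kbar = kbar, U = U),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("n=%d  sites=%d  S=%d  H=%d  Hd=%.3f  pi=%.5f  kbar=%.3f\n",
              x$n, x$L_eff, x$S, x$H, x$Hd, x$pi, x$kbar))
  invisible(x)
}

# log unsigned Stirling numbers of the first kind, row n: log|s(n, 1..n)|
log_stirling_row <- function(n) {
  ls <- 0 # row 1: s(1,1)=1
  for (i in 2:n) {
    prev <- ls
    k <- seq_len(i)
    lower <- c(-Inf, prev)           # |s(i-1, k-1)|
    upper <- c(prev, -Inf) + log(i - 1) # (i-1)|s(i-1, k)|
    m <- pmax(lower, upper)
    ls <- m + log(exp(lower - m) + exp(upper - m))
    ls[is.nan(ls)] <- -Inf
  }
  ls
}

#' Fu's Fs statistic
#'
#' Given the mean pairwise difference kbar (the theta estimate) and the
#' observed haplotype count H, computes S' = Pr(K >= H | theta = kbar, n)
#' under the Ewens sampling formula, with unsigned Stirling numbers of the
#' first kind evaluated in log space, and returns Fs = ln(S'/(1 - S')).
#' Large negative values indicate an excess of haplotypes relative to
#' neutrality (demographic expansion).
#'
#' @param stats a `summary_stats` object from [alignment_summary()], or a
#'   list with n, kbar, H, S.
#' @return numeric Fs; +/-Inf (with a warning) when S' reaches 1 or 0
#'   numerically.
#' @export
fu_fs <- function(stats) {
  if (stats$S < 1) stop("Fs is undefined when there are no segregating sites")
  fs_from_ewens(stats$n, stats$kbar, stats$H, log_stirling_row(stats$n))
}

fs_from_ewens <- function(n, theta, H, ls_row) {
  if (theta <= 0) stop("theta (kbar) must be positive")
  denom <- sum(log(theta + 0:(n - 1)))
  logpk <- ls_row + seq_len(n) * log(theta) - denom
  # S' = P(K >= H); complement sum in log space for stability
  lse <- function(v) { m <- max(v); if (!is.finite(m)) -Inf else m + log(sum(exp(v - m))) }
  logS <- lse(logpk[H:n])
  logS_c <- if (H == 1) -Inf else lse(logpk[1:(H - 1)])
  if (logS_c == -Inf) { warning("S' = 1; Fs is +Inf"); return(Inf) }
  if (logS == -Inf) { warning("S' = 0; Fs is -Inf"); return(-Inf) }
  logS - logS_c # ln(S'/(1-S'))
}

#' Ramos-Onsins & Rozas R2 statistic
#'
#' R2 = sqrt(mean((U_i - kbar/2)^2)) / S, where U_i is the number of
#' singleton mutations carried by sequence i. Low values indicate an excess
#' of singletons relative to pairwise diversity (population growth).
#'
#' @inheritParams fu_fs
#' @return numeric R2.
#' @export
r2_stat <- function(stats) {
  if (stats$S < 1) stop("R2 is undefined when there are no segregating sites")
  sqrt(mean((stats$U - stats$kbar / 2)^2)) / stats$S
}

# One fixed-S coalescent replicate: kbar, H, U for n samples and S mutations
sim_fixed_s_stats <- function(n, S) {
  tree <- ape::rcoal(n)
  edge_of <- sample.int(nrow(tree$edge), S, replace = TRUE,
                        prob = tree$edge.length)
  tips_below <- edge_tip_sets(tree)
  carriers <- lapply(edge_of, function(e) tips_below[[e]])
  cnt <- lengths(carriers)
  kbar <- sum(cnt * (n - cnt)) / (n * (n - 1) / 2)
  inc <- matrix(0L, n, S)
  for (s in seq_len(S)) inc[carriers[[s]], s] <- 1L
  H <- length(unique(apply(inc, 1, paste, collapse = "")))
  U <- rep(0, n)
  for (s in which(cnt == 1)) U[carriers[[s]]] <- U[carriers[[s]]] + 1
  list(kbar = kbar, H = H, U = U)
}

#' Coalescent-simulation significance for neutrality statistics
#'
#' Simulates `n_sims` standard-coalescent genealogies conditioned on exactly
#' `S` mutations (multinomial placement proportional to branch length),
#' recomputes the chosen statistic on each, and reports the left-tail
#' probability p = (1 + #[sim <= observed])/(n_sims + 1), the complementary
#' right tail, and the empirical 95% interval of the null distribution.
#'
#' @param observed observed statistic value.
#' @param statistic "Fs" or "R2".
#' @param n sample size (>= 3).
#' @param S segregating sites (>= 1).
#' @param n_sims number of coalescent replicates.
#' @param seed optional integer seed.
#' @return list of class `neutrality_result`.
#' @export
neutrality_significance <- function(observed, statistic = c("Fs", "R2"),
                                    n, S, n_sims = 1000, seed = NULL) {
  statistic <- match.arg(statistic)
  if (n < 3) stop("need n >= 3")
  if (S < 1) stop("need S >= 1")
  if (!is.null(seed)) set.seed(seed)
  ls_row <- if (statistic == "Fs") log_stirling_row(n) else NULL
  sims <- vapply(seq_len(n_sims), function(b) {
    st <- sim_fixed_s_stats(n, S)
    if (statistic == "Fs")
      suppressWarnings(fs_from_ewens(n, st$kbar, st$H, ls_row))
    else sqrt(mean((st$U - st$kbar / 2)^2)) / S
  }, numeric(1))
  p <- (1 + sum(sims <= observed)) / (n_sims + 1)
  p_upper <- (1 + sum(sims >= observed)) / (n_sims + 1)
  ci <- stats::quantile(sims, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
  structure(list(statistic = statistic, value = observed, p = p,
                 p_upper = p_upper, ci95 = ci, n_sims = n_sims, seed = seed,
                 sims = sims),
            class = "neutrality_result")
}

#' @export
print.neutrality_result <- function(x, ...) {
  cat(sprintf("%s = %.3f, left-tail p = %.4g (95%% null CI %.3f..%.3f, %d sims)\n",
              x$statistic, x$value, x$p, x$ci95[1], x$ci95[2], x$n_sims))
  invisible(x)
}

haversine_km <- function(lat1, lon1, lat2, lon2, R = 6371) {
  to <- pi / 180
  dlat <- (lat2 - lat1) * to; dlon <- (lon2 - lon1) * to
  a <- sin(dlat / 2)^2 + cos(lat1 * to) * cos(lat2 * to) * sin(dlon / 2)^2
  2 * R * asin(pmin(1, sqrt(a)))
}

#' Great-circle distance matrix (km)
#'
#' Haversine distances on a sphere of radius 6371 km.
#'
#' @param points data.frame with columns lat, lon (degrees), optionally an
#'   id/locality column used for labels.
#' @return symmetric matrix of distances in km.
#' @export
great_circle_matrix <- function(points) {
  if (any(points$lat < -90 | points$lat > 90) ||
      any(points$lon < -180 | points$lon > 180))
    stop("invalid coordinates")
  n <- nrow(points)
  lab <- if (!is.null(points$locality)) as.character(points$locality)
         else if (!is.null(points$id)) as.character(points$id)
         else as.character(seq_len(n))
  D <- matrix(0, n, n, dimnames = list(lab, lab))
  for (i in seq_len(n))
    D[i, ] <- haversine_km(points$lat[i], points$lon[i], points$lat, points$lon)
  D[cbind(seq_len(n), seq_len(n))] <- 0
  (D + t(D)) / 2
}

#' Mantel test of isolation by distance
#'
#' Pearson correlation between the upper triangles of a genetic and a
#' geographic distance matrix, the latter log-transformed by default (zero
#' distances are replaced by half the smallest positive distance before the
#' log). Significance comes from simultaneous row/column permutations:
#' p = (1 + #[r_perm >= r_obs])/(n_perm + 1). Refuses matrices of fewer than
#' five localities, mirroring the exclusion rule used for sparsely sampled
#' lineages.
#'
#' @param genetic,geographic conformable symmetric distance matrices.
#' @param n_perm number of permutations (default 999).
#' @param seed optional integer seed.
#' @param log_geo log-transform the geographic matrix (default TRUE).
#' @return list of class `mantel_result` with r, p, n_perm.
#' @export
mantel_ibd <- function(genetic, geographic, n_perm = 999, seed = NULL,
                       log_geo = TRUE) {
  if (!all(dim(genetic) == dim(geographic)))
    stop("matrices are not conformable")
  n <- nrow(genetic)
  if (n < 5) stop("Mantel test refused: fewer than five localities")
  if (!is.null(seed)) set.seed(seed)
  G <- geographic
  if (log_geo) {
    pos <- G[G > 0]
    if (length(pos) == 0) stop("geographic distances are all zero (degenerate)")
    G[G == 0] <- min(pos) / 2
    G <- log(G)
  }
  ut <- upper.tri(genetic)
  x <- genetic[ut]
  if (stats::sd(x) == 0 || stats::sd(G[ut]) == 0)
    stop("constant distance matrix: correlation undefined")
  r_obs <- stats::cor(x, G[ut])
  r_perm <- vapply(seq_len(n_perm), function(b) {
    ix <- sample.int(n)
    stats::cor(x, G[ix, ix][ut])
  }, numeric(1))
  p <- (1 + sum(r_perm >= r_obs)) / (n_perm + 1)
  structure(list(r = r_obs, p = p, n_perm = n_perm), class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel r = %.3f, p = %.4g (%d permutations)\n",
              x$r, x$p, x$n_perm))
  invisible(x)
}

#' Genetic distance matrix between localities
#'
#' Mean pairwise p-distance between the sequences of each pair of localities
#' (within-locality mean on the diagonal region is not used by the Mantel
#' test). Convenience for [mantel_ibd()].
#'
#' @param geoaln a [geo_alignment()].
#' @return symmetric matrix labelled by locality, plus the matching
#'   geographic matrix as attribute `geographic`.
#' @export
locality_distance_matrices <- function(geoaln) {
  stopifnot(inherits(geoaln, "geo_alignment"))
  D <- p_distance_matrix(geoaln)
  loc <- geoaln$samples$locality
  lv <- sort(unique(loc))
  Gn <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
  for (a in seq_along(lv)) for (b in seq_len(a)) {
    sub <- D[loc == lv[a], loc == lv[b], drop = FALSE]
    vals <- if (a == b) sub[lower.tri(sub)] else as.vector(sub)
    Gn[a, b] <- Gn[b, a] <- if (length(vals)) mean(vals, na.rm = TRUE) else 0
  }
  diag(Gn) <- 0
  coords <- unique(geoaln$samples[, c("locality", "lat", "lon")])
  coords <- coords[match(lv, coords$locality), ]
  attr(Gn, "geographic") <- great_circle_matrix(coords)
  Gn
}

#' Grid-based bootstrap diversity and rarity mapping
#'
#' Lays grid points every `spacing` km in latitude and longitude over the
#' sampled area; at each point, the samples within `radius` km form a pool.
#' Pools of at least `m` samples are bootstrapped `B` times with subsamples
#' of size `m` drawn without replacement; each draw yields total haplotype
#' diversity H_T (with small-sample correction), haplotype richness H_R
#' (distinct haplotypes in the draw) and the rarity index R (mean over drawn
#' individuals of 1/number of localities occupied by their haplotype,
#' dataset-wide). Bootstrap means are reported; under-sampled points are
#' flagged missing.
#'
#' @param geoaln a [geo_alignment()].
#' @param spacing grid spacing in km (default 100).
#' @param radius pool radius in km (default = spacing).
#' @param m subsample size (>= 2, default 5).
#' @param B bootstrap draws (default 1000).
#' @param seed optional integer seed.
#' @return data.frame of class `diversity_grid` with lat, lon, n_available,
#'   HT_mean, HR_mean, R_mean, missing.
#' @export
diversity_grid <- function(geoaln, spacing = 100, radius = spacing, m = 5,
                           B = 1000, seed = NULL) {
  stopifnot(inherits(geoaln, "geo_alignment"))
  if (m < 2) stop("m must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  haps <- collapse_haplotypes(geoaln)
  smp <- geoaln$samples[geoaln$samples$id %in% names(haps$hap_of), ]
  hap <- haps$hap_of[smp$id]
  loc_per_hap <- vapply(seq_len(haps$H), function(h)
    length(unique(smp$locality[hap == h])), integer(1))
  rarity <- 1 / pmax(loc_per_hap, 1)
  dlat <- spacing / 111.32
  lat_pts <- seq(min(smp$lat), max(smp$lat) + dlat, by = dlat)
  rows <- list()
  for (la in lat_pts) {
    dlon <- spacing / (111.32 * max(cos(la * pi / 180), 0.05))
    lon_pts <- seq(min(smp$lon), max(smp$lon) + dlon, by = dlon)
    for (lo in lon_pts) {
      d <- haversine_km(la, lo, smp$lat, smp$lon)
      pool <- which(d <= radius)
      if (length(pool) < m) {
        rows[[length(rows) + 1]] <- data.frame(
          lat = la, lon = lo, n_available = length(pool),
          HT_mean = NA_real_, HR_mean = NA_real_, R_mean = NA_real_,
          missing = TRUE)
        next
      }
      ht <- hr <- rr <- numeric(B)
      for (b in seq_len(B)) {
        draw <- hap[pool[sample.int(length(pool), m)]]
        tab <- tabulate(draw, nbins = haps$H)
        p <- tab[tab > 0] / m
        ht[b] <- m * (1 - sum(p^2)) / (m - 1)
        hr[b] <- length(p)
        rr[b] <- mean(rarity[draw])
      }
      rows[[length(rows) + 1]] <- data.frame(
        lat = la, lon = lo, n_available = length(pool),
        HT_mean = mean(ht), HR_mean = mean(hr), R_mean = mean(rr),
        missing = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "params") <- list(spacing = spacing, radius = radius, m = m, B = B)
  class(out) <- c("diversity_grid", "data.frame")
  out
}
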