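#' Statistical-parsimony connection limit
#'
#' The maximum number of mutational steps between two haplotypes for which a
#' parsimonious relationship (no multiple substitutions underlying any single
#' nucleotide difference) holds with the stated probability. The cumulative
#' parsimony probability after j steps is operationalized as
#' P_j = prod_{i=1..j} (1 - i/(2L)); the i-th additional substitution on the
#' 2L site-lineage copies of the two diverging sequences must avoid the i
#' sites already hit. The limit is the largest j with P_j >= confidence. For
#' an alignment of 1016 sites this yields 13 steps at 95% and 5 steps at 99%.
#'
#' @param L alignment length in sites (>= 1).
#' @param confidence probability in (0, 1); conventionally 0.95 or 0.99.
#' @return list of class `connection_limit` with L, confidence, max_steps
#'   and the cumulative probability at the limit.
#' @export
connection_limit <- function(L, confidence = 0.95) {
  if (L < 1) stop("L must be at least 1")
  if (confidence <= 0 || confidence >= 1) stop("confidence must be in (0, 1)")
  j <- 0L; P <- 1
  repeat {
    q <- 1 - (j + 1) / (2 * L)
    if (q <= 0 || P * q < confidence) break
    P <- P * q
    j <- j + 1L
  }
  structure(list(L = L, confidence = confidence, max_steps = j, prob = P),
            class = "connection_limit")
}

#' @export
print.connection_limit <- function(x, ...) {
  cat(sprintf("connection limit: %d steps at %.0f%% for L = %d (P = %.4f)\n",
              x$max_steps, 100 * x$confidence, x$L, x$prob))
  invisible(x)
}

# mutational steps between haplotype representatives; gaps/N treated as
# missing (pairwise deletion). Returns an integer matrix.
hap_step_matrix <- function(haps) {
  m <- do.call(rbind, strsplit(haps$haplotypes$sequence, ""))
  cm <- code_matrix(m)
  H <- nrow(cm)
  D <- matrix(0L, H, H)
  if (H > 1) for (i in seq_len(H - 1)) for (j in (i + 1):H) {
    both <- !is.na(cm[i, ]) & !is.na(cm[j, ])
    D[i, j] <- D[j, i] <- sum(cm[i, both] != cm[j, both])
  }
  D
}

#' Statistical-parsimony haplotype networks
#'
#' Connects haplotypes at mutational distance 1, 2, ... up to the connection
#' limit. At each distance level, all pairs at that distance whose components
#' were distinct at the start of the level are joined, so alternative
#' equal-length connections (loops) are retained. The resulting connected
#' components are the putative evolutionary units.
#'
#' @param haps a `haplotype_table` from [collapse_haplotypes()].
#' @param limit a [connection_limit()] (or an integer step count).
#' @return list of class `parsimony_networks`: `nodes` (haplotype, count),
#'   `edges` (h1, h2, steps), `components` (list of haplotype-index
#'   vectors), `max_steps`.
#' @export
parsimony_networks <- function(haps, limit) {
  stopifnot(inherits(haps, "haplotype_table"))
  max_steps <- if (inherits(limit, "connection_limit")) limit$max_steps
               else as.integer(limit)
  H <- haps$H
  D <- hap_step_matrix(haps)
  comp <- seq_len(H)
  edges <- NULL
  for (d in seq_len(max_steps)) {
    if (H < 2) break
    at_d <- which(D == d & upper.tri(D), arr.ind = TRUE)
    if (nrow(at_d) == 0) next
    comp_at_start <- comp
    for (k in seq_len(nrow(at_d))) {
      i <- at_d[k, 1]; j <- at_d[k, 2]
      if (comp_at_start[i] != comp_at_start[j]) {
        edges <- rbind(edges, data.frame(h1 = i, h2 = j, steps = d))
        comp[comp == comp[j]] <- comp[i]
      }
    }
  }
  components <- unname(split(seq_len(H), comp))
  structure(list(nodes = haps$haplotypes[, c("haplotype", "count")],
                 edges = if (is.null(edges))
                   data.frame(h1 = integer(), h2 = integer(),
                              steps = integer()) else edges,
                 components = components, max_steps = max_steps),
            class = "parsimony_networks")
}

#' @export
print.parsimony_networks <- function(x, ...) {
  cat(sprintf("parsimony networks: %d haplotypes in %d network(s), limit %d steps\n",
              nrow(x$nodes), length(x$components), x$max_steps))
  invisible(x)
}

# --- GMYC -------------------------------------------------------------------

# Interval bookkeeping for one threshold age T on an ultrametric tree.
# Returns, per inter-event interval: waiting time x, number of
# between-cluster (Yule) lineages nY, and the list of within-cluster lineage
# counts. Intervals run between successive branching events.
gmyc_intervals <- function(tree, ages, T) {
  ntip <- ape::Ntip(tree)
  node_age <- c(rep(0, ntip), ages[order(as.integer(names(ages)))])
  names(node_age) <- NULL
  ev <- sort(unique(ages), decreasing = TRUE)
  if (length(ev) < 2) return(NULL)
  # cluster root of each node: deepest ancestor chain of nodes with age <= T
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ntip + 1
  cluster_of <- integer(ntip + tree$Nnode) # 0 = none (Yule side)
  pre <- ape::reorder.phylo(tree, "cladewise")
  order_nodes <- c(root, pre$edge[, 2])
  for (v in order_nodes) {
    if (node_age[v] > T) { cluster_of[v] <- 0L; next }
    p <- if (v == root) 0L else parent[v]
    if (v == root || node_age[p] > T) cluster_of[v] <- v    # cluster root
    else cluster_of[v] <- cluster_of[p]
  }
  n_int <- length(ev) - 1
  out <- vector("list", n_int)
  e_par <- tree$edge[, 1]; e_chl <- tree$edge[, 2]
  ap <- node_age[e_par]; ac <- node_age[e_chl]
  for (i in seq_len(n_int)) {
    hi <- ev[i]; lo <- ev[i + 1]
    span <- ap >= hi - 1e-12 & ac <= lo + 1e-12
    yule <- span & node_age[e_par] > T
    within <- span & !yule
    cl <- cluster_of[e_par[within]]
    out[[i]] <- list(x = hi - lo, nY = sum(yule),
                     ncl = if (any(within)) as.integer(table(cl)) else integer(0))
  }
  out
}

gmyc_loglik <- function(ints, la1, la2, p1, p2) {
  ll <- 0
  for (it in ints) {
    A <- if (it$nY > 0) it$nY^p1 else 0
    B <- if (length(it$ncl)) sum((it$ncl * (it$ncl - 1))^p2) else 0
    b <- la1 * A + la2 * B
    if (b <= 0) return(-Inf)
    ll <- ll + log(b) - b * it$x
  }
  ll
}

# maximize gmyc_loglik over rates (and exponents unless fixed)
gmyc_fit_threshold <- function(ints, fix_exponents) {
  nev <- length(ints)
  xtot <- sum(vapply(ints, `[[`, numeric(1), "x"))
  la0 <- max(nev / max(xtot, 1e-9), 1e-3)
  obj <- function(par) {
    la1 <- exp(par[1]); la2 <- exp(par[2])
    p1 <- if (fix_exponents) 1 else exp(par[3])
    p2 <- if (fix_exponents) 1 else exp(par[4])
    -gmyc_loglik(ints, la1, la2, p1, p2)
  }
  starts <- list(c(log(la0), log(la0)), c(log(la0 / 4), log(la0 * 4)),
                 c(log(la0 * 4), log(la0 / 4)))
  best <- NULL
  for (s in starts) {
    par0 <- if (fix_exponents) s else c(s, 0, 0)
    lim <- if (fix_exponents) rep(20, 2) else c(20, 20, log(3), log(3))
    fit <- tryCatch(
      stats::optim(par0, obj, method = "L-BFGS-B", lower = -lim, upper = lim),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) return(list(loglik = -Inf))
  list(loglik = -best$value, par = best$par)
}

# null single-process likelihood b = lambda * n^p over the same intervals
gmyc_null_fit <- function(tree, ages, fix_exponents) {
  ev <- sort(unique(ages), decreasing = TRUE)
  n_int <- length(ev) - 1
  x <- ev[-length(ev)] - ev[-1]
  nlin <- 1 + seq_len(n_int) # after i-th event, i+1 lineages
  prof <- function(p) {
    A <- nlin^p
    la <- n_int / sum(A * x)
    sum(log(la * A) - la * A * x)
  }
  if (fix_exponents) list(loglik = prof(1), p = 1)
  else {
    op <- stats::optimize(function(lp) -prof(exp(lp)), c(log(0.05), log(3)))
    list(loglik = -op$objective, p = exp(op$minimum))
  }
}

gmyc_entities <- function(tree, ages, T) {
  ntip <- ape::Ntip(tree)
  node_age <- c(rep(0, ntip), ages[order(as.integer(names(ages)))])
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ntip + 1
  internal <- (ntip + 1):(ntip + tree$Nnode)
  pa <- parent[internal]
  pa_age <- ifelse(pa == 0, Inf, node_age[pmax(pa, 1)]) # root: no parent
  cl_roots <- internal[node_age[internal] <= T & pa_age > T]
  singletons <- sum(node_age[parent[seq_len(ntip)]] > T)
  list(clusters = length(cl_roots), singletons = singletons,
       entities = length(cl_roots) + singletons)
}

#' Single-threshold GMYC lineage delimitation
#'
#' Fits the generalized mixed Yule-coalescent model on an ultrametric tree:
#' a threshold age T separates between-lineage (Yule-like) branching from
#' within-lineage coalescence. Between successive branching events the total
#' hazard is b = lambda1 * nY^p1 + lambda2 * sum_c (n_c (n_c - 1))^p2, where
#' nY counts between-cluster lineages and n_c the lineages inside cluster c;
#' the log-likelihood is sum(log b - b x) over waiting times x. The model is
#' maximized over the rates (and exponents unless `fix_exponents`) and over
#' candidate thresholds (every branching age, plus the all-singleton
#' threshold at age 0, which makes the null single-process model an exact
#' special case). The likelihood-ratio test against the single-process null
#' b = lambda n^p uses a chi-square reference with 3 df (1 when exponents
#' are fixed).
#'
#' @param tree binary ultrametric `phylo` with >= 3 tips, one tip per
#'   haplotype (identical sequences must be removed beforehand).
#' @param fix_exponents fix p1 = p2 = 1 (default FALSE).
#' @param df degrees of freedom for the LRT (default 3, or 1 when exponents
#'   are fixed); a convention, exposed for sensitivity checks.
#' @return list of class `gmyc_result`: threshold_age, entities, clusters,
#'   singletons, loglik_alt, loglik_null, LR, p, ci_entities, profile.
#' @export
gmyc_single_threshold <- function(tree, fix_exponents = FALSE, df = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object")
  if (!ape::is.binary(tree)) stop("tree must be fully bifurcating")
  if (ape::Ntip(tree) < 3) stop("need at least 3 tips")
  depths <- ape::node.depth.edgelength(tree)
  tipd <- depths[seq_len(ape::Ntip(tree))]
  if (diff(range(tipd)) > 1e-6 * max(depths))
    stop("tree is not ultrametric (tip ages differ)")
  cd <- stats::cophenetic(tree)
  if (any(cd[upper.tri(cd)] < 1e-12))
    stop("duplicate haplotypes (zero-distance tips) must be removed")
  ages <- ape::branching.times(tree)
  cands <- c(sort(unique(as.numeric(ages))), 0)
  null_fit <- gmyc_null_fit(tree, ages, fix_exponents)
  prof <- data.frame(T = cands, loglik = NA_real_, entities = NA_integer_)
  best <- list(loglik = -Inf)
  for (k in seq_along(cands)) {
    T <- cands[k]
    ints <- gmyc_intervals(tree, ages, T)
    if (is.null(ints)) next
    fit <- gmyc_fit_threshold(ints, fix_exponents)
    ent <- gmyc_entities(tree, ages, T)
    prof$loglik[k] <- fit$loglik
    prof$entities[k] <- ent$entities
    if (fit$loglik > best$loglik ||
        (fit$loglik == best$loglik && T > best$T %||% -1))
      best <- c(fit, list(T = T, ent = ent))
  }
  loglik_alt <- max(best$loglik, null_fit$loglik)
  LR <- max(0, 2 * (loglik_alt - null_fit$loglik))
  if (is.null(df)) df <- if (fix_exponents) 1 else 3
  keep <- !is.na(prof$loglik) & prof$loglik >= best$loglik - 2
  structure(list(threshold_age = best$T,
                 entities = best$ent$entities,
                 clusters = best$ent$clusters,
                 singletons = best$ent$singletons,
                 loglik_alt = loglik_alt,
                 loglik_null = null_fit$loglik,
                 LR = LR,
                 p = stats::pchisq(LR, df, lower.tail = FALSE),
                 ci_entities = range(prof$entities[keep]),
                 profile = prof),
            class = "gmyc_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gmyc_result <- function(x, ...) {
  cat(sprintf(
    "GMYC: %d entities (%d clusters + %d singletons) at T = %.4g\n  LR = %.3f, p = %.4g, CI entities %d..%d\n",
    x$entities, x$clusters, x$singletons, x$threshold_age, x$LR, x$p,
    x$ci_entities[1], x$ci_entities[2]))
  invisible(x)
}

#' Per-tip entity assignments at the fitted GMYC threshold
#'
#' @param tree the tree passed to [gmyc_single_threshold()].
#' @param result its `gmyc_result`.
#' @return data.frame with tip and entity label.
#' @export
gmyc_assignments <- function(tree, result) {
  ntip <- ape::Ntip(tree)
  ages <- ape::branching.times(tree)
  node_age <- c(rep(0, ntip), ages[order(as.integer(names(ages)))])
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ntip + 1
  lab <- integer(ntip + tree$Nnode)
  pre <- ape::reorder.phylo(tree, "cladewise")
  nxt <- 0L
  for (v in c(root, pre$edge[, 2])) {
    if (node_age[v] > result$threshold_age) { lab[v] <- 0L; next }
    p <- if (v == root) 0L else parent[v]
    if (v == root || node_age[p] > result$threshold_age) {
      nxt <- nxt + 1L; lab[v] <- nxt
    } else lab[v] <- lab[p]
  }
  data.frame(tip = tree$tip.label, entity = lab[seq_len(ntip)])
}
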