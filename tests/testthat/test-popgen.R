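test_that("haplotype collapsing groups identical and partial sequences", {
  m <- aln_matrix(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGA")
  h <- collapse_haplotypes(m)
  expect_equal(h$H, 2)
  expect_equal(sort(h$haplotypes$count), c(1, 3))
  # all-N sequence is unassignable under the strict policy
  m2 <- aln_matrix(a = "ACG", b = "ACG", c = "ACT", d = "NNN")
  expect_warning(h2 <- collapse_haplotypes(m2), "unassignable")
  expect_equal(h2$excluded, "d")
  expect_equal(h2$H, 2)
  # ambiguous merge: N-sequence compatible with two classes
  m3 <- aln_matrix(a = "ACG", b = "TCG", c = "NCG")
  expect_warning(h3 <- collapse_haplotypes(m3), "unassignable")
  expect_equal(h3$H, 2)
  h3l <- collapse_haplotypes(m3, ambiguous_policy = "lenient")
  expect_equal(h3l$H, 2)
  expect_equal(sum(h3l$haplotypes$count), 3)
  # unique compatible class: merged
  m4 <- aln_matrix(a = "ACG", b = "ACG", c = "NCG")
  h4 <- collapse_haplotypes(m4)
  expect_equal(h4$H, 1)
  expect_equal(h4$haplotypes$count, 3)
  expect_error(collapse_haplotypes(m[0, , drop = FALSE]), "empty")
})

test_that("haplotype structure is invariant under sample reordering", {
  set.seed(21)
  tr <- simulate_genealogy(12)
  a <- simulate_alignment(tr, S_fixed = 6, L = 60)
  h1 <- collapse_haplotypes(a)
  perm <- sample(nrow(a))
  h2 <- collapse_haplotypes(a[perm, ])
  expect_equal(h1$H, h2$H)
  expect_equal(sort(h1$haplotypes$count), sort(h2$haplotypes$count))
})

test_that("p-distances use pairwise deletion and report group means", {
  m <- aln_matrix(a = "AAAAAAAAAA", b = "AAAAAAAAAA")
  expect_equal(unname(p_distance_matrix(m)[1, 2]), 0)
  # 10 sites, 2 deleted pairwise, 1 difference among the 8 compared
  m2 <- aln_matrix(x = "AACCGGTTAN", y = "AACCGGTAN-")
  D <- p_distance_matrix(m2)
  expect_equal(unname(D[1, 2]), 1 / 8)
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
  # no comparable sites -> missing entry
  m3 <- aln_matrix(x = "ANN", y = "NNA", z = "AAA")
  expect_true(is.na(p_distance_matrix(m3)[1, 2]))
  # group means are arithmetic means of cross-group entries
  m4 <- aln_matrix(a = "AAAA", b = "AAAT", c = "TTTT", d = "TTTA")
  D4 <- p_distance_matrix(m4, groups = c("g1", "g1", "g2", "g2"))
  expect_equal(attr(D4, "between")["g1", "g2"],
               mean(c(D4[1, 3], D4[1, 4], D4[2, 3], D4[2, 4])))
  expect_equal(unname(attr(D4, "within")["g1"]), D4[1, 2])
})

test_that("alignment summaries match closed forms", {
  m <- aln_matrix(a = "ACGT", b = "ACGT", c = "ACGT")
  s <- alignment_summary(m)
  expect_equal(s$Hd, 0)
  expect_equal(s$pi, 0)
  expect_equal(s$S, 0)
  # 4 sequences, haplotype counts {3,1}: Hd = (4/3)(1 - 10/16) = 0.5
  m2 <- aln_matrix(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGA")
  s2 <- alignment_summary(m2)
  expect_equal(s2$Hd, 0.5)
  expect_equal(s2$S, 1)
  # pi: 3 of 6 pairs differ at 1 of 4 sites
  expect_equal(s2$pi, (3 / 6) / 4)
  expect_equal(s2$kbar, 0.5)
  expect_error(alignment_summary(m[1, , drop = FALSE]), "two sequences")
  # Hd = 1 iff all haplotypes unique; order invariance
  set.seed(3)
  tr <- simulate_genealogy(8)
  a <- simulate_alignment(tr, S_fixed = 12, L = 100)
  s3 <- alignment_summary(a)
  s4 <- alignment_summary(a[sample(8), ])
  expect_equal(s3$Hd, s4$Hd)
  expect_equal(s3$pi, s4$pi)
  if (s3$H == 8) expect_equal(s3$Hd, 1)
  # complete deletion removes sites with any missing base
  m5 <- aln_matrix(a = "ACGTN", b = "ACGTA", c = "ACCTA")
  expect_equal(alignment_summary(m5)$L_eff, 4)
})

test_that("Fu's Fs equals the exact Ewens-formula oracle", {
  # brute-force oracle: exact integer Stirling numbers, direct Ewens sum
  n <- 4; theta <- 1.5; H <- 3
  pk <- ewens_pmf(n, theta)
  Sp <- sum(pk[H:n])
  fs_oracle <- log(Sp / (1 - Sp))
  got <- fu_fs(list(n = n, kbar = theta, H = H, S = 2))
  expect_equal(got, fs_oracle, tolerance = 1e-10)
  # a second configuration
  n <- 7; theta <- 2.25; H <- 5
  pk <- ewens_pmf(n, theta)
  fs_oracle2 <- log(sum(pk[H:n]) / sum(pk[1:(H - 1)]))
  expect_equal(fu_fs(list(n = n, kbar = theta, H = H, S = 3)), fs_oracle2,
               tolerance = 1e-10)
  # H = 1: S' = 1 exactly, flagged +Inf
  expect_warning(v <- fu_fs(list(n = 5, kbar = 0.5, H = 1, S = 1)), "Inf")
  expect_identical(v, Inf)
  expect_error(fu_fs(list(n = 5, kbar = 0, H = 2, S = 0)), "undefined")
  # large n stays finite in log space (no overflow up to Table-1 sizes)
  expect_true(is.finite(fu_fs(list(n = 200, kbar = 3, H = 40, S = 50))))
  expect_true(is.finite(fu_fs(list(n = 310, kbar = 8, H = 63, S = 90))))
})

test_that("R2 matches its closed form and a textbook recomputation", {
  # n = 2, one difference: U = (1,1), kbar = 1 -> R2 = 0.5
  m <- aln_matrix(a = "AT", b = "AA")
  s <- alignment_summary(m)
  expect_equal(r2_stat(s), 0.5)
  # independent recomputation on a random alignment
  set.seed(17)
  tr <- simulate_genealogy(9)
  a <- simulate_alignment(tr, S_fixed = 10, L = 80)
  s2 <- alignment_summary(a)
  # oracle: recount singletons and mean pairwise differences directly
  n <- nrow(a)
  U <- rep(0, n)
  kbar_pairs <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    kbar_pairs <- c(kbar_pairs, sum(a[i, ] != a[j, ]))
  for (site in seq_len(ncol(a))) {
    tab <- table(a[, site])
    if (length(tab) < 2) next
    for (b in names(tab)[tab == 1]) U[which(a[, site] == b)] <-
        U[which(a[, site] == b)] + 1
  }
  r2_oracle <- sqrt(mean((U - mean(kbar_pairs) / 2)^2)) / s2$S
  expect_equal(r2_stat(s2), r2_oracle, tolerance = 1e-12)
  expect_error(r2_stat(list(n = 4, kbar = 0, U = c(0, 0), S = 0)),
               "undefined")
})

test_that("fixed-S significance simulation is calibrated and deterministic", {
  r1 <- neutrality_significance(0.1, "R2", n = 12, S = 6, n_sims = 300,
                                seed = 42)
  r2 <- neutrality_significance(0.1, "R2", n = 12, S = 6, n_sims = 300,
                                seed = 42)
  expect_identical(r1$p, r2$p)
  expect_identical(r1$ci95, r2$ci95)
  expect_true(r1$p >= 0 && r1$p <= 1)
  expect_lte(r1$ci95[1], r1$ci95[2])
  # observed at the simulated median gives p near 0.5
  med <- median(r1$sims)
  rm <- neutrality_significance(med, "R2", n = 12, S = 6, n_sims = 400,
                                seed = 7)
  expect_lt(abs(rm$p - 0.5), 0.1)
  # left and right tails are complementary up to ties
  expect_gte(rm$p + rm$p_upper, 1)
  expect_error(neutrality_significance(0, "Fs", n = 2, S = 3), "n >= 3")
})

test_that("great-circle distances match the geodesic oracle", {
  pts <- data.frame(lat = c(10, 10), lon = c(20, 20))
  expect_equal(unname(great_circle_matrix(pts)[1, 2]), 0)
  anti <- data.frame(lat = c(0, 0), lon = c(0, 180))
  expect_equal(unname(great_circle_matrix(anti)[1, 2]), pi * 6371,
               tolerance = 1e-9)
  skip_if_not_installed("geosphere")
  set.seed(8)
  pts <- data.frame(lat = runif(12, -60, 60), lon = runif(12, -170, 170))
  D <- great_circle_matrix(pts)
  G <- geosphere::distm(cbind(pts$lon, pts$lat), fun = geosphere::distGeo) / 1000
  off <- abs(D - G) / pmax(G, 1)
  expect_lt(max(off[upper.tri(off)]), 0.005)
  expect_error(great_circle_matrix(data.frame(lat = 100, lon = 0)), "invalid")
})

test_that("Mantel test matches enumeration and external implementations", {
  set.seed(31)
  n <- 5
  pts <- data.frame(locality = 1:n, lat = runif(n, 30, 40),
                    lon = runif(n, 0, 10))
  geo <- great_circle_matrix(pts)
  gen <- log(geo + 1) / 10 + matrix(runif(n * n, 0, 1e-3), n, n)
  gen <- (gen + t(gen)) / 2; diag(gen) <- 0
  m <- mantel_ibd(gen, geo, n_perm = 9999, seed = 2)
  # exhaustive oracle over all 120 simultaneous row/column permutations
  G <- geo; G[G == 0] <- min(G[G > 0]) / 2; G <- log(G)
  ut <- upper.tri(gen)
  perms <- as.matrix(expand.grid(rep(list(1:n), n)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == n), ]
  r_all <- apply(perms, 1, function(p) cor(gen[ut], G[p, p][ut]))
  r_obs <- cor(gen[ut], G[ut])
  expect_equal(m$r, r_obs, tolerance = 1e-12)
  q <- mean(r_all >= r_obs - 1e-12)
  expect_lt(abs(m$p - q), 0.02 + 3 * sqrt(q * (1 - q) / 9999))
  skip_if_not_installed("vegan")
  vm <- vegan::mantel(as.dist(gen), as.dist(G), permutations = 999)
  expect_equal(m$r, unname(vm$statistic), tolerance = 1e-12)
})

test_that("Mantel refuses degenerate inputs", {
  m4 <- matrix(runif(16), 4, 4); m4 <- (m4 + t(m4)) / 2; diag(m4) <- 0
  expect_error(mantel_ibd(m4, m4), "fewer than five")
  const <- matrix(1, 6, 6); diag(const) <- 0
  geo <- great_circle_matrix(data.frame(lat = 30:35, lon = 0:5))
  expect_error(mantel_ibd(const * 0, geo), "constant")
  zero_geo <- matrix(0, 6, 6)
  expect_error(mantel_ibd(const, zero_geo), "all zero")
  # a perfect monotone relation gives r = 1 and the smallest possible p
  set.seed(5)
  pts <- data.frame(locality = 1:7, lat = runif(7, 30, 40),
                    lon = runif(7, 0, 20))
  geo7 <- great_circle_matrix(pts)
  gen7 <- log(geo7 + 0.1) # genetic = monotone transform of log-geographic
  m <- mantel_ibd(gen7, geo7, n_perm = 199, seed = 1)
  expect_gt(m$r, 0.99)
  expect_equal(m$p, 1 / 200)
})

test_that("diversity grid reproduces degenerate closed forms", {
  # one haplotype, one locality: H_T = 0, H_R = 1, R = 1
  m <- aln_matrix(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT",
                  e = "ACGT", f = "ACGT")
  g <- as_geo(m, locality = rep(1, 6), lat = rep(35, 6), lon = rep(0, 6))
  dg <- diversity_grid(g, spacing = 100, m = 5, B = 50, seed = 1)
  row <- dg[!dg$missing, ][1, ]
  expect_equal(row$HT_mean, 0)
  expect_equal(row$HR_mean, 1)
  expect_equal(row$R_mean, 1)
  # every draw of 5 unique localized haplotypes: H_T = 1, H_R = 5
  m2 <- aln_matrix(a = "AAAA", b = "CCCC", c = "GGGG", d = "TTTT",
                   e = "AATT", f = "CCGG")
  g2 <- as_geo(m2, locality = 1:6, lat = rep(35, 6),
               lon = seq(0, 0.05, length.out = 6))
  dg2 <- diversity_grid(g2, spacing = 100, m = 5, B = 50, seed = 2)
  row2 <- dg2[!dg2$missing, ][1, ]
  expect_equal(row2$HT_mean, 1)
  expect_equal(row2$HR_mean, 5)
  expect_error(diversity_grid(g2, m = 1), "at least 2")
})

test_that("diversity grid bootstrap means match exhaustive enumeration", {
  # 6-individual pool, haplotypes {A,A,B,C,D,E}, two localities
  m <- aln_matrix(a = "AAAA", b = "AAAA", c = "CAAA", d = "GAAA",
                  e = "TAAA", f = "AACC")
  loc <- c(1, 2, 1, 1, 2, 2)
  g <- as_geo(m, locality = loc, lat = rep(35, 6),
              lon = c(0, 0.4, 0, 0, 0.4, 0.4))
  B <- 4000
  dg <- diversity_grid(g, spacing = 100, radius = 100, m = 5, B = B,
                       seed = 9)
  row <- dg[!dg$missing, ][1, ]
  expect_equal(row$n_available, 6)
  # oracle: enumerate all choose(6,5) draws
  hap <- c(1, 1, 2, 3, 4, 5)
  nloc_of_hap <- sapply(1:5, function(h) length(unique(loc[hap == h])))
  rarity <- 1 / nloc_of_hap
  draws <- combn(6, 5)
  stats <- apply(draws, 2, function(ix) {
    tab <- table(hap[ix]); p <- tab / 5
    c(HT = 5 * (1 - sum(p^2)) / 4, HR = length(tab),
      R = mean(rarity[hap[ix]]))
  })
  exp_stats <- rowMeans(stats)
  sds <- apply(stats, 1, sd)
  for (nm in c("HT", "HR", "R")) {
    se <- sds[nm] / sqrt(B)
    expect_lt(abs(row[[paste0(nm, "_mean")]] - exp_stats[nm]),
              3 * se + 1e-12)
  }
})
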