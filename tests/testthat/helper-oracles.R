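# Independent oracle helpers shared across test files. These deliberately
# re-derive quantities through different code paths than the package.

# exact unsigned Stirling numbers of the first kind, row n (integer arithmetic)
stirling1_row_exact <- function(n) {
  row <- 1
  if (n == 1) return(row)
  for (i in 2:n) {
    prev <- c(0, row, 0)                      # s(i-1, k-1), s(i-1, k)
    row <- sapply(seq_len(i), function(k) prev[k] + (i - 1) * prev[k + 1])
  }
  row
}

# Ewens sampling formula P(K = k | theta, n) by direct evaluation
ewens_pmf <- function(n, theta) {
  s <- stirling1_row_exact(n)
  denom <- prod(theta + 0:(n - 1))
  s * theta^seq_len(n) / denom
}

# trapezoid area under y(x)
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# tiny fixed alignment as a character matrix
aln_matrix <- function(...) {
  seqs <- c(...)
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- names(seqs) %||% paste0("s", seq_along(seqs))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# wrap a matrix with trivial coordinates into a geo_alignment
as_geo <- function(m, locality = NULL, lat = NULL, lon = NULL) {
  n <- nrow(m)
  samples <- data.frame(
    id = rownames(m),
    locality = locality %||% seq_len(n),
    lat = lat %||% rep(35, n),
    lon = lon %||% seq(0, 1, length.out = n))
  geo_alignment(m, samples)
}

# small raster from a matrix (0.5 deg cells anchored at lon 0, lat 40 top)
toy_raster <- function(values, cellsize = 0.5) {
  mr_raster(values, xmin = 0, ymin = 40 - nrow(values) * cellsize,
            cellsize = cellsize)
}

# constant monthly climatology on a small grid
constant_climatology <- function(nr = 4, nc = 5, tmean = 10, tmax = 15,
                                 tmin = 5, prec = 100) {
  tpl <- mr_raster(matrix(0, nr, nc), 0, 30, 0.5)
  monthly_climatology(list(
    tmean = array(tmean, c(nr, nc, 12)), tmax = array(tmax, c(nr, nc, 12)),
    tmin = array(tmin, c(nr, nc, 12)), prec = array(prec, c(nr, nc, 12))),
    tpl)
}
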