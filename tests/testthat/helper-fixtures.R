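# Fixture builders and independent brute-force oracles used across the suite.

# Exactly representable linear DVH family: V(d) = V0 * (1 - d / D0) on [0, D0].
linearStructure <- function(V0 = 100, D0 = 100, step = 1, name = "PTV") {
  grid <- seq(0, D0, by = step)
  StructureDVH(name, grid, V0 * (1 - grid / D0))
}

# Random piecewise-linear cumulative DVH. Volumes are drawn non-increasing
# from V0 down to endVol (0 unless truncated).
randomStructure <- function(name = "S", npts = NULL, maxDose = NULL,
                            V0 = NULL, truncated = FALSE) {
  if (is.null(npts)) npts <- sample(6:40, 1)
  if (is.null(maxDose)) maxDose <- runif(1, 40, 80)
  if (is.null(V0)) V0 <- runif(1, 10, 500)
  grid <- c(0, sort(runif(npts - 1, 0, maxDose)))
  grid <- grid[!duplicated(signif(grid, 12))]
  endVol <- if (truncated) runif(1, 0.05, 0.3) * V0 else 0
  inner <- sort(runif(length(grid) - 2, endVol / V0, 1), decreasing = TRUE) * V0
  StructureDVH(name, grid, c(V0, inner, endVol))
}

# Brute-force oracle on a dense resample grid (about `m` uniform points plus
# the original kink doses, so the piecewise-linear curve is reproduced
# exactly). Independent re-derivation of the query semantics: dense scan for
# the supremum, trapezoid sum for the mean.
denseOracle <- function(s, m = 1e5) {
  g <- doseGrid(s)
  d <- sort(unique(c(seq(g[1], g[length(g)], length.out = m), g)))
  v <- stats::approx(g, cumVolume(s), xout = d)$y
  n <- length(d)
  total <- v[1]
  list(
    volumeAt = function(q) stats::approx(d, v, xout = q, rule = 2)$y,
    doseAt = function(q) {
      vapply(q, function(qi) {
        if (qi == 0) return(d[n])
        if (qi > total) return(0)
        if (qi <= v[n]) return(d[n])
        i <- max(which(v >= qi))
        d[i] + (v[i] - qi) / (v[i] - v[i + 1]) * (d[i + 1] - d[i])
      }, numeric(1))
    },
    mean = sum(diff(d) * (v[-1] + v[-n]) / 2) / total
  )
}

# All thirteen documented expression spellings.
standardExpressions <- function() {
  c("D(Gy)40(cc)", "D(Gy)40(%)", "D(%)40(cc)", "D(%)40(%)",
    "V(cc)40(Gy)", "V(cc)40(%)", "V(%)40(Gy)", "V(%)40(%)",
    "Dmax", "Dmin", "Dmean", "Dmean/Rx", "Dmean/Rx \u00d7 100")
}

# Closed-form values of the thirteen expressions on the linear family
# V(d) = V0 (1 - d/D0) with reference/prescription dose ref.
linearFamilyTruth <- function(V0 = 100, D0 = 100, ref = 50) {
  out <- c(D0 * (1 - 40 / V0),          # D(Gy)40(cc)
           D0 * (1 - 0.4),              # D(Gy)40(%)
           D0 * (1 - 40 / V0) / ref * 100,
           D0 * 0.6 / ref * 100,
           V0 * (1 - 40 / D0),          # V(cc)40(Gy)
           V0 * (1 - 0.4 * ref / D0),
           (1 - 40 / D0) * 100,
           (1 - 0.4 * ref / D0) * 100,
           D0 * (1 - 0.03 / V0),        # Dmax
           D0 * 0.03 / V0,              # Dmin
           D0 / 2,                      # Dmean
           D0 / 2 / ref,                # Dmean/Rx
           D0 / 2 / ref * 100)          # Dmean/Rx x 100
  names(out) <- standardExpressions()
  out
}

writeTempDVH <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
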