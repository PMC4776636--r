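#' @include AllClasses.R
NULL

# Synthetic cumulative-DVH families with known ground truth:
#   uniform(d0):        V(d) = V0 for d < d0, 0 after; the drop occupies one
#                       grid interval [d0, d0 + step]
#   linear(D0):         V(d) = V0 * max(0, 1 - d/D0)
#   sigmoid(d50,slope): V(d) = V0 / (1 + exp(slope * (d - d50)))
# Dose parameters are snapped to the grid step so the uniform/linear curves
# are exactly representable and their truths are closed forms; sigmoid truths
# come from a high-resolution numeric oracle (step/100) applying the same
# supremum/truncation conventions as the evaluator, independently of its code.

#' Synthetic dose profiles
#'
#' Constructors for the three DVH shapes of the generator: \code{uniform}
#' (every voxel receives \code{d0} Gy, as in a well-covered target),
#' \code{linear} (volume falls off linearly to zero at \code{D0} Gy), and
#' \code{sigmoid} (logistic fall-off around \code{d50} Gy with the given
#' slope in 1/Gy, resembling an organ-at-risk curve).
#'
#' @param d0,D0,d50 Characteristic dose of the profile, Gy (> 0).
#' @param slope Logistic steepness, 1/Gy (> 0).
#' @return A profile description used by \code{\link{syntheticSpec}}.
#' @name profiles
NULL

#' @rdname profiles
#' @export
profileUniform <- function(d0) {
  stopifnot(isScalarNumber(d0), d0 > 0)
  structure(list(type = "uniform", d0 = d0), class = "dvhProfile")
}
#' @rdname profiles
#' @export
profileLinear <- function(D0) {
  stopifnot(isScalarNumber(D0), D0 > 0)
  structure(list(type = "linear", D0 = D0), class = "dvhProfile")
}
#' @rdname profiles
#' @export
profileSigmoid <- function(d50, slope = 0.5) {
  stopifnot(isScalarNumber(d50), d50 > 0, isScalarNumber(slope), slope > 0)
  structure(list(type = "sigmoid", d50 = d50, slope = slope),
            class = "dvhProfile")
}

profileDose <- function(p) switch(p$type, uniform = p$d0, linear = p$D0,
                                  sigmoid = p$d50)

#' Specify a synthetic DVH case
#'
#' @param structures Named list: structure name -> \code{list(volume = cc,
#'   profile = \link{profiles} object)}.
#' @param rxDose Optional prescription dose, Gy (written to header cell C1).
#' @param globalMaxDose Optional global maximum dose, Gy (header cell D1).
#' @param gridStep Dose-grid spacing, Gy (default 0.1 Gy, fine enough that
#'   sigmoid interpolation error stays well below 1e-3 relative).
#' @param gridMax Top of the dose grid, Gy; defaults to 1.2 times the largest
#'   characteristic profile dose, rounded up to the step.
#' @return A spec list consumed by \code{\link{generateCase}}.
#' @examples
#' syntheticSpec(list(PTV = list(volume = 100, profile = profileLinear(100))),
#'               rxDose = 50)
#' @export
syntheticSpec <- function(structures, rxDose = NA_real_,
                          globalMaxDose = NA_real_, gridStep = 0.1,
                          gridMax = NULL) {
  stopifnot(is.list(structures), length(structures) >= 1L,
            !is.null(names(structures)), all(nzchar(names(structures))),
            isScalarNumber(gridStep), gridStep > 0)
  for (nm in names(structures)) {
    st <- structures[[nm]]
    if (!is.list(st) || !all(c("volume", "profile") %in% names(st)) ||
        !inherits(st$profile, "dvhProfile"))
      validationError(sprintf(
        "structure \"%s\" must be list(volume =, profile = profile*())", nm))
    if (!isScalarNumber(st$volume) || st$volume <= 0.03)
      validationError(sprintf(
        "structure \"%s\": volume must exceed 0.03 cc", nm))
  }
  if (is.null(gridMax)) {
    topDose <- max(vapply(structures, function(st) profileDose(st$profile),
                          numeric(1)))
    gridMax <- ceiling(1.2 * topDose / gridStep) * gridStep
  }
  structure(list(structures = structures, rxDose = as.numeric(rxDose),
                 globalMaxDose = as.numeric(globalMaxDose),
                 gridStep = gridStep, gridMax = gridMax),
            class = "dvhSyntheticSpec")
}

snapToStep <- function(x, step) max(step, round(x / step) * step)

# Dense-scan oracle for sigmoid truths: same conventions as the evaluator
# (supremum dose covering v; curve treated as ending at gridMax), but
# computed by brute force on a step/100 grid from the analytic curve.
sigmoidTruths <- function(V0, d50, slope, gridMax, step) {
  dd <- seq(0, gridMax, by = step / 100)
  vv <- V0 / (1 + exp(slope * (dd - d50)))
  total <- vv[1L]
  doseAt <- function(v) if (v <= vv[length(vv)]) gridMax else max(dd[vv >= v])
  meanD <- sum(diff(dd) * (vv[-1L] + vv[-length(vv)]) / 2) / total
  list(total = total, mean = meanD, dmax = doseAt(0.03),
       dmin = doseAt(total - 0.03), doseAt = doseAt)
}

#' Generate one synthetic case with its ground-truth metrics
#'
#' Builds a \linkS4class{DVHCase} on a shared grid from the spec's profiles
#' and records, per structure, ground-truth values for \code{Dmean},
#' \code{Dmax}, \code{Dmin} and one probe query in each direction
#' (\code{D(Gy)...(cc)} at 40\% of the structure volume and
#' \code{V(cc)...(Gy)} at a profile-specific probe dose), computed
#' independently of the evaluator: closed forms for the uniform/linear
#' families, a dense numeric oracle for the sigmoid family.
#'
#' @param spec A \code{\link{syntheticSpec}}.
#' @param caseID Case identifier for the generated case.
#' @return \code{list(case = DVHCase, truth = data.frame(structure,
#'   expression, value))}; every truth expression parses with
#'   \code{\link{parseExpression}}.
#' @export
generateCase <- function(spec, caseID = "SYN001") {
  stopifnot(inherits(spec, "dvhSyntheticSpec"))
  step <- spec$gridStep
  grid <- step * seq.int(0L, round(spec$gridMax / step))
  structuresList <- list()
  truths <- list()
  for (nm in names(spec$structures)) {
    st <- spec$structures[[nm]]
    V0 <- st$volume
    p <- st$profile
    if (p$type == "uniform") {
      d0 <- snapToStep(p$d0, step)
      if (d0 + step > spec$gridMax)
        validationError(sprintf(
          "structure \"%s\": grid must extend past the uniform dose %g Gy", nm, d0))
      vol <- ifelse(grid <= d0 + step / 2, V0, 0)
      truth <- data.frame(
        structure = nm,
        expression = c("Dmean", "Dmax", "Dmin",
                       sprintf("D(Gy)%s(cc)", fmtNum(0.4 * V0)),
                       sprintf("V(cc)%s(Gy)", fmtNum(d0 / 2))),
        value = c(d0 + step / 2,
                  d0 + step * (1 - 0.03 / V0),
                  d0 + step * (0.03 / V0),
                  d0 + step * (1 - 0.4),
                  V0),
        stringsAsFactors = FALSE)
    } else if (p$type == "linear") {
      D0 <- snapToStep(p$D0, step)
      if (D0 > spec$gridMax)
        validationError(sprintf(
          "structure \"%s\": grid must reach the linear fall-off dose %g Gy", nm, D0))
      vol <- V0 * pmax(0, 1 - grid / D0)
      truth <- data.frame(
        structure = nm,
        expression = c("Dmean", "Dmax", "Dmin",
                       sprintf("D(Gy)%s(cc)", fmtNum(0.4 * V0)),
                       sprintf("V(cc)%s(Gy)", fmtNum(D0 / 2))),
        value = c(D0 / 2,
                  D0 * (1 - 0.03 / V0),
                  D0 * 0.03 / V0,
                  0.6 * D0,
                  0.5 * V0),
        stringsAsFactors = FALSE)
    } else {
      vol <- V0 / (1 + exp(p$slope * (grid - p$d50)))
      orc <- sigmoidTruths(V0, p$d50, p$slope, spec$gridMax, step)
      truth <- data.frame(
        structure = nm,
        expression = c("Dmean", "Dmax", "Dmin",
                       sprintf("D(Gy)%s(cc)", fmtNum(0.4 * orc$total)),
                       sprintf("V(cc)%s(Gy)", fmtNum(p$d50))),
        value = c(orc$mean, orc$dmax, orc$dmin,
                  orc$doseAt(0.4 * orc$total),
                  V0 / 2),
        stringsAsFactors = FALSE)
    }
    structuresList[[length(structuresList) + 1L]] <-
      StructureDVH(name = nm, doseGrid = grid, cumVolume = vol)
    truths[[length(truths) + 1L]] <- truth
  }
  case <- DVHCase(caseID = caseID, rxDose = spec$rxDose,
                  globalMaxDose = spec$globalMaxDose,
                  structures = structuresList)
  list(case = case, truth = do.call(rbind, truths))
}

#' Generate a synthetic cohort
#'
#' Draws \code{n} cases around a base spec: each structure's volume and
#' characteristic profile dose are multiplied by independent lognormal factors
#' \code{exp(N(0, jitter))}, so all quantities stay positive and the base
#' value is the cohort median. The grid is re-derived per case so it always
#' covers the jittered profiles. Fully deterministic for a given seed.
#'
#' @param n Number of cases (>= 1).
#' @param base A \code{\link{syntheticSpec}}.
#' @param jitter Lognormal sigma of the multiplicative spread (0 gives
#'   \code{n} identical cases); default 0.1 (about 10\% case-to-case spread,
#'   a realistic cohort variation for organ volumes and plan fall-off).
#' @param seed Integer RNG seed (mandatory; no hidden global randomness).
#' @return List of \code{n} \code{list(case, truth)} pairs, case IDs
#'   \code{SYN001...}.
#' @export
generateCohort <- function(n, base, jitter = 0.1, seed) {
  stopifnot(isScalarNumber(n), n >= 1, inherits(base, "dvhSyntheticSpec"),
            isScalarNumber(jitter), jitter >= 0, isScalarNumber(seed))
  set.seed(as.integer(seed))
  lapply(seq_len(n), function(i) {
    structures <- lapply(base$structures, function(st) {
      fv <- exp(stats::rnorm(1L, 0, jitter))
      fd <- exp(stats::rnorm(1L, 0, jitter))
      p <- st$profile
      p[[switch(p$type, uniform = "d0", linear = "D0", sigmoid = "d50")]] <-
        profileDose(p) * fd
      list(volume = st$volume * fv, profile = p)
    })
    spec <- syntheticSpec(structures, rxDose = base$rxDose,
                          globalMaxDose = base$globalMaxDose,
                          gridStep = base$gridStep)
    generateCase(spec, caseID = sprintf("SYN%03d", i))
  })
}

#' Write a synthetic cohort as DVH CSV files plus a truths sidecar
#'
#' @param cohort Result of \code{\link{generateCohort}}.
#' @param path Output directory (created if missing).
#' @return Invisibly, the paths written (one DVH CSV per case and
#'   \code{truths.csv} with columns caseID, structure, expression, value).
#' @export
writeCohort <- function(cohort, path) {
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    ioError(sprintf("cannot create output directory %s", path))
  written <- character(0)
  truthLines <- "caseID,structure,expression,value"
  for (item in cohort) {
    f <- file.path(path, paste0(caseID(item$case), ".csv"))
    writeDVH(item$case, f)
    written <- c(written, f)
    truthLines <- c(truthLines, vapply(seq_len(nrow(item$truth)), function(i)
      csvLine(c(caseID(item$case), item$truth$structure[i],
                item$truth$expression[i], fmtNum(item$truth$value[i]))),
      character(1)))
  }
  tf <- file.path(path, "truths.csv")
  writeLinesUtf8(truthLines, tf)
  invisible(c(written, tf))
}

#' Built-in example review request (lung-trial style)
#'
#' A realistic thoracic review request of 6 structures and 14 dose/volume
#' points, the workload scale of a typical lung-trial dosimetry review. Used
#' by the examples and the command-line demo.
#'
#' @return A \linkS4class{ReviewRequest}.
#' @examples
#' exampleRequest()
#' @export
exampleRequest <- function() {
  reviewRequest(
    PTV = c("D(%)95(%)", "D(Gy)95(%)", "Dmax", "Dmean/Rx x 100"),
    Lungs = c("V(%)20(Gy)", "V(%)5(Gy)", "Dmean"),
    Heart = c("V(%)30(Gy)", "Dmean"),
    Esophagus = c("Dmean", "Dmax"),
    SpinalCord = "Dmax",
    BrachialPlexus = c("Dmax", "D(Gy)0.03(cc)"))
}

#' Built-in example synthetic cohort spec matching \code{\link{exampleRequest}}
#'
#' Six thoracic structures with profile shapes loosely emulating a lung plan:
#' a uniformly covered target near the 60 Gy prescription and organs at risk
#' with sigmoid or linear fall-off at lower doses.
#'
#' @param rxDose Prescription dose, Gy.
#' @return A \code{\link{syntheticSpec}}.
#' @export
exampleSpec <- function(rxDose = 60) {
  syntheticSpec(
    structures = list(
      PTV = list(volume = 350, profile = profileUniform(60)),
      Lungs = list(volume = 3000, profile = profileSigmoid(18, 0.12)),
      Heart = list(volume = 600, profile = profileSigmoid(12, 0.15)),
      Esophagus = list(volume = 40, profile = profileSigmoid(25, 0.2)),
      SpinalCord = list(volume = 50, profile = profileLinear(45)),
      BrachialPlexus = list(volume = 30, profile = profileLinear(55))),
    rxDose = rxDose, globalMaxDose = 66)
}
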