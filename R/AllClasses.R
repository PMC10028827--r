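#' Bias deposition schedule for synthetic unbinding runs
#'
#' Describes the deterministic scalar bias ramp used by the synthetic
#' trajectory generator. In infrequent metadynamics a history-dependent
#' bias is deposited at a fixed stride (10 ps in the emulated protocol);
#' for residence-time rescaling only the accumulated acceleration factor
#' exp(beta V(t)) along the escape matters, so the generator replaces the
#' two-dimensional well-tempered bias with a scalar schedule: a step ramp
#' that grows by \code{hillHeight} per deposition, optionally saturating
#' towards \code{biasCap} the way a well-tempered bias flattens out.
#'
#' @slot depositionStride Deposition stride in ps (default 10).
#' @slot hillHeight Bias increment per deposition in kcal/mol.
#' @slot growthModel Either \code{"step_ramp"} or \code{"saturating"}.
#' @slot biasCap Upper bound on the bias in kcal/mol.
#' @slot temperature Temperature in Kelvin.
#' @export
setClass("BiasSchedule",
  representation(
    depositionStride = "numeric",
    hillHeight       = "numeric",
    growthModel      = "character",
    biasCap          = "numeric",
    temperature      = "numeric"
  )
)

setValidity("BiasSchedule", function(object) {
  msg <- character()
  if (length(object@depositionStride) != 1L || !is.finite(object@depositionStride) ||
      object@depositionStride <= 0)
    msg <- c(msg, "depositionStride must be a single positive number (ps)")
  if (length(object@hillHeight) != 1L || !is.finite(object@hillHeight) ||
      object@hillHeight < 0)
    msg <- c(msg, "hillHeight must be >= 0 (kcal/mol)")
  if (!object@growthModel %in% c("step_ramp", "saturating"))
    msg <- c(msg, "growthModel must be 'step_ramp' or 'saturating'")
  if (length(object@biasCap) != 1L || !is.finite(object@biasCap) || object@biasCap < 0)
    msg <- c(msg, "biasCap must be >= 0 (kcal/mol)")
  if (length(object@temperature) != 1L || !is.finite(object@temperature) ||
      object@temperature <= 0)
    msg <- c(msg, "temperature must be positive (K)")
  if (length(msg)) msg else TRUE
})

#' Construct a BiasSchedule
#'
#' @param depositionStride Deposition stride in ps.
#' @param hillHeight Bias increment per deposition in kcal/mol.
#' @param growthModel \code{"step_ramp"} or \code{"saturating"}.
#' @param biasCap Bias cap in kcal/mol.
#' @param temperature Temperature in Kelvin.
#' @return A \linkS4class{BiasSchedule}.
#' @examples
#' BiasSchedule(hillHeight = 0.05)
#' @export
BiasSchedule <- function(depositionStride = 10, hillHeight = 0.05,
                         growthModel = c("step_ramp", "saturating"),
                         biasCap = 25, temperature = 300) {
  growthModel <- match.arg(growthModel)
  new("BiasSchedule", depositionStride = depositionStride,
      hillHeight = hillHeight, growthModel = growthModel,
      biasCap = biasCap, temperature = temperature)
}

#' Per-frame record of one biased unbinding trajectory
#'
#' Holds the two collective variables monitored during ligand unbinding
#' (the ligand z position relative to the orthosteric-site centre of mass,
#' in Angstrom, and the ligand-receptor contact count) together with the
#' instantaneous deposited bias at each frame.
#'
#' @slot ligandId Ligand identifier token.
#' @slot frames data.frame with columns \code{time} (ps, strictly
#'   increasing), \code{z} (Angstrom), \code{contacts}, \code{bias}
#'   (kcal/mol, finite).
#' @slot temperature Temperature in Kelvin.
#' @export
setClass("BiasedTrajectory",
  representation(
    ligandId    = "character",
    frames      = "data.frame",
    temperature = "numeric"
  )
)

setValidity("BiasedTrajectory", function(object) {
  fr <- object@frames
  msg <- character()
  need <- c("time", "z", "contacts", "bias")
  if (!all(need %in% names(fr)))
    return(sprintf("frames must have columns: %s", paste(need, collapse = ", ")))
  if (nrow(fr) < 2L) msg <- c(msg, "a trajectory needs at least 2 frames")
  if (any(diff(fr$time) <= 0)) msg <- c(msg, "frame times must be strictly increasing")
  if (!all(is.finite(fr$bias))) msg <- c(msg, "bias values must be finite")
  if (length(object@temperature) != 1L || !is.finite(object@temperature) ||
      object@temperature <= 0)
    msg <- c(msg, "temperature must be positive (K)")
  if (length(msg)) msg else TRUE
})

#' Construct a BiasedTrajectory
#'
#' @param ligandId Ligand identifier.
#' @param frames data.frame with columns \code{time}, \code{z},
#'   \code{contacts}, \code{bias}.
#' @param temperature Temperature in Kelvin.
#' @return A \linkS4class{BiasedTrajectory}.
#' @export
BiasedTrajectory <- function(ligandId, frames, temperature = 300) {
  new("BiasedTrajectory", ligandId = as.character(ligandId),
      frames = as.data.frame(frames), temperature = temperature)
}

#' Rescaled dissociation times for one ligand
#'
#' One entry per trajectory with a detected unbinding event: the wall-clock
#' first-passage time (ns) and the rescaled, unbiased dissociation time (s)
#' obtained by summing dt * exp(beta V) up to the event.
#'
#' @slot ligandId Ligand identifier.
#' @slot rescaledTimes Rescaled dissociation times in seconds.
#' @slot wallTimes Wall-clock unbinding times in ns.
#' @export
setClass("DissociationSample",
  representation(
    ligandId      = "character",
    rescaledTimes = "numeric",
    wallTimes     = "numeric"
  )
)

setValidity("DissociationSample", function(object) {
  msg <- character()
  if (length(object@rescaledTimes) != length(object@wallTimes))
    msg <- c(msg, "rescaledTimes and wallTimes must have equal length")
  if (any(!is.finite(object@rescaledTimes)) || any(object@rescaledTimes <= 0))
    msg <- c(msg, "rescaled times must be positive and finite")
  if (any(!is.finite(object@wallTimes)) || any(object@wallTimes <= 0))
    msg <- c(msg, "wall times must be positive and finite")
  if (length(msg)) msg else TRUE
})

#' Construct a DissociationSample
#'
#' @param ligandId Ligand identifier.
#' @param rescaledTimes Rescaled dissociation times (s).
#' @param wallTimes Wall-clock unbinding times (ns).
#' @return A \linkS4class{DissociationSample}.
#' @export
DissociationSample <- function(ligandId, rescaledTimes, wallTimes) {
  new("DissociationSample", ligandId = as.character(ligandId),
      rescaledTimes = as.numeric(rescaledTimes),
      wallTimes = as.numeric(wallTimes))
}

#' Poisson-process fit of rescaled dissociation times
#'
#' The characteristic time tau minimising the squared deviation between the
#' empirical CDF of the rescaled times and the homogeneous-Poisson CDF
#' 1 - exp(-t/tau), plus the two-sample Kolmogorov-Smirnov reliability test
#' result once \code{\link{ksReliability}} has been run.
#'
#' @slot tauHat Fitted residence time in seconds.
#' @slot ksStatistic KS statistic (NA before \code{ksReliability}).
#' @slot pValue KS p-value (NA before \code{ksReliability}).
#' @slot nEvents Number of unbinding events used in the fit.
#' @slot reliable TRUE iff pValue > threshold (strict).
#' @slot threshold The p-value acceptance threshold (default 0.05).
#' @slot converged FALSE if the CDF fit fell back to the sample mean.
#' @export
setClass("PoissonFit",
  representation(
    tauHat      = "numeric",
    ksStatistic = "numeric",
    pValue      = "numeric",
    nEvents     = "integer",
    reliable    = "logical",
    threshold   = "numeric",
    converged   = "logical"
  )
)

setValidity("PoissonFit", function(object) {
  msg <- character()
  if (!is.finite(object@tauHat) || object@tauHat <= 0)
    msg <- c(msg, "tauHat must be positive")
  if (is.finite(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    msg <- c(msg, "pValue must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Bootstrap summary of the residence time
#'
#' @slot meanTau Mean of the bootstrap tau distribution (s).
#' @slot semTau Standard error (sd of the bootstrap tau distribution, s).
#' @slot nBoot Number of bootstrap resamples.
#' @slot sampleSize Resample size.
#' @slot seed Seed used.
#' @export
setClass("BootstrapResult",
  representation(
    meanTau    = "numeric",
    semTau     = "numeric",
    nBoot      = "integer",
    sampleSize = "integer",
    seed       = "integer"
  )
)

setValidity("BootstrapResult", function(object) {
  msg <- character()
  if (!is.finite(object@semTau) || object@semTau < 0)
    msg <- c(msg, "semTau must be >= 0")
  if (object@nBoot < 1L) msg <- c(msg, "nBoot must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Frames with normalised unbiasing weights
#'
#' Frame observables (one or two columns: distances in Angstrom, energies
#' in kcal/mol, angles in degrees) paired with normalised non-negative
#' per-frame weights proportional to exp(+beta V).
#'
#' @slot values Numeric matrix, one row per frame, 1 or 2 columns.
#' @slot weights Normalised weights (sum to 1, all >= 0).
#' @slot temperature Temperature in Kelvin.
#' @export
setClass("WeightedEnsemble",
  representation(
    values      = "matrix",
    weights     = "numeric",
    temperature = "numeric"
  )
)

setValidity("WeightedEnsemble", function(object) {
  msg <- character()
  if (!ncol(object@values) %in% 1:2)
    msg <- c(msg, "values must have 1 or 2 columns")
  if (nrow(object@values) != length(object@weights))
    msg <- c(msg, "values and weights lengths differ")
  if (any(object@weights < 0)) msg <- c(msg, "weights must be >= 0")
  if (abs(sum(object@weights) - 1) > 1e-8)
    msg <- c(msg, "weights must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Construct a WeightedEnsemble
#'
#' Raw weights are normalised to sum to one.
#'
#' @param values Numeric vector (1D) or matrix with 1-2 columns.
#' @param weights Raw non-negative weights; default uniform.
#' @param temperature Temperature in Kelvin.
#' @return A \linkS4class{WeightedEnsemble}.
#' @export
WeightedEnsemble <- function(values, weights = NULL, temperature = 300) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  values <- as.matrix(values)
  if (is.null(weights)) weights <- rep(1, nrow(values))
  s <- sum(weights)
  if (!is.finite(s) || s <= 0) .stopf("weights must have a positive finite sum")
  new("WeightedEnsemble", values = values, weights = as.numeric(weights) / s,
      temperature = temperature)
}

#' Free-energy surface on a regular grid
#'
#' F = -kT log(reweighted density), shifted so the minimum over occupied
#' bins is zero; unoccupied bins are NA and flagged in \code{occupied}.
#'
#' @slot edges List of bin-edge vectors, one per dimension.
#' @slot freeEnergy Numeric array (kcal/mol), NA where unoccupied.
#' @slot occupied Logical array of the same shape.
#' @slot temperature Temperature in Kelvin.
#' @export
setClass("FreeEnergySurface",
  representation(
    edges       = "list",
    freeEnergy  = "array",
    occupied    = "array",
    temperature = "numeric"
  )
)

setValidity("FreeEnergySurface", function(object) {
  msg <- character()
  if (!any(object@occupied)) msg <- c(msg, "at least one bin must be occupied")
  else {
    mn <- min(object@freeEnergy[object@occupied])
    if (!is.finite(mn) || abs(mn) > 1e-8)
      msg <- c(msg, "minimum over occupied bins must be 0")
  }
  if (any(is.finite(object@freeEnergy[!object@occupied])))
    msg <- c(msg, "unoccupied bins must be NA")
  if (length(msg)) msg else TRUE
})

#' Ground truth behind a synthetic dataset
#'
#' @slot tauTrue True residence time in seconds (NA for feature datasets).
#' @slot rescaledTimesTrue The exponential first-passage draws (s).
#' @slot plantedWeights Named effect coefficients (log10 s per kcal/mol)
#'   for the planted (residue, substituent) pairs.
#' @slot noiseSd Target noise sd in log10 s.
#' @slot seed Seed used.
#' @export
setClass("SyntheticTruth",
  representation(
    tauTrue           = "numeric",
    rescaledTimesTrue = "numeric",
    plantedWeights    = "numeric",
    noiseSd           = "numeric",
    seed              = "integer"
  )
)

setValidity("SyntheticTruth", function(object) {
  if (length(object@tauTrue) == 1L && is.finite(object@tauTrue) &&
      object@tauTrue <= 0)
    "tauTrue must be positive" else TRUE
})

#' Log-scale Pearson correlation result
#'
#' @slot xField,yField The compared fields.
#' @slot subsetRule Description of the subset applied.
#' @slot n Number of qualifying records.
#' @slot r Pearson correlation of log10(x) vs log10(y).
#' @slot slope,intercept log10-scale regression line.
#' @slot excluded Ligand ids dropped for missing values.
#' @export
setClass("CorrelationResult",
  representation(
    xField     = "character",
    yField     = "character",
    subsetRule = "character",
    n          = "integer",
    r          = "numeric",
    slope      = "numeric",
    intercept  = "numeric",
    excluded   = "character"
  )
)

setValidity("CorrelationResult", function(object) {
  msg <- character()
  if (object@n < 3L) msg <- c(msg, "n must be >= 3")
  if (is.finite(object@r) && abs(object@r) > 1 + 1e-12)
    msg <- c(msg, "|r| must be <= 1")
  if (length(msg)) msg else TRUE
})
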