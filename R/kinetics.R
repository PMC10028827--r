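#' Detect the first unbinding event in a trajectory
#'
#' An unbinding event is defined as the ligand z position exceeding a
#' threshold (15 Angstrom by default) relative to the orthosteric-site
#' centre of mass. The time of the first frame with z > threshold is
#' returned; \code{NA} if the trajectory never crosses.
#'
#' @param traj A \linkS4class{BiasedTrajectory}.
#' @param zThreshold Unbinding threshold in Angstrom (default 15).
#' @return Event time in ps, or \code{NA_real_} if no event.
#' @examples
#' fr <- data.frame(time = c(0, 10, 20, 30), z = c(5, 10, 16, 20),
#'                  contacts = 4:1, bias = 0)
#' detectUnbinding(BiasedTrajectory("demo", fr))
#' @export
detectUnbinding <- function(traj, zThreshold = 15) {
  stopifnot(is(traj, "BiasedTrajectory"))
  fr <- frames(traj)
  if (nrow(fr) == 0L) .stopf("empty trajectory")
  idx <- which(fr$z > zThreshold)
  if (!length(idx)) return(NA_real_)
  fr$time[idx[1L]]
}

#' Rescale a biased first-passage time to its unbiased dissociation time
#'
#' Infrequent metadynamics accelerates escape by the instantaneous factor
#' exp(beta V(t)); the unbiased dissociation time is recovered as the
#' accumulated sum over frame increments dt * exp(beta V). The increment
#' between consecutive frames is weighted by the bias at the later frame,
#' so the bias at the crossing frame is included and frames after the
#' first crossing contribute nothing (first-passage convention).
#'
#' @param traj A \linkS4class{BiasedTrajectory} (times in ps, bias in
#'   kcal/mol).
#' @param eventTime Event time in ps, e.g. from
#'   \code{\link{detectUnbinding}}.
#' @return Rescaled dissociation time in seconds.
#' @examples
#' fr <- data.frame(time = c(0, 10, 20), z = c(5, 10, 16),
#'                  contacts = c(2, 1, 0),
#'                  bias = c(0, 0, kT(300) * log(2)))
#' rescaleTime(BiasedTrajectory("demo", fr), 20)  # (10 + 10*2) ps in s
#' @export
rescaleTime <- function(traj, eventTime) {
  stopifnot(is(traj, "BiasedTrajectory"))
  fr <- frames(traj)
  if (!is.finite(eventTime) || eventTime < fr$time[1L])
    .stopf("eventTime (%s ps) is before the first frame", format(eventTime))
  if (eventTime > fr$time[nrow(fr)])
    .stopf("eventTime (%s ps) is beyond the trajectory span", format(eventTime))
  idx <- max(which(fr$time <= eventTime))
  if (idx < 2L) return(0)
  beta <- 1 / kT(temperature(traj))
  dt <- diff(fr$time[seq_len(idx)])
  sum(dt * exp(beta * fr$bias[2:idx])) / .PS_PER_S
}

#' Collect rescaled dissociation times from a set of trajectories
#'
#' Runs event detection and time rescaling over a list of trajectories for
#' one ligand; trajectories without an unbinding event are dropped.
#'
#' @param trajs List of \linkS4class{BiasedTrajectory} objects.
#' @param zThreshold Unbinding threshold in Angstrom.
#' @return A \linkS4class{DissociationSample}.
#' @export
makeDissociationSample <- function(trajs, zThreshold = 15) {
  stopifnot(length(trajs) >= 1L)
  lig <- unique(vapply(trajs, ligandId, character(1)))
  if (length(lig) != 1L)
    .stopf("trajectories belong to multiple ligands: %s", paste(lig, collapse = ", "))
  ev <- vapply(trajs, detectUnbinding, numeric(1), zThreshold = zThreshold)
  keep <- which(!is.na(ev))
  resc <- vapply(keep, function(i) rescaleTime(trajs[[i]], ev[i]), numeric(1))
  DissociationSample(lig, resc, ev[keep] / 1e3)  # ps -> ns
}

# Internal tau estimator with fallback; returns list(tau, converged).
# method "ecdf": least squares of the ECDF (plotting positions (i-0.5)/n)
# against 1 - exp(-t/tau), solved on log(tau) by golden-section search.
# method "mle": the exponential maximum-likelihood estimator, the sample mean.
.fitTau <- function(ts, method = "ecdf") {
  m <- mean(ts)
  if (method == "mle") return(list(tau = m, converged = TRUE))
  if (stats::sd(ts) == 0 || !is.finite(m) || m <= 0)
    return(list(tau = m, converged = FALSE))
  n <- length(ts)
  Fi <- (seq_len(n) - 0.5) / n
  ts <- sort(ts)
  sse <- function(logTau) {
    tau <- exp(logTau)
    sum((Fi - (1 - exp(-ts / tau)))^2)
  }
  opt <- stats::optimize(sse, interval = log(m) + c(-7, 7), tol = 1e-10)
  tau <- exp(opt$minimum)
  if (!is.finite(tau) || tau <= 0) list(tau = m, converged = FALSE)
  else list(tau = tau, converged = TRUE)
}

#' Fit the residence time by matching the empirical CDF to a Poisson process
#'
#' The empirical cumulative distribution of the rescaled dissociation times
#' is fitted to the homogeneous-Poisson CDF 1 - exp(-t/tau) by nonlinear
#' least squares (plotting positions (i - 0.5)/n). If the fit degenerates,
#' tau falls back to the sample mean (the exponential ML estimator) and the
#' fit is flagged as not converged. \code{method = "mle"} requests the
#' sample mean directly.
#'
#' @param sample A \linkS4class{DissociationSample} with >= 3 events.
#' @param method \code{"ecdf"} (default) or \code{"mle"}.
#' @param threshold KS acceptance threshold stored for downstream use.
#' @return A \linkS4class{PoissonFit}; KS slots are NA until
#'   \code{\link{ksReliability}} is run.
#' @examples
#' ts <- -1 * log(1 - (seq_len(100) - 0.5) / 100)  # exact Exp(1) quantiles
#' tauHat(fitPoissonCDF(DissociationSample("demo", ts, ts * 1e9)))
#' @export
fitPoissonCDF <- function(sample, method = c("ecdf", "mle"), threshold = 0.05) {
  stopifnot(is(sample, "DissociationSample"))
  method <- match.arg(method)
  ts <- rescaledTimes(sample)
  if (length(ts) < 3L)
    .stopf("insufficient data: %d event(s), need >= 3", length(ts))
  if (stats::sd(ts) == 0)
    .stopf("degenerate sample: all dissociation times are identical")
  fit <- .fitTau(ts, method)
  new("PoissonFit", tauHat = fit$tau, ksStatistic = NA_real_,
      pValue = NA_real_, nEvents = length(ts), reliable = NA,
      threshold = threshold, converged = fit$converged)
}

#' Kolmogorov-Smirnov reliability test of a Poisson fit
#'
#' Tests the null hypothesis that the observed rescaled times and a large
#' sample drawn from the fitted exponential distribution Exp(tauHat) share
#' the same underlying Poisson distribution, via the two-sample KS test.
#' The null is accepted (the estimate deemed reliable) when the p-value
#' exceeds the threshold strictly.
#'
#' @param sample The \linkS4class{DissociationSample} that was fitted.
#' @param fit The \linkS4class{PoissonFit} to test.
#' @param nRandom Size of the reference sample drawn from Exp(tauHat).
#' @param seed Integer seed for the reference draw.
#' @return The \linkS4class{PoissonFit} with \code{ksStatistic},
#'   \code{pValue} and \code{reliable} filled in (see \code{\link{pValue}},
#'   \code{\link{isReliable}}).
#' @export
ksReliability <- function(sample, fit, nRandom = 1e6, seed = 1L) {
  stopifnot(is(sample, "DissociationSample"), is(fit, "PoissonFit"))
  ts <- rescaledTimes(sample)
  if (nRandom < length(ts))
    .stopf("nRandom (%d) must be >= the observed sample size (%d)",
           nRandom, length(ts))
  ref <- .withSeed(seed, stats::rexp(nRandom, rate = 1 / tauHat(fit)))
  ks <- suppressWarnings(stats::ks.test(ts, ref))
  fit@ksStatistic <- unname(ks$statistic)
  fit@pValue <- ks$p.value
  fit@reliable <- ks$p.value > fit@threshold  # strict inequality
  validObject(fit)
  fit
}

#' Bootstrap mean and standard error of the residence time
#'
#' Resamples the rescaled dissociation times with replacement (samples of
#' the given size), refits tau on each resample, and reports the mean and
#' standard error (sd of the bootstrap tau distribution). The protocol
#' default is 10,000 resamples of size 15. Degenerate resamples (all times
#' identical) fall back to the sample-mean estimator.
#'
#' @param sample A \linkS4class{DissociationSample}.
#' @param nBoot Number of bootstrap resamples.
#' @param size Resample size (>= 3).
#' @param seed Integer seed.
#' @param method Passed to the tau refit, \code{"ecdf"} or \code{"mle"}.
#' @return A \linkS4class{BootstrapResult}.
#' @export
bootstrapTau <- function(sample, nBoot = 10000, size = 15, seed = 1L,
                         method = c("ecdf", "mle")) {
  stopifnot(is(sample, "DissociationSample"))
  method <- match.arg(method)
  ts <- rescaledTimes(sample)
  if (!length(ts)) .stopf("empty dissociation sample")
  if (size < 3L) .stopf("insufficient data: resample size %d, the fit needs >= 3", size)
  taus <- .withSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      .fitTau(base::sample(ts, size, replace = TRUE), method)$tau
    }, numeric(1))
  })
  new("BootstrapResult", meanTau = mean(taus), semTau = stats::sd(taus),
      nBoot = as.integer(nBoot), sampleSize = as.integer(size),
      seed = as.integer(seed))
}

#' Per-ligand kinetics summary table
#'
#' Runs the full estimation chain (event detection, time rescaling,
#' Poisson-CDF fit, KS reliability, bootstrap) over per-ligand trajectory
#' sets and returns the summary emitted by the pipeline.
#'
#' @param trajSets Named list: ligand id -> list of
#'   \linkS4class{BiasedTrajectory}.
#' @param zThreshold Unbinding threshold in Angstrom.
#' @param nRandom Reference sample size for the KS test.
#' @param nBoot,size Bootstrap parameters.
#' @param seed Master seed; per-ligand seeds are derived from it.
#' @return data.frame with columns ligand_id, n_events, tau_hat_s, ks_p,
#'   mean_tau_s, sem_tau_s, seed.
#' @export
kineticsSummary <- function(trajSets, zThreshold = 15, nRandom = 1e5,
                            nBoot = 1000, size = 15, seed = 1L) {
  stopifnot(is.list(trajSets), length(trajSets) >= 1L)
  seeds <- .deriveSeeds(seed, 2L * length(trajSets))
  rows <- lapply(seq_along(trajSets), function(i) {
    smp <- makeDissociationSample(trajSets[[i]], zThreshold)
    fit <- fitPoissonCDF(smp)
    fit <- ksReliability(smp, fit, nRandom = nRandom, seed = seeds[2 * i - 1])
    bt <- bootstrapTau(smp, nBoot = nBoot, size = size, seed = seeds[2 * i])
    data.frame(ligand_id = ligandId(smp),
               n_events = length(rescaledTimes(smp)),
               tau_hat_s = tauHat(fit), ks_p = pValue(fit),
               mean_tau_s = meanTau(bt), sem_tau_s = semTau(bt),
               seed = seeds[2 * i])
  })
  do.call(rbind, rows)
}
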