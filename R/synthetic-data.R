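# Bias value active during stride k (k = 1 is the first, unbiased stride):
# deposition happens at the end of each stride, so stride k carries k-1
# accumulated hills, capped (step_ramp) or saturating towards the cap the
# way a well-tempered bias flattens.
.biasAtStride <- function(schedule, k) {
  h <- schedule@hillHeight
  cap <- schedule@biasCap
  switch(schedule@growthModel,
    step_ramp  = pmin(h * (k - 1), cap),
    saturating = if (cap == 0) rep(0, length(k)) else
                 cap * (1 - exp(-h * (k - 1) / cap))
  )
}

# First stride index at which the accumulated rescaled time reaches
# `targetPs`, plus the per-stride rescaled increments up to it.
.escapeStride <- function(schedule, targetPs) {
  beta <- 1 / kT(schedule@temperature)
  dt <- schedule@depositionStride
  chunk <- 4096L
  from <- 1L
  total <- 0
  incs <- numeric(0)
  repeat {
    k <- seq.int(from, from + chunk - 1L)
    inc <- dt * exp(beta * .biasAtStride(schedule, k))
    cum <- total + cumsum(inc)
    hit <- which(cum >= targetPs)
    if (length(hit)) {
      incs <- c(incs, inc[seq_len(hit[1L])])
      return(list(stride = from + hit[1L] - 1L, increments = incs))
    }
    incs <- c(incs, inc)
    total <- cum[chunk]
    from <- from + chunk
    if (from > 5e7) .stopf("bias schedule never accumulates the target rescaled time")
  }
}

#' Generate synthetic biased unbinding trajectories
#'
#' Emulates infrequent-metadynamics unbinding runs from a known
#' homogeneous Poisson process: for each trajectory an exponential
#' first-passage time T* ~ Exp(tauTrue) is drawn, the deterministic bias
#' schedule is integrated stride by stride, and the trajectory unbinds
#' (z crosses 15 Angstrom) at the first stride where the accumulated
#' rescaled time sum(dt * exp(beta V)) reaches T*. The z trace rises
#' monotonically (plus noise) from 2 Angstrom to the threshold with an
#' anti-correlated contact count, so the event detector sees realistic
#' shapes. By construction the rescaled time recomputed from the emitted
#' frames equals T* to within one stride's rescaled increment.
#'
#' @param tauTrue True residence time in seconds.
#' @param schedule A \linkS4class{BiasSchedule}.
#' @param nTraj Number of trajectories (>= 1).
#' @param seed Integer seed (all randomness derives from it).
#' @param ligandId Ligand id stamped on the trajectories.
#' @param zThreshold Unbinding threshold in Angstrom.
#' @return list with \code{trajectories} (list of
#'   \linkS4class{BiasedTrajectory}) and \code{truth}
#'   (\linkS4class{SyntheticTruth} carrying the drawn T* values).
#' @examples
#' out <- genUnbindingTrajectories(1e-9, BiasSchedule(hillHeight = 0),
#'                                 nTraj = 3, seed = 7)
#' length(out$trajectories)
#' @export
genUnbindingTrajectories <- function(tauTrue, schedule = BiasSchedule(),
                                     nTraj = 15L, seed = 1L,
                                     ligandId = "synthetic",
                                     zThreshold = 15) {
  if (!is.finite(tauTrue) || tauTrue <= 0) .stopf("tauTrue must be positive")
  stopifnot(is(schedule, "BiasSchedule"))
  validObject(schedule)
  if (nTraj < 1L) .stopf("nTraj must be >= 1")
  dt <- schedule@depositionStride
  .withSeed(seed, {
    targets <- -tauTrue * log(stats::runif(nTraj))      # Exp(tauTrue) draws, s
    trajs <- lapply(seq_len(nTraj), function(i) {
      esc <- .escapeStride(schedule, targets[i] * .PS_PER_S)
      k <- esc$stride
      times <- seq.int(0L, k + 2L) * dt
      bias <- c(0, .biasAtStride(schedule, seq_len(k + 2L)))
      # monotone-plus-noise approach from 2 A to the threshold; the event
      # frame crosses and the two trailing frames stay above it
      prog <- 2 + (zThreshold - 0.5 - 2) * (seq.int(0L, k) / k)^1.5
      z <- pmin(prog + c(0, stats::rnorm(k, 0, 0.3)), zThreshold - 0.1)
      z[k + 1L] <- zThreshold + 0.2 + abs(stats::rnorm(1, 0, 0.3))
      z <- c(z, z[k + 1L] + c(1, 2) + abs(stats::rnorm(2, 0, 0.3)))
      contacts <- round(pmax(0, 50 * (1 - (z - 2) / (zThreshold - 2)) +
                                  stats::rnorm(k + 3L, 0, 1)))
      BiasedTrajectory(ligandId,
        data.frame(time = times, z = z, contacts = contacts, bias = bias),
        temperature = schedule@temperature)
    })
    truth <- new("SyntheticTruth", tauTrue = tauTrue,
                 rescaledTimesTrue = targets,
                 plantedWeights = numeric(0), noiseSd = NA_real_,
                 seed = as.integer(seed))
    list(trajectories = trajs, truth = truth)
  })
}

#' Generate a synthetic residue-substituent feature dataset
#'
#' Emulates the interaction-energy inputs of the structure-kinetics ML
#' stage: per-ligand per-pair mean energies mu_ij are drawn from
#' Gaussians, frame-level energies scatter around them, and the target
#' log10 residence time is an exact linear function of the planted pairs'
#' means plus Gaussian noise. Non-planted pairs have zero effect. One
#' decoy pair receives the largest energy magnitude but zero effect,
#' mirroring a strong-but-kinetically-silent anchor interaction, so
#' importance rankings can be checked against ground truth.
#'
#' @param nLigands Number of ligands (default 19).
#' @param nPairs Number of (residue, substituent) pairs (default 24; must
#'   be >= number of planted pairs + 1 for the decoy).
#' @param plantedWeights Named numeric vector of effect coefficients in
#'   log10 s per kcal/mol; names become pair ids (residue and substituent
#'   separated by "."). Defaults to three stabilising modulators.
#' @param noiseSd Target noise sd in log10 s (default 0.05).
#' @param framesPerLigand Frames per ligand (default 500).
#' @param seed Integer seed.
#' @param frameSd Frame-level energy sd around the per-ligand mean
#'   (kcal/mol).
#' @param decoyPair Pair id for the strong zero-effect decoy, or NULL.
#' @param exitFraction Fraction of frames placed past the 15 Angstrom
#'   exit threshold (ineligible for feature sampling).
#' @return list with \code{energyTable} (long-format data.frame:
#'   ligand_id, trajectory_id, frame_time, residue_id, substituent,
#'   energy, frame_bias, z), \code{tauTable} (ligand_id, log10_tau,
#'   tau_s), \code{pairMeans} (ligand x pair matrix of true means) and
#'   \code{truth} (\linkS4class{SyntheticTruth}).
#' @export
genFeatureDataset <- function(nLigands = 19L, nPairs = 24L,
                              plantedWeights = c("H297.R4" = -0.5,
                                                 "H297.R1" = -0.4,
                                                 "W293.R1" = -0.35),
                              noiseSd = 0.05, framesPerLigand = 500L,
                              seed = 1L, frameSd = 2,
                              decoyPair = "D147.R1",
                              exitFraction = 0.05) {
  if (noiseSd < 0) .stopf("noiseSd must be >= 0")
  if (is.null(names(plantedWeights)) && length(plantedWeights))
    .stopf("plantedWeights must be named by pair id ('RES.Rk')")
  nPlanted <- length(plantedWeights)
  if (nPairs < nPlanted + length(decoyPair))
    .stopf("nPairs must cover the planted pairs and the decoy")
  if (framesPerLigand < 1L) .stopf("framesPerLigand must be >= 1")

  residuePool <- c("D147", "H297", "W293", "W318", "M151", "S154", "I296",
                   "V300", "Y148", "Q124", "W133", "K233", "V236", "F237",
                   "L219", "C217", "T218", "G325", "I322", "Y326", "N127",
                   "I144", "V143", "A240", "F152", "E229", "K303", "T315")
  subsPool <- c("R1", "R2", "R4")
  allPairs <- as.vector(outer(residuePool, subsPool, paste, sep = "."))
  pairs <- c(names(plantedWeights), decoyPair)
  pairs <- c(pairs, setdiff(allPairs, pairs))[seq_len(nPairs)]

  w <- stats::setNames(numeric(nPairs), pairs)
  w[names(plantedWeights)] <- plantedWeights

  .withSeed(seed, {
    ligands <- sprintf("L%02d", seq_len(nLigands))
    # per-ligand pair means: planted pairs get a wide stabilising spread,
    # the decoy the largest magnitude, the rest a mild background
    mu <- matrix(0, nLigands, nPairs, dimnames = list(ligands, pairs))
    for (j in seq_len(nPairs)) {
      p <- pairs[j]
      mu[, j] <- if (p %in% names(plantedWeights)) stats::rnorm(nLigands, -6, 3)
      else if (!is.null(decoyPair) && p == decoyPair) stats::rnorm(nLigands, -12, 1)
      else stats::rnorm(nLigands, -2, 1)
    }
    log10tau <- as.vector(mu %*% w) + stats::rnorm(nLigands, 0, noiseSd)

    nf <- framesPerLigand
    frameTimes <- 10 * seq_len(nf)
    trajIds <- sprintf("t%02d", ((seq_len(nf) - 1L) %% 15L) + 1L)
    tabs <- lapply(seq_len(nLigands), function(i) {
      z <- stats::runif(nf, 2, 14)
      nExit <- floor(exitFraction * nf)
      if (nExit > 0) z[sample.int(nf, nExit)] <- stats::runif(nExit, 15.5, 30)
      fb <- stats::runif(nf, 0, 3)
      energy <- as.vector(vapply(seq_len(nPairs), function(j)
        stats::rnorm(nf, mu[i, j], frameSd), numeric(nf)))
      data.frame(
        ligand_id = ligands[i],
        trajectory_id = rep(trajIds, nPairs),
        frame_time = rep(frameTimes, nPairs),
        residue_id = rep(sub("\\.R[124]$", "", pairs), each = nf),
        substituent = rep(sub("^.*\\.", "", pairs), each = nf),
        energy = energy,
        frame_bias = rep(fb, nPairs),
        z = rep(z, nPairs))
    })
    energyTable <- do.call(rbind, tabs)
    rownames(energyTable) <- NULL
    truth <- new("SyntheticTruth", tauTrue = NA_real_,
                 rescaledTimesTrue = numeric(0), plantedWeights = w,
                 noiseSd = noiseSd, seed = as.integer(seed))
    list(energyTable = energyTable,
         tauTable = data.frame(ligand_id = ligands, log10_tau = log10tau,
                               tau_s = 10^log10tau),
         pairMeans = mu, truth = truth)
  })
}

#' Packaged opioid ligand records
#'
#' Returns the 19-compound study set (15 fentanyl analogs including the
#' parent fentanyl, and 4 morphinans) with transcribed canonical SMILES
#' and substituent-class labels. Experimental kinetic and affinity values
#' (tau_exp, K_d, K_i,NLX) and the calculated residence times live in
#' optional columns; they are shipped empty because the source value
#' tables are not redistributed with the package, and can be filled from
#' a user-supplied CSV via \code{\link{readLigandTable}}.
#'
#' @return data.frame of ligand records (one row per ligand).
#' @examples
#' nrow(ligandFixture())
#' @export
ligandFixture <- function() {
  path <- system.file("extdata", "ligands.csv", package = "MetadKinetics",
                      mustWork = TRUE)
  readLigandTable(path)
}
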