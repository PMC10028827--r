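# Shared fixture builders; everything is generated in code.

# A hand-sized trajectory with explicit frames.
tinyTrajectory <- function(time = c(0, 10, 20, 30),
                           z = c(5, 10, 16, 20),
                           bias = rep(0, length(time)),
                           contacts = rev(seq_along(time)),
                           temperature = 300) {
  BiasedTrajectory("tiny", data.frame(time = time, z = z,
                                      contacts = contacts, bias = bias),
                   temperature = temperature)
}

# Random trajectory whose z never crosses until the last frame.
randomTrajectory <- function(n = 50, seed = 1, temperature = 300,
                             maxBias = 3) {
  set.seed(seed)
  fr <- data.frame(time = cumsum(runif(n, 5, 15)),
                   z = c(runif(n - 1, 2, 14), 16),
                   contacts = sample(0:40, n, replace = TRUE),
                   bias = runif(n, 0, maxBias))
  BiasedTrajectory("rand", fr, temperature = temperature)
}

# Energy table with exactly known per-(ligand, pair) frame energies.
# `means` is a ligand x pair matrix; each frame's energy equals the mean
# (no frame noise), bias zero, all frames eligible.
exactEnergyTable <- function(means, framesPerLigand = 4) {
  pairs <- colnames(means)
  rows <- list()
  for (lig in rownames(means)) {
    for (p in pairs) {
      rows[[length(rows) + 1L]] <- data.frame(
        ligand_id = lig, trajectory_id = "t1",
        frame_time = 10 * seq_len(framesPerLigand),
        residue_id = sub("\\.R[124]$", "", p),
        substituent = sub("^.*\\.", "", p),
        energy = means[lig, p], frame_bias = 0,
        z = 5)
    }
  }
  do.call(rbind, rows)
}

# Feature table with target exactly linear in one feature.
linearFeatureTable <- function(n = 1000, p = 6, seed = 1, noise = 0) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("P", seq_len(p), ".R1")))
  df <- data.frame(ligand_id = rep(sprintf("L%02d", 1:10), length.out = n),
                   X, check.names = FALSE)
  df$log10_tau <- 2 * X[, 1L] + rnorm(n, 0, noise)
  df
}
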