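test_that("frame weights follow exp(beta V) with stable normalisation", {
  expect_equal(frameWeights(rep(0, 4)), rep(0.25, 4))
  expect_equal(frameWeights(c(0, kT(300) * log(3))), c(0.25, 0.75))
  # shift invariance
  b <- runif(20, 0, 5)
  expect_equal(frameWeights(b), frameWeights(b + 2.7))
  # numerically stable at huge biases
  expect_equal(sum(frameWeights(c(0, 5000))), 1)
  expect_error(frameWeights(numeric(0)), "empty")
  expect_error(frameWeights(c(1, Inf)), "finite")
})

test_that("reweighted histograms integrate to one and honour the weights", {
  set.seed(1)
  x <- rnorm(5000)
  h <- reweightedHistogram(WeightedEnsemble(x), bins = 40)
  widths <- diff(h$edges[[1]])
  expect_equal(sum(h$density * widths), 1)
  # all weight on one frame: a single occupied bin with full mass
  h1 <- reweightedHistogram(WeightedEnsemble(c(1, 2, 3), c(0, 1, 0)),
                            bins = seq(0, 4, 1))
  expect_equal(sum(h1$occupied), 1L)
  expect_equal(sum(h1$density * diff(h1$edges[[1]])), 1)
  # weighting equals literal frame replication
  v <- c(0.5, 1.5, 2.5)
  hw <- reweightedHistogram(WeightedEnsemble(v, c(1, 2, 3)), bins = seq(0, 3, 1))
  hr <- reweightedHistogram(WeightedEnsemble(rep(v, c(1, 2, 3))), bins = seq(0, 3, 1))
  expect_equal(hw$density, hr$density)
  expect_error(reweightedHistogram(WeightedEnsemble(c(1, 10)), bins = seq(0, 5, 1)),
               "cover the data range")
})

test_that("the FES of unweighted samples equals -kT log of the plain histogram", {
  set.seed(2)
  x <- rnorm(2000)
  edges <- seq(-4.5, 4.5, 0.25)
  surf <- fes(WeightedEnsemble(x), bins = edges)
  counts <- hist(x, breaks = edges, plot = FALSE)$density
  ref <- -kT(300) * log(counts)
  ref <- ref - min(ref[is.finite(ref)])
  fe <- freeEnergy(surf)
  expect_equal(fe[occupiedBins(surf)], ref[counts > 0], ignore_attr = TRUE)
  # multiplying all raw weights by a constant changes nothing
  surf2 <- fes(WeightedEnsemble(x, rep(7, length(x))), bins = edges)
  expect_equal(freeEnergy(surf2), fe)
})

test_that("reweighting biased samples recovers the unbiased free energy", {
  # the biased ensemble carries the potential U + V; weights exp(+beta V)
  # remove the deposited bias and recover the U-based surface
  kTv <- kT(300)
  U <- function(x) 2 * (x^2 - 1)^2
  V <- function(x) 1.5 * cos(2 * x)
  set.seed(3)
  xs <- seq(-1.8, 1.8, length.out = 3601)
  p <- exp(-(U(xs) + V(xs)) / kTv)
  samp <- sample(xs, 2e5, replace = TRUE, prob = p / sum(p))
  samp <- samp + runif(length(samp), -5e-4, 5e-4)
  ens <- WeightedEnsemble(samp, weights = frameWeights(V(samp)))
  surf <- fes(ens, bins = seq(-2, 2, 0.05))
  centres <- (head(gridEdges(surf)[[1]], -1) + tail(gridEdges(surf)[[1]], -1)) / 2
  well <- abs(abs(centres) - 1) < 0.3
  ref <- U(centres) - min(U(centres)[well])
  fe <- freeEnergy(surf)
  expect_lt(max(abs(fe[well] - ref[well]), na.rm = TRUE), 0.3)
})

test_that("basin detection separates and merges wells by barrier depth", {
  kTv <- kT(300)
  set.seed(4)
  # two wells at -1 and 1; sd 0.3 keeps the saddle region occupied so the
  # merge rule (not an unoccupied gap) decides the basin count
  x <- c(rnorm(8000, -1, 0.3), rnorm(8000, 1, 0.3))
  surf <- fes(WeightedEnsemble(x), bins = seq(-2.5, 2.5, 0.1))
  bas <- locateBasins(surf, depthCutoff = 1)
  expect_length(bas, 2L)
  mins <- sort(vapply(bas, function(b) b$minLocation, numeric(1)))
  expect_equal(mins, c(-1, 1), tolerance = 0.2, ignore_attr = TRUE)
  # flood-fill oracle: occupied bins below the barrier form 2 components
  fe <- freeEnergy(surf)
  low <- which(!is.na(fe) & fe < 1)
  comp <- 0L; seen <- logical(length(fe))
  for (s in low) {
    if (seen[s]) next
    comp <- comp + 1L
    queue <- s
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      if (seen[cur]) next
      seen[cur] <- TRUE
      for (nb in c(cur - 1L, cur + 1L))
        if (nb %in% low && !seen[nb]) queue <- c(queue, nb)
    }
  }
  expect_equal(length(bas), comp)
  # the same surface with a generous cutoff merges into one basin
  basMerged <- locateBasins(surf, depthCutoff = 50)
  expect_length(basMerged, 1L)
  # single quadratic well: exactly one basin at the minimum
  xq <- rnorm(5000, 0.5, 0.2)
  sq <- fes(WeightedEnsemble(xq), bins = seq(-1, 2, 0.1))
  bq <- locateBasins(sq, depthCutoff = 0.5)
  expect_length(bq, 1L)
  expect_equal(bq[[1]]$minLocation, 0.5, tolerance = 0.15)
})

test_that("binding modes are read from basin minima in distance windows", {
  mk2d <- function(cx, cy) cbind(c(rnorm(3000, cx[1], 0.25), rnorm(3000, cx[2], 0.25)),
                                 c(rnorm(3000, cy[1], 0.25), rnorm(3000, cy[2], 0.25)))
  set.seed(5)
  edges <- list(seq(0, 16, 0.25), seq(0, 16, 0.25))
  # one minimum at (3.5, 8): salt bridge only
  s1 <- fes(WeightedEnsemble(cbind(rnorm(4000, 3.5, 0.25), rnorm(4000, 8, 0.25))),
            bins = edges)
  expect_identical(classifyBindingMode(s1), "D147 salt bridge")
  # minima at (3.5, 8) and (7, 3): both anchor modes, the dual-mode pattern
  s2 <- fes(WeightedEnsemble(mk2d(c(3.5, 7), c(8, 3))), bins = edges)
  expect_setequal(classifyBindingMode(s2), c("D147 salt bridge", "H297 h-bond"))
  # minimum at (8, 14): the loosely bound window
  s3 <- fes(WeightedEnsemble(cbind(rnorm(4000, 8, 0.25), rnorm(4000, 14, 0.25))),
            bins = edges)
  expect_identical(classifyBindingMode(s3), "loosely bound")
})
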