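test_that("frame sampling respects eligibility and set inclusion", {
  gen <- genFeatureDataset(nLigands = 3, nPairs = 4, framesPerLigand = 60,
                           seed = 1, exitFraction = 0.2)
  tab <- gen$energyTable
  samp <- sampleFrames(tab, 20, seed = 2)
  expect_true(all(samp$z <= 15))
  keyAll <- paste(tab$ligand_id, tab$trajectory_id, tab$frame_time)
  keySmp <- paste(samp$ligand_id, samp$trajectory_id, samp$frame_time)
  expect_true(all(keySmp %in% keyAll[tab$z <= 15]))     # inclusion oracle
  expect_equal(unname(table(unique(data.frame(samp$ligand_id, keySmp))[, 1])),
               rep(20L, 3), ignore_attr = TRUE)
  # requesting every eligible frame returns them all
  elig <- tab[tab$ligand_id == "L01" & tab$z <= 15, ]
  nElig <- length(unique(paste(elig$trajectory_id, elig$frame_time)))
  full <- sampleFrames(tab[tab$ligand_id == "L01", ], nElig, seed = 3)
  expect_equal(length(unique(paste(full$trajectory_id, full$frame_time))), nElig)
  # all frames past the threshold: insufficient data, ligand named
  tabExit <- tab
  tabExit$z <- 20
  expect_error(sampleFrames(tabExit, 5, seed = 4), "L01")
})

test_that("pair filtering applies the magnitude-and-spread rule exactly", {
  # 5 ligands x 6 pairs with hand-picked means; zero bias so the
  # reweighted means equal the plain means
  means <- rbind(
    c(0, -5.0, -0.5, -3.0, -1.2, 2.0),
    c(0, -5.0, -0.5, -2.0, -1.0, 0.5),
    c(0, -5.0, -0.5, -4.0, -0.9, 1.0),
    c(0, -5.0, -0.5, -2.5, -1.1, 3.0),
    c(0, -5.0, -0.5, -3.5, -1.0, 1.5))
  dimnames(means) <- list(sprintf("L%02d", 1:5),
                          c("A1.R1", "A2.R1", "A3.R2", "A4.R4", "A5.R1", "A6.R2"))
  tab <- exactEnergyTable(means)
  flt <- filterPairs(tab, magnitudeCutoff = 1, spreadCutoff = 0.25)
  # brute-force oracle
  oracle <- apply(abs(means), 2, max) >= 1 & apply(means, 2, sd) >= 0.25
  expect_equal(setNames(flt$keep, flt$pair), oracle[order(names(oracle))])
  # the all-zero pair fails magnitude, the constant -5 pair fails spread
  expect_false(flt$keep[flt$pair == "A1.R1"])
  expect_false(flt$keep[flt$pair == "A2.R1"])
  expect_true(flt$keep[flt$pair == "A4.R4"])
})

test_that("reweighted pair means respond to the frame bias", {
  tab <- data.frame(ligand_id = "L", trajectory_id = "t1",
                    frame_time = c(10, 20), residue_id = "D147",
                    substituent = "R1", energy = c(0, 10),
                    frame_bias = c(0, kT(300) * log(3)), z = 5)
  mu <- pairMeansReweighted(tab)
  expect_equal(mu["L", "D147.R1"], 0.25 * 0 + 0.75 * 10)
})

test_that("block-mean augmentation reduces to the plain mean and shrinks variance", {
  gen <- genFeatureDataset(nLigands = 4, nPairs = 5, framesPerLigand = 200,
                           seed = 5, exitFraction = 0)
  tab <- gen$energyTable
  # degenerate: block = all frames, one row -> per-ligand mean
  ft1 <- augmentDataset(tab, gen$tauTable, nAug = 1, blockSize = 200, seed = 6)
  pid <- paste(tab$residue_id, tab$substituent, sep = ".")
  for (lig in gen$tauTable$ligand_id) {
    sel <- tab$ligand_id == lig
    plain <- tapply(tab$energy[sel], pid[sel], mean)
    got <- unlist(ft1[ft1$ligand_id == lig, names(plain)])
    expect_equal(got, plain, ignore_attr = TRUE)
  }
  # determinism
  a <- augmentDataset(tab, gen$tauTable, nAug = 10, blockSize = 50, seed = 7)
  b <- augmentDataset(tab, gen$tauTable, nAug = 10, blockSize = 50, seed = 7)
  expect_identical(a, b)
  # variance shrinkage with block size
  small <- augmentDataset(tab, gen$tauTable, nAug = 80, blockSize = 10, seed = 8)
  large <- augmentDataset(tab, gen$tauTable, nAug = 80, blockSize = 150, seed = 8)
  fc <- setdiff(names(small), c("ligand_id", "log10_tau"))
  sdS <- sd(small[small$ligand_id == "L01", fc[1]])
  sdL <- sd(large[large$ligand_id == "L01", fc[1]])
  expect_lt(sdL, sdS)
  # targets must cover every ligand
  expect_error(augmentDataset(tab, gen$tauTable[-1, ], nAug = 2, blockSize = 10,
                              seed = 9), "missing target")
  expect_error(augmentDataset(tab, gen$tauTable, nAug = 2, blockSize = 1e5,
                              seed = 9), "exceeds")
})

test_that("all four tree ensembles learn a noise-free linear signal", {
  ft <- linearFeatureTable(n = 1000, noise = 0)
  tm <- trainModels(ft, seed = 11, tune = FALSE)
  expect_true(all(tm$metrics$r2 >= 0.99))
  expect_setequal(tm$metrics$model, c("rf", "et", "gb", "xgb"))
})

test_that("a permuted target yields no generalisation", {
  set.seed(12)
  r2s <- replicate(10, {
    ft <- linearFeatureTable(n = 300, seed = sample.int(1e6, 1))
    ft$log10_tau <- sample(ft$log10_tau)
    tm <- trainModels(ft, models = c("rf", "xgb"), seed = sample.int(1e6, 1),
                      tune = FALSE)
    mean(tm$metrics$r2, na.rm = TRUE)
  })
  expect_lt(mean(r2s, na.rm = TRUE), 0.2)
})

test_that("constant targets give zero test error and an undefined r2", {
  ft <- linearFeatureTable(n = 100)
  ft$log10_tau <- 3.5
  tm <- trainModels(ft, models = c("rf", "xgb"), seed = 13, tune = FALSE)
  expect_true(all(tm$metrics$rmse < 1e-8))
  expect_true(all(is.na(tm$metrics$r2)))
})

test_that("training validates its inputs", {
  ft <- linearFeatureTable(n = 100)
  ft$ligand_id <- "L01"
  expect_error(trainModels(ft, seed = 1), "degenerate target")
  expect_error(trainModels(linearFeatureTable(n = 8), seed = 1), "at least 10")
})

test_that("permutation importance isolates the informative feature", {
  ft <- linearFeatureTable(n = 400, noise = 0)
  ft[["P3.R1"]] <- 1    # constant column: never split on
  tm <- trainModels(ft, models = c("rf", "xgb"), seed = 14, tune = FALSE)
  fc <- setdiff(names(ft), c("ligand_id", "log10_tau"))
  Xte <- as.matrix(ft[tm$testIdx, fc])
  yte <- ft$log10_tau[tm$testIdx]
  for (kind in c("rf", "xgb")) {
    sc <- permutationImportance(tm$fits[[kind]], Xte, yte, nRepeats = 3, seed = 15)
    expect_identical(unname(sc["P3.R1"]), 0)          # unused feature: exactly 0
    expect_equal(names(which.max(sc)), "P1.R1")       # planted signal on top
    # forced identity permutation scores 0 everywhere
    sc0 <- permutationImportance(tm$fits[[kind]], Xte, yte, nRepeats = 2,
                                 seed = 16, permuteFun = seq_len)
    expect_true(all(sc0 == 0))
  }
})

test_that("additive attributions are locally accurate for every model", {
  ft <- linearFeatureTable(n = 300, noise = 0.1)
  tm <- trainModels(ft, seed = 17, tune = FALSE)
  fc <- setdiff(names(ft), c("ligand_id", "log10_tau"))
  X <- as.matrix(ft[tm$testIdx, fc])[1:40, ]
  for (kind in names(tm$fits)) {
    at <- additiveAttributions(tm$fits[[kind]], X)
    pred <- predict(tm$fits[[kind]], X)
    scale <- max(abs(pred))
    tol <- if (kind %in% c("rf", "et")) 1e-9 else 1e-5  # float32 TreeSHAP
    expect_lt(max(abs(at$prediction - pred)) / scale, tol)
  }
  expect_error(additiveAttributions(lm(log10_tau ~ ., ft[, -1]), X),
               "unsupported model")
})

test_that("a single-split stump attributes only its split feature", {
  set.seed(18)
  X <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- ifelse(X[, "b"] > 0, 2, -2)
  d <- xgboost::xgb.DMatrix(X, label = y)
  bst <- xgboost::xgb.train(params = list(max_depth = 1L, eta = 1,
                                          objective = "reg:squarederror",
                                          nthread = 1L),
                            data = d, nrounds = 1, verbose = 0)
  fit <- structure(list(kind = "xgb", model = bst, featureNames = colnames(X),
                        trainX = X, trainY = y), class = "mkModelFit")
  at <- additiveAttributions(fit, X)
  expect_true(all(at$contributions[, c("a", "c")] == 0))
  expect_equal(at$contributions[, "b"] + at$base, predict(fit, X),
               tolerance = 1e-6)
})

test_that("trial aggregation matches the brute-force mean of per-trial scores", {
  gen <- genFeatureDataset(nLigands = 6, nPairs = 6, framesPerLigand = 80,
                           seed = 19)
  samp <- sampleFrames(gen$energyTable, 60, seed = 20)
  rep2 <- runTrials(sampledTable = samp, tauTable = gen$tauTable, nTrials = 3,
                    seed = 21, models = c("rf", "xgb"), nAug = 30,
                    blockSize = 30, nRepeats = 2)
  for (m in c("rf", "xgb")) {
    sub <- rep2$scores[rep2$scores$model == m, ]
    brute <- tapply(sub$score, sub$feature, mean)
    got <- rep2$perModel[rep2$perModel$model == m, ]
    expect_equal(setNames(got$mean_score, got$feature),
                 setNames(as.vector(brute[got$feature]), got$feature))
  }
  # a single trial is just one train + importance pass
  rep1 <- runTrials(sampledTable = samp, tauTable = gen$tauTable, nTrials = 1,
                    seed = 22, models = "rf", nAug = 30, blockSize = 30,
                    nRepeats = 2)
  expect_equal(max(rep1$scores$trial), 1L)
  expect_true(all(rep1$perModel$sd_score == 0))
  # determinism of the whole loop under the master seed
  rep1b <- runTrials(sampledTable = samp, tauTable = gen$tauTable, nTrials = 1,
                     seed = 22, models = "rf", nAug = 30, blockSize = 30,
                     nRepeats = 2)
  expect_identical(rep1$scores, rep1b$scores)
})

test_that("top-k selection follows the aggregate ranking exactly", {
  agg <- data.frame(feature = sprintf("F%02d", 1:24),
                    score = seq(1, 0.08, length.out = 24),
                    sd = 0.01)
  rep <- structure(list(aggregate = agg), class = "ImportanceReport")
  sel <- selectTopFeatures(rep, k = 15)
  expect_length(sel$selected, 15L)
  expect_length(sel$removed, 9L)                       # 24 - 15
  expect_identical(sel$selected, agg$feature[order(-agg$score)][1:15])
  # identity when k equals the feature count
  expect_length(selectTopFeatures(rep, k = 24)$removed, 0L)
  expect_error(selectTopFeatures(rep, k = 25), "exceeds")
  # ties broken by token order when no attributions are given
  agg2 <- data.frame(feature = c("B", "A", "C"), score = c(1, 1, 0), sd = 0)
  rep2 <- structure(list(aggregate = agg2), class = "ImportanceReport")
  expect_identical(selectTopFeatures(rep2, k = 2)$selected, c("A", "B"))
})
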