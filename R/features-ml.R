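.ENERGY_COLS <- c("ligand_id", "trajectory_id", "frame_time", "residue_id",
                  "substituent", "energy", "frame_bias", "z")

#' Validate an interaction-energy table
#'
#' Long-format table with one row per (frame, residue, substituent):
#' ligand_id, trajectory_id, frame_time (ps), residue_id, substituent
#' (R1/R2/R4), energy (kcal/mol), frame_bias (kcal/mol), z (Angstrom).
#'
#' @param tab data.frame to validate.
#' @return The table, invisibly, or an error.
#' @export
validateEnergyTable <- function(tab) {
  miss <- setdiff(.ENERGY_COLS, names(tab))
  if (length(miss))
    .stopf("energy table is missing column(s): %s", paste(miss, collapse = ", "))
  bad <- setdiff(unique(tab$substituent), c("R1", "R2", "R4"))
  if (length(bad))
    .stopf("unknown substituent token(s): %s", paste(bad, collapse = ", "))
  if (!all(is.finite(tab$energy))) .stopf("energies must be finite")
  invisible(tab)
}

.pairId <- function(tab) paste(tab$residue_id, tab$substituent, sep = ".")
.frameKey <- function(tab) paste(tab$trajectory_id, tab$frame_time, sep = "@")

#' Randomly sample eligible frames per ligand
#'
#' Uniform sampling without replacement of pre-exit frames (z <= threshold,
#' the portion of the trajectories before the compound left the receptor);
#' all pair rows of a selected frame are retained together.
#'
#' @param tab Energy table (see \code{\link{validateEnergyTable}}).
#' @param nFrames Frames to draw per ligand.
#' @param seed Integer seed.
#' @param zThreshold Exit threshold in Angstrom (default 15).
#' @return The sampled energy table.
#' @export
sampleFrames <- function(tab, nFrames, seed = 1L, zThreshold = 15) {
  validateEnergyTable(tab)
  keys <- .frameKey(tab)
  keep <- .withSeed(seed, {
    unlist(lapply(split(seq_len(nrow(tab)), tab$ligand_id), function(rows) {
      elig <- unique(keys[rows][tab$z[rows] <= zThreshold])
      if (length(elig) < nFrames)
        .stopf("insufficient data for ligand '%s': %d eligible frame(s), need %d",
               tab$ligand_id[rows[1L]], length(elig), nFrames)
      chosen <- sample(elig, nFrames)
      rows[keys[rows] %in% chosen & tab$z[rows] <= zThreshold]
    }), use.names = FALSE)
  })
  out <- tab[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reweighted per-ligand mean energy for every residue-substituent pair
#'
#' Frame weights proportional to exp(+beta V) are computed per ligand from
#' the frame bias and applied to the frame-level energies.
#'
#' @param tab Energy table.
#' @param temperature Temperature in Kelvin.
#' @return Matrix (ligand x pair) of reweighted mean energies (kcal/mol).
#' @export
pairMeansReweighted <- function(tab, temperature = 300) {
  validateEnergyTable(tab)
  pairs <- sort(unique(.pairId(tab)))
  ligands <- sort(unique(tab$ligand_id))
  out <- matrix(NA_real_, length(ligands), length(pairs),
                dimnames = list(ligands, pairs))
  pid <- .pairId(tab)
  keys <- .frameKey(tab)
  for (lig in ligands) {
    rows <- which(tab$ligand_id == lig)
    uk <- !duplicated(keys[rows])
    wtab <- frameWeights(tab$frame_bias[rows][uk], temperature)
    names(wtab) <- keys[rows][uk]
    w <- wtab[keys[rows]]
    for (p in pairs) {
      sel <- rows[pid[rows] == p]
      ws <- w[pid[rows] == p]
      out[lig, p] <- sum(ws * tab$energy[sel]) / sum(ws)
    }
  }
  out
}

#' Filter residue-substituent pairs by magnitude and spread
#'
#' A pair survives iff the largest absolute reweighted per-ligand mean
#' energy reaches \code{magnitudeCutoff} AND the standard deviation of the
#' per-ligand means reaches \code{spreadCutoff} (a pair identical across
#' ligands carries no kinetic signal). Both statistics are reported.
#'
#' @param tab Energy table over all ligands.
#' @param magnitudeCutoff kcal/mol (default 1.0).
#' @param spreadCutoff kcal/mol (default 0.25).
#' @param temperature Temperature in Kelvin for the reweighting.
#' @return data.frame with pair, max_abs_mean, sd_mean, keep.
#' @export
filterPairs <- function(tab, magnitudeCutoff = 1, spreadCutoff = 0.25,
                        temperature = 300) {
  mu <- pairMeansReweighted(tab, temperature)
  maxAbs <- apply(abs(mu), 2L, max)
  sdMean <- apply(mu, 2L, stats::sd)
  if (nrow(mu) < 2L) sdMean[] <- 0
  keep <- maxAbs >= magnitudeCutoff & sdMean >= spreadCutoff
  if (!any(keep)) warning("no residue-substituent pair survived the filter")
  data.frame(pair = colnames(mu), max_abs_mean = unname(maxAbs),
             sd_mean = unname(sdMean), keep = unname(keep))
}

#' Block-mean augmentation of the feature dataset
#'
#' Each augmented row is the per-pair mean energy over a freshly drawn
#' (with replacement) block of frames of one ligand; the target is that
#' ligand's log10 residence time replicated across its rows. Block means
#' preserve the per-ligand location while creating within-ligand variance,
#' which is what makes row-level train/test splits meaningful. When
#' \code{blockSize} equals a ligand's full frame count the block is the
#' complete frame set, so a single augmented row reduces to the plain
#' per-ligand mean.
#'
#' @param tab (Sampled) energy table.
#' @param tauTable data.frame with ligand_id and either log10_tau or tau_s.
#' @param nAug Augmented rows per ligand (default 200).
#' @param blockSize Frames per block (default 100; must not exceed the
#'   frames available per ligand).
#' @param seed Integer seed.
#' @param pairs Optional character vector of surviving pair ids; default
#'   all pairs present.
#' @return Feature table: data.frame with ligand_id, one column per pair,
#'   and log10_tau.
#' @export
augmentDataset <- function(tab, tauTable, nAug = 200, blockSize = 100,
                           seed = 1L, pairs = NULL) {
  validateEnergyTable(tab)
  if (!"log10_tau" %in% names(tauTable)) {
    if (!"tau_s" %in% names(tauTable))
      .stopf("tauTable needs a log10_tau or tau_s column")
    tauTable$log10_tau <- log10(tauTable$tau_s)
  }
  pid <- .pairId(tab)
  if (is.null(pairs)) pairs <- sort(unique(pid))
  ligands <- sort(unique(tab$ligand_id))
  missing <- setdiff(ligands, tauTable$ligand_id)
  if (length(missing))
    .stopf("missing target: ligand(s) %s absent from the tau table",
           paste(missing, collapse = ", "))
  tau <- stats::setNames(tauTable$log10_tau, tauTable$ligand_id)
  keys <- .frameKey(tab)
  .withSeed(seed, {
    rows <- lapply(ligands, function(lig) {
      sel <- which(tab$ligand_id == lig & pid %in% pairs)
      E <- tapply(tab$energy[sel], list(keys[sel], pid[sel]), mean)
      E <- E[, pairs, drop = FALSE]
      nf <- nrow(E)
      if (blockSize > nf)
        .stopf("blockSize (%d) exceeds the %d frames of ligand '%s'",
               blockSize, nf, lig)
      feats <- t(vapply(seq_len(nAug), function(a) {
        idx <- if (blockSize == nf) seq_len(nf)
               else sample.int(nf, blockSize, replace = TRUE)
        colMeans(E[idx, , drop = FALSE])
      }, numeric(length(pairs))))
      df <- data.frame(ligand_id = lig, feats, check.names = FALSE)
      df$log10_tau <- tau[[lig]]
      df
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

.featureCols <- function(features)
  setdiff(names(features), c("ligand_id", "log10_tau"))

# ---- model backends ---------------------------------------------------

.fitOne <- function(kind, X, y, pars, seed) {
  fit <- switch(kind,
    rf = .withSeed(seed,   # all features per split, as in sklearn-style RF
      randomForest::randomForest(x = X, y = y, ntree = pars$ntree,
                                 mtry = ncol(X))),
    et = ranger::ranger(x = X, y = y, num.trees = pars$ntree,
                        mtry = ncol(X), splitrule = "extratrees",
                        num.random.splits = 1L, replace = FALSE,
                        sample.fraction = 1, num.threads = 1L,
                        seed = seed),
    gb = xgboost::xgb.train(
      params = list(max_depth = 3L, eta = pars$eta, subsample = 1,
                    colsample_bytree = 1, lambda = 0,
                    colsample_bynode = if (is.null(pars$colsample)) 1
                                       else pars$colsample,
                    objective = "reg:squarederror", nthread = 1L,
                    seed = seed),
      data = xgboost::xgb.DMatrix(X, label = y), nrounds = pars$nrounds,
      verbose = 0),
    xgb = xgboost::xgb.train(
      params = list(max_depth = 6L, eta = pars$eta,
                    colsample_bytree = if (is.null(pars$colsample)) 1
                                       else pars$colsample,
                    objective = "reg:squarederror", nthread = 1L,
                    seed = seed),
      data = xgboost::xgb.DMatrix(X, label = y), nrounds = pars$nrounds,
      verbose = 0),
    .stopf("unknown model kind '%s'", kind))
  structure(list(kind = kind, model = fit, featureNames = colnames(X),
                 pars = pars, trainX = X, trainY = y),
            class = "mkModelFit")
}

#' Predict from a fitted tree-ensemble wrapper
#'
#' @param object An object of class \code{mkModelFit} from
#'   \code{\link{trainModels}}.
#' @param newdata Numeric matrix with the model's feature columns.
#' @param ... Ignored.
#' @return Numeric prediction vector.
#' @export
predict.mkModelFit <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$featureNames, drop = FALSE])
  switch(object$kind,
    rf  = unname(stats::predict(object$model, X)),
    et  = stats::predict(object$model, data.frame(X, check.names = FALSE),
                         num.threads = 1L)$predictions,
    gb  = ,
    xgb = stats::predict(object$model, X))
}

.modelGrid <- function(kind) {
  switch(kind,
    rf  = list(list(ntree = 100L), list(ntree = 300L)),
    et  = list(list(ntree = 100L), list(ntree = 300L)),
    gb  = list(list(eta = 0.05, nrounds = 300L, colsample = 1),
               list(eta = 0.1, nrounds = 300L, colsample = 1),
               list(eta = 0.05, nrounds = 300L, colsample = 0.5),
               list(eta = 0.1, nrounds = 300L, colsample = 0.5)),
    xgb = list(list(eta = 0.05, nrounds = 300L, colsample = 1),
               list(eta = 0.1, nrounds = 300L, colsample = 1),
               list(eta = 0.05, nrounds = 300L, colsample = 0.5),
               list(eta = 0.1, nrounds = 300L, colsample = 0.5)))
}

.rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))

#' Train the four tree-ensemble regressors
#'
#' Random forest, extremely randomized trees, gradient boosting and
#' extreme gradient boosting are trained to predict log10 residence time
#' from the interaction-energy features. Rows are split 80:20 into
#' training and held-out test portions (row-level by default; set
#' \code{splitBy = "ligand"} for the stricter leave-ligands-out variant),
#' hyperparameters are tuned by k-fold cross-validation on the training
#' portion only, and metrics (squared Pearson r and RMSE) are reported on
#' the held-out rows.
#'
#' @param features Feature table from \code{\link{augmentDataset}}.
#' @param models Subset of c("rf", "et", "gb", "xgb").
#' @param split Training fraction (default 0.8).
#' @param cvFolds Cross-validation folds for tuning (default 10).
#' @param seed Integer seed controlling the split, tuning and fits.
#' @param tune Tune over the small per-model grid (default TRUE); when
#'   FALSE the first grid entry is used.
#' @param splitBy "row" (default) or "ligand".
#' @return list with \code{fits} (named list of mkModelFit),
#'   \code{metrics} (data.frame model, r2, rmse), \code{testIdx},
#'   \code{features}.
#' @export
trainModels <- function(features, models = c("rf", "et", "gb", "xgb"),
                        split = 0.8, cvFolds = 10L, seed = 1L, tune = TRUE,
                        splitBy = c("row", "ligand")) {
  splitBy <- match.arg(splitBy)
  models <- match.arg(models, c("rf", "et", "gb", "xgb"), several.ok = TRUE)
  fc <- .featureCols(features)
  if (length(unique(features$ligand_id)) < 2L)
    .stopf("degenerate target: a single ligand cannot support regression")
  if (nrow(features) < 10L) .stopf("need at least 10 rows")
  X <- as.matrix(features[, fc, drop = FALSE])
  y <- features$log10_tau
  seeds <- .deriveSeeds(seed, 3L + length(models))

  testIdx <- .withSeed(seeds[1L], {
    if (splitBy == "row") sort(sample.int(nrow(X), round((1 - split) * nrow(X))))
    else {
      ligs <- unique(features$ligand_id)
      hold <- sample(ligs, max(1L, round((1 - split) * length(ligs))))
      which(features$ligand_id %in% hold)
    }
  })
  trainIdx <- setdiff(seq_len(nrow(X)), testIdx)
  Xtr <- X[trainIdx, , drop = FALSE]; ytr <- y[trainIdx]
  Xte <- X[testIdx, , drop = FALSE];  yte <- y[testIdx]

  folds <- .withSeed(seeds[2L],
    sample(rep_len(seq_len(cvFolds), length(trainIdx))))

  fits <- list()
  metrics <- NULL
  for (mi in seq_along(models)) {
    kind <- models[mi]
    grid <- .modelGrid(kind)
    best <- grid[[1L]]
    if (tune && length(grid) > 1L) {
      cvErr <- vapply(grid, function(pars) {
        errs <- vapply(seq_len(cvFolds), function(f) {
          tr <- folds != f
          fit <- .fitOne(kind, Xtr[tr, , drop = FALSE], ytr[tr], pars,
                         seeds[3L] + f)
          .rmse(ytr[!tr], predict(fit, Xtr[!tr, , drop = FALSE]))
        }, numeric(1))
        mean(errs)
      }, numeric(1))
      best <- grid[[which.min(cvErr)]]
    }
    fit <- .fitOne(kind, Xtr, ytr, best, seeds[3L + mi])
    pred <- predict(fit, Xte)
    r2 <- if (stats::sd(yte) == 0 || stats::sd(pred) == 0) NA_real_
          else stats::cor(yte, pred)^2
    metrics <- rbind(metrics, data.frame(model = kind, r2 = r2,
                                         rmse = .rmse(yte, pred)))
    fits[[kind]] <- fit
  }
  list(fits = fits, metrics = metrics, testIdx = testIdx, features = features)
}

#' Permutation feature importance
#'
#' The importance of a feature is the mean decrease in the model's test
#' score (coefficient of determination R^2) when that feature's column is
#' randomly shuffled. A feature the model never uses scores exactly zero.
#'
#' @param fit An \code{mkModelFit}.
#' @param X Test feature matrix (>= 2 rows).
#' @param y Test targets.
#' @param nRepeats Shuffles per feature (default 5).
#' @param seed Integer seed.
#' @param permuteFun Permutation generator, by default
#'   \code{sample.int}; injectable for degenerate checks.
#' @return Named numeric vector of importance scores.
#' @export
permutationImportance <- function(fit, X, y, nRepeats = 5L, seed = 1L,
                                  permuteFun = sample.int) {
  stopifnot(inherits(fit, "mkModelFit"), nrow(X) >= 2L)
  X <- as.matrix(X[, fit$featureNames, drop = FALSE])
  ssTot <- sum((y - mean(y))^2)
  score <- function(pred) 1 - sum((y - pred)^2) / ssTot
  base <- score(predict(fit, X))
  .withSeed(seed, {
    vapply(fit$featureNames, function(f) {
      mean(vapply(seq_len(nRepeats), function(r) {
        Xp <- X
        Xp[, f] <- Xp[permuteFun(nrow(X)), f]
        base - score(predict(fit, Xp))
      }, numeric(1)))
    }, numeric(1))
  })
}

# ---- additive per-sample attributions ---------------------------------

# Normalised tree-table: data.frame(left, right, var, splitval, terminal,
# pred) with 1-based child indices, children after parents; x <= splitval
# descends left for both randomForest and ranger trees.
.rfTreeTable <- function(model, k) {
  tr <- randomForest::getTree(model, k, labelVar = FALSE)
  data.frame(left = tr[, 1L], right = tr[, 2L], var = tr[, 3L],
             splitval = tr[, 4L], terminal = tr[, 5L] == -1,
             pred = tr[, 6L])
}

.rangerTreeTable <- function(model, k) {
  ti <- ranger::treeInfo(model, k)
  data.frame(left = ti$leftChild + 1L, right = ti$rightChild + 1L,
             var = ti$splitvarID + 1L, splitval = ti$splitval,
             terminal = ti$terminal, pred = ti$prediction)
}

# Descend rows of X through a tree-table; returns the list of node indices
# visited per descent step (level-wise, vectorised over rows).
.descend <- function(tt, X, record = FALSE) {
  node <- rep(1L, nrow(X))
  path <- if (record) list(node)
  repeat {
    act <- which(!tt$terminal[node])
    if (!length(act)) break
    v <- tt$var[node[act]]
    left <- X[cbind(act, v)] <= tt$splitval[node[act]]
    node[act] <- ifelse(left, tt$left[node[act]], tt$right[node[act]])
    if (record) path[[length(path) + 1L]] <- node
  }
  if (record) path else node
}

# Saabas path attribution for one tree: contributions of each feature are
# the changes in node value along each row's root-to-leaf path. Internal
# node values are count-weighted means of descendant leaf predictions
# (counts from the training rows), so base + sum(contrib) telescopes
# exactly to the leaf prediction.
.saabasTree <- function(tt, X, Xtrain) {
  n <- nrow(tt)
  leaf <- .descend(tt, Xtrain)
  cnt <- tabulate(leaf, n)
  val <- tt$pred
  for (i in rev(seq_len(n))) {
    if (!tt$terminal[i]) {
      l <- tt$left[i]; r <- tt$right[i]
      cl <- cnt[l]; cr <- cnt[r]
      cnt[i] <- cl + cr
      val[i] <- if (cl + cr > 0) (cl * val[l] + cr * val[r]) / (cl + cr)
                else (val[l] + val[r]) / 2
    }
  }
  contrib <- matrix(0, nrow(X), ncol(X))
  node <- rep(1L, nrow(X))
  repeat {
    act <- which(!tt$terminal[node])
    if (!length(act)) break
    cur <- node[act]
    v <- tt$var[cur]
    left <- X[cbind(act, v)] <= tt$splitval[cur]
    nxt <- ifelse(left, tt$left[cur], tt$right[cur])
    contrib[cbind(act, v)] <- contrib[cbind(act, v)] + val[nxt] - val[cur]
    node[act] <- nxt
  }
  list(contrib = contrib, base = val[1L])
}

#' Additive per-sample feature attributions
#'
#' Decomposes each prediction into a base value plus one additive
#' contribution per feature. For the xgboost-backed models this is exact
#' TreeSHAP (\code{predcontrib}); for random forest and extremely
#' randomized trees it is the exact tree-path (Saabas) attribution
#' computed from the stored tree structures. In both cases local accuracy
#' holds: base + sum of contributions equals the model prediction.
#'
#' @param fit An \code{mkModelFit} (tree ensembles only).
#' @param X Feature matrix to attribute.
#' @return list with \code{contributions} (matrix, one column per
#'   feature), \code{base} (scalar) and \code{prediction}
#'   (= base + rowSums(contributions)).
#' @export
additiveAttributions <- function(fit, X) {
  if (!inherits(fit, "mkModelFit"))
    .stopf("unsupported model: additive attributions need a tree ensemble")
  X <- as.matrix(X[, fit$featureNames, drop = FALSE])
  if (fit$kind %in% c("gb", "xgb")) {
    pc <- stats::predict(fit$model, X, predcontrib = TRUE)
    p <- ncol(pc) - 1L
    contrib <- pc[, seq_len(p), drop = FALSE]
    base <- pc[1L, p + 1L]
  } else {
    ntree <- if (fit$kind == "rf") fit$model$ntree else fit$model$num.trees
    getTT <- if (fit$kind == "rf") .rfTreeTable else .rangerTreeTable
    contrib <- matrix(0, nrow(X), ncol(X))
    base <- 0
    for (k in seq_len(ntree)) {
      s <- .saabasTree(getTT(fit$model, k), X, fit$trainX)
      contrib <- contrib + s$contrib
      base <- base + s$base
    }
    contrib <- contrib / ntree
    base <- base / ntree
  }
  colnames(contrib) <- fit$featureNames
  list(contributions = contrib, base = unname(base),
       prediction = unname(base + rowSums(contrib)))
}

#' Repeat the ML protocol over many trials
#'
#' Re-runs augmentation (optional), the 80:20 split, training and
#' permutation importance with trial-specific seeds derived from the
#' master seed, to remove dataset bias. Importance scores are aggregated
#' across trials per model, and across models via min-max-normalised
#' means.
#'
#' @param features Feature table (used directly when \code{sampledTable}
#'   is NULL; each trial then only re-splits).
#' @param nTrials Number of trials (default 100).
#' @param seed Master seed.
#' @param models Model kinds to train.
#' @param sampledTable Optional sampled energy table; when given, each
#'   trial re-augments from it.
#' @param tauTable Required with \code{sampledTable}.
#' @param nAug,blockSize,pairs Augmentation parameters per trial.
#' @param split,cvFolds,tune Passed to \code{\link{trainModels}}.
#' @param nRepeats Permutation repeats per feature.
#' @return An object of class \code{ImportanceReport}: list with
#'   \code{scores} (model, trial, feature, score), \code{perModel}
#'   (mean/sd over trials), \code{aggregate} (feature, score, sd; min-max
#'   normalised means across models) and \code{metrics} per trial.
#' @export
runTrials <- function(features = NULL, nTrials = 100L, seed = 1L,
                      models = c("rf", "et", "gb", "xgb"),
                      sampledTable = NULL, tauTable = NULL,
                      nAug = 200L, blockSize = 100L, pairs = NULL,
                      split = 0.8, cvFolds = 10L, tune = FALSE,
                      nRepeats = 5L) {
  if (is.null(features) && is.null(sampledTable))
    .stopf("provide a feature table or a sampled energy table")
  seeds <- .deriveSeeds(seed, 3L * nTrials)
  scores <- list(); metrics <- list()
  for (t in seq_len(nTrials)) {
    ft <- if (!is.null(sampledTable))
      augmentDataset(sampledTable, tauTable, nAug = nAug,
                     blockSize = blockSize, seed = seeds[3 * t - 2],
                     pairs = pairs)
    else features
    tm <- trainModels(ft, models = models, split = split, cvFolds = cvFolds,
                      seed = seeds[3 * t - 1], tune = tune)
    fc <- .featureCols(ft)
    Xte <- as.matrix(ft[tm$testIdx, fc, drop = FALSE])
    yte <- ft$log10_tau[tm$testIdx]
    for (kind in names(tm$fits)) {
      sc <- permutationImportance(tm$fits[[kind]], Xte, yte,
                                  nRepeats = nRepeats, seed = seeds[3 * t])
      scores[[length(scores) + 1L]] <-
        data.frame(model = kind, trial = t, feature = names(sc),
                   score = unname(sc))
    }
    metrics[[t]] <- cbind(trial = t, tm$metrics)
  }
  scores <- do.call(rbind, scores)
  perModel <- do.call(rbind, lapply(split(scores, scores$model), function(d) {
    agg <- tapply(d$score, d$feature, mean)
    sds <- tapply(d$score, d$feature, stats::sd)
    data.frame(model = d$model[1L], feature = names(agg),
               mean_score = unname(agg),
               sd_score = unname(if (nTrials > 1L) sds else 0 * agg))
  }))
  rownames(perModel) <- NULL
  norm <- do.call(rbind, lapply(split(perModel, perModel$model), function(d) {
    rng <- range(d$mean_score)
    d$norm <- if (diff(rng) > 0) (d$mean_score - rng[1L]) / diff(rng) else 0
    d
  }))
  aggregate <- do.call(rbind, lapply(split(norm, norm$feature), function(d)
    data.frame(feature = d$feature[1L], score = mean(d$norm),
               sd = stats::sd(d$norm))))
  aggregate <- aggregate[order(-aggregate$score), ]
  rownames(aggregate) <- NULL
  structure(list(scores = scores, perModel = perModel,
                 aggregate = aggregate,
                 metrics = do.call(rbind, metrics)),
            class = "ImportanceReport")
}

#' @export
print.ImportanceReport <- function(x, ...) {
  cat(sprintf("ImportanceReport: %d model(s) x %d trial(s) x %d feature(s)\n",
              length(unique(x$scores$model)), max(x$scores$trial),
              length(unique(x$scores$feature))))
  cat("Top features by aggregate score:\n")
  print(utils::head(x$aggregate, 5), row.names = FALSE)
  invisible(x)
}

#' Tree-ensemble benchmark on the canonical synthetic feature dataset
#'
#' Runs the full structure-kinetics ML protocol on the synthetic dataset
#' emulating the study's feature structure: 19 ligands x 24
#' residue-substituent pairs with 3 planted kinetic modulators and 0.05
#' log10-unit target noise; 400 pre-exit frames sampled per ligand; 200
#' block-mean augmented rows per ligand (blocks of 100 frames); row-level
#' 80:20 split; 10-fold CV tuning; all four tree ensembles. Reports the
#' held-out squared Pearson correlation and RMSE per model.
#'
#' @param seed Master seed; generator, sampling, augmentation and
#'   training seeds are derived from it.
#' @param cvFolds Cross-validation folds (default 10).
#' @return list with \code{metrics} (per-model r2 and rmse),
#'   \code{minR2}, \code{maxRMSE}, \code{nRows}, and the fitted
#'   \code{models}.
#' @export
syntheticBenchmark <- function(seed = 1L, cvFolds = 10L) {
  seeds <- .deriveSeeds(seed, 4L)
  gen <- genFeatureDataset(seed = seeds[1L])
  samp <- sampleFrames(gen$energyTable, 400, seed = seeds[2L])
  ft <- augmentDataset(samp, gen$tauTable, nAug = 200, blockSize = 100,
                       seed = seeds[3L])
  tm <- trainModels(ft, seed = seeds[4L], tune = TRUE, cvFolds = cvFolds)
  list(metrics = tm$metrics, minR2 = min(tm$metrics$r2),
       maxRMSE = max(tm$metrics$rmse), nRows = nrow(ft), models = tm)
}

#' Keep the top-k features by aggregate importance
#'
#' Features are ordered by aggregate mean permutation score; ties are
#' broken by mean absolute attribution (when supplied) and then by token
#' order. With 24 features and the default k = 15, exactly 9 are removed.
#'
#' @param report An \code{ImportanceReport}.
#' @param k Features to keep (default 15).
#' @param attributions Optional attribution matrix (columns = features)
#'   used for tie-breaking.
#' @return list with \code{selected} and \code{removed} feature ids.
#' @export
selectTopFeatures <- function(report, k = 15L, attributions = NULL) {
  agg <- report$aggregate
  if (k > nrow(agg))
    .stopf("k (%d) exceeds the number of features (%d)", k, nrow(agg))
  tie1 <- rep(0, nrow(agg))
  if (!is.null(attributions)) {
    m <- colMeans(abs(attributions))
    tie1 <- unname(m[agg$feature])
    tie1[is.na(tie1)] <- 0
  }
  ord <- order(-agg$score, -tie1, agg$feature)
  sel <- agg$feature[ord[seq_len(k)]]
  list(selected = sel, removed = setdiff(agg$feature, sel))
}
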