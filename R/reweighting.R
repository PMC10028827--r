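#' Unbiasing weights from an instantaneous bias series
#'
#' Post-hoc reweighting of biased frames: each frame receives weight
#' proportional to exp(+beta V), computed stably by shifting by the
#' maximum before exponentiation, and normalised to sum to one.
#'
#' @param bias Bias per frame in kcal/mol (finite).
#' @param temperature Temperature in Kelvin.
#' @return Normalised weight vector.
#' @examples
#' frameWeights(c(0, kT(300) * log(3)), 300)  # 0.25, 0.75
#' @export
frameWeights <- function(bias, temperature = 300) {
  if (!length(bias)) .stopf("empty bias series")
  if (!all(is.finite(bias))) .stopf("bias values must be finite")
  bv <- bias / kT(temperature)
  w <- exp(bv - max(bv))
  w / sum(w)
}

# Bin index per dimension with range check; breaks must cover the data.
.binIndex <- function(x, breaks) {
  if (any(x < breaks[1L] | x > breaks[length(breaks)]))
    .stopf("bins do not cover the data range [%g, %g]", min(x), max(x))
  findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
}

.resolveBreaks <- function(x, bins) {
  if (length(bins) > 1L) return(bins)                 # explicit edges
  r <- range(x)
  if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
  seq(r[1], r[2], length.out = bins + 1L)
}

#' Reweighted histogram density
#'
#' Accumulates the normalised frame weights on a regular grid and divides
#' by the bin measure, so the density integrates to one over occupied
#' bins. Works in one or two dimensions.
#'
#' @param ensemble A \linkS4class{WeightedEnsemble}.
#' @param bins Either a bin count or an explicit vector of bin edges; for
#'   2D data, a list with one entry per dimension.
#' @return list with \code{edges}, \code{density} (array), and
#'   \code{occupied} (logical array).
#' @export
reweightedHistogram <- function(ensemble, bins = 50) {
  stopifnot(is(ensemble, "WeightedEnsemble"))
  vals <- ensemble@values
  w <- ensemble@weights
  d <- ncol(vals)
  if (!is.list(bins)) bins <- rep(list(bins), d)
  edges <- lapply(seq_len(d), function(k) .resolveBreaks(vals[, k], bins[[k]]))
  idx <- lapply(seq_len(d), function(k) .binIndex(vals[, k], edges[[k]]))
  nb <- vapply(edges, function(e) length(e) - 1L, integer(1))
  dens <- array(0, dim = nb)
  flat <- idx[[1L]]
  if (d == 2L) flat <- flat + nb[1L] * (idx[[2L]] - 1L)
  acc <- rowsum(w, flat)
  dens[as.integer(rownames(acc))] <- acc[, 1L]
  if (sum(dens) <= 0) .stopf("empty density: zero total weight in range")
  widths <- lapply(edges, diff)
  measure <- widths[[1L]]
  if (d == 2L) measure <- outer(widths[[1L]], widths[[2L]])
  dens <- dens / sum(dens) / array(measure, dim = nb)
  list(edges = edges, density = dens, occupied = dens > 0)
}

#' Free-energy surface from a weighted ensemble
#'
#' F = -kT log(density) per bin, shifted so the minimum over occupied
#' bins is zero; unoccupied bins are NA.
#'
#' @param ensemble A \linkS4class{WeightedEnsemble}.
#' @param bins As in \code{\link{reweightedHistogram}}.
#' @return A \linkS4class{FreeEnergySurface}.
#' @export
fes <- function(ensemble, bins = 50) {
  h <- reweightedHistogram(ensemble, bins)
  fe <- -kT(temperature(ensemble)) * log(h$density)
  fe[!h$occupied] <- NA_real_
  fe <- fe - min(fe, na.rm = TRUE)
  new("FreeEnergySurface", edges = h$edges,
      freeEnergy = array(fe, dim = dim(h$density)),
      occupied = array(h$occupied, dim = dim(h$density)),
      temperature = temperature(ensemble))
}

# Neighbour offsets: 2 for 1D, 4-connectivity for 2D.
.neighbours <- function(dims) {
  if (length(dims) == 1L) list(c(-1L), c(1L))
  else list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
}

#' Locate free-energy basins
#'
#' Identifies basins by a persistence-style sweep: occupied bins are
#' visited in order of increasing free energy; a bin with no lower
#' labelled neighbour seeds a new basin (a local minimum), and where two
#' basins meet, the shallower one is merged into the deeper whenever the
#' saddle lies less than \code{depthCutoff} above its minimum. The result
#' is one basin per local minimum that is separated from deeper minima by
#' a barrier of at least \code{depthCutoff}.
#'
#' @param surface A \linkS4class{FreeEnergySurface} (1D or 2D).
#' @param depthCutoff Saddle-merging depth in kcal/mol.
#' @return list of basins, each a list with \code{bins} (matrix of bin
#'   indices), \code{minValue} (kcal/mol) and \code{minLocation} (bin
#'   centres of the minimum).
#' @export
locateBasins <- function(surface, depthCutoff = 1) {
  stopifnot(is(surface, "FreeEnergySurface"))
  fe <- surface@freeEnergy
  occ <- surface@occupied
  if (!any(occ)) .stopf("empty FES: all bins unoccupied")
  dims <- dim(fe)
  if (is.null(dims)) dims <- length(fe)
  nd <- length(dims)
  cells <- which(occ)
  ord <- cells[order(fe[cells])]
  coord <- arrayInd(ord, .dim = dims)

  label <- rep(NA_integer_, prod(dims))
  parent <- integer(0)                 # union-find over basin labels
  minVal <- numeric(0)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }

  offs <- .neighbours(dims)
  for (i in seq_along(ord)) {
    cc <- coord[i, , drop = TRUE]
    labs <- integer(0)
    for (off in offs) {
      nb <- cc + off
      if (any(nb < 1L) || any(nb > dims)) next
      flat <- if (nd == 1L) nb else nb[1L] + dims[1L] * (nb[2L] - 1L)
      if (!is.na(label[flat])) labs <- c(labs, find(label[flat]))
    }
    labs <- unique(labs)
    if (!length(labs)) {               # new local minimum
      parent <- c(parent, length(parent) + 1L)
      minVal <- c(minVal, fe[ord[i]])
      label[ord[i]] <- length(parent)
    } else if (length(labs) == 1L) {
      label[ord[i]] <- labs
    } else {                           # saddle between basins
      deepest <- labs[which.min(minVal[labs])]
      for (b in setdiff(labs, deepest)) {
        if (fe[ord[i]] - minVal[b] < depthCutoff) parent[b] <- deepest
      }
      label[ord[i]] <- find(deepest)
    }
  }
  resolved <- vapply(label[cells], find, integer(1))
  centres <- lapply(surface@edges, function(e) (e[-1L] + e[-length(e)]) / 2)
  lapply(split(cells, resolved), function(cs) {
    binIdx <- arrayInd(cs, .dim = dims)
    mn <- which.min(fe[cs])
    list(bins = binIdx, minValue = fe[cs][mn],
         minLocation = vapply(seq_len(nd), function(k)
           centres[[k]][binIdx[mn, k]], numeric(1)))
  })
}

#' Default binding-mode distance windows
#'
#' Salt-bridge and hydrogen-bond contacts are read off the FES axes as
#' minimum-distance windows (<= 4 Angstrom by default); the loosely bound
#' window follows the 7-9 / 13-15 Angstrom box reported for buprenorphine.
#'
#' @param contactMax Upper contact distance bound in Angstrom.
#' @return Named list of boxes; each box is a list with \code{x} and
#'   \code{y} ranges (NULL = unbounded).
#' @export
bindingModeBoxes <- function(contactMax = 4) {
  list(
    "D147 salt bridge" = list(x = c(0, contactMax), y = NULL),
    "H297 h-bond"      = list(x = NULL, y = c(0, contactMax)),
    "loosely bound"    = list(x = c(7, 9), y = c(13, 15))
  )
}

#' Classify binding modes from FES basin minima
#'
#' A mode is reported when any basin minimum falls inside its named
#' distance window on the (ligand-D147 distance, ligand-H297 distance)
#' surface. The empty set is allowed.
#'
#' @param surface A 2D \linkS4class{FreeEnergySurface} over the two
#'   contact distances.
#' @param boxes Named list of windows as from
#'   \code{\link{bindingModeBoxes}}.
#' @param depthCutoff Basin depth cutoff passed to
#'   \code{\link{locateBasins}}.
#' @param basins Optional pre-computed basin list.
#' @return Character vector of mode names (possibly empty).
#' @export
classifyBindingMode <- function(surface, boxes = bindingModeBoxes(),
                                depthCutoff = 1, basins = NULL) {
  if (is.null(basins)) basins <- locateBasins(surface, depthCutoff)
  inBox <- function(loc, box) {
    okx <- is.null(box$x) || (loc[1L] >= box$x[1L] && loc[1L] <= box$x[2L])
    oky <- is.null(box$y) || (length(loc) < 2L) ||
      (loc[2L] >= box$y[1L] && loc[2L] <= box$y[2L])
    okx && oky
  }
  hit <- vapply(names(boxes), function(nm)
    any(vapply(basins, function(b) inBox(b$minLocation, boxes[[nm]]), logical(1))),
    logical(1))
  names(hit)[hit]
}

#' Dense-grid export of a free-energy surface
#'
#' @param surface A \linkS4class{FreeEnergySurface}.
#' @return data.frame with bin-centre coordinates and free energy
#'   (NA for unoccupied bins), suitable for CSV export.
#' @export
fesTable <- function(surface) {
  stopifnot(is(surface, "FreeEnergySurface"))
  centres <- lapply(surface@edges, function(e) (e[-1L] + e[-length(e)]) / 2)
  grid <- do.call(expand.grid, centres)
  names(grid) <- paste0("x", seq_along(centres))
  grid$free_energy <- as.vector(surface@freeEnergy)
  grid
}
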