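.LIGAND_CLASSES <- c("parent", "R2_modified", "R1_R4_modified", "morphinan")

#' Log-scale Pearson correlation between two ligand quantities
#'
#' Computes the Pearson correlation between log10(x) and log10(y) over the
#' records where both fields are present (missing values are excluded
#' pairwise and logged in the result), together with the log10-scale
#' regression line. Residence times correlate with dissociation constants
#' with a negative sign: longer residence means tighter binding.
#'
#' @param records Ligand record data.frame (see
#'   \code{\link{readLigandTable}}).
#' @param xField,yField Column names of positive-valued quantities.
#' @param subset Optional filter function applied to the records first
#'   (e.g. \code{\link{subsetExcludeR2}}).
#' @param subsetRule Label describing the subset.
#' @return A \linkS4class{CorrelationResult}.
#' @examples
#' rec <- data.frame(ligand_id = letters[1:4], a = c(1, 10, 100, 1000))
#' rec$b <- 5 / rec$a
#' pearsonLog(rec, "a", "b")  # r = -1 on the log scale
#' @export
pearsonLog <- function(records, xField, yField, subset = NULL,
                       subsetRule = if (is.null(subset)) "all records"
                                    else "custom subset") {
  if (!is.null(subset)) records <- subset(records)
  for (f in c(xField, yField))
    if (!f %in% names(records)) .stopf("no column '%s' in the records", f)
  x <- records[[xField]]
  y <- records[[yField]]
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  excluded <- as.character(records$ligand_id[!ok])
  if (sum(ok) < 3L)
    .stopf("insufficient data: %d record(s) with both '%s' and '%s' (need >= 3)",
           sum(ok), xField, yField)
  lx <- log10(x[ok]); ly <- log10(y[ok])
  fit <- stats::lm(ly ~ lx)
  new("CorrelationResult", xField = xField, yField = yField,
      subsetRule = subsetRule, n = sum(ok), r = stats::cor(lx, ly),
      slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]), excluded = excluded)
}

#' Drop the R2-modified compounds
#'
#' Removes records whose substituent class is \code{R2_modified} (the
#' butyrfentanyl-like analogs that differ from the parent only at R2),
#' retaining the parent, the R1/R4-modified derivatives and any
#' morphinans present.
#'
#' @param records Ligand record data.frame.
#' @return The filtered records.
#' @export
subsetExcludeR2 <- function(records) {
  if (!"substituent_class" %in% names(records))
    .stopf("records lack a substituent_class column")
  records[records$substituent_class != "R2_modified", , drop = FALSE]
}

# Parse SMILES into an SDFset, erroring with the ligand name on failure.
# smiles2sdf silently drops molecules it cannot convert, so missing cids
# are treated as parse failures too.
.parseSmiles <- function(records) {
  sm <- stats::setNames(records$smiles, records$ligand_id)
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(sm)),
                  error = function(e)
    .stopf("SMILES parse failure: %s", conditionMessage(e)))
  missing <- setdiff(records$ligand_id, ChemmineR::cid(sdf))
  bad <- ChemmineR::cid(sdf)[!ChemmineR::validSDF(sdf)]
  if (length(c(missing, bad)))
    .stopf("unparsable SMILES for ligand(s): %s",
           paste(unique(c(missing, bad)), collapse = ", "))
  sdf
}

#' Tanimoto similarity matrix of the ligand set
#'
#' T(a, b) = |FP_a & FP_b| / |FP_a | FP_b| on binary molecular
#' fingerprints. The default is a circular (Morgan-style, radius 2)
#' fingerprint (ECFP4); MACCS-style keys and a 1024-bit atom-pair
#' fingerprint are offered as alternatives. Circular fingerprints resolve
#' local-environment changes such as a quaternary substitution at the
#' piperidine 4-position, which pair-based fingerprints largely miss.
#' The matrix is symmetric with a unit diagonal.
#'
#' @param records Ligand record data.frame with smiles.
#' @param fingerprint \code{"circular"} (default), \code{"maccs"} or
#'   \code{"atompair"}.
#' @return Symmetric numeric matrix in [0, 1] with ligand ids as
#'   dimnames.
#' @export
tanimotoMatrix <- function(records,
                           fingerprint = c("circular", "maccs", "atompair")) {
  fingerprint <- match.arg(fingerprint)
  sdf <- .parseSmiles(records)
  n <- length(records$ligand_id)
  out <- matrix(1, n, n, dimnames = list(records$ligand_id,
                                         records$ligand_id))
  fp <- if (fingerprint == "atompair") {
    # binary fingerprint over the most common atom pairs; the descriptor
    # list is loaded explicitly (desc2fp's own data() lookup needs
    # ChemmineR on the search path)
    e <- new.env()
    utils::data("apfp", package = "ChemmineR", envir = e)
    ChemmineR::desc2fp(ChemmineR::sdf2ap(sdf),
                       descnames = as.character(e$apfp$AP)[1:1024],
                       type = "FPset")
  } else {
    ChemmineR::fingerprintOB(sdf, if (fingerprint == "maccs") "MACCS"
                                  else "ECFP4")
  }
  for (i in seq_len(n)) {
    s <- ChemmineR::fpSim(fp[i], fp, method = "Tanimoto", sorted = FALSE)
    out[i, ] <- as.numeric(s)
  }
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  out
}

#' Basic structural validity of a ligand record set
#'
#' Checks that every SMILES parses and that each molecule carries at least
#' one basic (sp3, non-amide) nitrogen, as expected for the protonatable
#' piperidine or morphinan amine that anchors the D147 salt bridge.
#'
#' @param records Ligand record data.frame.
#' @return data.frame with ligand_id, parses, n_basic_amine.
#' @export
ligandValidity <- function(records) {
  sdf <- .parseSmiles(records)
  nBasic <- vapply(seq_along(records$ligand_id), function(i) {
    mol <- sdf[[i]]
    ab <- ChemmineR::atomblock(mol)
    bb <- ChemmineR::bondblock(mol)
    elems <- gsub("_.*$", "", rownames(ab))
    nIdx <- which(elems == "N")
    neighboursOf <- function(a) {
      rows <- which(bb[, 1L] == a | bb[, 2L] == a)
      data.frame(atom = ifelse(bb[rows, 1L] == a, bb[rows, 2L], bb[rows, 1L]),
                 order = bb[rows, 3L])
    }
    isBasic <- vapply(nIdx, function(a) {
      nb <- neighboursOf(a)
      if (any(nb$order > 1)) return(FALSE)         # sp2 / aromatic N
      # amide nitrogen: a carbon neighbour carries a double bond to oxygen
      !any(vapply(nb$atom, function(p) {
        if (elems[p] != "C") return(FALSE)
        pnb <- neighboursOf(p)
        any(elems[pnb$atom] == "O" & pnb$order == 2)
      }, logical(1)))
    }, logical(1))
    sum(isBasic)
  }, numeric(1))
  data.frame(ligand_id = records$ligand_id, parses = TRUE,
             n_basic_amine = nBasic)
}
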