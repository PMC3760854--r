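#' @import methods
NULL

#' StructureModel: an atom table with a chain index
#'
#' Lightweight container for a parsed macromolecular structure: one row per
#' atom with chain id, residue number/name, atom name, record type
#' (`ATOM`/`HETATM`) and Cartesian coordinates in Angstrom. The chain index
#' (see [chains()]) is derived from standard `ATOM` records only, so
#' heteroatoms (waters, ions) never contribute to chain bounding boxes.
#'
#' @slot atoms data.frame with columns `type`, `chain`, `resno`, `resid`,
#'   `elety`, `x`, `y`, `z`.
#' @export
setClass("StructureModel", representation(atoms = "data.frame"),
  validity = function(object) {
    need <- c("type", "chain", "resno", "resid", "elety", "x", "y", "z")
    if (!all(need %in% names(object@atoms)))
      return(paste("atoms must have columns:", paste(need, collapse = ", ")))
    xyz <- as.matrix(object@atoms[, c("x", "y", "z")])
    if (nrow(xyz) > 0 && !all(is.finite(xyz)))
      return("atom coordinates must be finite")
    TRUE
  })

#' SearchBox: axis-aligned docking search space
#'
#' Centre and edge lengths (Angstrom) of the box a docking engine samples,
#' derived from the bound peptide chain of a receptor structure.
#'
#' @slot centre numeric(3), box centre (x, y, z) in Angstrom.
#' @slot dims numeric(3), edge lengths in Angstrom, strictly positive.
#' @export
setClass("SearchBox", representation(centre = "numeric", dims = "numeric"),
  validity = function(object) {
    if (length(object@centre) != 3 || length(object@dims) != 3)
      return("centre and dims must have length 3")
    if (!all(is.finite(object@centre)) || !all(is.finite(object@dims)))
      return("centre and dims must be finite")
    if (any(object@dims <= 0))
      return("dims must be strictly positive")
    TRUE
  })

#' ProteinRegion: a candidate binding window with residue labels
#'
#' A window (at most `window` residues, conventionally 50) cut from a parent
#' protein sequence around a motif, carrying 1-based inclusive coordinates on
#' the parent and a per-residue binary binding label (motif residues are the
#' positives).
#'
#' @slot parentId character, identifier of the parent sequence.
#' @slot parentLength integer, length of the parent sequence.
#' @slot start,end integer, 1-based inclusive region coordinates on the parent.
#' @slot seq character, the region's residue string.
#' @slot labels integer vector, one 0/1 label per region residue.
#' @export
setClass("ProteinRegion",
  representation(parentId = "character", parentLength = "integer",
                 start = "integer", end = "integer",
                 seq = "character", labels = "integer"),
  validity = function(object) {
    L <- nchar(object@seq)
    if (L < 1) return("region sequence must be non-empty")
    if (object@end - object@start + 1L != L)
      return("end - start + 1 must equal the sequence length")
    if (object@start < 1L || object@end > object@parentLength)
      return("region must lie within the parent sequence")
    if (length(object@labels) != L)
      return("labels must have one entry per residue")
    if (!all(object@labels %in% c(0L, 1L)))
      return("labels must be 0/1")
    TRUE
  })

#' ROCCurve: receiver operating characteristic with its AUC
#'
#' Thresholds run from above the largest score down to below the smallest, so
#' the curve starts at (FPR, TPR) = (0, 0) and ends at (1, 1); a call is
#' positive when score >= threshold. The AUC is the trapezoidal area under the
#' (FPR, TPR) polyline and equals the probability that a random positive
#' outranks a random negative (ties counted half).
#'
#' @slot thresholds numeric, decreasing decision thresholds (with sentinels).
#' @slot fpr,tpr numeric, false/true positive rate at each threshold.
#' @slot auc numeric(1) in [0, 1].
#' @export
setClass("ROCCurve",
  representation(thresholds = "numeric", fpr = "numeric", tpr = "numeric",
                 auc = "numeric"),
  validity = function(object) {
    n <- length(object@thresholds)
    if (length(object@fpr) != n || length(object@tpr) != n)
      return("thresholds, fpr and tpr must have equal length")
    if (is.unsorted(object@fpr) || is.unsorted(object@tpr))
      return("fpr and tpr must be non-decreasing along the curve")
    if (object@auc < 0 || object@auc > 1)
      return("auc must lie in [0, 1]")
    TRUE
  })

#' BRNNModel: a bidirectional recurrent sequence-labelling network
#'
#' Per-residue outputs are computed from a forward and a backward chain of
#' hidden state vectors plus a local window of inputs. Three two-layer
#' feed-forward networks parametrise the forward update, backward update and
#' output functions; chain boundary states are fixed at zero and the output is
#' squashed to (0, 1) by a logistic unit.
#'
#' @slot nIn integer, input channels per residue (26 with all features: 20
#'   one-hot amino-acid channels, 1 sequence-length channel, helix/strand/coil
#'   probabilities, disorder, normalised docking score).
#' @slot window integer, odd local input window width for the output network.
#' @slot hidden integer, hidden-chain state width.
#' @slot ffHidden integer, hidden-layer width of the three update networks.
#' @slot weights named list of weight matrices and bias vectors.
#' @slot log data.frame training trace (epoch, loss, lr); empty before training.
#' @export
setClass("BRNNModel",
  representation(nIn = "integer", window = "integer", hidden = "integer",
                 ffHidden = "integer", weights = "list", log = "data.frame"),
  validity = function(object) {
    if (object@window < 1L || object@window %% 2L == 0L)
      return("window must be a positive odd integer")
    need <- c("Wf1", "bf1", "Wf2", "bf2", "Wb1", "bb1", "Wb2", "bb2",
              "Wo1", "bo1", "Wo2", "bo2")
    if (!all(need %in% names(object@weights)))
      return(paste("weights must contain:", paste(need, collapse = ", ")))
    d <- object@nIn + object@hidden
    if (nrow(object@weights$Wf1) != d)
      return("Wf1 rows must equal nIn + hidden")
    if (nrow(object@weights$Wo1) != object@nIn * object@window + 2L * object@hidden)
      return("Wo1 rows must equal nIn * window + 2 * hidden")
    TRUE
  })

# ---- accessors ----

#' @describeIn StructureModel-class atom table accessor
#' @param object,x a `StructureModel`
#' @export
atoms <- function(x) {
  stopifnot(is(x, "StructureModel"))
  x@atoms
}

#' Chain index of a structure
#'
#' Chains holding at least one standard `ATOM` record (heteroatom-only chains
#' are excluded by the default policy).
#'
#' @param x a [StructureModel-class]
#' @return character vector of chain identifiers, sorted
#' @export
chains <- function(x) {
  stopifnot(is(x, "StructureModel"))
  sort(unique(x@atoms$chain[x@atoms$type == "ATOM"]))
}

#' @rdname SearchBox-class
#' @param x a `SearchBox`
#' @export
boxCentre <- function(x) { stopifnot(is(x, "SearchBox")); x@centre }

#' @rdname SearchBox-class
#' @export
boxDims <- function(x) { stopifnot(is(x, "SearchBox")); x@dims }

#' @rdname ProteinRegion-class
#' @param x a `ProteinRegion`
#' @export
regionSeq <- function(x) { stopifnot(is(x, "ProteinRegion")); x@seq }

#' @rdname ProteinRegion-class
#' @export
regionLabels <- function(x) { stopifnot(is(x, "ProteinRegion")); x@labels }

#' @rdname ProteinRegion-class
#' @export
regionSpan <- function(x) {
  stopifnot(is(x, "ProteinRegion"))
  c(start = x@start, end = x@end)
}

#' @rdname ROCCurve-class
#' @param x a `ROCCurve`
#' @export
auc <- function(x) { stopifnot(is(x, "ROCCurve")); x@auc }

#' @rdname ROCCurve-class
#' @export
rocTable <- function(x) {
  stopifnot(is(x, "ROCCurve"))
  data.frame(threshold = x@thresholds, fpr = x@fpr, tpr = x@tpr)
}

# ---- show methods ----

setMethod("show", "StructureModel", function(object) {
  ch <- chains(object)
  cat(sprintf("StructureModel: %d atoms (%d ATOM, %d HETATM), chains: %s\n",
              nrow(object@atoms), sum(object@atoms$type == "ATOM"),
              sum(object@atoms$type == "HETATM"),
              if (length(ch)) paste(ch, collapse = ", ") else "<none>"))
})

setMethod("show", "SearchBox", function(object) {
  cat(sprintf("SearchBox: centre (%.2f, %.2f, %.2f) A, dims (%.2f, %.2f, %.2f) A\n",
              object@centre[1], object@centre[2], object@centre[3],
              object@dims[1], object@dims[2], object@dims[3]))
})

setMethod("show", "ProteinRegion", function(object) {
  cat(sprintf("ProteinRegion %s:%d-%d (parent %d aa), %d residues, %d labelled positive\n",
              object@parentId, object@start, object@end, object@parentLength,
              nchar(object@seq), sum(object@labels)))
})

setMethod("show", "ROCCurve", function(object) {
  cat(sprintf("ROCCurve: %d points, AUC = %.4f\n",
              length(object@fpr), object@auc))
})

setMethod("show", "BRNNModel", function(object) {
  np <- sum(vapply(object@weights, length, integer(1)))
  cat(sprintf("BRNNModel: %d input channels, window %d, hidden chain %d, ff hidden %d (%d parameters)%s\n",
              object@nIn, object@window, object@hidden, object@ffHidden, np,
              if (nrow(object@log)) sprintf("; trained %d epochs", max(object@log$epoch)) else ""))
})
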