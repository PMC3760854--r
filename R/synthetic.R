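#' Generate a synthetic corpus of labelled binding regions
#'
#' Emulates the study conditions the pipeline is built for: `n` regions of
#' `len` residues, each carrying a single contiguous planted binding span
#' whose length is drawn uniformly from `spanRange` (default 3-12, the short
#' linear motif length range), a smooth disorder track that always passes the
#' strict mean > 0.5 disorder filter, and valid three-class secondary-
#' structure probability tracks tilted towards coil, as expected inside
#' disordered regions. Residues are drawn uniformly over the 20 standard
#' amino acids: the sequence channel deliberately carries no binding signal,
#' so any recovered signal must come from the structural tracks. Generation
#' is a pure function of the arguments.
#'
#' @param n number of regions (default 84)
#' @param len region length (default 50)
#' @param spanRange integer range of planted-span lengths (default `c(3, 12)`)
#' @param seed integer seed
#' @return list of entries `list(region, ss, disorder)` where `region` is a
#'   [ProteinRegion-class], `ss` an L x 3 probability matrix and `disorder`
#'   a numeric track
#' @export
syntheticRegions <- function(n = 84L, len = 50L, spanRange = c(3L, 12L),
                             seed = 1L) {
  n <- as.integer(n); len <- as.integer(len)
  spanRange <- as.integer(spanRange)
  if (spanRange[1] < 1L || spanRange[2] > len || spanRange[1] > spanRange[2])
    stop("infeasible span range for region length ", len, call. = FALSE)
  withSeed(seed, lapply(seq_len(n), function(i) {
    seq <- paste(sample(AA_ALPHABET20, len, replace = TRUE), collapse = "")
    spanLen <- if (spanRange[1] == spanRange[2]) spanRange[1] else
      sample(spanRange[1]:spanRange[2], 1L)
    spanStart <- sample.int(len - spanLen + 1L, 1L)
    labels <- integer(len)
    labels[spanStart:(spanStart + spanLen - 1L)] <- 1L
    # smooth high disorder: moving-average noise shifted into [0.55, 0.95]
    raw <- stats::filter(stats::runif(len + 8L), rep(1 / 9, 9L), sides = 2L)
    raw <- raw[!is.na(raw)][seq_len(len)]
    disorder <- 0.55 + 0.4 * (raw - min(raw)) / max(max(raw) - min(raw), 1e-9)
    # coil-tilted Dirichlet(1, 1, 3) per residue
    gm <- cbind(stats::rgamma(len, 1), stats::rgamma(len, 1), stats::rgamma(len, 3))
    ss <- gm / rowSums(gm)
    colnames(ss) <- c("helix", "strand", "coil")
    region <- new("ProteinRegion", parentId = sprintf("synth%03d", i),
                  parentLength = len, start = 1L, end = len,
                  seq = seq, labels = labels)
    list(region = region, ss = ss, disorder = pmin(disorder, 1))
  }))
}

#' Deterministic mock docking engine
#'
#' A stand-in docking adapter generating fragment affinities from the planted
#' labels of a region: the best pose for a fragment starting at offset `o`
#' scores `-(base + effect * f) + N(0, sigma^2)`, where `f` is the fraction of
#' the fragment's residues labelled positive — so binding fragments score more
#' favourably (more negative) and the strength of the planted signal is
#' controlled by `effect` relative to `sigma`. Two less-favourable decoy
#' poses (+0.5 and +1.2 kcal/mol) are returned alongside the best pose so
#' best-pose selection is exercised. Noise is drawn once per fragment offset
#' at engine creation, making repeated calls on the same fragment
#' bit-identical.
#'
#' @param labels 0/1 label vector of the region the engine scores
#' @param k fragment length the engine will be called with (default 3)
#' @param effect label effect size in kcal/mol (default 2)
#' @param sigma Gaussian noise s.d. in kcal/mol (default 0.1)
#' @param base baseline affinity magnitude in kcal/mol (default 4)
#' @param seed integer seed
#' @return a docking adapter function, see [dockFragment()]
#' @export
mockEngine <- function(labels, k = 3L, effect = 2, sigma = 0.1, base = 4,
                       seed = 1L) {
  stopifnot(sigma >= 0, all(labels %in% c(0, 1)))
  k <- as.integer(k)
  nFrag <- length(labels) - k + 1L
  if (nFrag < 1L) stop("fragment length exceeds region length", call. = FALSE)
  noise <- withSeed(seed, stats::rnorm(nFrag, 0, sigma))
  function(receptor, box, kmer, offset) {
    offset <- as.integer(offset)
    if (is.na(offset) || offset < 1L || offset > nFrag)
      stop("mock engine needs a valid fragment offset")
    frac <- mean(labels[offset:(offset + k - 1L)])
    best <- -(base + effect * frac) + noise[offset]
    c(best, best + 0.5, best + 1.2)
  }
}

#' Build the full synthetic training corpus with docking-score tracks
#'
#' Runs the docking leg of the pipeline (mock engine, best-pose selection,
#' residue aggregation, per-region normalisation) over a synthetic corpus and
#' encodes the requested feature channels, yielding the
#' `list(x, y)` dataset the trainer and cross-validation consume.
#'
#' @inheritParams syntheticRegions
#' @param effect,sigma mock-engine signal and noise, see [mockEngine()]
#' @param k fragment length (default 3)
#' @param features structural channels to fill, see [encodeInputs()]
#' @return list of `list(x = feature matrix, y = labels, region, vina)`
#' @export
syntheticCorpus <- function(n = 84L, len = 50L, spanRange = c(3L, 12L),
                            effect = 2, sigma = 0.1, k = 3L, seed = 1L,
                            features = c("ss", "disorder", "vina")) {
  fixtures <- syntheticRegions(n = n, len = len, spanRange = spanRange,
                               seed = seed)
  lapply(seq_along(fixtures), function(i) {
    fx <- fixtures[[i]]
    eng <- mockEngine(fx$region@labels, k = k, effect = effect, sigma = sigma,
                      seed = childSeed(seed, i))
    frags <- dockRegion(eng, receptor = NULL, box = NULL, fx$region, k = k)
    raw <- aggregateToResidues(frags, len, k = k)
    vina <- normalizeScores(raw)
    x <- encodeInputs(fx$region, ss = fx$ss, disorder = fx$disorder,
                      vina = vina, features = features)
    list(x = x, y = fx$region@labels, region = fx$region, vina = vina)
  })
}

#' Write a toy receptor + peptide PDB file
#'
#' Builds a parseable two-chain structure: chain A, a small synthetic
#' "receptor" of CA atoms on a jittered grid away from the origin, and chain
#' B, a short synthetic peptide whose CA atoms are placed inside a known
#' bounding box (`bbox`, default the unit cube scaled to 0-10 Angstrom) with
#' its first and last atoms pinned to the box corners — so the search box
#' derived from chain B is exactly predictable.
#'
#' @param path output path
#' @param peptideLength number of peptide residues (chain B; default 3)
#' @param bbox numeric(2), low/high corner value of the peptide bounding cube
#'   (default `c(0, 10)`)
#' @param receptorAtoms number of receptor CA atoms (default 20)
#' @param seed integer seed
#' @return `path`, invisibly
#' @export
genToyPDB <- function(path, peptideLength = 3L, bbox = c(0, 10),
                      receptorAtoms = 20L, seed = 1L) {
  peptideLength <- as.integer(peptideLength)
  stopifnot(peptideLength >= 1L, bbox[2] > bbox[1])
  withSeed(seed, {
    recXYZ <- cbind(stats::runif(receptorAtoms, bbox[2] + 5, bbox[2] + 15),
                    stats::runif(receptorAtoms, bbox[1], bbox[2]),
                    stats::runif(receptorAtoms, bbox[1], bbox[2]))
    pepXYZ <- if (peptideLength == 1L) {
      matrix((bbox[1] + bbox[2]) / 2, 1L, 3L)
    } else {
      m <- cbind(stats::runif(peptideLength, bbox[1], bbox[2]),
                 stats::runif(peptideLength, bbox[1], bbox[2]),
                 stats::runif(peptideLength, bbox[1], bbox[2]))
      m[1L, ] <- bbox[1]; m[peptideLength, ] <- bbox[2]
      m
    }
    resnames <- sample(c("ALA", "GLY", "SER", "LEU", "VAL"),
                       receptorAtoms + peptideLength, replace = TRUE)
  })
  atoms <- data.frame(
    type = "ATOM",
    chain = c(rep("A", receptorAtoms), rep("B", peptideLength)),
    resno = c(seq_len(receptorAtoms), seq_len(peptideLength)),
    resid = resnames,
    elety = "CA",
    x = c(recXYZ[, 1], pepXYZ[, 1]),
    y = c(recXYZ[, 2], pepXYZ[, 2]),
    z = c(recXYZ[, 3], pepXYZ[, 3]),
    stringsAsFactors = FALSE)
  writePDB(new("StructureModel", atoms = atoms), path)
  invisible(path)
}
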