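#' @name pipeline
#' @title End-to-end workflows
#' @description
#' The `run*` functions orchestrate the full method on local files, mirroring
#' the interactive workflow: `runDock` prepares the receptor and search box
#' and turns fragments into score tracks, `runTrain` fits cross-validated
#' BRNN ensembles per feature combination, `runPredict` scores a query
#' sequence and averages predictions over motif matches, `runSimulate` writes
#' synthetic fixtures and `runEvaluate` writes a ROC/AUC report. All are
#' reproducible from their `seed` argument; each writes a JSON run manifest
#' recording inputs, seeds and parameter values.
NULL

writeManifest <- function(outDir, command, params) {
  manifest <- list(command = command,
                   package = as.character(utils::packageVersion("SLiMBind")),
                   rversion = as.character(getRversion()),
                   params = params)
  jsonlite::write_json(manifest, file.path(outDir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' @rdname pipeline
#' @param fasta path to a FASTA file; the first record is the query unless
#'   `id` names another
#' @param motifStart,motifEnd 1-based motif span on the query sequence
#' @param receptorPdb path to a PDB structure containing the receptor with a
#'   bound peptide chain
#' @param peptideChain chain identifier of the bound peptide in `receptorPdb`
#' @param engine `"mock"`, or a docking adapter function (e.g. from
#'   [vinaEngine()])
#' @param outDir output directory (created if needed)
#' @param k fragment length (default 3)
#' @param window candidate window length (default 50)
#' @param padding,maxEdge search-box geometry, see [computeSearchBox()]
#' @param id optional record id to select from `fasta`
#' @param seed integer seed (drives the mock engine)
#' @return `runDock`: invisibly, a list with the region, fragment table, raw
#'   and normalised tracks and the paths written
#' @export
runDock <- function(fasta, motifStart, motifEnd, receptorPdb, peptideChain,
                    engine = "mock", outDir = ".", k = 3L, window = 50L,
                    padding = 5, maxEdge = 30, id = NULL, seed = 1L) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seqs <- readFasta(fasta)
  if (is.null(id)) id <- names(seqs)[1]
  if (!id %in% names(seqs))
    stop("record '", id, "' not found in ", fasta, call. = FALSE)
  region <- extractWindow(as.character(seqs[[id]]), motifStart, motifEnd,
                          window = window, parentId = id)
  model <- parsePDB(receptorPdb)
  box <- computeSearchBox(model, peptideChain, padding = padding,
                          maxEdge = maxEdge)
  receptor <- stripChain(model, peptideChain)
  recPath <- file.path(outDir, "receptor.pdb")
  writePDB(receptor, recPath)
  boxPath <- file.path(outDir, "box_config.txt")
  writeBoxConfig(box, boxPath)
  if (identical(engine, "mock"))
    engine <- mockEngine(region@labels, k = k, seed = seed)
  else if (!is.function(engine))
    stop("engine must be \"mock\" or a docking adapter function; for ",
         "AutoDock Vina build one with vinaEngine()", call. = FALSE)
  frags <- dockRegion(engine, receptor, box, region, k = k)
  raw <- aggregateToResidues(frags, nchar(region@seq), k = k)
  normalized <- normalizeScores(raw)
  fragPath <- file.path(outDir, "fragment_scores.tsv")
  utils::write.table(frags, fragPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  trackPath <- file.path(outDir, "residue_track.tsv")
  writeScoreTrack(region, raw, normalized, trackPath)
  writeManifest(outDir, "dock",
                list(fasta = fasta, id = id, motifStart = motifStart,
                     motifEnd = motifEnd, receptorPdb = receptorPdb,
                     peptideChain = peptideChain, k = k, window = window,
                     padding = padding, maxEdge = maxEdge, seed = seed))
  invisible(list(region = region, fragments = frags, raw = raw,
                 normalized = normalized,
                 paths = c(receptor = recPath, box = boxPath,
                           fragments = fragPath, track = trackPath)))
}

# the seven trained input combinations: sequence plus every non-empty subset
# of {secondary structure, disorder, docking score}
featureCombinations <- function() {
  list("ss" = "ss", "disorder" = "disorder", "vina" = "vina",
       "ss+disorder" = c("ss", "disorder"), "ss+vina" = c("ss", "vina"),
       "disorder+vina" = c("disorder", "vina"),
       "ss+disorder+vina" = c("ss", "disorder", "vina"))
}

#' @rdname pipeline
#' @param corpus a labelled dataset as produced by [syntheticCorpus()] with
#'   all features encoded, or `NULL` to generate one
#' @param n,effect,sigma synthetic-corpus parameters (used when
#'   `corpus = NULL`), see [syntheticCorpus()]
#' @param featureSets named list of feature subsets to train (default: the
#'   seven combinations of secondary structure, disorder and docking score)
#' @param folds,windows,epochs,lr,patience,hidden,ffHidden training and
#'   cross-validation settings, see [crossValidate()]
#' @return `runTrain`: invisibly, a list with `aucTable` (one AUC per feature
#'   combination, from pooled out-of-fold predictions) and `cv` (per-set
#'   cross-validation results); checkpoints and the table are written under
#'   `outDir`
#' @export
runTrain <- function(corpus = NULL, outDir = ".", n = 84L, effect = 2,
                     sigma = 0.1, featureSets = featureCombinations(),
                     folds = 10L, windows = c(7L, 9L, 11L), epochs = 10000L,
                     lr = 0.01, patience = 50L, hidden = 11L, ffHidden = 20L,
                     seed = 1L) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(corpus))
    corpus <- syntheticCorpus(n = n, effect = effect, sigma = sigma,
                              seed = seed)
  labels <- unlist(lapply(corpus, `[[`, "y"))
  aucs <- numeric(length(featureSets))
  cvs <- vector("list", length(featureSets))
  for (s in seq_along(featureSets)) {
    keep <- featureSets[[s]]
    # zero out deselected channels so every set shares one input geometry
    dataset <- lapply(corpus, function(d) {
      x <- d$x
      if (!"ss" %in% keep) x[, 22:24] <- 0
      if (!"disorder" %in% keep) x[, 25] <- 0
      if (!"vina" %in% keep) x[, 26] <- 0
      list(x = x, y = d$y)
    })
    cv <- crossValidate(dataset, folds = folds, windows = windows,
                        epochs = epochs, lr = lr, patience = patience,
                        hidden = hidden, ffHidden = ffHidden,
                        seed = childSeed(seed, s))
    aucs[s] <- aucFromScores(unlist(cv$predictions), labels)
    cvs[[s]] <- cv
    setDir <- file.path(outDir, paste0("models_", names(featureSets)[s]))
    dir.create(setDir, showWarnings = FALSE)
    for (f in seq_along(cv$models))
      for (m in seq_along(cv$models[[f]]))
        writeBRNNModel(cv$models[[f]][[m]],
                       file.path(setDir, sprintf("fold%02d_w%d.json", f,
                                                 cv$models[[f]][[m]]@window)))
  }
  aucTable <- data.frame(input = names(featureSets), auc = aucs)
  utils::write.table(aucTable, file.path(outDir, "auc_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeManifest(outDir, "train",
                list(n = length(corpus), folds = folds, windows = windows,
                     epochs = epochs, lr = lr, patience = patience,
                     hidden = hidden, ffHidden = ffHidden, seed = seed))
  invisible(list(aucTable = aucTable, cv = cvs))
}

#' @rdname pipeline
#' @param models list of trained [BRNNModel-class] (for an unseen sequence,
#'   all fold ensembles are averaged together); a single model is accepted
#' @param start 1-based residue at which the candidate window starts (the
#'   window covers `start .. start + window - 1`, truncated at the terminus)
#' @param ss,disorder structural tracks over the window (L x 3 matrix and
#'   numeric vector); omit to zero-fill those channels
#' @param pattern optional motif regular expression; matches inside the
#'   window get their predictions averaged over the motif residues
#' @param threshold decision cutoff on the prediction (default 0.4)
#' @return `runPredict`: invisibly, a list with `scores` (data.frame:
#'   position, residue, score, call) and `motifs` (per-match mean scores),
#'   both written as TSV under `outDir`
#' @export
runPredict <- function(models, fasta, start, receptorPdb, peptideChain,
                       ss = NULL, disorder = NULL, engine = "mock",
                       pattern = NULL, threshold = 0.4, outDir = ".",
                       k = 3L, window = 50L, id = NULL, seed = 1L) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (is(models, "BRNNModel")) models <- list(models)
  seqs <- readFasta(fasta)
  if (is.null(id)) id <- names(seqs)[1]
  parent <- as.character(seqs[[id]])
  L <- nchar(parent)
  if (start < 1 || start > L)
    stop("start residue ", start, " outside sequence of length ", L,
         call. = FALSE)
  end <- min(start + window - 1L, L)
  region <- new("ProteinRegion", parentId = id, parentLength = L,
                start = as.integer(start), end = as.integer(end),
                seq = substr(parent, start, end),
                labels = integer(end - start + 1L))
  structure <- parsePDB(receptorPdb)
  box <- computeSearchBox(structure, peptideChain)
  receptor <- stripChain(structure, peptideChain)
  writePDB(receptor, file.path(outDir, "receptor.pdb"))
  writeBoxConfig(box, file.path(outDir, "box_config.txt"))
  if (identical(engine, "mock"))
    engine <- mockEngine(region@labels, k = k, seed = seed)
  frags <- dockRegion(engine, receptor, box, region, k = k)
  vina <- normalizeScores(aggregateToResidues(frags, nchar(region@seq), k = k))
  feats <- c(if (!is.null(ss)) "ss", if (!is.null(disorder)) "disorder", "vina")
  x <- encodeInputs(region, ss = ss, disorder = disorder, vina = vina,
                    features = feats)
  score <- Reduce(`+`, lapply(models, brnnPredict, x = x)) / length(models)
  scores <- data.frame(position = region@start:region@end,
                       residue = strsplit(region@seq, "")[[1]],
                       score = score, call = score >= threshold)
  utils::write.table(scores, file.path(outDir, "predictions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  motifs <- NULL
  if (!is.null(pattern)) {
    hits <- scanMotif(region@seq, pattern, id = id)
    if (nrow(hits)) {
      hits$meanScore <- vapply(seq_len(nrow(hits)), function(i)
        mean(score[hits$start[i]:hits$end[i]]), numeric(1))
      hits$call <- hits$meanScore >= threshold
      hits$start <- hits$start + region@start - 1L
      hits$end <- hits$end + region@start - 1L
    }
    motifs <- hits
    utils::write.table(hits, file.path(outDir, "motif_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeManifest(outDir, "predict",
                list(fasta = fasta, id = id, start = start,
                     receptorPdb = receptorPdb, peptideChain = peptideChain,
                     pattern = pattern, threshold = threshold, k = k,
                     window = window, seed = seed))
  invisible(list(scores = scores, motifs = motifs, region = region))
}

#' @rdname pipeline
#' @return `runSimulate`: invisibly, the paths written (FASTA of regions,
#'   per-region track TSVs, a toy receptor+peptide PDB)
#' @export
runSimulate <- function(outDir = ".", n = 84L, effect = 2, sigma = 0.1,
                        k = 3L, seed = 1L) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  corpus <- syntheticCorpus(n = n, effect = effect, sigma = sigma, k = k,
                            seed = seed)
  seqs <- vapply(corpus, function(d) d$region@seq, character(1))
  names(seqs) <- vapply(corpus, function(d) d$region@parentId, character(1))
  fastaPath <- file.path(outDir, "regions.fasta")
  writeFasta(seqs, fastaPath)
  trackPath <- file.path(outDir, "tracks.tsv")
  tracks <- do.call(rbind, lapply(corpus, function(d)
    data.frame(id = d$region@parentId,
               position = seq_len(nchar(d$region@seq)),
               label = d$region@labels,
               helix = d$x[, 22], strand = d$x[, 23], coil = d$x[, 24],
               disorder = d$x[, 25], vina = d$x[, 26])))
  utils::write.table(tracks, trackPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pdbPath <- file.path(outDir, "toy_receptor.pdb")
  genToyPDB(pdbPath, seed = seed)
  writeManifest(outDir, "simulate",
                list(n = n, effect = effect, sigma = sigma, k = k, seed = seed))
  invisible(c(fasta = fastaPath, tracks = trackPath, pdb = pdbPath))
}

#' @rdname pipeline
#' @param scores,labels pooled per-residue predictions and binary labels
#' @return `runEvaluate`: invisibly, the [ROCCurve-class]; the curve TSV
#'   (with an AUC summary line) is written under `outDir`
#' @export
runEvaluate <- function(scores, labels, outDir = ".") {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  curve <- rocPoints(scores, labels)
  writeROC(curve, file.path(outDir, "roc.tsv"))
  invisible(curve)
}

#' CORNR-box motif instances bundled with the package
#'
#' The worked proteome-scan example: 67 instances of the nuclear-receptor
#' co-repressor (CORNR box) motif found in 65 human proteins, with the
#' predictor score averaged over the nine motif residues and an evolutionary
#' conservation p-value per instance. Shipped as plain TSV under
#' `inst/extdata/`.
#'
#' @return data.frame with columns `accession`, `motif`, `score`, `pvalue`,
#'   `elm_tp` (flag for the two instances validated as true positives)
#' @export
cornrInstances <- function() {
  path <- system.file("extdata", "cornr_box_instances.tsv",
                      package = "SLiMBind")
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' The CORNR-box motif pattern
#'
#' Regular expression for the nuclear-receptor co-repressor box,
#' `L[^P]{2}[HI]I[^P]{2}[IAV][IL]` (nine residues).
#'
#' @return character(1)
#' @export
cornrPattern <- function() "L[^P]{2}[HI]I[^P]{2}[IAV][IL]"
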