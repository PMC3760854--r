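#' Dock a single fragment and keep its best pose
#'
#' The engine adapter contract: `engine(receptor, box, peptide, offset)`
#' returns a numeric vector of pose affinities (kcal/mol, more negative =
#' stronger) with at least one pose. The best (minimum) pose score is
#' retained; adapter failures are surfaced as errors carrying the fragment,
#' never as silent zeros.
#'
#' @param engine a docking adapter function (see [mockEngine()], [vinaEngine()])
#' @param receptor a [StructureModel-class] (peptide chain already stripped)
#' @param box a [SearchBox-class]
#' @param kmer fragment residue string
#' @param offset 1-based fragment offset on the region (passed to the adapter;
#'   external engines may ignore it)
#' @return numeric(1), best pose affinity
#' @export
dockFragment <- function(engine, receptor, box, kmer, offset = NA_integer_) {
  stopifnot(is.function(engine))
  poses <- tryCatch(engine(receptor, box, kmer, offset),
                    error = function(e) stop("docking engine failed on fragment '",
                                             kmer, "' (offset ", offset, "): ",
                                             conditionMessage(e), call. = FALSE))
  if (length(poses) == 0 || !is.numeric(poses) || any(!is.finite(poses)))
    stop("docking engine returned no finite poses for fragment '", kmer,
         "' (offset ", offset, ")", call. = FALSE)
  min(poses)
}

#' Dock every fragment of a region
#'
#' Applies [dockFragment()] across the fragment set of a region. A fragment
#' whose docking fails is retried once; if it fails again its score is imputed
#' with the median of the successful fragments, with a warning, so one bad
#' fragment cannot kill a run.
#'
#' @inheritParams dockFragment
#' @param region a [ProteinRegion-class] or residue string
#' @param k fragment length (default 3)
#' @return data.frame with columns `offset`, `kmer`, `score`
#' @export
dockRegion <- function(engine, receptor, box, region, k = 3L) {
  frags <- generateFragments(region, k)
  scores <- rep(NA_real_, nrow(frags))
  for (i in seq_len(nrow(frags))) {
    s <- try(dockFragment(engine, receptor, box, frags$kmer[i],
                          frags$offset[i]), silent = TRUE)
    if (inherits(s, "try-error"))     # retry once
      s <- try(dockFragment(engine, receptor, box, frags$kmer[i],
                            frags$offset[i]), silent = TRUE)
    if (!inherits(s, "try-error")) scores[i] <- s
  }
  if (anyNA(scores)) {
    if (all(is.na(scores)))
      stop("docking failed for every fragment of the region", call. = FALSE)
    warning(sum(is.na(scores)),
            " fragment(s) failed twice; imputing the region median score")
    scores[is.na(scores)] <- stats::median(scores, na.rm = TRUE)
  }
  cbind(frags, score = scores)
}

#' Aggregate fragment scores to a per-residue track
#'
#' Each residue takes the minimum (most favourable) best-pose score over all
#' fragments covering it, echoing best-pose selection at the fragment level.
#' Set `method = "mean"` for the average over covering fragments instead.
#'
#' @param frags data.frame with columns `offset` and `score`, as returned by
#'   [dockRegion()]; offsets must tile the region (consecutive from 1)
#' @param regionLength region length the track covers
#' @param k fragment length used to generate `frags`
#' @param method `"min"` (default) or `"mean"`
#' @return numeric vector of length `regionLength` (raw score track)
#' @export
aggregateToResidues <- function(frags, regionLength, k = 3L,
                                method = c("min", "mean")) {
  method <- match.arg(method)
  regionLength <- as.integer(regionLength); k <- as.integer(k)
  expected <- seq_len(regionLength - k + 1L)
  if (!identical(as.integer(sort(frags$offset)), expected))
    stop("fragment offsets do not tile the region: expected 1..",
         regionLength - k + 1L, call. = FALSE)
  score <- frags$score[order(frags$offset)]
  vapply(seq_len(regionLength), function(i) {
    cover <- max(1L, i - k + 1L):min(i, regionLength - k + 1L)
    if (method == "min") min(score[cover]) else mean(score[cover])
  }, numeric(1))
}

#' Normalise a raw docking-score track to [0, 1]
#'
#' Per-region min-max normalisation with the upper reference pinned at zero:
#' `v_i = clamp(-s_i, 0, |s_min|) / |s_min|`, where `s_min` is the most
#' negative score in the track. The most negative score maps to 1, a score of
#' zero to 0, and positive raw scores clamp to 0. Normalisation is per region:
#' scores from different receptors are not comparable.
#'
#' @param track numeric vector of raw best-pose scores (kcal/mol)
#' @return numeric vector in [0, 1]
#' @export
normalizeScores <- function(track) {
  if (length(track) == 0) stop("empty score track", call. = FALSE)
  if (any(!is.finite(track))) stop("scores must be finite", call. = FALSE)
  smin <- min(track)
  if (smin >= 0) {
    warning("degenerate score track: no negative scores; returning zeros")
    return(rep(0, length(track)))
  }
  pmin(pmax(-track, 0), -smin) / (-smin)
}

#' Write a residue score track as TSV
#'
#' @param region a [ProteinRegion-class]
#' @param raw,normalized numeric tracks over the region
#' @param path output path
#' @return `path`, invisibly
#' @export
writeScoreTrack <- function(region, raw, normalized, path) {
  stopifnot(is(region, "ProteinRegion"),
            length(raw) == nchar(region@seq),
            length(normalized) == length(raw))
  df <- data.frame(position = region@start:region@end,
                   residue = strsplit(region@seq, "")[[1]],
                   raw = raw, normalized = normalized)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse an AutoDock-Vina-style result table
#'
#' Extracts (mode, affinity) pairs from the engine's stdout table, whose rows
#' look like `"   1       -6.3      0.000      0.000"` below the
#' `mode | affinity` header.
#'
#' @param text character vector of output lines
#' @return data.frame with columns `mode` and `affinity`; zero rows when the
#'   table is absent
#' @export
parseVinaOutput <- function(text) {
  rows <- regmatches(text,
    regexec("^\\s*(\\d+)\\s+(-?\\d+(?:\\.\\d+)?)\\s+\\d+(?:\\.\\d+)?\\s+\\d+(?:\\.\\d+)?\\s*$",
            text))
  rows <- rows[vapply(rows, length, integer(1)) == 3]
  if (!length(rows))
    return(data.frame(mode = integer(), affinity = numeric()))
  data.frame(mode = as.integer(vapply(rows, `[`, "", 2)),
             affinity = as.numeric(vapply(rows, `[`, "", 3)))
}

#' Build an adapter around an external AutoDock Vina binary
#'
#' Returns a docking adapter (see [dockFragment()]) that writes the receptor
#' and box configuration, prepares the fragment ligand via `ligandPrep`, runs
#' the binary and parses its result table. Ligand preparation (k-mer to
#' SMILES to a 3D ligand file) is deliberately delegated: supply a
#' `ligandPrep(kmer, dir)` function returning the path to a prepared ligand
#' file for your toolchain.
#'
#' @param binary path to the engine executable (default `"vina"` on `PATH`)
#' @param ligandPrep function `(kmer, dir) -> ligand file path`
#' @param workDir scratch directory for engine inputs/outputs
#' @return adapter function `(receptor, box, kmer, offset) -> pose affinities`
#' @export
vinaEngine <- function(binary = "vina", ligandPrep = NULL,
                       workDir = tempfile("vina")) {
  if (Sys.which(binary) == "" && !file.exists(binary))
    stop("docking binary '", binary, "' not found; install AutoDock Vina or ",
         "use engine = \"mock\"", call. = FALSE)
  if (is.null(ligandPrep))
    stop("vinaEngine needs a ligandPrep(kmer, dir) function producing a ",
         "prepared ligand file", call. = FALSE)
  dir.create(workDir, recursive = TRUE, showWarnings = FALSE)
  function(receptor, box, kmer, offset) {
    recPath <- file.path(workDir, "receptor.pdb")
    writePDB(receptor, recPath)
    cfgPath <- file.path(workDir, "box.txt")
    writeBoxConfig(box, cfgPath)
    lig <- ligandPrep(kmer, workDir)
    out <- suppressWarnings(system2(binary,
      c("--receptor", recPath, "--ligand", lig, "--config", cfgPath),
      stdout = TRUE, stderr = TRUE))
    status <- attr(out, "status")
    if (!is.null(status) && status != 0)
      stop("engine exited with status ", status, ": ",
           paste(utils::tail(out, 3), collapse = " / "))
    tab <- parseVinaOutput(out)
    if (nrow(tab) == 0) stop("engine produced no poses")
    tab$affinity
  }
}
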