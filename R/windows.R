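#' Extract the candidate binding window around a motif
#'
#' Cuts a window of `window` residues (default 50) from the parent sequence
#' with the motif at its centre, unless the motif centre falls within the
#' terminal half-window of either end, in which case the first or last
#' `window` residues are taken. Sequences shorter than `window` are returned
#' whole. The motif centre is `ceiling((motifStart + motifEnd) / 2)`; per-
#' residue labels mark the motif span intersected with the region.
#'
#' @param seq residue string (or anything coercible via `as.character`)
#' @param motifStart,motifEnd 1-based inclusive motif span on `seq`
#' @param window window length (default 50)
#' @param parentId identifier recorded on the region (default `"seq"`)
#' @return a [ProteinRegion-class]
#' @export
extractWindow <- function(seq, motifStart, motifEnd, window = 50L,
                          parentId = "seq") {
  seq <- toupper(as.character(seq))
  L <- nchar(seq)
  motifStart <- as.integer(motifStart); motifEnd <- as.integer(motifEnd)
  window <- as.integer(window)
  if (motifStart < 1L || motifEnd > L || motifStart > motifEnd)
    stop("motif span [", motifStart, ", ", motifEnd,
         "] outside sequence of length ", L, call. = FALSE)
  if (L <= window) {
    start <- 1L; end <- L
  } else {
    centre <- as.integer(ceiling((motifStart + motifEnd) / 2))
    half <- window %/% 2L
    if (centre <= half) {                 # N-terminal rule
      start <- 1L
    } else if (centre >= L - (window - half) + 1L) {  # C-terminal rule
      start <- L - window + 1L
    } else {
      start <- centre - half + 1L
    }
    end <- start + window - 1L
  }
  labels <- integer(end - start + 1L)
  lo <- max(motifStart, start); hi <- min(motifEnd, end)
  if (lo <= hi) labels[(lo - start + 1L):(hi - start + 1L)] <- 1L
  new("ProteinRegion", parentId = parentId, parentLength = L,
      start = start, end = end,
      seq = substr(seq, start, end), labels = labels)
}

#' Generate overlapping k-mer fragments from a region
#'
#' Slides a window of `k` residues (default 3, the tripeptide setting) along
#' the region, producing the `L - k + 1` overlapping fragments that are docked
#' against the receptor.
#'
#' @param region a [ProteinRegion-class] or a residue string
#' @param k fragment length, between 2 and 5 in the supported range
#'   (default 3); `k = nchar(region)` is allowed as a degenerate case
#' @return data.frame with columns `offset` (1-based on the region) and `kmer`
#' @export
generateFragments <- function(region, k = 3L) {
  seq <- if (is(region, "ProteinRegion")) region@seq else as.character(region)
  L <- nchar(seq)
  k <- as.integer(k)
  if (k < 1L || k > L)
    stop("fragment length k = ", k, " out of range for region of length ", L,
         call. = FALSE)
  offs <- seq_len(L - k + 1L)
  data.frame(offset = offs,
             kmer = substring(seq, offs, offs + k - 1L),
             stringsAsFactors = FALSE)
}

#' Scan a sequence with a motif regular expression
#'
#' Reports every match, including overlapping ones, left to right with 1-based
#' inclusive spans. Patterns use standard (Perl-compatible) regex syntax over
#' the amino-acid alphabet, e.g. the CORNR-box pattern
#' `L[^P]{2}[HI]I[^P]{2}[IAV][IL]`.
#'
#' @param seq residue string
#' @param pattern regular expression
#' @param id identifier recorded on each match (default `"seq"`)
#' @return data.frame with columns `id`, `start`, `end`, `match`; zero rows
#'   when nothing matches
#' @export
scanMotif <- function(seq, pattern, id = "seq") {
  seq <- toupper(as.character(seq))
  ok <- tryCatch({suppressWarnings(regexpr(pattern, "", perl = TRUE)); TRUE},
                 error = function(e) FALSE)
  if (!ok) stop("invalid regular expression: ", pattern, call. = FALSE)
  # a zero-width lookahead wrapper exposes overlapping matches
  m <- gregexpr(sprintf("(?=(%s))", pattern), seq, perl = TRUE)[[1]]
  if (m[1] == -1)
    return(data.frame(id = character(), start = integer(), end = integer(),
                      match = character(), stringsAsFactors = FALSE))
  starts <- as.integer(attr(m, "capture.start")[, 1])
  lens <- as.integer(attr(m, "capture.length")[, 1])
  data.frame(id = id, start = starts, end = starts + lens - 1L,
             match = substring(seq, starts, starts + lens - 1L),
             stringsAsFactors = FALSE)
}

#' Disorder filter for a candidate window
#'
#' A window is kept as disordered when the mean of its per-residue disorder
#' scores strictly exceeds the threshold (default 0.5).
#'
#' @param track numeric vector of per-residue disorder scores in [0, 1]
#' @param threshold mean-disorder cutoff (default 0.5, strict)
#' @return logical(1)
#' @export
disorderFilter <- function(track, threshold = 0.5) {
  assertProb(track, "disorder")
  mean(track) > threshold
}
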