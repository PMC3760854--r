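#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and whitespace-stripped; the accepted alphabet is
#' the 20 standard amino acids plus `X` for an unknown residue.
#'
#' @param path path to a FASTA file
#' @return a named [Biostrings::AAStringSet] with one entry per record,
#'   in file order
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- withCallingHandlers(
    tryCatch(Biostrings::readAAStringSet(path),
             error = function(e) stop("malformed FASTA file '", path, "': ",
                                      conditionMessage(e), call. = FALSE)),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        # name the offending record instead of silently dropping letters
        lines <- readLines(path, warn = FALSE)
        rec <- "?"
        for (ln in lines) {
          if (startsWith(ln, ">")) rec <- sub("^>\\s*(\\S+).*$", "\\1", ln)
          else if (grepl("[^A-Za-z*\\s-]", ln))
            stop("record '", rec, "' contains characters outside the ",
                 "amino-acid alphabet", call. = FALSE)
        }
        stop("FASTA file '", path, "' contains invalid sequence characters",
             call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  if (length(set) == 0) stop("FASTA file '", path, "' contains no records",
                             call. = FALSE)
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  ids <- sub("\\s.*$", "", names(set))
  bad <- which(nchar(seqs) == 0)
  if (length(bad))
    stop("empty sequence for record '", ids[bad[1]], "'", call. = FALSE)
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", seqs)
  if (!all(ok))
    stop("record '", ids[which(!ok)[1]],
         "' contains characters outside the amino-acid alphabet", call. = FALSE)
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector or [Biostrings::AAStringSet]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeFasta <- function(seqs, path) {
  if (!is(seqs, "XStringSet")) seqs <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Parse a PDB file into a StructureModel
#'
#' All `ATOM` and `HETATM` records are captured with chain ids, residue
#' numbers/names, atom names and coordinates; every other record type is
#' ignored. Alternate locations are resolved by keeping the first conformer
#' (blank or `A`). Heteroatoms are kept in the atom table but excluded from
#' the chain index and from chain bounding boxes.
#'
#' @param path path to a PDB-format text file
#' @return a [StructureModel-class]
#' @export
parsePDB <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  isAtom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(isAtom))
    stop("no ATOM/HETATM records in PDB file '", path, "'", call. = FALSE)
  # locate unparseable coordinate fields up front so errors carry line numbers
  coordTxt <- substr(lines[isAtom], 31, 54)
  fields <- cbind(substr(coordTxt, 1, 8), substr(coordTxt, 9, 16),
                  substr(coordTxt, 17, 24))
  badRow <- which(apply(fields, 1, function(f)
    any(is.na(suppressWarnings(as.numeric(f))))))
  if (length(badRow))
    stop("unparseable coordinates at line ", which(isAtom)[badRow[1]],
         " of '", path, "'", call. = FALSE)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("failed to parse PDB file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  at <- pdb$atom
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep, , drop = FALSE]
  at$chain[is.na(at$chain)] <- ""
  atoms <- data.frame(type = at$type, chain = at$chain, resno = at$resno,
                      resid = at$resid, elety = at$elety,
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  new("StructureModel", atoms = atoms)
}

#' Write a StructureModel as PDB text
#'
#' Emits standard fixed-column `ATOM`/`HETATM` records followed by `END`.
#' Occupancy and B-factor are written as 1.00 and 0.00.
#'
#' @param model a [StructureModel-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writePDB <- function(model, path) {
  stopifnot(is(model, "StructureModel"))
  at <- model@atoms
  lines <- character(nrow(at))
  for (i in seq_len(nrow(at))) {
    rec <- if (at$type[i] == "HETATM") "HETATM" else "ATOM  "
    name <- at$elety[i]
    # atom-name column convention: 1-3 character names start in column 14
    name <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
    lines[i] <- sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                        rec, i, name, at$resid[i], at$chain[i], at$resno[i],
                        at$x[i], at$y[i], at$z[i], 1, 0,
                        substr(trimws(at$elety[i]), 1, 1))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Derive the docking search box from a bound peptide chain
#'
#' The box centre is the midpoint of the peptide chain's axis-aligned bounding
#' box; each edge is the bounding-box extent plus `2 * padding`, clamped to
#' `maxEdge` (with a warning) so the search space never exceeds the engine's
#' recommended maximum. Before clamping, the box geometrically contains every
#' peptide-chain atom.
#'
#' @param model a [StructureModel-class] holding receptor and bound peptide
#' @param chain chain identifier of the bound peptide
#' @param padding margin added on each side of the peptide bounding box
#'   (Angstrom; default 5)
#' @param maxEdge maximum allowed box edge length (Angstrom; default 30)
#' @return a [SearchBox-class]
#' @export
computeSearchBox <- function(model, chain, padding = 5, maxEdge = 30) {
  stopifnot(is(model, "StructureModel"), padding >= 0, maxEdge > 0)
  at <- model@atoms
  sel <- at$type == "ATOM" & at$chain == chain
  if (!any(at$chain == chain))
    stop("chain '", chain, "' not present in structure", call. = FALSE)
  if (!any(sel))
    stop("chain '", chain, "' has no standard ATOM records", call. = FALSE)
  xyz <- as.matrix(at[sel, c("x", "y", "z")])
  lo <- apply(xyz, 2, min)
  hi <- apply(xyz, 2, max)
  centre <- (lo + hi) / 2
  dims <- (hi - lo) + 2 * padding
  if (any(dims > maxEdge)) {
    warning(sprintf("search box clamped to maximum edge %g A on axis %s",
                    maxEdge,
                    paste(c("x", "y", "z")[dims > maxEdge], collapse = ",")))
    dims <- pmin(dims, maxEdge)
  }
  new("SearchBox", centre = unname(centre), dims = unname(dims))
}

#' Remove a chain from a structure
#'
#' Drops every atom (including heteroatoms) of the named chain, leaving all
#' other atoms untouched; used to strip the bound peptide so its binding site
#' is free for docking.
#'
#' @param model a [StructureModel-class]
#' @param chain chain identifier to remove
#' @return a [StructureModel-class] without the named chain
#' @export
stripChain <- function(model, chain) {
  stopifnot(is(model, "StructureModel"))
  at <- model@atoms
  if (!any(at$chain == chain))
    stop("chain '", chain, "' not present in structure", call. = FALSE)
  out <- at[at$chain != chain, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0)
    warning("stripping chain '", chain, "' leaves an empty structure")
  new("StructureModel", atoms = out)
}

#' Write a Vina-style box configuration
#'
#' Emits the `center_x`/.../`size_z` key-value block a docking engine adapter
#' consumes.
#'
#' @param box a [SearchBox-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeBoxConfig <- function(box, path) {
  stopifnot(is(box, "SearchBox"))
  keys <- c("center_x", "center_y", "center_z", "size_x", "size_y", "size_z")
  vals <- c(box@centre, box@dims)
  writeLines(sprintf("%s = %.3f", keys, vals), path)
  invisible(path)
}
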