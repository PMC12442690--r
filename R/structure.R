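#' @include AllClasses.R
NULL

#' Read a (multi-model) PDB file into a StructureEnsemble
#'
#' Parses ATOM/HETATM records, honouring MODEL/ENDMDL blocks; a file without
#' MODEL records yields a single-frame ensemble. Parsing is delegated to
#' \pkg{bio3d}; a validation pre-pass reports non-numeric coordinates with
#' their line numbers.
#'
#' @param path PDB file.
#' @return a [StructureEnsemble-class]; coordinates in Angstrom, residue
#'   numbering and insertion codes preserved in the atom table.
#' @export
readPdbEnsemble <- function(path) {
  lines <- readLines(path)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    flds <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
              substr(lines[i], 47, 54))
    if (anyNA(suppressWarnings(as.numeric(flds))))
      stop("non-numeric coordinate at line ", i, ": ", trimws(lines[i]))
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  element <- trimws(at$elesy)
  noel <- is.na(element) | element == ""
  # fall back on the first letter of the atom name (digits stripped)
  element[noel] <- substr(gsub("[0-9]", "", trimws(at$elety[noel])), 1, 1)
  atoms <- data.frame(name = trimws(at$elety), element = element,
                      resid = at$resno, resname = trimws(at$resid),
                      chain = ifelse(is.na(at$chain), "A", at$chain),
                      insert = ifelse(is.na(at$insert), "", at$insert),
                      stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  na <- nrow(atoms)
  coords <- array(NA_real_, c(na, 3, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  structureEnsemble(atoms, coords)
}

#' Write a StructureEnsemble as a multi-model PDB file
#'
#' @param ensemble a [StructureEnsemble-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writePdbEnsemble <- function(ensemble, path) {
  stopifnot(is(ensemble, "StructureEnsemble"))
  at <- ensemble@atoms
  nf <- dim(ensemble@coords)[3]
  con <- file(path, "w")
  on.exit(close(con))
  multi <- nf > 1
  for (f in seq_len(nf)) {
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    x <- ensemble@coords[, , f]
    nm <- at$name
    # PDB column-13 convention: 1-3 character names start in column 14
    nm4 <- ifelse(nchar(nm) >= 4, substr(nm, 1, 4), sprintf(" %-3s", nm))
    writeLines(sprintf(
      "ATOM  %5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(at)), nm4, substr(at$resname, 1, 3),
      substr(at$chain, 1, 1), at$resid,
      if (!is.null(at$insert)) substr(paste0(at$insert, " "), 1, 1) else " ",
      x[, 1], x[, 2], x[, 3], at$element), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Atom selections
#'
#' \code{caIndices} returns the alpha-carbon indices, \code{heavyIndices}
#' all non-hydrogen atoms, and \code{amideGroups} the backbone amide N/H
#' pairs (one row per residue possessing both atoms).
#'
#' @param ensemble a [StructureEnsemble-class].
#' @return integer vector of atom indices, or for \code{amideGroups} a
#'   data.frame with columns \code{resid}, \code{resname}, \code{n}, \code{h}
#'   (atom indices).
#' @export
caIndices <- function(ensemble) {
  which(ensemble@atoms$name == "CA" & ensemble@atoms$element != "H")
}

#' @rdname caIndices
#' @export
heavyIndices <- function(ensemble) {
  which(!(ensemble@atoms$element %in% c("H", "D")))
}

#' @rdname caIndices
#' @export
amideGroups <- function(ensemble) {
  at <- ensemble@atoms
  out <- list()
  for (r in unique(at$resid)) {
    rows <- which(at$resid == r)
    n <- rows[at$name[rows] == "N"]
    h <- rows[at$name[rows] %in% c("H", "HN", "HT1", "H1")]
    if (length(n) == 1 && length(h) >= 1)
      out[[length(out) + 1]] <- data.frame(resid = r,
                                           resname = at$resname[n],
                                           n = n, h = h[1])
  }
  if (!length(out)) return(data.frame(resid = integer(), resname = character(),
                                      n = integer(), h = integer()))
  do.call(rbind, out)
}

.ring_defs <- list(
  PHE = list(list(label = "6-ring",
                  atoms = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"))),
  TYR = list(list(label = "6-ring",
                  atoms = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"))),
  HIS = list(list(label = "5-ring",
                  atoms = c("CG", "ND1", "CD2", "CE1", "NE2"))),
  TRP = list(list(label = "5-ring",
                  atoms = c("CG", "CD1", "NE1", "CE2", "CD2")),
             list(label = "6-ring",
                  atoms = c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"))))

#' Aromatic ring specifications for one frame
#'
#' Builds ring descriptors (member atoms, center of mass, unit normal from
#' the smallest singular vector of the centred member coordinates) for Phe
#' and Tyr 6-rings, His 5-rings, and both Trp rings, which are evaluated
#' independently.
#'
#' @param ensemble a [StructureEnsemble-class].
#' @param frame frame index.
#' @param includeHis include histidine rings (default TRUE).
#' @return list of ring specs: \code{resid}, \code{resname}, \code{label},
#'   \code{members} (atom indices), \code{com}, \code{normal},
#'   \code{planarity_rms}.
#' @export
buildRings <- function(ensemble, frame = 1, includeHis = TRUE) {
  at <- ensemble@atoms
  x <- getFrame(ensemble, frame)
  rings <- list()
  for (r in unique(at$resid)) {
    rows <- which(at$resid == r)
    rn <- at$resname[rows[1]]
    defs <- .ring_defs[[rn]]
    if (is.null(defs)) next
    if (!includeHis && rn == "HIS") next
    for (d in defs) {
      m <- rows[match(d$atoms, at$name[rows])]
      if (anyNA(m)) next
      xm <- x[m, , drop = FALSE]
      com <- colMeans(xm)
      xc <- sweep(xm, 2, com)
      sv <- svd(xc)
      normal <- sv$v[, 3]
      normal <- normal / sqrt(sum(normal^2))
      rings[[length(rings) + 1]] <- list(
        resid = r, resname = rn, label = d$label, members = m, com = com,
        normal = normal, planarity_rms = sqrt(mean((xc %*% normal)^2)))
    }
  }
  rings
}
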