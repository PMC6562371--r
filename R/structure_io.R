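#' Convert a three-letter residue name to its one-letter code
#'
#' @param resname Character vector of three-letter residue names (case
#'   insensitive).
#' @param synonyms Named character vector of extra accepted names mapped to
#'   one-letter codes, e.g. `c(MSE = "M")` for selenomethionine.
#' @return Character vector of one-letter codes.
#' @examples
#' three_to_one(c("GLY", "TRP"))
#' @export
three_to_one <- function(resname, synonyms = c(MSE = "M")) {
  resname <- toupper(resname)
  map <- c(AA_THREE, synonyms)
  out <- unname(map[resname])
  if (anyNA(out)) {
    bad <- unique(resname[is.na(out)])
    stop("unknown residue name(s): ", paste(bad, collapse = ", "))
  }
  out
}

#' Construct a C-alpha structure object
#'
#' One site per residue: author-numbered position, one-letter amino acid and
#' the C-alpha coordinate in Angstrom. An optional per-position secondary
#' structure map (`helix`, `strand`, `coil`) travels with the object.
#'
#' @param position Integer vector of residue numbers, strictly increasing.
#' @param aa Character vector of one-letter amino acid codes.
#' @param xyz Numeric matrix, one row per site, columns x, y, z (Angstrom).
#' @param chain Single chain identifier.
#' @param secondary Optional character vector (same length as `position`, or
#'   named by position) with values `helix`, `strand` or `coil`.
#' @return An object of class `calpha_structure`.
#' @export
calpha_structure <- function(position, aa, xyz, chain = "A", secondary = NULL) {
  position <- as.integer(position)
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  n <- length(position)
  if (length(aa) != n || nrow(xyz) != n || ncol(xyz) != 3)
    stop("position, aa and xyz rows must agree (3 coordinate columns)")
  if (n && any(diff(position) <= 0))
    stop("residue positions must be strictly increasing")
  if (!all(aa %in% AA20))
    stop("non-standard amino acid code(s): ",
         paste(unique(aa[!aa %in% AA20]), collapse = ", "))
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  if (!is.null(secondary)) {
    if (is.null(names(secondary))) {
      if (length(secondary) != n)
        stop("secondary must be named by position or match the site count")
      names(secondary) <- position
    }
    bad <- setdiff(unique(secondary), c("helix", "strand", "coil"))
    if (length(bad))
      stop("secondary classes must be helix/strand/coil, got: ",
           paste(bad, collapse = ", "))
    secondary <- secondary[as.character(position)]
    secondary[is.na(secondary)] <- "coil"
    names(secondary) <- position
  } else {
    secondary <- setNames(rep("coil", n), position)
  }
  dimnames(xyz) <- list(position, c("x", "y", "z"))
  structure(
    list(position = position, aa = aa, xyz = xyz, chain = chain,
         secondary = secondary),
    class = "calpha_structure")
}

#' @export
print.calpha_structure <- function(x, ...) {
  cat(sprintf("C-alpha structure: %d residues, chain %s, positions %d-%d\n",
              length(x$position), x$chain,
              min(x$position), max(x$position)))
  invisible(x)
}

#' @export
length.calpha_structure <- function(x) length(x$position)

#' Read the C-alpha model of one chain from a PDB file
#'
#' Parses ATOM records (first model only) of the requested chain, resolves
#' alternate locations by highest occupancy (ties broken by altloc
#' identifier), and populates the secondary-structure map from HELIX/SHEET
#' header records (everything else is `coil`).
#'
#' @param pdb Path to a PDB file, or PDB-format text (a single string with
#'   newlines or a character vector of lines).
#' @param chain Chain identifier to extract.
#' @param range Optional inclusive residue-number interval `c(lo, hi)`;
#'   default keeps every residue of the chain.
#' @param synonyms Non-standard residue-name synonyms, see [three_to_one()].
#' @param secondary Optional named character vector overriding the
#'   header-derived secondary-structure assignment.
#' @return A [calpha_structure()] object. A residue inside `range` that has
#'   atoms but no C-alpha is an error (no silent skipping); insertion codes
#'   are rejected.
#' @export
read_calpha_structure <- function(pdb, chain = "A", range = NULL,
                                  synonyms = c(MSE = "M"), secondary = NULL) {
  path <- pdb
  if (length(pdb) > 1L || grepl("\n", pdb[1]) || !file.exists(pdb[1])) {
    path <- tempfile(fileext = ".pdb")
    writeLines(unlist(strsplit(pdb, "\n", fixed = TRUE)), path)
    on.exit(unlink(path))
  }
  p <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- p$atom[p$atom$type == "ATOM", , drop = FALSE]
  at <- at[!is.na(at$chain) & at$chain == chain, , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records for chain '", chain, "'")
  if (any(!is.na(at$insert) & at$insert != ""))
    stop("insertion codes present in chain '", chain,
         "'; renumber the structure first")
  if (!is.null(range)) {
    if (length(range) != 2L || range[2] < range[1])
      stop("range must be an inclusive interval c(lo, hi)")
    at <- at[at$resno >= range[1] & at$resno <= range[2], , drop = FALSE]
    if (!nrow(at)) stop("no residues of chain '", chain, "' in range ",
                        range[1], ":", range[2])
  }
  resnos <- sort(unique(at$resno))
  ca <- at[at$elety == "CA", , drop = FALSE]
  missing_ca <- setdiff(resnos, unique(ca$resno))
  if (length(missing_ca))
    stop("residue(s) without a C-alpha atom at position(s): ",
         paste(missing_ca, collapse = ", "))
  # altloc: highest occupancy wins, ties by altloc identifier order
  pick <- unlist(lapply(split(seq_len(nrow(ca)), ca$resno), function(idx) {
    if (length(idx) == 1L) return(idx)
    o <- ca$o[idx]
    o[is.na(o)] <- 1
    alt <- ca$alt[idx]
    alt[is.na(alt)] <- ""
    idx[order(-o, alt)][1]
  }))
  ca <- ca[pick, , drop = FALSE]
  ca <- ca[order(ca$resno), , drop = FALSE]

  sec <- NULL
  if (!is.null(secondary)) {
    sec <- secondary
  } else {
    sec <- setNames(rep("coil", length(resnos)), resnos)
    mark <- function(tab, label) {
      if (is.null(tab) || !length(tab$start)) return()
      keep <- which(tab$chain == chain)
      for (k in keep) {
        span <- seq(tab$start[k], tab$end[k])
        sec[as.character(intersect(span, resnos))] <<- label
      }
    }
    mark(p$helix, "helix")
    mark(p$sheet, "strand")
  }
  calpha_structure(
    position = ca$resno,
    aa = three_to_one(ca$resid, synonyms = synonyms),
    xyz = cbind(ca$x, ca$y, ca$z),
    chain = chain,
    secondary = sec)
}

#' Write a C-alpha structure as minimal PDB text
#'
#' Emits one ATOM record per site (CA only, 3-decimal coordinates), suitable
#' for round-tripping through [read_calpha_structure()].
#'
#' @param x A [calpha_structure()] object.
#' @param file Optional path; when `NULL` the PDB text is returned invisibly
#'   as a character vector of lines.
#' @return The PDB lines, invisibly.
#' @export
write_calpha_pdb <- function(x, file = NULL) {
  stopifnot(inherits(x, "calpha_structure"))
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_along(x$position), AA_ONE_TO_THREE[x$aa], x$chain, x$position,
    x$xyz[, 1], x$xyz[, 2], x$xyz[, 3])
  lines <- c(lines, "END")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
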