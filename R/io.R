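#' Expand run-length HP notation
#'
#' Benchmark HP sequences are conventionally written with repeat counts
#' attached to the letters (subscripts in print).  Accepted token
#' syntaxes: \code{"H4"}, \code{"H_4_"} and \code{"H^4"}; a missing count
#' means 1.  Whitespace is ignored.
#'
#' @param compressed run-length string over \code{H}/\code{P}.
#' @return the expanded sequence string.
#' @examples
#' expandHPString("H4P")    # "HHHHP"
#' expandHPString("H2P3H")  # "HHPPPH"
#' @export
expandHPString <- function(compressed) {
  s <- gsub("[[:space:]]", "", compressed)
  if (!nzchar(s)) stop("empty HP string")
  pat <- "([HP])(?:_([0-9]+)_|\\^([0-9]+)|([0-9]+))?"
  m <- gregexpr(pat, s, perl = TRUE)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(s)) {
    stop("malformed HP run-length string: ", compressed)
  }
  expanded <- vapply(toks, function(tk) {
    letter <- substr(tk, 1L, 1L)
    count <- gsub("[^0-9]", "", substr(tk, 2L, nchar(tk)))
    k <- if (nzchar(count)) as.integer(count) else 1L
    if (k < 1L) stop("repeat count must be positive in token: ", tk)
    strrep(letter, k)
  }, character(1))
  paste(expanded, collapse = "")
}

#' Bundled benchmark HP sequences
#'
#' The classic benchmark set: the ten 48-residue Harvard instances
#' (24 hydrophobic residues each), the 24-residue first half of instance
#' 9, and four longer sequences of 90 to 200 residues.  Each entry records
#' the run-length notation together with the published chain length and
#' hydrophobic count, and the loader treats the (length, H-count) pair as
#' ground truth: every sequence is expanded and checked against it, and
#' entries whose run-length string could not be recovered in full (true of
#' several longer entries in the bundled table) are refused with a
#' warning rather than returned corrupted.
#'
#' @param validate drop entries failing the length/H-count check
#'   (default); \code{validate = FALSE} returns every row un-expanded for
#'   inspection.
#' @return a data frame with columns \code{id}, \code{compressed},
#'   \code{sequence}, \code{length}, \code{n_hydrophobic}, \code{note}.
#' @examples
#' b <- loadBenchmarks()
#' subset(b, id == "HI 4")$length  # 48
#' @export
loadBenchmarks <- function(validate = TRUE) {
  path <- system.file("extdata", "benchmarks.csv", package = "latticeFold",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!validate) return(tab)
  tab$sequence <- vapply(tab$compressed, expandHPString, character(1),
                         USE.NAMES = FALSE)
  ok <- nchar(tab$sequence) == tab$length &
    vapply(tab$sequence, function(s) {
      sum(strsplit(s, "", fixed = TRUE)[[1]] == "H")
    }, numeric(1)) == tab$n_hydrophobic
  if (any(!ok)) {
    warning("refusing benchmark entries failing the length/H-count check: ",
            paste(tab$id[!ok], collapse = ", "))
  }
  tab <- tab[ok, c("id", "compressed", "sequence", "length",
                   "n_hydrophobic", "note")]
  rownames(tab) <- NULL
  tab
}

#' Fetch one benchmark sequence
#'
#' @param id entry identifier, e.g. \code{"HI 4"} or \code{"HI 9/2"}.
#' @return the expanded sequence string.
#' @export
benchmarkSequence <- function(id) {
  tab <- loadBenchmarks()
  row <- tab[tab$id == id, ]
  if (!nrow(row)) stop("no validated benchmark entry named '", id, "'")
  row$sequence[[1L]]
}

#' Read and write conformation files
#'
#' Conformations are serialised as JSON:
#' \code{\{"lattice": \{"kind", "dim"\}, "sequence", "coords": [[...], ...]\}}
#' with integer lattice coordinates, one row per residue.  The round trip
#' is exact.  Reading a conformation that is not a self-avoiding walk
#' raises a warning (not an error), so candidate or hand-edited
#' conformations can still be inspected.
#'
#' @param path file path.
#' @return \code{readConformation}: a \code{\linkS4class{LatticeProtein}};
#'   \code{writeConformation}: the path, invisibly.
#' @export
readConformation <- function(path) {
  x <- jsonlite::fromJSON(path)
  if (is.null(x$lattice$kind) || is.null(x$lattice$dim) ||
      is.null(x$sequence) || is.null(x$coords)) {
    stop("conformation file must provide lattice{kind,dim}, sequence, coords")
  }
  lattice <- Lattice(x$lattice$kind, x$lattice$dim)
  coords <- matrix(as.numeric(x$coords), ncol = ncol(x$coords))
  if (ncol(coords) != lattice@dim) {
    stop("coordinate dimension does not match the declared lattice")
  }
  model <- LatticeProtein(x$sequence, lattice, coords = coords)
  if (!isSelfAvoiding(model)) {
    warning("conformation in ", path, " is not a self-avoiding walk")
  }
  model
}

#' @rdname readConformation
#' @param model a \code{\linkS4class{LatticeProtein}}.
#' @export
writeConformation <- function(model, path) {
  x <- list(
    lattice = list(kind = model@lattice@kind, dim = model@lattice@dim),
    sequence = model@sequence,
    coords = unname(apply(model@coords, 1L, function(r) as.integer(r),
                          simplify = FALSE)))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read 3-D coordinates for radial profiles
#'
#' Accepts either a whitespace-separated x y z table or a PDB file (the
#' PDB reader is delegated to \pkg{bio3d}; only C-alpha atoms are kept),
#' returning the coordinate matrix expected by
#' \code{\link{radialNeighborProfile}}.
#'
#' @param path input file.
#' @param format \code{"auto"} (by extension), \code{"table"} or
#'   \code{"pdb"}.
#' @return numeric matrix with columns x, y, z (Angstroms).
#' @export
readCAlphaCoords <- function(path, format = c("auto", "table", "pdb")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(pdb|ent)$", path, ignore.case = TRUE)) "pdb"
              else "table"
  }
  if (format == "pdb") {
    if (!requireNamespace("bio3d", quietly = TRUE)) {
      stop("reading PDB files requires the bio3d package")
    }
    pdb <- bio3d::read.pdb(path)
    sel <- bio3d::atom.select(pdb, elety = "CA", verbose = FALSE)
    m <- matrix(pdb$xyz[sel$xyz], ncol = 3L, byrow = TRUE)
  } else {
    tab <- utils::read.table(path)
    if (ncol(tab) < 3L) stop("coordinate table needs three columns")
    m <- as.matrix(tab[, 1:3])
  }
  colnames(m) <- c("x", "y", "z")
  m
}

#' Project a high-dimensional conformation to 3-D
#'
#' For lattices in dimension greater than 3 a conformation can be drawn
#' only after projecting it: the Cartesian coordinates (optionally rotated
#' first, e.g. slightly, to separate vertices that would superpose) are
#' restricted to three chosen axes — an orthogonal projection.  Distinct
#' lattice vertices may legitimately map to the same 3-D point.
#'
#' @param model a \code{\linkS4class{LatticeProtein}} on a lattice of
#'   dimension at least 3.
#' @param axes three distinct axis indices (default the first three).
#' @param preRotation optional \code{\linkS4class{Rotation}} applied
#'   before projecting.
#' @return an \eqn{N \times 3} matrix of 3-D coordinates.
#' @export
project3D <- function(model, axes = c(1L, 2L, 3L), preRotation = NULL) {
  n <- model@lattice@dim
  if (n < 3L) stop("projection needs a lattice of dimension >= 3")
  axes <- as.integer(axes)
  if (length(axes) != 3L || anyDuplicated(axes) ||
      any(axes < 1L | axes > n)) {
    stop("axes must be three distinct indices within the lattice dimension")
  }
  cart <- .toCartesianMatrix(model@lattice, model@coords)
  if (!is.null(preRotation)) {
    cart <- cart %*% t(preRotation@cartesian)
  }
  cart[, axes, drop = FALSE]
}
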