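#' Parametric square and triangular lattices
#'
#' A \code{Lattice} describes the regular lattice a protein model lives on:
#' its kind (\code{"square"} or \code{"triangular"}), its dimension \eqn{n},
#' the basis matrix \eqn{B} whose columns are the primitive vectors
#' (Cartesian, unit edge length), and the ordered set of \emph{main
#' directions} \eqn{D}: the integer lattice vectors joining any vertex to
#' each of its neighbours.  The coordination number \eqn{c = |D|} is
#' \eqn{2n} for square lattices and \eqn{n(n+1)} for triangular ones, so the
#' planar square, cubic, planar triangular and FCC lattices come out with
#' the familiar values 4, 6, 6 and 12.
#'
#' All lattice vertices are addressed by their integer coordinates in the
#' basis \eqn{B}; Cartesian positions are only ever needed for geometry
#' (edge lengths, rotations, projections) and are obtained with
#' \code{\link{toCartesian}}.
#'
#' @slot kind character, \code{"square"} or \code{"triangular"}.
#' @slot dim integer, lattice dimension \eqn{n} (\eqn{\ge 1}; \eqn{\ge 2}
#'   for triangular lattices).
#' @slot basis \eqn{n \times n} numeric matrix whose columns are the
#'   primitive vectors; every edge has Cartesian length 1.
#' @slot mainDirs integer matrix with one main direction per row, sorted
#'   lexicographically; closed under negation and free of the zero vector.
#' @slot coordNumber integer, the coordination number \eqn{|D|}.
#' @slot edgeThreshold numeric, the Euclidean distance defining an edge
#'   (fixed at 1, the minimum yielding connectivity).
#'
#' @name Lattice-class
#' @aliases Lattice-class
#' @exportClass Lattice
setClass("Lattice",
  representation(
    kind = "character",
    dim = "integer",
    basis = "matrix",
    mainDirs = "matrix",
    coordNumber = "integer",
    edgeThreshold = "numeric"
  )
)

setValidity("Lattice", function(object) {
  msg <- character()
  n <- object@dim
  if (!object@kind %in% c("square", "triangular")) {
    msg <- c(msg, "kind must be 'square' or 'triangular'")
  }
  if (n < 1L) msg <- c(msg, "dim must be >= 1")
  if (object@kind == "triangular" && n < 2L) {
    msg <- c(msg, "triangular lattices need dim >= 2")
  }
  D <- object@mainDirs
  if (nrow(D) != object@coordNumber) {
    msg <- c(msg, "coordNumber must equal the number of main directions")
  }
  expected <- if (object@kind == "square") 2L * n else n * (n + 1L)
  if (object@coordNumber != expected) {
    msg <- c(msg, sprintf("coordination number should be %d", expected))
  }
  # every main direction is a unit Cartesian vector and D is closed under
  # negation with no zero vector
  lens <- sqrt(rowSums((D %*% t(object@basis))^2))
  if (any(abs(lens - object@edgeThreshold) > 1e-9)) {
    msg <- c(msg, "all main directions must map to unit Cartesian vectors")
  }
  if (any(rowSums(abs(D)) == 0)) msg <- c(msg, "zero vector in main directions")
  keyed <- .packCoords(D)
  if (anyDuplicated(keyed)) msg <- c(msg, "duplicate main directions")
  if (!all(.packCoords(-D) %in% keyed)) {
    msg <- c(msg, "main directions must be closed under negation")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a lattice
#'
#' Builds the \code{\linkS4class{Lattice}} object for the given kind and
#' dimension, computing the basis matrix and the lexicographically sorted
#' main-direction list.
#'
#' @param kind \code{"square"} or \code{"triangular"}.  The triangular
#'   family generalises the planar triangular lattice; in three dimensions
#'   it is the FCC lattice.
#' @param dim lattice dimension (>= 1 for square, >= 2 for triangular).
#' @return A \code{\linkS4class{Lattice}}.
#' @examples
#' Lattice("square", 2)            # coordination number 4
#' Lattice("triangular", 3)        # FCC, coordination number 12
#' @export
Lattice <- function(kind = c("square", "triangular"), dim) {
  kind <- match.arg(kind)
  if (!is.numeric(dim) || length(dim) != 1L || dim != round(dim)) {
    stop("dim must be a single integer")
  }
  dim <- as.integer(dim)
  if (dim < 1L) stop("dim must be >= 1")
  if (kind == "triangular" && dim < 2L) {
    stop("triangular lattices are defined for dim >= 2")
  }
  B <- basisMatrix(kind, dim)
  D <- .mainDirectionSet(kind, dim)
  new("Lattice",
      kind = kind, dim = dim, basis = B, mainDirs = D,
      coordNumber = nrow(D), edgeThreshold = 1)
}

#' Basis matrix of a lattice
#'
#' For square lattices the basis is the standard one (the identity).  The
#' triangular basis is built iteratively: the \eqn{n}-dimensional basis
#' embeds the \eqn{(n-1)}-dimensional one (zero-padded) and appends a new
#' unit column whose inner product with every previous column is 1/2, the
#' sign ambiguity being fixed by requiring its last component positive.
#' The resulting Gram matrix \eqn{B^\top B} has unit diagonal and all
#' off-diagonal entries equal to 1/2 (equal edge lengths, equal angles).
#'
#' @inheritParams Lattice
#' @return An \eqn{n \times n} numeric matrix with the primitive vectors as
#'   columns.
#' @examples
#' basisMatrix("triangular", 2)  # columns (1, 0) and (1/2, sqrt(3)/2)
#' @export
basisMatrix <- function(kind = c("square", "triangular"), dim) {
  kind <- match.arg(kind)
  dim <- as.integer(dim)
  if (dim < 1L || (kind == "triangular" && dim < 2L)) {
    stop("dim out of range for this lattice kind")
  }
  if (kind == "square") return(diag(dim))
  B <- matrix(1, 1L, 1L)
  for (k in 2:dim) {
    # first k-1 components of the new column: solve B[1:(k-1),]^T x = 1/2
    x <- solve(t(B), rep(0.5, k - 1L))
    last <- sqrt(1 - sum(x^2))
    B <- rbind(cbind(B, x), c(rep(0, k - 1L), last))
  }
  dimnames(B) <- NULL
  B
}

# Integer main-direction set, sorted lexicographically.
.mainDirectionSet <- function(kind, n) {
  if (kind == "square" && n == 1L) {
    D <- matrix(c(1, -1), ncol = 1L)
  } else if (kind == "square") {
    D <- rbind(diag(n), -diag(n))
  } else {
    D <- rbind(diag(n), -diag(n))
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        v <- numeric(n); v[i] <- 1; v[j] <- -1
        D <- rbind(D, v, -v)
      }
    }
  }
  D <- matrix(as.numeric(D), nrow = nrow(D))
  ord <- do.call(order, lapply(seq_len(ncol(D)), function(j) D[, j]))
  unname(D[ord, , drop = FALSE])
}

#' @describeIn Lattice-class ordered main-direction list (one integer vector
#'   per row, lexicographic order).
#' @param lattice a \code{\linkS4class{Lattice}}.
#' @export
mainDirections <- function(lattice) lattice@mainDirs

#' @describeIn Lattice-class coordination number \eqn{c = |D|}.
#' @export
coordinationNumber <- function(lattice) lattice@coordNumber

#' @describeIn Lattice-class lattice kind.
#' @export
latticeKind <- function(lattice) lattice@kind

#' @describeIn Lattice-class lattice dimension.
#' @export
latticeDim <- function(lattice) lattice@dim

#' Adjacency of two lattice vertices
#'
#' Two vertices are adjacent when their difference is a main direction,
#' equivalently when the Cartesian distance between them is 1.  The test is
#' carried out arithmetically (hop distance equal to one), which coincides
#' with membership of \eqn{q - p} in \eqn{D} for both lattice families.
#'
#' @param lattice a \code{\linkS4class{Lattice}}.
#' @param p,q integer coordinate vectors of length \code{latticeDim(lattice)}.
#' @return \code{TRUE} when \code{q - p} is a main direction.
#' @export
isAdjacent <- function(lattice, p, q) {
  n <- lattice@dim
  p <- .checkVector(p, n, "p"); q <- .checkVector(q, n, "q")
  .hopFromDelta(lattice, q - p) == 1L
}

#' Euclidean distance between lattice vertices
#'
#' Computed through the basis matrix as \eqn{\|B (q - p)\|}; adjacent
#' vertices are at distance 1 by construction.
#'
#' @inheritParams isAdjacent
#' @return a non-negative number.
#' @export
euclideanDistance <- function(lattice, p, q) {
  n <- lattice@dim
  p <- .checkVector(p, n, "p"); q <- .checkVector(q, n, "q")
  sqrt(sum((lattice@basis %*% (q - p))^2))
}

# Hop distance from a coordinate difference.  Square lattices: Manhattan
# distance.  Triangular lattices: with steps +/- e_i and +/- (e_i - e_j),
# every step changes the running positive-part sum by at most 1 and the
# negative-part sum by at most 1, and a step e_i - e_j reduces both at
# once, so the minimum number of hops is max(sum of positive components,
# sum of negative components).  In two dimensions this equals the sum of
# the two smallest of |d1|, |d2|, |d1 + d2|; the equivalence (and the BFS
# ground truth) is exercised in the tests.
.hopFromDelta <- function(lattice, delta) {
  if (lattice@kind == "square") {
    as.integer(sum(abs(delta)))
  } else {
    as.integer(max(sum(pmax(delta, 0)), sum(pmax(-delta, 0))))
  }
}

# Vectorised hop distances from the point p to every row of M.
.hopRows <- function(lattice, M, p) {
  delta <- .addPoint(M, -p)
  if (lattice@kind == "square") {
    rowSums(abs(delta))
  } else {
    pmax(rowSums(pmax(delta, 0)), rowSums(pmax(-delta, 0)))
  }
}

# Vectorised adjacency of every row of M to the point p.
.adjacentRows <- function(lattice, M, p) {
  .hopRows(lattice, M, p) == 1
}

#' Hop distance (lattice shortest path)
#'
#' The minimum number of hops across adjacent vertices needed to go from
#' \code{p} to \code{q}.  On square lattices this is the classical
#' Manhattan distance \eqn{\sum_i |\Delta_i|}.  On triangular lattices the
#' step set \eqn{\pm e_i, \pm(e_i - e_j)} admits the closed form
#' \eqn{\max(\sum_i \max(\Delta_i, 0), \sum_i \max(-\Delta_i, 0))}, exact in
#' every dimension; for \eqn{n = 2} it reduces to the sum of the two
#' smallest of \eqn{|\Delta_1|, |\Delta_2|, |\Delta_1 + \Delta_2|}.
#'
#' @inheritParams isAdjacent
#' @return a non-negative integer.
#' @examples
#' sq3 <- Lattice("square", 3)
#' hopDistance(sq3, c(0, 0, 0), c(1, 2, 3))  # 6
#' tr2 <- Lattice("triangular", 2)
#' hopDistance(tr2, c(0, 0), c(2, -1))       # 2
#' @export
hopDistance <- function(lattice, p, q) {
  n <- lattice@dim
  p <- .checkVector(p, n, "p"); q <- .checkVector(q, n, "q")
  .hopFromDelta(lattice, q - p)
}

#' Cartesian coordinates of a lattice vertex
#'
#' @inheritParams isAdjacent
#' @return the numeric vector \eqn{B p}.
#' @export
toCartesian <- function(lattice, p) {
  n <- lattice@dim
  p <- .checkVector(p, n, "p")
  drop(lattice@basis %*% p)
}

# Cartesian coordinates for a whole coordinate matrix (rows = vertices).
.toCartesianMatrix <- function(lattice, m) {
  m %*% t(lattice@basis)
}

setMethod("show", "Lattice", function(object) {
  cat(sprintf("%s lattice in dimension %d (coordination number %d)\n",
              object@kind, object@dim, object@coordNumber))
  cat("basis matrix (columns = primitive vectors):\n")
  print(round(object@basis, 4))
  invisible(object)
})

#' Integer rotation generating the planar triangular directions
#'
#' The counterclockwise 60-degree rotation of the two-dimensional
#' triangular lattice, expressed in lattice coordinates, where it is an
#' integer matrix.  Repeated application to \eqn{(1, 0)} enumerates the six
#' main directions; it is kept as a documented constant so tests can
#' cross-validate the rotational construction of \eqn{D} against the
#' difference-of-basis-vectors one.
#'
#' @format a 2 x 2 integer matrix.
#' @export
triangularRotation2D <- matrix(c(0L, 1L, -1L, 1L), nrow = 2L)
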