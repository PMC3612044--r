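#' Protein conformations as self-avoiding walks
#'
#' A \code{LatticeProtein} binds an HP-style residue sequence to a
#' \code{\linkS4class{Lattice}} and an absolute-encoding conformation: an
#' ordered list of integer lattice coordinates, residue \eqn{i} at row
#' \eqn{i} (1-based).  Builders anchor the first residue at the origin; a
#' valid conformation is a self-avoiding walk (consecutive residues on
#' adjacent vertices, no vertex used twice), checked with
#' \code{\link{isSelfAvoiding}} rather than enforced by the class, so that
#' candidate conformations produced by moves can be represented before
#' being accepted.
#'
#' An optimizer object (see \code{\link{CgOptimizer}},
#' \code{\link{SaOptimizer}}) can be attached to the model and triggered
#' with \code{\link{foldit}}.
#'
#' @slot sequence character scalar over the residue alphabet (typically
#'   \code{H}/\code{P}).
#' @slot lattice the supporting \code{\linkS4class{Lattice}}.
#' @slot coords numeric matrix (integer-valued), one residue per row.
#' @slot optimizer an optimizer object or \code{NULL}.
#'
#' @name LatticeProtein-class
#' @aliases LatticeProtein-class
#' @exportClass LatticeProtein
setClass("LatticeProtein",
  representation(
    sequence = "character",
    lattice = "Lattice",
    coords = "matrix",
    optimizer = "ANY"
  ),
  prototype(optimizer = NULL)
)

setValidity("LatticeProtein", function(object) {
  msg <- character()
  N <- nchar(object@sequence)
  if (length(object@sequence) != 1L || N < 1L) {
    msg <- c(msg, "sequence must be a single non-empty string")
  }
  if (nrow(object@coords) != N) {
    msg <- c(msg, "coords must have one row per residue")
  }
  if (ncol(object@coords) != object@lattice@dim) {
    msg <- c(msg, "coords dimension must match the lattice dimension")
  }
  if (!.isWholeNumber(object@coords)) {
    msg <- c(msg, "coords must be integer-valued")
  }
  if (length(msg)) msg else TRUE
})

#' Create a lattice protein model
#'
#' @param sequence residue string (e.g. \code{"HPHPPH"}).
#' @param lattice a \code{\linkS4class{Lattice}}.
#' @param coords integer coordinate matrix, one residue per row; defaults
#'   to a seeded random self-avoiding walk (the default build-up), see
#'   \code{\link{randomWalkBuild}}.
#' @param build initial-configuration builder used when \code{coords} is
#'   missing: \code{"random"} (random self-avoiding walk) or
#'   \code{"linear"} (straight chain along the first main direction).
#' @param seed optional integer seed for the random builder.
#' @return a \code{\linkS4class{LatticeProtein}}.
#' @examples
#' sq2 <- Lattice("square", 2)
#' m <- LatticeProtein("HPPH", sq2, build = "linear")
#' coords(m)
#' @export
LatticeProtein <- function(sequence, lattice, coords = NULL,
                           build = c("random", "linear"), seed = NULL) {
  build <- match.arg(build)
  if (is.null(coords)) {
    m <- if (build == "linear") linearBuild(lattice, sequence)
         else randomWalkBuild(lattice, sequence, seed = seed)
    return(m)
  }
  coords <- round(as.matrix(coords))
  new("LatticeProtein", sequence = sequence, lattice = lattice,
      coords = unname(coords), optimizer = NULL)
}

#' @describeIn LatticeProtein-class residue sequence.
#' @param model a \code{\linkS4class{LatticeProtein}}.
#' @export
hpSequence <- function(model) model@sequence

#' @describeIn LatticeProtein-class coordinate matrix (absolute encoding).
#' @export
coords <- function(model) model@coords

#' @describeIn LatticeProtein-class supporting lattice.
#' @export
modelLattice <- function(model) model@lattice

.residues <- function(model) strsplit(model@sequence, "", fixed = TRUE)[[1]]

# Internal fast path: callers guarantee a well-formed coordinate matrix
# (same shape, integer-valued), so the validity re-check is skipped.
.replaceCoords <- function(model, coords) {
  slot(model, "coords", check = FALSE) <- unname(coords)
  model
}

setMethod("show", "LatticeProtein", function(object) {
  N <- nrow(object@coords)
  cat(sprintf("LatticeProtein: %d residues on a %s lattice (dim %d)\n",
              N, object@lattice@kind, object@lattice@dim))
  s <- object@sequence
  cat(sprintf("sequence: %s\n",
              if (nchar(s) > 60) paste0(substr(s, 1, 57), "...") else s))
  cat(sprintf("self-avoiding: %s\n", isSelfAvoiding(object)))
  if (!is.null(object@optimizer)) {
    cat(sprintf("attached optimizer: %s\n", class(object@optimizer)))
  }
  invisible(object)
})

#' Differential encoding of a conformation
#'
#' The sequence of \eqn{N - 1} steps between consecutive residues; for a
#' valid walk every step is a main direction.  The differential encoding is
#' translation-insensitive and \code{\link{fromDifferential}} inverts it
#' exactly on origin-anchored models.
#'
#' @param model a \code{\linkS4class{LatticeProtein}}.
#' @return an \eqn{(N-1) \times n} matrix of steps (empty for a single
#'   residue).
#' @export
toDifferential <- function(model) {
  m <- model@coords
  N <- nrow(m)
  if (N < 2L) return(m[0L, , drop = FALSE])
  m[-1L, , drop = FALSE] - m[-N, , drop = FALSE]
}

#' Rebuild a conformation from steps
#'
#' Anchors the first residue at the origin and accumulates the steps.  No
#' self-avoidance validation is performed (use
#' \code{\link{isSelfAvoiding}}), so arbitrary step lists can be inspected.
#'
#' @param lattice a \code{\linkS4class{Lattice}}.
#' @param sequence residue string of length \code{nrow(steps) + 1}.
#' @param steps matrix of integer step vectors, one per row (possibly with
#'   zero rows for a single residue).
#' @return a \code{\linkS4class{LatticeProtein}}.
#' @export
fromDifferential <- function(lattice, sequence, steps) {
  n <- lattice@dim
  steps <- as.matrix(steps)
  if (length(steps) == 0L) steps <- matrix(numeric(), 0L, n)
  if (ncol(steps) != n) stop("step dimension must match the lattice dimension")
  if (nrow(steps) + 1L != nchar(sequence)) {
    stop("need exactly one step less than residues")
  }
  if (nrow(steps) == 0L) {
    m <- matrix(0, 1L, n)
  } else {
    m <- rbind(rep(0, n),
               matrix(apply(steps, 2L, cumsum), ncol = n))
  }
  LatticeProtein(sequence, lattice, coords = m)
}

#' Self-avoiding-walk check
#'
#' A conformation is admissible when (i) every residue but the first is one
#' step away from its predecessor (each consecutive difference is a main
#' direction) and (ii) no vertex is occupied twice.  The clash check uses
#' hashed occupancy keys, so the whole test is linear in the chain length.
#'
#' @param model a \code{\linkS4class{LatticeProtein}}.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
isSelfAvoiding <- function(model) {
  m <- model@coords
  .coordsSelfAvoiding(model@lattice, m)
}

.coordsSelfAvoiding <- function(lattice, m) {
  N <- nrow(m)
  if (N == 0L) return(FALSE)
  if (anyDuplicated(.packCoords(m))) return(FALSE)
  if (N == 1L) return(TRUE)
  steps <- m[-1L, , drop = FALSE] - m[-N, , drop = FALSE]
  if (lattice@kind == "square") {
    all(rowSums(abs(steps)) == 1)
  } else {
    all(pmax(rowSums(pmax(steps, 0)), rowSums(pmax(-steps, 0))) == 1)
  }
}

#' Translate a conformation
#'
#' Rigid translation by an integer lattice vector; the differential
#' encoding is unchanged.
#'
#' @param model a \code{\linkS4class{LatticeProtein}}.
#' @param t integer translation vector.
#' @return the translated model.
#' @export
translateModel <- function(model, t) {
  t <- .checkVector(t, model@lattice@dim, "t")
  .replaceCoords(model, sweep(model@coords, 2L, t, "+"))
}

#' Lattice rotations between main directions
#'
#' Under the linear hypothesis an \eqn{n}-dimensional rigid rotation acts in
#' a two-dimensional plane and fixes the orthogonal \eqn{(n-2)}-dimensional
#' subspace.  \code{planeRotation} builds the rotation that carries a
#' source main direction \eqn{u} onto a destination \eqn{v}, rotating in
#' the plane they span.  Note that \eqn{R(v) = -u} is guaranteed only on
#' square lattices.
#'
#' @slot matrix rotation matrix expressed in lattice coordinates
#'   (\eqn{B^{-1} R_{cart} B}); generally not integer.
#' @slot cartesian the Cartesian rotation matrix (orthogonal, det +1).
#' @slot src,dst the source and destination main directions.
#' @name Rotation-class
#' @aliases Rotation-class
#' @exportClass Rotation
setClass("Rotation",
  representation(matrix = "matrix", cartesian = "matrix",
                 src = "numeric", dst = "numeric"))

setMethod("show", "Rotation", function(object) {
  cat(sprintf("lattice rotation %s -> %s\n",
              paste0("(", paste(object@src, collapse = ","), ")"),
              paste0("(", paste(object@dst, collapse = ","), ")")))
  print(round(object@matrix, 4))
  invisible(object)
})

#' @describeIn Rotation-class construct the plane rotation mapping main
#'   direction \code{u} onto \code{v} (both in lattice coordinates, both in
#'   \eqn{D}).  When \eqn{\hat u = -\hat v} the half-turn plane is chosen
#'   deterministically: the plane spanned by \eqn{\hat u} and the
#'   lowest-index main direction not parallel to it.
#' @param lattice a \code{\linkS4class{Lattice}}.
#' @param u,v source and destination main directions.
#' @export
planeRotation <- function(lattice, u, v) {
  n <- lattice@dim
  u <- .checkVector(u, n, "u"); v <- .checkVector(v, n, "v")
  keys <- .packCoords(lattice@mainDirs)
  if (!(.packCoords(matrix(u, 1L)) %in% keys) ||
      !(.packCoords(matrix(v, 1L)) %in% keys)) {
    stop("u and v must be main directions of the lattice")
  }
  B <- lattice@basis
  a <- drop(B %*% u)
  b <- drop(B %*% v)
  cth <- sum(a * b)
  if (abs(cth - 1) < 1e-12) {
    R <- diag(n)
  } else if (abs(cth + 1) < 1e-12) {
    # opposite directions: half turn in the plane of a and the first main
    # direction not parallel to a
    w0 <- NULL
    for (r in seq_len(nrow(lattice@mainDirs))) {
      cand <- drop(B %*% lattice@mainDirs[r, ])
      if (abs(abs(sum(cand * a)) - 1) > 1e-9) { w0 <- cand; break }
    }
    w <- w0 - sum(w0 * a) * a
    w <- w / sqrt(sum(w^2))
    R <- diag(n) - 2 * tcrossprod(a) - 2 * tcrossprod(w)
  } else {
    w <- b - cth * a
    s <- sqrt(sum(w^2))
    w <- w / s
    R <- diag(n) + (cth - 1) * (tcrossprod(a) + tcrossprod(w)) +
      s * (tcrossprod(w, a) - tcrossprod(a, w))
  }
  new("Rotation", matrix = solve(B, R %*% B), cartesian = R,
      src = u, dst = v)
}

#' Rotate one branch of a conformation
#'
#' Applies a \code{\linkS4class{Rotation}} to the branch of the chain on
#' one side of a pivot residue, about the pivot vertex: each branch vertex
#' \eqn{p} is mapped to \eqn{pivot + R (p - pivot)}.  On triangular
#' lattices the lattice-frame rotation matrix is generally non-integer, so
#' rotated vertices need not exist on the lattice; images are rounded when
#' they are within \code{tol} of integers and the result is flagged
#' otherwise.  No clash checking is done here (that is the pivot move's
#' job).
#'
#' @param model a \code{\linkS4class{LatticeProtein}}.
#' @param pivotIndex residue index (1-based) of the pivot.
#' @param branch \code{"forward"} (residues after the pivot) or
#'   \code{"backward"} (residues before it).
#' @param rotation a \code{\linkS4class{Rotation}}.
#' @param tol integrality tolerance for rotated coordinates.
#' @return a list with \code{coords} (the candidate coordinate matrix,
#'   branch images rounded) and \code{onLattice} (\code{FALSE} when any
#'   image missed an integer vertex by more than \code{tol}).
#' @export
rotateBranch <- function(model, pivotIndex, branch = c("forward", "backward"),
                         rotation, tol = 1e-6) {
  branch <- match.arg(branch)
  m <- model@coords
  N <- nrow(m)
  if (pivotIndex < 1L || pivotIndex > N) stop("pivot index out of range")
  idx <- if (branch == "forward") seq_len(N) > pivotIndex
         else seq_len(N) < pivotIndex
  if (!any(idx)) {
    return(list(coords = m, onLattice = TRUE))
  }
  pivot <- m[pivotIndex, ]
  rel <- sweep(m[idx, , drop = FALSE], 2L, pivot, "-")
  img <- rel %*% t(rotation@matrix)
  onLattice <- max(abs(img - round(img))) < tol
  m[idx, ] <- sweep(round(img), 2L, pivot, "+")
  list(coords = m, onLattice = onLattice)
}

#' Random-walk build-up
#'
#' Grows an origin-anchored self-avoiding walk one residue at a time,
#' choosing uniformly among the free neighbouring vertices.  A dead end
#' restarts the walk with the random-number state advanced; after
#' \code{100 * N} failed attempts the builder gives up with an error
#' (unreachable for chain lengths the supported lattices accommodate).
#' Deterministic given \code{seed}.
#'
#' @param lattice a \code{\linkS4class{Lattice}}.
#' @param sequence residue string.
#' @param seed optional integer seed.
#' @return a self-avoiding \code{\linkS4class{LatticeProtein}}.
#' @export
randomWalkBuild <- function(lattice, sequence, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- nchar(sequence)
  n <- lattice@dim
  D <- lattice@mainDirs
  dkeys <- .packDirs(D)
  maxAttempts <- 100L * N
  for (attempt in seq_len(maxAttempts)) {
    m <- matrix(0, N, n)
    keys <- numeric(N); keys[1L] <- .packCoords(m[1L, , drop = FALSE])
    ok <- TRUE
    i <- 1L
    while (i < N) {
      cand <- keys[i] + dkeys
      free <- which(!(cand %in% keys[seq_len(i)]))
      if (!length(free)) { ok <- FALSE; break }
      pick <- .sampleOne(free)
      m[i + 1L, ] <- m[i, ] + D[pick, ]
      keys[i + 1L] <- cand[pick]
      i <- i + 1L
    }
    if (ok) return(LatticeProtein(sequence, lattice, coords = m))
  }
  stop("random walk build-up exceeded its retry budget")
}

#' Linear build-up
#'
#' Places residue \eqn{i} at \eqn{(i - 1) \cdot D_1}, the first main
#' direction in lexicographic order: a straight chain, always
#' self-avoiding, used as the initial conformation of the annealing
#' optimizer.
#'
#' @inheritParams randomWalkBuild
#' @return a \code{\linkS4class{LatticeProtein}}.
#' @export
linearBuild <- function(lattice, sequence) {
  N <- nchar(sequence)
  d1 <- lattice@mainDirs[1L, ]
  m <- outer(seq_len(N) - 1L, d1)
  LatticeProtein(sequence, lattice, coords = m)
}

#' Radial neighbour profile of a point cloud
#'
#' For each radius \eqn{r}, the number of points (excluding any point
#' coincident with the centre) within Euclidean distance \eqn{r} of the
#' centre.  Intended for 3-D C-alpha coordinate tables (Angstroms), where
#' the profile characterises how many neighbours a residue can have and
#' hence which coordination numbers are admissible.
#'
#' @param points numeric matrix of 3-D coordinates, one point per row.
#' @param center numeric 3-vector.
#' @param radii positive, ascending radii.
#' @return integer vector of counts, monotone non-decreasing.
#' @export
radialNeighborProfile <- function(points, center, radii) {
  points <- as.matrix(points)
  if (length(radii) == 0L) stop("radii must be non-empty")
  if (any(radii <= 0) || is.unsorted(radii)) {
    stop("radii must be positive and ascending")
  }
  # points identical to the centre are excluded; all others count
  keep <- !apply(points, 1L, function(p) all(p == center))
  d <- sqrt(colSums((t(points[keep, , drop = FALSE]) - center)^2))
  as.integer(vapply(radii, function(r) sum(d <= r), numeric(1)))
}

#' Average radial neighbour profile
#'
#' Averages \code{\link{radialNeighborProfile}} over all points lying
#' within \code{fraction} of the cloud's gyration radius from its centroid,
#' i.e. over centres deep enough inside the molecule that the probing
#' sphere stays embedded in it.
#'
#' @inheritParams radialNeighborProfile
#' @param fraction fraction of the gyration radius bounding the centres
#'   used (default 0.5).
#' @return numeric vector of mean counts (NaN when no centre qualifies).
#' @export
meanRadialNeighborProfile <- function(points, radii, fraction = 0.5) {
  points <- as.matrix(points)
  centroid <- colMeans(points)
  d2 <- colSums((t(points) - centroid)^2)
  rg <- sqrt(mean(d2))
  centers <- which(sqrt(d2) <= fraction * rg)
  if (!length(centers)) return(rep(NaN, length(radii)))
  prof <- vapply(centers, function(i) {
    as.numeric(radialNeighborProfile(points, points[i, ], radii))
  }, numeric(length(radii)))
  if (length(radii) == 1L) prof <- matrix(prof, nrow = 1L)
  rowMeans(prof)
}
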