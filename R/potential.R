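#' Pairwise contact potentials
#'
#' A \code{PotentialModel} specifies the generalised pairwise potential
#' \deqn{\epsilon = \sum_{j \ge i+2} g(d(p_i, p_j)) \; C(s_i, s_j),}
#' the sum running over residue pairs that are not adjacent along the
#' backbone.  \eqn{C} is a symmetric residue-type coefficient table and
#' \eqn{g} a hop-distance factor that vanishes beyond a small cutoff, so
#' only near-contacts contribute.  The classic HP potential is the special
#' case \eqn{g(1) = 1} (zero otherwise), \eqn{C(H,H) = -1} and all other
#' coefficients zero: minus the number of H--H contacts.
#'
#' @slot coefficients symmetric numeric matrix with residue types as
#'   dimnames.
#' @slot distanceFactor numeric vector; element \eqn{d} is \eqn{g(d)}, and
#'   \eqn{g} is zero beyond its length (the cutoff).
#'
#' @name PotentialModel-class
#' @aliases PotentialModel-class
#' @exportClass PotentialModel
setClass("PotentialModel",
  representation(coefficients = "matrix", distanceFactor = "numeric"))

setValidity("PotentialModel", function(object) {
  C <- object@coefficients
  msg <- character()
  if (is.null(rownames(C)) || !identical(rownames(C), colnames(C))) {
    msg <- c(msg, "coefficients need matching residue-type dimnames")
  }
  if (!isSymmetric(unname(C))) msg <- c(msg, "coefficients must be symmetric")
  if (length(object@distanceFactor) < 1L) {
    msg <- c(msg, "distanceFactor needs at least g(1)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a potential model
#'
#' @param coefficients symmetric coefficient matrix with residue types as
#'   dimnames (or a data frame read from a CSV table, rows and columns
#'   labelled by residue type, to support e.g. 20-letter alphabets).
#' @param distanceFactor numeric vector giving \eqn{g(d)} for
#'   \eqn{d = 1, 2, \dots}; zero beyond its length.  Default: contacts
#'   only, \eqn{g(1) = 1}.
#' @return a \code{\linkS4class{PotentialModel}}.
#' @export
PotentialModel <- function(coefficients, distanceFactor = 1) {
  coefficients <- as.matrix(coefficients)
  new("PotentialModel", coefficients = coefficients,
      distanceFactor = as.numeric(distanceFactor))
}

#' @describeIn PotentialModel-class the classic HP model:
#'   \eqn{C(H,H) = -1}, all other pairs 0, contacts only.
#' @export
hpPotentialModel <- function() {
  C <- matrix(0, 2, 2, dimnames = list(c("H", "P"), c("H", "P")))
  C["H", "H"] <- -1
  PotentialModel(C)
}

#' @describeIn PotentialModel-class the compaction ("warm-up") potential
#'   used early in simulated annealing: \eqn{C(H,H) = -1} as in the HP
#'   model plus a uniform weak attraction \code{other} (default -0.25) for
#'   every other residue pair in contact, driving the chain towards a
#'   globular shape faster.
#' @param other contact coefficient for non-HH pairs.
#' @export
warmupPotentialModel <- function(other = -0.25) {
  C <- matrix(other, 2, 2, dimnames = list(c("H", "P"), c("H", "P")))
  C["H", "H"] <- -1
  PotentialModel(C)
}

# Occupancy-map contact enumeration: each residue inspects only its c
# neighbour vertices, so evaluation is O(N * c) instead of the O(N^2) pair
# loop (the straightforward transcription of which is kept as
# method = "pairwise" and used as the oracle in the tests).  Returns a
# 2-column matrix of residue index pairs (i, j), j >= i + 2, on adjacent
# vertices.
.contactPairs <- function(model) {
  lattice <- model@lattice
  m <- model@coords
  N <- nrow(m)
  if (N < 3L) return(matrix(integer(), 0L, 2L))
  keys <- .packCoords(m)
  if (is.character(keys)) {
    # high-dimensional fallback: string occupancy keys are not additive
    D <- lattice@mainDirs
    out <- lapply(seq_len(N), function(i) {
      nk <- .packCoords(sweep(D, 2L, m[i, ], "+"))
      j <- match(nk, keys)
      j <- j[!is.na(j) & j >= i + 2L]
      if (length(j)) cbind(i, j, deparse.level = 0L) else NULL
    })
    return(do.call(rbind, c(out, list(matrix(integer(), 0L, 2L)))))
  }
  dkeys <- .packDirs(lattice@mainDirs)
  # neighbour keys of every residue at once; match() is the occupancy map
  neigh <- outer(keys, dkeys, "+")
  j <- match(neigh, keys)
  i <- rep.int(seq_len(N), length(dkeys))
  keep <- !is.na(j) & j >= i + 2L
  cbind(i[keep], j[keep], deparse.level = 0L)
}

# Direct transcription of the simplistic O(N^2) evaluator: for every pair
# j >= i + 2 of H residues, test whether the difference vector is a main
# direction.
.hpPotentialPairwise <- function(model) {
  m <- model@coords
  res <- .residues(model)
  N <- nrow(m)
  dkeys <- .packDirs(model@lattice@mainDirs)
  pot <- 0
  if (N < 3L) return(0L)
  for (i in seq_len(N - 2L)) {
    if (res[i] != "H") next
    for (j in seq(i + 2L, N)) {
      if (res[j] != "H") next
      vd <- m[j, ] - m[i, ]
      if (.packCoords(matrix(vd, 1L)) %in% dkeys) pot <- pot - 1
    }
  }
  as.integer(pot)
}

#' HP potential of a conformation
#'
#' Minus the number of H--H contacts: pairs of H residues that are not
#' adjacent along the backbone (\eqn{j \ge i + 2}) but sit on adjacent
#' lattice vertices.  Adjacency is established lattice-agnostically through
#' the main directions.  The default \code{"neighbors"} method scans each
#' residue's \eqn{c} neighbour vertices via an occupancy map
#' (\eqn{O(Nc)}); \code{"pairwise"} is the straightforward quadratic pair
#' loop, kept as an independent route for validation.
#'
#' @param model a self-avoiding \code{\linkS4class{LatticeProtein}} over
#'   the \code{H}/\code{P} alphabet.
#' @param method evaluation route, see Details.
#' @return a non-positive integer.
#' @examples
#' sq2 <- Lattice("square", 2)
#' u <- LatticeProtein("HHHH", sq2, coords = rbind(c(0,0), c(1,0),
#'                                                 c(1,1), c(0,1)))
#' hpPotential(u)  # -1: the single (1, 4) contact
#' @export
hpPotential <- function(model, method = c("neighbors", "pairwise")) {
  method <- match.arg(method)
  res <- .residues(model)
  if (!all(res %in% c("H", "P"))) {
    stop("hpPotential is defined over the {H, P} alphabet")
  }
  if (method == "pairwise") return(.hpPotentialPairwise(model))
  pr <- .contactPairs(model)
  if (!nrow(pr)) return(0L)
  -as.integer(sum(res[pr[, 1L]] == "H" & res[pr[, 2L]] == "H"))
}

#' Generalised pairwise potential
#'
#' Evaluates the contact potential for an arbitrary symmetric coefficient
#' table and hop-distance factor.  With the HP coefficients it reduces
#' exactly to \code{\link{hpPotential}}.  When the distance factor has
#' cutoff 1 (contacts only) the occupancy-map enumeration is used;
#' otherwise every eligible pair is scored through the hop distance.
#'
#' @param model a \code{\linkS4class{LatticeProtein}}.
#' @param potentialModel a \code{\linkS4class{PotentialModel}} covering all
#'   residue types present in the sequence.
#' @return a number.
#' @export
genericPotential <- function(model, potentialModel = hpPotentialModel()) {
  res <- .residues(model)
  C <- potentialModel@coefficients
  if (!all(res %in% rownames(C))) {
    stop("coefficient table is missing residue types present in the sequence")
  }
  g <- potentialModel@distanceFactor
  if (length(g) == 1L) {
    pr <- .contactPairs(model)
    if (!nrow(pr)) return(0)
    return(g[1L] * sum(C[cbind(res[pr[, 1L]], res[pr[, 2L]])]))
  }
  m <- model@coords
  N <- nrow(m)
  if (N < 3L) return(0)
  lattice <- model@lattice
  pot <- 0
  for (i in seq_len(N - 2L)) {
    for (j in seq(i + 2L, N)) {
      d <- .hopFromDelta(lattice, m[j, ] - m[i, ])
      if (d >= 1L && d <= length(g) && g[d] != 0) {
        pot <- pot + g[d] * C[res[i], res[j]]
      }
    }
  }
  pot
}

#' Count typed contacts
#'
#' Number of unordered non-bonded residue pairs of the given type
#' combination on adjacent vertices.  \code{countContacts(m, "H", "H")}
#' times -1 equals the HP potential.
#'
#' @param model a \code{\linkS4class{LatticeProtein}}.
#' @param typeA,typeB residue types (order irrelevant).
#' @return a non-negative integer.
#' @export
countContacts <- function(model, typeA, typeB) {
  pr <- .contactPairs(model)
  if (!nrow(pr)) return(0L)
  res <- .residues(model)
  a <- res[pr[, 1L]]; b <- res[pr[, 2L]]
  as.integer(sum((a == typeA & b == typeB) | (a == typeB & b == typeA)))
}
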