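#' Outcome of a Monte Carlo move attempt
#'
#' Every move function returns a \code{MoveOutcome}.  When the attempted
#' move was feasible (\code{applied}), \code{moveCoords} holds the new
#' self-avoiding coordinate matrix, guaranteed to differ from the input
#' conformation (a destination equal to the current position counts as
#' infeasible: a move must produce a different admissible conformation).
#'
#' @slot applied logical.
#' @slot moveType one of \code{"end"}, \code{"kinkjump"},
#'   \code{"crankshaft"}, \code{"snake"}, \code{"pivot"}, \code{"pull"}.
#' @slot coords new coordinate matrix (zero rows when not applied).
#' @slot displacedCount number of residues whose position changed.
#' @name MoveOutcome-class
#' @aliases MoveOutcome-class
#' @exportClass MoveOutcome
setClass("MoveOutcome",
  representation(applied = "logical", moveType = "character",
                 coords = "matrix", displacedCount = "integer"))

.moveTypes <- c("end", "kinkjump", "crankshaft", "snake", "pivot", "pull")

# Built once and copied: outcome construction sits in the Monte Carlo hot
# loop, so the S4 initialize/validity machinery is bypassed.
.outcomeProto <- NULL

.outcome <- function(applied, type, coords = NULL, displaced = 0L) {
  out <- .outcomeProto
  if (is.null(out)) {
    out <- new("MoveOutcome", applied = FALSE, moveType = "end",
               coords = matrix(numeric(), 0L, 0L), displacedCount = 0L)
    utils::assignInMyNamespace(".outcomeProto", out)
  }
  slot(out, "applied", check = FALSE) <- applied
  slot(out, "moveType", check = FALSE) <- type
  if (!is.null(coords)) slot(out, "coords", check = FALSE) <- coords
  slot(out, "displacedCount", check = FALSE) <- as.integer(displaced)
  out
}

setMethod("show", "MoveOutcome", function(object) {
  cat(sprintf("%s move: %s (%d residue%s displaced)\n", object@moveType,
              if (object@applied) "applied" else "infeasible",
              object@displacedCount,
              if (object@displacedCount == 1L) "" else "s"))
  invisible(object)
})

#' @describeIn MoveOutcome-class accessor for the new coordinates.
#' @param outcome a \code{MoveOutcome}.
#' @export
moveCoords <- function(outcome) outcome@coords

#' @describeIn MoveOutcome-class apply an outcome to the model it came
#'   from, returning the updated model (or the model unchanged when the
#'   move was infeasible).
#' @param model the \code{\linkS4class{LatticeProtein}} the move was
#'   attempted on.
#' @export
applyMove <- function(model, outcome) {
  if (!outcome@applied) return(model)
  .replaceCoords(model, outcome@coords)
}

# Occupancy keys of all residues except those listed in `exclude`.
.occupiedKeys <- function(m, exclude = integer()) {
  keys <- .packCoords(m)
  if (length(exclude)) keys[-exclude] else keys
}

#' Single-residue end move
#'
#' Relocates a terminal residue onto a free vertex one step away from its
#' adjacent residue, chosen uniformly among the candidates.
#'
#' @param model a self-avoiding \code{\linkS4class{LatticeProtein}} with at
#'   least 2 residues.
#' @param terminus \code{"first"} or \code{"last"}.
#' @return a \code{\linkS4class{MoveOutcome}}.
#' @export
endMove <- function(model, terminus = c("first", "last")) {
  terminus <- match.arg(terminus)
  m <- model@coords
  N <- nrow(m)
  if (N < 2L) stop("end move needs at least 2 residues")
  t <- if (terminus == "first") 1L else N
  a <- if (terminus == "first") 2L else N - 1L
  D <- model@lattice@mainDirs
  cand <- .addPoint(D, m[a, ])
  ck <- .packCoords(cand)
  occ <- .occupiedKeys(m, exclude = t)
  cur <- .packCoords(m[t, , drop = FALSE])
  ok <- which(!(ck %in% occ) & ck != cur)
  if (!length(ok)) return(.outcome(FALSE, "end"))
  m[t, ] <- cand[.sampleOne(ok), ]
  .outcome(TRUE, "end", m, 1L)
}

#' Kink-jump (corner) move
#'
#' Relocates an interior residue onto a free vertex that is one step away
#' from both of its chain neighbours, chosen uniformly.
#'
#' @param model a self-avoiding \code{\linkS4class{LatticeProtein}}.
#' @param index interior residue index (between 2 and N - 1).
#' @return a \code{\linkS4class{MoveOutcome}}.
#' @export
kinkJump <- function(model, index) {
  m <- model@coords
  N <- nrow(m)
  if (index < 2L || index > N - 1L) stop("kink-jump index out of range")
  lattice <- model@lattice
  D <- lattice@mainDirs
  cand <- .addPoint(D, m[index - 1L, ])
  adjNext <- .adjacentRows(lattice, cand, m[index + 1L, ])
  ck <- .packCoords(cand)
  occ <- .occupiedKeys(m, exclude = index)
  cur <- .packCoords(m[index, , drop = FALSE])
  ok <- which(adjNext & !(ck %in% occ) & ck != cur)
  if (!length(ok)) return(.outcome(FALSE, "kinkjump"))
  m[index, ] <- cand[.sampleOne(ok), ]
  .outcome(TRUE, "kinkjump", m, 1L)
}

#' Two-residue crankshaft move
#'
#' Given four successive residues \eqn{i, i+1, i+2, i+3}, relocates the two
#' middle ones onto a uniformly chosen pair of free vertices \eqn{u', v'}
#' with \eqn{u'} adjacent to residue \eqn{i}, \eqn{v'} adjacent to residue
#' \eqn{i+3} and \eqn{u'} adjacent to \eqn{v'}.  All \eqn{c^2} candidate
#' pairs are enumerated; the pair currently occupied does not count (the
#' two old vertices may however be reused in swapped roles).
#'
#' @param model a self-avoiding \code{\linkS4class{LatticeProtein}}.
#' @param index index of the first of the four residues (1 to N - 3).
#' @return a \code{\linkS4class{MoveOutcome}}.
#' @export
crankshaftMove <- function(model, index) {
  m <- model@coords
  N <- nrow(m)
  if (index < 1L || index > N - 3L) stop("crankshaft index out of range")
  lattice <- model@lattice
  D <- lattice@mainDirs
  c2 <- nrow(D)
  u <- .addPoint(D, m[index, ])                  # candidates for i+1
  occ <- .occupiedKeys(m, exclude = c(index + 1L, index + 2L))
  uk <- .packCoords(u)
  curU <- .packCoords(m[index + 1L, , drop = FALSE])
  curV <- .packCoords(m[index + 2L, , drop = FALSE])
  pairs <- NULL
  for (r in which(!(uk %in% occ))) {
    v <- .addPoint(D, u[r, ])                    # adjacent to u'
    vk <- .packCoords(v)
    adjEnd <- .adjacentRows(lattice, v, m[index + 3L, ])
    good <- which(adjEnd & !(vk %in% occ) & vk != uk[r] &
                    !(uk[r] == curU & vk == curV))
    if (length(good)) {
      pairs <- rbind(pairs, cbind(r, good, deparse.level = 0L))
    }
  }
  if (is.null(pairs)) return(.outcome(FALSE, "crankshaft"))
  pick <- pairs[sample.int(nrow(pairs), 1L), ]
  m[index + 1L, ] <- u[pick[1L], ]
  m[index + 2L, ] <- u[pick[1L], ] + D[pick[2L], ]
  displaced <- sum(.packCoords(m[c(index + 1L, index + 2L), , drop = FALSE]) !=
                     c(curU, curV))
  .outcome(TRUE, "crankshaft", m, displaced)
}

#' Slithering-snake (reptation) move
#'
#' Looks for a free vertex adjacent to the target end, moves that terminus
#' onto it and shifts every other residue by one position along the
#' backbone path; the opposite end's vertex is vacated.  Every residue is
#' displaced.
#'
#' @param model a self-avoiding \code{\linkS4class{LatticeProtein}}.
#' @param terminus the end that advances (\code{"first"} or \code{"last"}).
#' @return a \code{\linkS4class{MoveOutcome}}.
#' @export
slitheringSnake <- function(model, terminus = c("first", "last")) {
  terminus <- match.arg(terminus)
  m <- model@coords
  N <- nrow(m)
  if (N < 2L) stop("slithering snake needs at least 2 residues")
  D <- model@lattice@mainDirs
  head <- if (terminus == "first") 1L else N
  vacated <- if (terminus == "first") N else 1L
  cand <- .addPoint(D, m[head, ])
  ck <- .packCoords(cand)
  occ <- .occupiedKeys(m, exclude = vacated)
  ok <- which(!(ck %in% occ))
  if (!length(ok)) return(.outcome(FALSE, "snake"))
  v <- cand[.sampleOne(ok), ]
  m2 <- if (terminus == "first") rbind(v, m[-N, , drop = FALSE])
        else rbind(m[-1L, , drop = FALSE], v)
  .outcome(TRUE, "snake", unname(m2), N)
}

#' Pivot move
#'
#' Chooses one residue as pivot and rigidly rotates one whole branch of
#' the chain about its vertex, using the plane rotation that carries the
#' branch's first step direction onto \code{dstDir}.  The attempt is
#' rejected when the rotation is the identity (no-op), when any rotated
#' vertex misses the lattice (non-integer image, possible on triangular
#' lattices) or when the rotated branch clashes with the fixed one.
#'
#' @param model a self-avoiding \code{\linkS4class{LatticeProtein}}.
#' @param pivotIndex pivot residue index; the chosen branch must be
#'   non-empty.
#' @param branch \code{"forward"} or \code{"backward"}.
#' @param dstDir destination main direction for the branch's first step;
#'   when \code{NULL} one is drawn uniformly among the legal candidates
#'   (main directions, different from the current step, whose vertex next
#'   to the pivot is free).
#' @return a \code{\linkS4class{MoveOutcome}}.
#' @export
pivotMove <- function(model, pivotIndex, branch = c("forward", "backward"),
                      dstDir = NULL) {
  branch <- match.arg(branch)
  m <- model@coords
  N <- nrow(m)
  if (pivotIndex < 1L || pivotIndex > N) stop("pivot index out of range")
  first <- if (branch == "forward") pivotIndex + 1L else pivotIndex - 1L
  if (first < 1L || first > N) stop("chosen branch is empty")
  lattice <- model@lattice
  u <- m[first, ] - m[pivotIndex, ]
  fixedIdx <- if (branch == "forward") seq_len(pivotIndex)
              else seq(pivotIndex, N)
  occ <- .packCoords(m[fixedIdx, , drop = FALSE])
  if (is.null(dstDir)) {
    D <- lattice@mainDirs
    ck <- .packCoords(.addPoint(D, m[pivotIndex, ]))
    legal <- which(!(ck %in% occ) & .packDirs(D) != .packDirs(matrix(u, 1L)))
    if (!length(legal)) return(.outcome(FALSE, "pivot"))
    dstDir <- D[.sampleOne(legal), ]
  } else {
    dstDir <- .checkVector(dstDir, lattice@dim, "dstDir")
    if (all(dstDir == u)) return(.outcome(FALSE, "pivot"))
    if (.packCoords(matrix(m[pivotIndex, ] + dstDir, 1L)) %in% occ) {
      return(.outcome(FALSE, "pivot"))
    }
  }
  rot <- .memoGet(lattice,
                  paste("rot", paste(u, collapse = " "),
                        paste(dstDir, collapse = " ")),
                  function() planeRotation(lattice, u, dstDir))
  res <- rotateBranch(model, pivotIndex, branch, rot)
  if (!res$onLattice) return(.outcome(FALSE, "pivot"))
  if (!.coordsSelfAvoiding(lattice, res$coords)) {
    return(.outcome(FALSE, "pivot"))
  }
  displaced <- sum(.packCoords(res$coords) != .packCoords(m))
  if (displaced == 0L) return(.outcome(FALSE, "pivot"))
  .outcome(TRUE, "pivot", res$coords, displaced)
}

#' Topology-dependent pull displacement
#'
#' The smallest number of steps a chain can be pulled: the minimum hop
#' distance from a residue's vertex to a destination vertex that is
#' adjacent to one of the residue's neighbours but distinct from the
#' residue's own vertex, derived by enumerating pairs of main directions.
#' Square lattices give 2 (no two main directions are mutually adjacent),
#' triangular lattices give 1.
#'
#' @param lattice a \code{\linkS4class{Lattice}}.
#' @return an integer (\eqn{\nu}).
#' @export
pullDisplacement <- function(lattice) {
  D <- lattice@mainDirs
  best <- Inf
  for (i in seq_len(nrow(D))) {
    for (j in seq_len(nrow(D))) {
      q <- D[i, ] + D[j, ]               # adjacent to the neighbour at D[i, ]
      if (all(q == 0)) next              # the residue's own vertex
      best <- min(best, .hopFromDelta(lattice, q))
    }
  }
  as.integer(best)
}

#' Pull move
#'
#' Semi-local move: the target residue jumps to a free vertex \eqn{q}
#' adjacent to its anchor-side neighbour and \eqn{\nu} hops away from its
#' current vertex (\eqn{\nu = 2} on square lattices, 1 on triangular
#' ones), reachable through \eqn{\nu - 1} free intermediate vertices; the
#' chosen branch is then pulled along, each pulled residue dropping into
#' the position vacated two steps earlier in the pulled order (on square
#' lattices the first pulled residue takes the intermediate vertex),
#' stopping at the first residue that is already adjacent to its
#' predecessor's new position.  On average only a few residues move.
#'
#' @param model a self-avoiding \code{\linkS4class{LatticeProtein}}.
#' @param index target residue index.
#' @param branch side that gets pulled: \code{"forward"} pulls residues
#'   \code{index + 1 .. N} (anchoring on residue \code{index - 1}),
#'   \code{"backward"} pulls residues \code{index - 1 .. 1} (anchoring on
#'   residue \code{index + 1}).  The pulled branch may be empty (end
#'   residues).
#' @param dstVertex destination vertex \eqn{q}; \code{NULL} draws one
#'   uniformly among the legal candidates.
#' @return a \code{\linkS4class{MoveOutcome}}.
#' @export
pullMove <- function(model, index, branch = c("forward", "backward"),
                     dstVertex = NULL) {
  branch <- match.arg(branch)
  m <- model@coords
  N <- nrow(m)
  lattice <- model@lattice
  nu <- .memoGet(lattice, "pullNu", function() pullDisplacement(lattice))
  anchor <- if (branch == "forward") index - 1L else index + 1L
  if (anchor < 1L || anchor > N) stop("no anchor neighbour on that side")
  pulled <- if (branch == "forward") {
    if (index < N) seq(index + 1L, N) else integer()
  } else {
    if (index > 1L) seq(index - 1L, 1L) else integer()
  }
  D <- lattice@mainDirs
  occ <- .packCoords(m)
  p <- m[index, ]
  candQ <- function() {
    cand <- .addPoint(D, m[anchor, ])
    ck <- .packCoords(cand)
    keep <- which(!(ck %in% occ) & .hopRows(lattice, cand, p) == nu)
    cand[keep, , drop = FALSE]
  }
  if (is.null(dstVertex)) {
    qs <- candQ()
    if (!nrow(qs)) return(.outcome(FALSE, "pull"))
    q <- qs[sample.int(nrow(qs), 1L), ]
  } else {
    q <- .checkVector(dstVertex, lattice@dim, "dstVertex")
    qk <- .packCoords(matrix(q, 1L))
    if (qk %in% occ ||
        .hopFromDelta(lattice, q - m[anchor, ]) != 1L ||
        .hopFromDelta(lattice, q - p) != nu) {
      return(.outcome(FALSE, "pull"))
    }
  }
  # free path from p to q with nu - 1 internal vertices (square lattices):
  # intermediates adjacent to both p and q
  targets <- list()
  if (nu == 2L) {
    inter <- .addPoint(D, p)
    ik <- .packCoords(inter)
    good <- which(!(ik %in% occ) & .adjacentRows(lattice, inter, q))
    if (!length(good)) return(.outcome(FALSE, "pull"))
    targets[[1L]] <- inter[.sampleOne(good), ]
  }
  targets <- c(targets, list(p))                 # vacated positions follow
  m2 <- m
  m2[index, ] <- q
  prevNew <- q
  k <- 0L
  for (a in pulled) {
    k <- k + 1L
    if (.hopFromDelta(lattice, m2[a, ] - prevNew) == 1L) break
    if (k > length(targets)) break               # defensive; cannot happen
    old <- m2[a, ]
    m2[a, ] <- targets[[k]]
    targets <- c(targets, list(old))
    prevNew <- m2[a, ]
  }
  if (!.coordsSelfAvoiding(lattice, m2)) return(.outcome(FALSE, "pull"))
  displaced <- sum(.packCoords(m2) != .packCoords(m))
  if (displaced == 0L) return(.outcome(FALSE, "pull"))
  .outcome(TRUE, "pull", m2, displaced)
}

#' Move-usage statistics
#'
#' Per-move-type counters of tried applications, feasible applications
#' (hits) and solution improvements, yielding the hit rate \eqn{h} (hits
#' over tries) and the improvement fraction \eqn{\sigma} (share of all
#' improving applications belonging to each type, summing to 1 once any
#' improvement occurred).
#'
#' @slot tries,hits,improvements named numeric counters over the six move
#'   types.
#' @name MoveStats-class
#' @aliases MoveStats-class
#' @exportClass MoveStats
setClass("MoveStats",
  representation(tries = "numeric", hits = "numeric",
                 improvements = "numeric"))

#' @describeIn MoveStats-class fresh zeroed counters.
#' @export
newMoveStats <- function() {
  z <- stats::setNames(numeric(length(.moveTypes)), .moveTypes)
  new("MoveStats", tries = z, hits = z, improvements = z)
}

#' @describeIn MoveStats-class record an improvement event for a move
#'   type (called by the optimizer when an accepted move lowered the best
#'   potential so far); returns the updated statistics.
#' @param stats a \code{MoveStats}.
#' @param type a move type.
#' @export
recordImprovement <- function(stats, type) {
  stats@improvements[type] <- stats@improvements[type] + 1
  stats
}

#' @describeIn MoveStats-class hit rates \eqn{h} per move type (NaN where
#'   never tried).
#' @export
hitRates <- function(stats) stats@hits / stats@tries

#' @describeIn MoveStats-class improvement fractions \eqn{\sigma} per move
#'   type (NaN when no improvement was recorded at all).
#' @export
improvementFractions <- function(stats) {
  tot <- sum(stats@improvements)
  if (tot == 0) return(stats@improvements * NaN)
  stats@improvements / tot
}

setMethod("show", "MoveStats", function(object) {
  print(as.data.frame(object))
  invisible(object)
})

#' @exportS3Method base::as.data.frame
as.data.frame.MoveStats <- function(x, ...) {
  data.frame(move_type = .moveTypes,
             tries = as.numeric(x@tries),
             hits = as.numeric(x@hits),
             improvements = as.numeric(x@improvements),
             h = as.numeric(hitRates(x)),
             sigma = as.numeric(improvementFractions(x)),
             row.names = NULL)
}

setMethod("as.data.frame", "MoveStats",
          function(x, ...) as.data.frame.MoveStats(x, ...))

#' @describeIn MoveStats-class write the statistics table (move_type,
#'   tries, hits, improvements, h, sigma) to a CSV file.
#' @param path output CSV path.
#' @export
writeMoveStats <- function(stats, path) {
  utils::write.csv(as.data.frame(stats), path, row.names = FALSE)
  invisible(path)
}

#' Default try-rate distribution
#'
#' Probabilities with which \code{\link{randomMove}} picks each move type.
#' The slithering snake is tried 5\% of the time and the pull move
#' dominates at 50\% (it is the workhorse semi-local move); the remaining
#' mass is spread over the local and pivot moves.  Only the snake rate is
#' canonical; the others are configurable defaults.
#'
#' @return a named probability vector over the six move types.
#' @export
defaultTryRates <- function() {
  c(end = 0.10, kinkjump = 0.15, crankshaft = 0.10,
    snake = 0.05, pivot = 0.10, pull = 0.50)
}

.checkTryRates <- function(tryRates) {
  if (is.null(names(tryRates)) || !all(.moveTypes %in% names(tryRates))) {
    stop("tryRates must be named with all six move types")
  }
  tryRates <- tryRates[.moveTypes]
  if (any(tryRates < 0) || abs(sum(tryRates) - 1) > 1e-9) {
    stop("tryRates must be non-negative and sum to 1")
  }
  tryRates
}

#' Attempt one randomly chosen move
#'
#' Samples a move type from the try-rate distribution, samples its free
#' parameters uniformly among the legal parameterisations (residue index,
#' terminus, branch, destination) and attempts it, updating the
#' statistics: the try counter always, the hit counter when the move was
#' feasible.  Improvement events are the caller's responsibility (see
#' \code{\link{recordImprovement}}).
#'
#' @param model a self-avoiding \code{\linkS4class{LatticeProtein}}.
#' @param tryRates named probability vector over the move types.
#' @param stats a \code{\linkS4class{MoveStats}}.
#' @return a list with elements \code{outcome} and \code{stats}.
#' @export
randomMove <- function(model, tryRates = defaultTryRates(),
                       stats = newMoveStats()) {
  tryRates <- .checkTryRates(tryRates)
  N <- nrow(model@coords)
  type <- sample(.moveTypes, 1L, prob = tryRates)
  out <- switch(type,
    end = if (N >= 2L) endMove(model, sample(c("first", "last"), 1L))
          else .outcome(FALSE, "end"),
    kinkjump = if (N >= 3L) kinkJump(model, .sampleOne(seq(2L, N - 1L)))
               else .outcome(FALSE, "kinkjump"),
    crankshaft = if (N >= 4L) crankshaftMove(model, sample.int(N - 3L, 1L))
                 else .outcome(FALSE, "crankshaft"),
    snake = if (N >= 2L) slitheringSnake(model, sample(c("first", "last"), 1L))
            else .outcome(FALSE, "snake"),
    pivot = {
      pivotIndex <- sample.int(N, 1L)
      branch <- sample(c("forward", "backward"), 1L)
      empty <- (branch == "forward" && pivotIndex == N) ||
               (branch == "backward" && pivotIndex == 1L)
      if (N >= 2L && !empty) pivotMove(model, pivotIndex, branch)
      else .outcome(FALSE, "pivot")
    },
    pull = {
      branch <- sample(c("forward", "backward"), 1L)
      lo <- if (branch == "forward") 2L else 1L
      hi <- if (branch == "forward") N else N - 1L
      if (N >= 2L) pullMove(model, .sampleOne(seq(lo, hi)), branch)
      else .outcome(FALSE, "pull")
    })
  stats@tries[type] <- stats@tries[type] + 1
  if (out@applied) stats@hits[type] <- stats@hits[type] + 1
  list(outcome = out, stats = stats)
}
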