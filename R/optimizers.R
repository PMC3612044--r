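#' Optimizer result bundle
#'
#' Returned by \code{\link{chainGrowth}}, \code{\link{simulatedAnnealing}}
#' and \code{\link{foldit}}: the best conformation encountered, its HP
#' potential, run/session bookkeeping, move statistics (annealing only)
#' and a potential trace.
#'
#' @slot bestModel the best \code{\linkS4class{LatticeProtein}} found
#'   (\code{NULL} when no run completed).
#' @slot bestPotential its HP potential.
#' @slot sessions number of runs (chain growth) or annealing sessions.
#' @slot fruitfulSessions annealing sessions that improved the best
#'   solution.
#' @slot moveStats a \code{\linkS4class{MoveStats}} or \code{NULL}.
#' @slot trace data frame of (step, potential, best) records.
#' @slot seed the seed used (or \code{NULL}).
#' @slot method \code{"chain_growth"} or \code{"simulated_annealing"}.
#' @name OptimizerResult-class
#' @aliases OptimizerResult-class
#' @exportClass OptimizerResult
setClass("OptimizerResult",
  representation(bestModel = "ANY", bestPotential = "numeric",
                 sessions = "integer", fruitfulSessions = "integer",
                 moveStats = "ANY", trace = "data.frame", seed = "ANY",
                 method = "character"))

setMethod("show", "OptimizerResult", function(object) {
  cat(sprintf("%s result: best potential %g over %d %s\n",
              object@method, object@bestPotential, object@sessions,
              if (object@method == "chain_growth") "runs" else "sessions"))
  if (object@method != "chain_growth") {
    cat(sprintf("fruitful sessions: %d\n", object@fruitfulSessions))
  }
  invisible(object)
})

#' @describeIn OptimizerResult-class best conformation found.
#' @param result an \code{OptimizerResult}.
#' @export
bestModel <- function(result) result@bestModel

#' @describeIn OptimizerResult-class best HP potential found.
#' @export
bestPotential <- function(result) result@bestPotential

#' @describeIn OptimizerResult-class move statistics (annealing).
#' @export
moveStats <- function(result) result@moveStats

#' @describeIn OptimizerResult-class potential trace as a data frame.
#' @export
traceTable <- function(result) result@trace

#' @describeIn OptimizerResult-class number of fruitful annealing
#'   sessions.
#' @export
fruitfulSessions <- function(result) result@fruitfulSessions

#' Metropolis acceptance test
#'
#' Accepts every non-worsening change (\eqn{\Delta E \le 0}); a worsening
#' one is accepted with the Boltzmann probability
#' \eqn{\exp(-\Delta E / (k_B T))}.
#'
#' @param deltaE potential difference of the proposed change.
#' @param temperature current temperature (positive).
#' @param kB Boltzmann constant, taken as 1 by convention.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
metropolisAccept <- function(deltaE, temperature, kB = 1) {
  if (temperature <= 0) stop("temperature must be positive")
  if (deltaE <= 0) return(TRUE)
  stats::runif(1L) < exp(-deltaE / (kB * temperature))
}

# Both the HP potential and the warm-up contact potential from a single
# contact enumeration.
.contactPotentials <- function(model, warmupC) {
  pr <- .contactPairs(model)
  if (!nrow(pr)) return(c(hp = 0, warm = 0))
  res <- .residues(model)
  hh <- sum(res[pr[, 1L]] == "H" & res[pr[, 2L]] == "H")
  c(hp = -hh, warm = sum(warmupC[cbind(res[pr[, 1L]], res[pr[, 2L]])]))
}

# --- chain growth ----------------------------------------------------------

# Per-(lattice, chunk length) tables for the exhaustive chunk enumeration:
# direction-index combinations, cumulative coordinate offsets per slot,
# additive packed offsets, Cartesian offsets, a mask of internally
# self-avoiding chunks and the eligible intra-chunk contact pairs.
.chunkTables <- function(lattice, kk, base) {
  D <- lattice@mainDirs
  c0 <- nrow(D)
  n <- lattice@dim
  idx <- as.matrix(expand.grid(rep(list(seq_len(c0)), kk)))
  off <- vector("list", kk)
  acc <- matrix(0, nrow(idx), n)
  for (s in seq_len(kk)) {
    acc <- acc + D[idx[, s], , drop = FALSE]
    off[[s]] <- acc
  }
  pows <- base^(seq_len(n) - 1L)
  pk <- lapply(off, function(o) drop(o %*% pows))
  cart <- lapply(off, function(o) o %*% t(lattice@basis))
  valid <- rep(TRUE, nrow(idx))
  for (s in seq_len(kk)) {
    valid <- valid & pk[[s]] != 0          # distinct from the chunk's base
    if (s < kk) for (t in seq(s + 1L, kk)) {
      valid <- valid & pk[[s]] != pk[[t]]  # internally self-avoiding
    }
  }
  # intra-chunk non-bonded adjacency (slots two or more apart)
  pairs <- list()
  if (kk >= 3L) {
    for (s in seq_len(kk - 2L)) for (t in seq(s + 2L, kk)) {
      delta <- off[[t]] - off[[s]]
      adj <- if (lattice@kind == "square") rowSums(abs(delta)) == 1
             else pmax(rowSums(pmax(delta, 0)), rowSums(pmax(-delta, 0))) == 1
      pairs[[length(pairs) + 1L]] <- list(s = s, t = t, adj = adj)
    }
  }
  list(idx = idx, off = off, pk = pk, cart = cart, valid = valid,
       pairs = pairs)
}

#' Chain-growth optimizer
#'
#' Builds conformations by repeated exhaustive look-ahead: residue 1 sits
#' at the origin; at every iteration all self-avoiding placements of the
#' next \eqn{k} residues (\eqn{c^k} direction words) are enumerated and
#' scored by the HP potential of the aggregate built so far, the first
#' \eqn{l} steps of a minimum-potential chunk are committed, and the
#' procedure repeats until the chain is complete.  Among minimum-potential
#' chunks, those whose vertices lie on average closest to the centroid of
#' the already placed residues are preferred (compactness tie-break); the
#' surviving ties are broken by a uniform random draw, which is what makes
#' independent runs explore different conformations.  A dead end (no
#' self-avoiding extension) aborts the run.  The result is the best over
#' \code{runs} independent runs and is reproducible given \code{seed}.
#'
#' @param sequence residue string over \code{H}/\code{P}.
#' @param lattice a \code{\linkS4class{Lattice}} (dimension at most 8 for
#'   48-residue chains; the occupancy keys are packed into doubles).
#' @param lookAhead look-ahead parameter \eqn{k \ge 1}.
#' @param commit number of committed steps \eqn{l}, \eqn{1 \le l \le k};
#'   both default to 3.
#' @param runs number of independent runs.
#' @param seed optional integer seed.
#' @return an \code{\linkS4class{OptimizerResult}}; its trace has one row
#'   per completed run.
#' @examples
#' r <- chainGrowth("HPPHHPPH", Lattice("square", 2), runs = 3, seed = 1)
#' bestPotential(r)
#' @export
chainGrowth <- function(sequence, lattice, lookAhead = 3L, commit = lookAhead,
                        runs = 10L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lookAhead <- as.integer(lookAhead); commit <- as.integer(commit)
  if (lookAhead < 1L || commit < 1L || commit > lookAhead) {
    stop("need 1 <= commit <= lookAhead")
  }
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  N <- length(res)
  n <- lattice@dim
  base <- 2L * N + 1L
  if (n * log2(base) > 52) {
    stop("lattice dimension too large for this chain length")
  }
  pows <- base^(seq_len(n) - 1L)
  D <- lattice@mainDirs
  dk <- drop(D %*% pows)
  tables <- lapply(seq_len(lookAhead), function(kk)
    .chunkTables(lattice, kk, base))
  Bt <- t(lattice@basis)

  bestPot <- Inf; bestCoords <- NULL
  trace <- list()
  completed <- 0L
  for (run in seq_len(runs)) {
    m <- matrix(0, N, n)
    keys <- numeric(N); keys[1L] <- 0
    isH <- res == "H"
    placed <- 1L
    sumCart <- numeric(n)
    dead <- FALSE
    while (placed < N) {
      kk <- min(lookAhead, N - placed)
      tb <- tables[[kk]]
      lastKey <- keys[placed]
      occ <- keys[seq_len(placed)]
      ok <- tb$valid
      for (s in seq_len(kk)) {
        ok <- ok & !((lastKey + tb$pk[[s]]) %in% occ)
      }
      cand <- which(ok)
      if (!length(cand)) { dead <- TRUE; break }
      # new H-H contacts of each candidate chunk
      score <- numeric(length(cand))
      hOcc <- occ[isH[seq_len(placed)]]
      for (s in seq_len(kk)) {
        if (!isH[placed + s]) next
        pk <- lastKey + tb$pk[[s]][cand]
        neigh <- outer(pk, dk, "+")
        cnt <- rowSums(matrix(neigh %in% hOcc, nrow = length(pk)))
        if (s == 1L && isH[placed]) cnt <- cnt - 1   # bonded predecessor
        score <- score + cnt
      }
      for (pp in tb$pairs) {
        if (pp$t <= kk && isH[placed + pp$s] && isH[placed + pp$t]) {
          score <- score + pp$adj[cand]
        }
      }
      best <- which(score == max(score))
      if (length(best) > 1L && placed > 1L) {
        # compactness: mean Cartesian distance of chunk vertices to the
        # centroid of the placed aggregate
        centroid <- sumCart / placed
        lastCart <- drop(m[placed, ] %*% Bt)
        dist <- numeric(length(best))
        for (s in seq_len(kk)) {
          pc <- tb$cart[[s]][cand[best], , drop = FALSE]
          pc <- sweep(pc, 2L, lastCart - centroid, "+")
          dist <- dist + sqrt(rowSums(pc^2))
        }
        best <- best[dist <= min(dist) + 1e-9]
      }
      chosen <- cand[.sampleOne(best)]
      nCommit <- min(commit, kk, N - placed)
      for (s in seq_len(nCommit)) {
        m[placed + s, ] <- m[placed, ] + tb$off[[s]][chosen, ]
        keys[placed + s] <- lastKey + tb$pk[[s]][chosen]
      }
      sumCart <- sumCart + colSums(
        matrix(m[placed + seq_len(nCommit), , drop = FALSE] %*% Bt, ncol = n))
      placed <- placed + nCommit
    }
    if (dead) next
    completed <- completed + 1L
    model <- LatticeProtein(sequence, lattice, coords = m)
    pot <- hpPotential(model)
    trace[[length(trace) + 1L]] <- data.frame(step = run, potential = pot)
    if (pot < bestPot) { bestPot <- pot; bestCoords <- m }
  }
  bm <- if (is.null(bestCoords)) NULL
        else LatticeProtein(sequence, lattice, coords = bestCoords)
  new("OptimizerResult",
      bestModel = bm,
      bestPotential = if (is.null(bm)) NA_real_ else as.numeric(bestPot),
      sessions = completed, fruitfulSessions = 0L, moveStats = NULL,
      trace = if (length(trace)) do.call(rbind, trace)
              else data.frame(step = integer(), potential = numeric()),
      seed = seed, method = "chain_growth")
}

# --- simulated annealing ---------------------------------------------------

#' Simulated-annealing optimizer
#'
#' Monte Carlo search over conformations with the generalised move set.
#' A session cools the temperature exponentially (\eqn{T \gets \alpha T})
#' from \code{T0} until it drops below \code{Tf}, attempting
#' \code{stepsPerT} random moves at each temperature with Metropolis
#' acceptance on the potential difference.  The first session starts from
#' the straight-chain conformation; while a session improves the best
#' conformation (it is \emph{fruitful}), another session is started from
#' that best conformation.  During the first half of the temperature steps
#' of the first session the compaction potential
#' (\code{\link{warmupPotentialModel}}) drives the chain towards a
#' globular shape; the pure HP potential is used afterwards, and the best
#' conformation is always tracked under the pure HP potential.
#'
#' @param sequence residue string over \code{H}/\code{P}.
#' @param lattice a \code{\linkS4class{Lattice}}.
#' @param T0,Tf initial and final temperature (defaults 2.0 and 0.15).
#' @param alpha cooling factor in (0, 1) (default 0.97).
#' @param stepsPerT move attempts per temperature; default \code{20 * N}.
#' @param kB Boltzmann constant (default 1).
#' @param tryRates move-type try-rate distribution.
#' @param warmup use the compaction potential early in the first session.
#' @param warmupOther non-HH contact coefficient of the compaction
#'   potential.
#' @param maxSessions safety cap on the number of sessions.
#' @param seed optional integer seed.
#' @return an \code{\linkS4class{OptimizerResult}} carrying the best
#'   conformation under the HP potential, the fruitful-session count, the
#'   move statistics and a per-temperature trace.
#' @export
simulatedAnnealing <- function(sequence, lattice, T0 = 2.0, Tf = 0.15,
                               alpha = 0.97, stepsPerT = NULL, kB = 1,
                               tryRates = defaultTryRates(), warmup = TRUE,
                               warmupOther = -0.25, maxSessions = 50L,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (T0 <= 0 || Tf <= 0 || Tf >= T0) stop("need 0 < Tf < T0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  tryRates <- .checkTryRates(tryRates)
  N <- nchar(sequence)
  if (is.null(stepsPerT)) stepsPerT <- 20L * N
  warmC <- warmupPotentialModel(warmupOther)@coefficients
  temps <- T0 * alpha^(0:floor(log(Tf / T0) / log(alpha)))
  temps <- temps[temps >= Tf]
  nT <- length(temps)

  current <- linearBuild(lattice, sequence)
  curPots <- .contactPotentials(current, warmC)
  best <- current
  bestHP <- curPots["hp"]
  stats <- newMoveStats()
  trace <- vector("list", 0L)
  sessions <- 0L; fruitful <- 0L; step <- 0L
  repeat {
    sessions <- sessions + 1L
    hpAtStart <- bestHP
    for (ti in seq_len(nT)) {
      useWarm <- warmup && sessions == 1L && ti <= nT / 2
      objIdx <- if (useWarm) "warm" else "hp"
      for (s in seq_len(stepsPerT)) {
        rm <- randomMove(current, tryRates, stats)
        stats <- rm$stats
        out <- rm$outcome
        if (!out@applied) next
        candidate <- .replaceCoords(current, out@coords)
        candPots <- .contactPotentials(candidate, warmC)
        dE <- candPots[objIdx] - curPots[objIdx]
        if (metropolisAccept(dE, temps[ti], kB)) {
          current <- candidate
          curPots <- candPots
          # reptation lets the chain drift; re-anchor at the origin so the
          # occupancy keys stay in their fast packed range (all potentials
          # are translation-invariant)
          if (max(abs(current@coords)) > 150) {
            current <- .replaceCoords(
              current, .addPoint(current@coords, -current@coords[1L, ]))
          }
          if (candPots["hp"] < bestHP) {
            bestHP <- candPots["hp"]
            best <- candidate
            stats <- recordImprovement(stats, out@moveType)
          }
        }
      }
      step <- step + 1L
      trace[[length(trace) + 1L]] <- data.frame(
        step = step, session = sessions, temperature = temps[ti],
        potential = unname(curPots["hp"]), best = unname(bestHP))
    }
    improved <- bestHP < hpAtStart
    if (improved) fruitful <- fruitful + 1L
    if (!improved || sessions >= maxSessions) break
    current <- best
    curPots <- .contactPotentials(current, warmC)
  }
  new("OptimizerResult", bestModel = best,
      bestPotential = as.numeric(bestHP), sessions = sessions,
      fruitfulSessions = fruitful, moveStats = stats,
      trace = do.call(rbind, trace), seed = seed,
      method = "simulated_annealing")
}

# --- strategy pattern ------------------------------------------------------

#' Chain-growth optimizer configuration
#'
#' @slot lookAhead,commit,runs,seed see \code{\link{chainGrowth}}.
#' @name CgOptimizer-class
#' @aliases CgOptimizer-class
#' @exportClass CgOptimizer
setClass("CgOptimizer",
  representation(lookAhead = "integer", commit = "integer", runs = "integer",
                 seed = "ANY"))

#' @describeIn CgOptimizer-class constructor.
#' @param lookAhead,commit,runs,seed see \code{\link{chainGrowth}}.
#' @export
CgOptimizer <- function(lookAhead = 3L, commit = 3L, runs = 10L, seed = NULL) {
  new("CgOptimizer", lookAhead = as.integer(lookAhead),
      commit = as.integer(commit), runs = as.integer(runs), seed = seed)
}

#' Simulated-annealing optimizer configuration
#'
#' @slot T0,Tf,alpha,stepsPerT,kB,tryRates,warmup,maxSessions,seed see
#'   \code{\link{simulatedAnnealing}}.
#' @name SaOptimizer-class
#' @aliases SaOptimizer-class
#' @exportClass SaOptimizer
setClass("SaOptimizer",
  representation(T0 = "numeric", Tf = "numeric", alpha = "numeric",
                 stepsPerT = "ANY", kB = "numeric", tryRates = "numeric",
                 warmup = "logical", maxSessions = "integer", seed = "ANY"))

#' @describeIn SaOptimizer-class constructor.
#' @param T0,Tf,alpha,stepsPerT,kB,tryRates,warmup,maxSessions,seed see
#'   \code{\link{simulatedAnnealing}}.
#' @export
SaOptimizer <- function(T0 = 2.0, Tf = 0.15, alpha = 0.97, stepsPerT = NULL,
                        kB = 1, tryRates = defaultTryRates(), warmup = TRUE,
                        maxSessions = 50L, seed = NULL) {
  new("SaOptimizer", T0 = T0, Tf = Tf, alpha = alpha, stepsPerT = stepsPerT,
      kB = kB, tryRates = .checkTryRates(tryRates), warmup = warmup,
      maxSessions = as.integer(maxSessions), seed = seed)
}

#' Attach or query a model's optimizer
#'
#' The folding strategy is pluggable: any optimizer configuration can be
#' bound to a protein model and triggered with \code{\link{foldit}}; the
#' same model can be re-bound to a different optimizer at any time.
#'
#' @param model a \code{\linkS4class{LatticeProtein}}.
#' @return the attached optimizer (or \code{NULL}).
#' @export
optimizer <- function(model) model@optimizer

#' @rdname optimizer
#' @param value a \code{\linkS4class{CgOptimizer}} or
#'   \code{\linkS4class{SaOptimizer}}.
#' @export
`optimizer<-` <- function(model, value) {
  initialize(model, optimizer = value)
}

#' Fold a protein model with its attached (or a given) optimizer
#'
#' Dispatches to the optimizer bound to the model — the strategy-pattern
#' hook — or to an optimizer passed explicitly; the model itself is not
#' modified.
#'
#' @param model a \code{\linkS4class{LatticeProtein}}.
#' @param optimizer optional optimizer configuration overriding the
#'   attached one.
#' @return an \code{\linkS4class{OptimizerResult}}.
#' @examples
#' m <- LatticeProtein("HPPHHPPH", Lattice("square", 2), build = "linear")
#' optimizer(m) <- CgOptimizer(runs = 3, seed = 1)
#' bestPotential(foldit(m))
#' @export
setGeneric("foldit", function(model, optimizer) standardGeneric("foldit"))

.runOptimizer <- function(model, opt) {
  if (is(opt, "CgOptimizer")) {
    chainGrowth(model@sequence, model@lattice, lookAhead = opt@lookAhead,
                commit = opt@commit, runs = opt@runs, seed = opt@seed)
  } else if (is(opt, "SaOptimizer")) {
    simulatedAnnealing(model@sequence, model@lattice, T0 = opt@T0,
                       Tf = opt@Tf, alpha = opt@alpha,
                       stepsPerT = opt@stepsPerT, kB = opt@kB,
                       tryRates = opt@tryRates, warmup = opt@warmup,
                       maxSessions = opt@maxSessions, seed = opt@seed)
  } else {
    stop("unsupported optimizer class: ", class(opt))
  }
}

#' @rdname foldit
setMethod("foldit", signature("LatticeProtein", "missing"),
  function(model, optimizer) {
    if (is.null(model@optimizer)) {
      stop("no optimizer attached to this model; see optimizer<-()")
    }
    .runOptimizer(model, model@optimizer)
  })

#' @rdname foldit
setMethod("foldit", signature("LatticeProtein", "ANY"),
  function(model, optimizer) .runOptimizer(model, optimizer))
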