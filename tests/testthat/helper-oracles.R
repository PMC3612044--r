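# Independent oracles used across the suite.  They deliberately avoid the
# package's own arithmetic shortcuts: shortest paths come from an explicit
# graph search, self-avoidance from a quadratic scan, neighbour counts from
# brute-force distance enumeration.

# Shortest-path distances from the origin to every vertex of the integer box
# [-radius, radius]^n, over the adjacency defined by the direction set D
# (rows).  Built as an igraph graph; returns a named vector keyed by
# comma-separated coordinates.
bfsDistancesFromOrigin <- function(D, radius) {
  n <- ncol(D)
  grid <- do.call(expand.grid, rep(list(seq(-radius, radius)), n))
  pts <- as.matrix(grid)
  key <- apply(pts, 1L, paste, collapse = ",")
  idx <- stats::setNames(seq_len(nrow(pts)), key)
  edges <- list()
  for (r in seq_len(nrow(D))) {
    shifted <- sweep(pts, 2L, D[r, ], "+")
    inside <- rowSums(abs(shifted) > radius) == 0
    from <- which(inside)
    to <- idx[apply(shifted[inside, , drop = FALSE], 1L, paste,
                    collapse = ",")]
    edges[[r]] <- cbind(from, to)
  }
  e <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::simplify(g)
  origin <- idx[paste(rep(0, n), collapse = ",")]
  d <- igraph::distances(g, v = origin)[1L, ]
  stats::setNames(as.numeric(d)[seq_len(nrow(pts))], key)
}

# Quadratic self-avoiding-walk check straight from the definition.
bruteForceSelfAvoiding <- function(lattice, m) {
  N <- nrow(m)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (i < j && all(m[i, ] == m[j, ])) return(FALSE)
    }
  }
  if (N < 2L) return(TRUE)
  D <- mainDirections(lattice)
  for (i in seq_len(N - 1L)) {
    step <- m[i + 1L, ] - m[i, ]
    hit <- FALSE
    for (r in seq_len(nrow(D))) if (all(D[r, ] == step)) hit <- TRUE
    if (!hit) return(FALSE)
  }
  TRUE
}

# Brute-force HP potential: double loop, Euclidean adjacency test.
bruteForceHP <- function(lattice, sequence, m) {
  res <- strsplit(sequence, "")[[1]]
  B <- basisMatrix(latticeKind(lattice), latticeDim(lattice))
  pot <- 0
  N <- nrow(m)
  if (N < 3L) return(0)
  for (i in seq_len(N - 2L)) for (j in seq(i + 2L, N)) {
    if (res[i] == "H" && res[j] == "H" &&
        abs(sqrt(sum((B %*% (m[j, ] - m[i, ]))^2)) - 1) < 1e-9) {
      pot <- pot - 1
    }
  }
  pot
}

# Random HP model on a random self-avoiding walk.
randomModel <- function(lattice, N, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sequence <- paste(sample(c("H", "P"), N, replace = TRUE), collapse = "")
  randomWalkBuild(lattice, sequence)
}

# All origin-anchored self-avoiding walks with `steps` steps on the 2-D
# square lattice (coordinate matrices).
enumerateSquareWalks <- function(steps) {
  D <- mainDirections(Lattice("square", 2))
  walks <- list(matrix(0, 1L, 2L))
  for (s in seq_len(steps)) {
    nxt <- list()
    for (w in walks) {
      last <- w[nrow(w), ]
      for (r in seq_len(nrow(D))) {
        p <- last + D[r, ]
        clash <- any(apply(w, 1L, function(row) all(row == p)))
        if (!clash) nxt[[length(nxt) + 1L]] <- rbind(w, p)
      }
    }
    walks <- nxt
  }
  walks
}

# Canonical run-length compressor (inverse direction of expandHPString).
compressHPString <- function(sequence) {
  r <- rle(strsplit(sequence, "")[[1]])
  paste(mapply(function(l, k) if (k == 1L) l else paste0(l, k),
               r$values, r$lengths), collapse = "")
}
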