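# Internal helpers shared across modules.

# Pack integer coordinate rows into scalar keys for O(1)-style occupancy
# lookups (the hashtable trick that makes self-avoidance checks linear).
# Coordinates are packed positionally in base .packBase, exact in doubles for
# dimensions up to 6 and |coordinate| <= .packHalf; beyond that we fall back
# to string keys.
.packBase <- 401
.packHalf <- 200

.packCoords <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  n <- ncol(m)
  if (n <= 6L && all(abs(m) <= .packHalf)) {
    drop(m %*% .packBase^(seq_len(n) - 1L))
  } else {
    apply(m, 1L, paste, collapse = ",")
  }
}

# Packed representation of direction vectors (no offset needed: packing is
# linear, so key(p + d) = key(p) + .packDirs(d) whenever both pack).
.packDirs <- function(D) {
  drop(D %*% .packBase^(seq_len(ncol(D)) - 1L))
}

# sample() treats a length-1 numeric as 1:x; this never does.
.sampleOne <- function(x) {
  if (length(x) == 1L) x else x[sample.int(length(x), 1L)]
}

.sampleRow <- function(m) {
  m[sample.int(nrow(m), 1L), , drop = TRUE]
}

# Per-lattice memo for quantities that are pure functions of (kind, dim),
# e.g. the pull displacement; avoids re-deriving them inside move loops.
.latticeMemo <- new.env(parent = emptyenv())

.memoGet <- function(lattice, what, compute) {
  key <- paste0(what, ":", lattice@kind, ":", lattice@dim)
  val <- .latticeMemo[[key]]
  if (is.null(val)) {
    val <- compute()
    .latticeMemo[[key]] <- val
  }
  val
}

# Add a point to every row of a direction matrix (fast sweep replacement;
# relies on column-major recycling).
.addPoint <- function(D, p) D + rep(p, each = nrow(D))

.isWholeNumber <- function(x, tol = 1e-6) {
  all(abs(x - round(x)) < tol)
}

.checkVector <- function(p, n, what = "coordinate vector") {
  if (!is.numeric(p) || length(p) != n) {
    stop(sprintf("%s must be a numeric vector of length %d", what, n),
         call. = FALSE)
  }
  if (!.isWholeNumber(p)) {
    stop(sprintf("%s must have integer entries", what), call. = FALSE)
  }
  round(p)
}
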