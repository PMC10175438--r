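# internal geometry and misc helpers

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize zero vector")
  v / n
}

# areas of 3D triangles; V: n x 3 vertices, T: m x 3 indices
.tri_areas <- function(V, Tm) {
  if (nrow(Tm) == 0) return(numeric(0))
  a <- V[Tm[, 1], , drop = FALSE]
  u <- V[Tm[, 2], , drop = FALSE] - a
  w <- V[Tm[, 3], , drop = FALSE] - a
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# signed volume via divergence theorem (triangles oriented outward)
.mesh_signed_volume <- function(V, Tm) {
  if (nrow(Tm) == 0) return(0)
  a <- V[Tm[, 1], , drop = FALSE]
  b <- V[Tm[, 2], , drop = FALSE]
  d <- V[Tm[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
      a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
      a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])) / 6
}

# deterministic 32-bit FNV-1a digest of a character representation,
# used to stamp a configuration fingerprint into reports
.fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "\n")))
  h <- 2166136261 # 0x811c9dc5, kept as double
  p <- 16777619
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), b)
    # 32-bit modular multiply, split to stay within double precision
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

.lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

# order of rows of a matrix in lexicographic order
.lex_order <- function(m) {
  do.call(order, lapply(seq_len(ncol(m)), function(j) m[, j]))
}
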