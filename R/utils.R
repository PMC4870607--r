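# Internal helpers shared across modules.

# Comparison slack when turning a real-valued radius (in voxel units) into a
# threshold on integer squared voxel distances. Keeps "wall exactly at d/2"
# on the permitted side regardless of floating-point representation.
EPS_R2 <- 1e-9

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# FNV-1a 32-bit hash of a character scalar, as 8 hex digits. Used only for
# provenance stamping of reports (no digest package available offline).
fnv1a_hex <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 0x811c9dc5
  for (b in bytes) {
    # xor only touches the low byte (b < 256); keep h as a double mod 2^32
    h <- h - h %% 256 + bitwXor(h %% 256, b)
    # 32-bit multiply by 16777619 without overflow: split into 16-bit halves
    lo <- h %% 65536
    hi <- (h %/% 65536) %% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  # h is a double mod 2^32; format as two 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Shift a 3D array by integer offsets, filling exposed planes with `fill`.
shift_array <- function(a, off, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    o <- off[ax]
    if (abs(o) >= d[ax]) return(out)
    if (o >= 0) {
      dst[[ax]] <- (1 + o):d[ax]
      src[[ax]] <- 1:(d[ax] - o)
    } else {
      dst[[ax]] <- 1:(d[ax] + o)
      src[[ax]] <- (1 - o):d[ax]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}
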