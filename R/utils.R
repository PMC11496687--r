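`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`;
# restores the caller's RNG state afterwards. seed = NULL runs as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a stream of child seeds from a master seed, kept within 32-bit range.
child_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, as.list(sample.int(.Machine$integer.max - 1L, n)))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Voxel lattice coordinates
#'
#' Enumerate the 0-based integer coordinates of every voxel in a 3-D lattice,
#' in column-major (x fastest) order. This ordering is the package's canonical
#' voxel order: all beta arrays and maps index voxels this way.
#'
#' @param dim Integer vector of length 3 (lattice shape).
#' @return Integer matrix with one row per voxel and columns x, y, z.
#' @export
lattice_coords <- function(dim) {
  stopifnot(length(dim) == 3, all(dim >= 1))
  g <- expand.grid(x = seq_len(dim[1]) - 1L,
                   y = seq_len(dim[2]) - 1L,
                   z = seq_len(dim[3]) - 1L)
  as.matrix(g)
}

# Columnwise Pearson correlations between each column of A and each column
# of B (rows = voxels). Returns ncol(A) x ncol(B). Zero-variance columns
# produce NA with a warning suppressed at this level; callers decide.
cor_columns <- function(A, B) {
  suppressWarnings(cor(A, B))
}
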