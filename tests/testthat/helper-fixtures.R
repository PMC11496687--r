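# Shared fixtures and independent brute-force oracles used across test files.

two_designs <- function(seed = 11) {
  list(make_map_design("A", seed = seed),
       make_map_design("B", seed = seed + 1L))
}

small_config <- function(...) {
  ground_truth_config(n_participants = 8, lattice_shape = c(8, 8, 4), ...)
}

# beta_patterns built directly from a participant x condition x voxel array
bp_from_array <- function(vals, conditions, shape, task = "localizer") {
  beta_patterns(vals, conditions, shape, task = task)
}

# ---- independent oracles ---------------------------------------------------

# across-participant reliability by the definition, voxel at a time
brute_reliability <- function(v) {
  P <- dim(v)[1]; V <- dim(v)[3]
  vapply(seq_len(V), function(j) {
    r <- vapply(seq_len(P), function(p) {
      own <- v[p, , j]
      oth <- colMeans(v[-p, , j, drop = FALSE][, , 1, drop = TRUE])
      suppressWarnings(cor(own, oth))
    }, numeric(1))
    mean(r)
  }, numeric(1))
}

# face-connected components by union-find (different algorithm from the
# package's BFS labelling)
brute_cluster_filter <- function(mask, dims, min_cluster) {
  n <- prod(dims)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  co <- lattice_coords(dims)
  idx <- which(mask)
  for (i in idx) {
    for (d in 1:3) {
      nb <- co[i, ]
      nb[d] <- nb[d] + 1L
      if (nb[d] >= dims[d]) next
      j <- nb[1] + nb[2] * dims[1] + nb[3] * dims[1] * dims[2] + 1L
      if (mask[j]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(idx, find, numeric(1))
  sizes <- table(roots)
  keep <- rep(FALSE, n)
  keep[idx] <- sizes[as.character(roots)] >= min_cluster
  keep
}

# directional-distinctness check written independently of the package
brute_distinct <- function(green, blue, max_shared = 2) {
  n <- length(green)
  nb <- function(ord, e, k) ord[((match(e, ord) - 1 + k) %% n) + 1]
  all(vapply(green, function(e) {
    gp <- nb(green, e, c(-2, -1)); gs <- nb(green, e, c(1, 2))
    bp <- nb(blue, e, c(-2, -1)); bs <- nb(blue, e, c(1, 2))
    !any(gp %in% bp) && !any(gs %in% bs) &&
      length(intersect(c(gp, gs), c(bp, bs))) <= max_shared
  }, logical(1)))
}

# all cyclic orders of 1..n with the first element fixed
all_cycles <- function(n) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  lapply(perms(seq_len(n)[-1]), function(p) c(1L, p))
}

# Gaussian-profile matrix for n participants with iid noise; antipode
# duplicated as in real profiles
noisy_profiles <- function(n, A, c, sb, sf, sd = 0.01) {
  base <- asym_gaussian(-4:4, A, c, sb, sf)
  base[1] <- base[9] <- mean(base[c(1, 9)])
  Y <- t(replicate(n, {
    e <- rnorm(8, sd = sd)             # 8 unique slots
    y <- base
    y[2:8] <- y[2:8] + e[1:7]
    y[1] <- y[9] <- y[9] + e[8]
    y
  }))
  Y
}

# exchangeable pure-noise profiles (values iid across the 8 unique slots)
noise_profiles <- function(n, sd = 0.02) {
  Y <- matrix(rnorm(n * 9, sd = sd), n, 9)
  Y[, 1] <- Y[, 9]
  Y
}
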