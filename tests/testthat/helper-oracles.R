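# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the Fourier oracle integrates the piecewise-linear
# parameterization in closed form (no FFT), the VCV oracle walks root-to-tip
# paths, and the raster congruence oracle lives in the package but uses a
# different geometry engine (point-in-polygon counting) than the Clipper
# boolean ops.

# Exact Fourier coefficients of the closed piecewise-linear curve through the
# vertices, parameterized uniformly (t_p = p * T / n): per-segment closed-form
# integrals of (x(t), y(t)) cos/sin, no discrete transform involved.
oracle_efa_uniform <- function(x, y, n_harmonics) {
  n <- length(x)
  dx <- diff(c(x, x[1]))
  dy <- diff(c(y, y[1]))
  t <- seq(0, 2 * pi, length.out = n + 1)  # segment endpoints
  dt <- 2 * pi / n
  coef <- matrix(0, n_harmonics, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  for (h in seq_len(n_harmonics)) {
    dcos <- cos(h * t[-1]) - cos(h * t[-(n + 1)])
    dsin <- sin(h * t[-1]) - sin(h * t[-(n + 1)])
    coef[h, "a"] <- sum((dx / dt) * dcos) / (pi * h^2)
    coef[h, "b"] <- sum((dx / dt) * dsin) / (pi * h^2)
    coef[h, "c"] <- sum((dy / dt) * dcos) / (pi * h^2)
    coef[h, "d"] <- sum((dy / dt) * dsin) / (pi * h^2)
  }
  coef
}

# Brute-force Brownian VCV: shared root-to-MRCA path length for every pair,
# via explicit root-to-tip edge paths.
oracle_vcv <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  path_nodes <- function(tip) {
    nodes <- integer(0)
    node <- tip
    while (node != root) {
      nodes <- c(nodes, node)
      node <- parent[node]
    }
    nodes
  }
  paths <- lapply(seq_len(ntip), path_nodes)
  V <- matrix(0, ntip, ntip,
              dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip)) {
    for (j in seq_len(i)) {
      shared <- intersect(paths[[i]], paths[[j]])
      V[i, j] <- V[j, i] <- sum(elen[shared])
    }
  }
  V
}

shoelace <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# a deterministic random band-limited blob for property loops
random_blob <- function(seed, n_points = 1024, max_harmonic = 12) {
  set.seed(seed)
  k <- sample(2:max_harmonic, 3)
  amp <- runif(3, 0.01, 0.45) * 60 / (2 * k)  # inside the safe bound
  make_shape(shape_spec(axes = c(100, 60),
                        perturb = data.frame(harmonic = k, amplitude = amp,
                                             phase = runif(3, 0, 2 * pi)),
                        n_points = n_points,
                        rotation = runif(1, 0, pi)),
             source_id = paste0("blob", seed))
}
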