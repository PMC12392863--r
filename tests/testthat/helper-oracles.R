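# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: adaptive quadrature instead of fixed
# Gauss-Legendre nodes, graph components instead of sorted chaining, a
# rotation-parameter search instead of the SVD superposition.

sinc_safe <- function(x) ifelse(abs(x) < 1e-8, 1, sin(x) / x)

# Orientation-averaged circular-cylinder form factor (single adaptive
# integral over the tilt angle).
circular_cylinder_oracle <- function(q, R, L, sigma_surf = 0) {
  vapply(q, function(qi) {
    if (qi == 0) return(1)
    f <- function(a) {
      u <- qi * R * sin(a)
      amp <- ifelse(u < 1e-8, 1, 2 * besselJ(u, 1) / u) *
        sinc_safe(qi * L * cos(a) / 2) *
        exp(-(qi * sin(a))^2 * sigma_surf^2 / 2)
      amp^2 * sin(a)
    }
    stats::integrate(f, 0, pi / 2, subdivisions = 5000L,
                     rel.tol = 1e-12)$value
  }, numeric(1))
}

# Brute-force pairwise single-linkage partition of genes into clusters:
# connect any two genes on the same contig whose boundary gap is below the
# threshold, then take connected components.
brute_force_clusters <- function(genes, max_gap_bp) {
  n <- nrow(genes)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (genes$contig_id[i] != genes$contig_id[j] ||
        genes$genome_id[i] != genes$genome_id[j]) next
    left <- if (genes$start[i] <= genes$start[j]) i else j
    right <- if (left == i) j else i
    gap <- genes$start[right] - genes$end[left] - 1
    if (gap < max_gap_bp) adj[i, j] <- TRUE
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  split(genes$gene_id, comp)
}

# Minimal RMSD by direct search over rotations (Euler angles), independent
# of the SVD construction: multi-start Nelder-Mead over the 3 angles with
# optimal translation absorbed by centering.
brute_force_rmsd <- function(A, B) {
  Ac <- scale(A, scale = FALSE)
  Bc <- scale(B, scale = FALSE)
  rot <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(mean(rowSums((Bc - Ac %*% t(rot(ang)))^2)))
  best <- Inf
  starts <- as.matrix(expand.grid(a = c(0, pi / 2, pi, 3 * pi / 2),
                                  b = c(-pi / 3, 0, pi / 3, 2),
                                  c = c(0, pi / 2, pi, 3 * pi / 2)))
  for (k in seq_len(nrow(starts))) {
    o <- stats::optim(starts[k, ], obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

# Small rigid helper: random rotation matrix from a seeded QR.
random_rotation <- function(seed) {
  withr::with_seed(seed, {
    M <- matrix(stats::rnorm(9), 3, 3)
    Q <- qr.Q(qr(M))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    Q
  })
}
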