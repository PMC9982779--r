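# Independent oracles and tiny fixture builders used across the suite.
# Each oracle is a deliberately naive re-implementation (explicit formulas,
# exhaustive loops) kept independent of the package code paths it checks.

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

# uniform random rotation via QR with positive diagonal, det fixed to +1
rand_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# explicit Gram-Schmidt projection: component of v orthogonal to unit z
oracle_orthogonalize <- function(v, z) {
  w <- v - as.numeric(crossprod(v, z)) * z
  w / sqrt(sum(w^2))
}

# Kabsch RMSD via SVD, from scratch
oracle_kabsch_rmsd <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  s <- svd(crossprod(B, A))          # H = B^T A = U S V^T
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)  # rotation applied to row vectors of B
  sqrt(mean(rowSums((A - B %*% R)^2)))
}

# exhaustive re-implementation of the neighbour-counting clustering loop
oracle_gromos <- function(mat, cutoff, max_clusters) {
  n <- nrow(mat)
  id <- rep(-1L, n); pool <- seq_len(n); k <- 0L
  medoids <- integer(0)
  while (length(pool) > 0 && k < max_clusters) {
    best <- -1L; best_i <- NA_integer_
    for (i in pool) {
      cnt <- sum(mat[i, pool] <= cutoff)
      if (cnt > best) { best <- cnt; best_i <- i }
    }
    members <- pool[mat[best_i, pool] <= cutoff]
    k <- k + 1L
    id[members] <- k
    medoids <- c(medoids, best_i)
    pool <- setdiff(pool, members)
  }
  list(id = id, medoids = medoids)
}

# exhaustive O(N^2) minimum pair distance
oracle_min_dist <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
  best
}

# exhaustive pair-count contacts for one residue's atoms vs a group
oracle_contact_count <- function(A, B, cutoff) {
  n <- 0L
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    if (sqrt(sum((A[i, ] - B[j, ])^2)) <= cutoff) n <- n + 1L
  n
}

# signed torsion via an independent formulation (acos magnitude + IUPAC sign
# from the scalar triple product)
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) c(a[2]*b[3]-a[3]*b[2], a[3]*b[1]-a[1]*b[3], a[1]*b[2]-a[2]*b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(max(-1, min(1, cosang))) * 180 / pi
  if (sum(cr(n1, n2) * b2) < 0) ang <- -ang
  ang
}

# minimal hand-built ensemble from a list of N x 3 coordinate frames
tiny_traj <- function(frames, elety = NULL, chain = NULL, resno = NULL,
                      elesy = NULL) {
  n <- nrow(frames[[1]])
  top <- data.frame(
    elety = if (is.null(elety)) rep("CA", n) else elety,
    resid = "UNK",
    chain = if (is.null(chain)) rep("A", n) else chain,
    resno = if (is.null(resno)) seq_len(n) else resno,
    elesy = if (is.null(elesy)) rep("C", n) else elesy)
  xyz <- do.call(rbind, lapply(frames, function(m) as.numeric(t(m))))
  traj_ensemble(top, xyz)
}

# hand-built axis-aligned antibody-like frame for geometry unit tests
axis_toy <- function() {
  coords <- rbind(
    c(0.2, 0, 0), c(-0.2, 0, 0),                 # hinge (centroid at origin)
    c(0.3, 0, -1), c(-0.3, 0, -1),               # Fc column
    c(0.3, 0, -2), c(-0.3, 0, -2),
    c(0.3, 0, -3), c(-0.3, 0, -3),
    c(-1, 0, -1.5),                              # CH2_A
    c(1, 0, -1.5),                               # CH2_B
    c(1.5, 0, 2.5), c(2.5, 0, 3.5),              # Fab1 (centroid (2,0,3))
    c(-1.5, 0, 2.5), c(-2.5, 0, 3.5))            # Fab2
  groups <- atom_groups(list(hinge = 1:2, Fc = 3:8, CH2_A = 9L, CH2_B = 10L,
                             Fab1 = 11:12, Fab2 = 13:14), nrow(coords))
  list(coords = coords, groups = groups)
}
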