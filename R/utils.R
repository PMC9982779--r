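# Boltzmann constant, kcal/mol/K
.kB <- 0.0019872041

.deg <- 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Wrap angles to (-180, 180] degrees
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped into the half-open interval (-180, 180].
#' @export
wrap_deg <- function(x) {
  w <- x %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

# frame f of an xyz matrix as an N x 3 coordinate matrix
frame_coords <- function(xyz, f) {
  matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
}

coords_to_row <- function(m) as.numeric(t(m))

group_centroid <- function(coords, idx) {
  colMeans(coords[idx, , drop = FALSE])
}

#' Torsion angle from four points
#'
#' Standard signed dihedral about the b-c axis, in degrees, range (-180, 180].
#'
#' @param a,b,c,d length-3 coordinate vectors.
#' @return dihedral angle in degrees.
#' @export
dihedral_deg <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  # IUPAC sign: positive for a clockwise far-bond rotation viewed along b-c
  wrap_deg(atan2(sum(cross3(n1, n2) * b2) / vnorm(b2), sum(n1 * n2)) * .deg)
}

# random rotation matrix (uniform over SO(3)) -- used by the generator
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3L, byrow = TRUE)
}
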