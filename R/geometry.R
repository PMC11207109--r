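## Low-level vector geometry shared across the package. All coordinates are
## in Angstroms, all angles in degrees unless noted.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("degenerate zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Torsion angle defined by four points
#'
#' Signed dihedral about the p2-p3 axis, using the IUPAC sign convention
#' (looking from p2 to p3, clockwise rotation of p4 relative to p1 is
#' positive). Result lies in [-180, 180).
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (Angstrom).
#' @return Angle in degrees in [-180, 180).
#' @export
torsionAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  wrapAngle(ang)
}

## wrap into [-180, 180)
wrapAngle <- function(a) {
  a <- (a + 180) %% 360
  a - 180
}

## reduce into [0, 360)
wrapAngle360 <- function(a) a %% 360

## Place an atom from three reference positions using internal coordinates
## (NeRF construction): distance r to a, angle theta at a against b,
## dihedral phi about the a-b axis measured against c.
placeAtom <- function(a, b, c, r, theta, phi) {
  th <- theta * pi / 180
  ph <- phi * pi / 180
  bc <- unitv(a - b)
  n <- unitv(cross3(c - b, bc))
  m <- cross3(n, bc)
  d <- c(-r * cos(th), -r * sin(th) * cos(ph), r * sin(th) * sin(ph))
  a + d[1L] * bc + d[2L] * m + d[3L] * n
}

## Random rotation matrix (uniform over SO(3)) -- used by property tests
## and the fixture generator.
randomRotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    n <- vnorm(q)
    if (n > 1e-8) break
  }
  q <- q / n
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3L, byrow = TRUE)
}

## Rotation by `angle` degrees about unit axis u (Rodrigues).
axisRotation <- function(u, angle) {
  u <- unitv(u)
  th <- angle * pi / 180
  K <- matrix(c(0, -u[3L], u[2L], u[3L], 0, -u[1L], -u[2L], u[1L], 0),
              nrow = 3L, byrow = TRUE)
  diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

## Evenly distributed unit sphere points (deterministic golden-spiral set).
spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
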