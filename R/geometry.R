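# Internal rigid-body and internal-coordinate geometry used across modules.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("zero-length vector")
  v / n
}

# Rotation matrix for angle theta (radians) about unit axis u (Rodrigues).
rotation_about_axis <- function(u, theta) {
  u <- unit(u)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Kabsch: optimal rotation R and translation t with y ~ x %*% R + t
# (rows are points). Returns list(R, t, rmsd).
kabsch <- function(x, y) {
  stopifnot(nrow(x) == nrow(y), nrow(x) >= 3)
  cx <- colMeans(x)
  cy <- colMeans(y)
  xc <- sweep(x, 2, cx)
  yc <- sweep(y, 2, cy)
  s <- svd(crossprod(xc, yc))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  t <- cy - as.numeric(cx %*% R)
  fit <- sweep(xc %*% R, 2, cy, "+")
  list(R = R, t = t, rmsd = sqrt(mean(rowSums((fit - y)^2))))
}

# Dihedral angle (degrees, in (-180, 180]) defined by points p1..p4.
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / vnorm(b2)
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Place a new atom D at bond length r from C, bond angle theta (deg, B-C-D)
# and dihedral chi (deg, A-B-C-D). Natural extension reference frame.
place_atom <- function(a, b, c, r, theta, chi) {
  theta <- theta * pi / 180
  chi <- chi * pi / 180
  bc <- unit(c - b)
  ab <- b - a
  n <- unit(c(ab[2] * bc[3] - ab[3] * bc[2],
              ab[3] * bc[1] - ab[1] * bc[3],
              ab[1] * bc[2] - ab[2] * bc[1]))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-r * cos(theta),
          r * sin(theta) * cos(chi),
          -r * sin(theta) * sin(chi))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build an idealized peptide backbone from dihedral angles
#'
#' Constructs N, CA, C backbone coordinates for a polypeptide with the
#' supplied phi/psi dihedrals and trans peptide bonds (omega = 180 deg),
#' using standard bond lengths (N-CA 1.458, CA-C 1.525, C-N 1.329 A) and
#' angles (N-CA-C 111.2, CA-C-N 116.2, C-N-CA 121.7 deg). Used to
#' synthesize reference secondary structures (ideal strands, helices) for
#' testing dihedral-based strand assignment.
#'
#' @param phi,psi numeric vectors of backbone dihedrals in degrees, one per
#'   residue (`phi[1]` and `psi[n]` are not geometrically defined and are
#'   ignored, but the vectors must have equal length).
#' @param chain chain label for the output model.
#' @param resno_start first residue number.
#' @return an [atomic_model()] with N, CA, C atoms per residue (GLY).
#' @examples
#' strand <- build_backbone(rep(-120, 6), rep(120, 6))
#' @export
build_backbone <- function(phi, psi, chain = "A", resno_start = 1L) {
  n <- length(phi)
  stopifnot(n == length(psi), n >= 2)
  xyz <- matrix(NA_real_, nrow = 3 * n, ncol = 3)
  # seed first residue in a canonical pose
  xyz[1, ] <- c(0, 0, 0)                     # N1
  xyz[2, ] <- c(1.458, 0, 0)                 # CA1
  ang <- (180 - 111.2) * pi / 180
  xyz[3, ] <- xyz[2, ] + 1.525 * c(cos(ang), sin(ang), 0)  # C1
  for (i in seq_len(n - 1L)) {
    b <- 3L * (i - 1L)
    # N(i+1): dihedral psi(i) about CA(i)-C(i)
    xyz[b + 4L, ] <- place_atom(xyz[b + 1L, ], xyz[b + 2L, ], xyz[b + 3L, ],
                                1.329, 116.2, psi[i])
    # CA(i+1): omega = 180
    xyz[b + 5L, ] <- place_atom(xyz[b + 2L, ], xyz[b + 3L, ], xyz[b + 4L, ],
                                1.458, 121.7, 180)
    # C(i+1): dihedral phi(i+1) about N(i+1)-CA(i+1)
    xyz[b + 6L, ] <- place_atom(xyz[b + 3L, ], xyz[b + 4L, ], xyz[b + 5L, ],
                                1.525, 111.2, phi[i + 1L])
  }
  atomic_model(data.frame(
    elety = rep(c("N", "CA", "C"), n),
    resid = "GLY",
    resno = rep(seq.int(resno_start, length.out = n), each = 3L),
    chain = chain,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE))
}
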