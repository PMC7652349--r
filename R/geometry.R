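# Rigid-body geometry primitives shared across the pipeline.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Optimal rigid superposition of two coordinate sets (Kabsch algorithm)
#'
#' Finds the proper rotation and translation that minimise the
#' root-mean-square deviation between paired points, using the
#' SVD formulation with the determinant sign correction so that the
#' returned rotation is always proper (no reflection).
#'
#' @param P numeric matrix, n x 3; the mobile coordinate set.
#' @param Q numeric matrix, n x 3; the fixed (reference) coordinate set.
#' @return list with `rotation` (3x3, det = +1), `translation` (length 3),
#'   `rmsd` (Angstrom), `transformed` (P after superposition onto Q) and
#'   `degenerate` (TRUE when the point set is collinear or smaller than the
#'   rank needed to fix the rotation uniquely; the RMSD is still valid).
#' @details The transform maps a mobile point x to
#'   `x %*% t(rotation) + translation`. Requires n >= 3.
#' @examples
#' P <- matrix(rnorm(30), 10, 3)
#' fit <- kabsch_superpose(P, P)
#' stopifnot(fit$rmsd < 1e-12)
#' @export
kabsch_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!is.numeric(P) || !is.numeric(Q) || ncol(P) != 3L || ncol(Q) != 3L)
    stop("P and Q must be numeric n x 3 matrices")
  if (nrow(P) != nrow(Q)) stop("coordinate sets differ in length")
  if (nrow(P) < 3L) stop("need at least 3 points for superposition")
  if (anyNA(P) || anyNA(Q)) stop("coordinates contain missing values")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Pr <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Pr - Qc)^2)))
  # collinear sets leave the rotation about the line undetermined
  degenerate <- sv$d[2] < 1e-8 * max(sv$d[1], 1e-12)
  list(rotation = R,
       translation = as.numeric(cq - R %*% cp),
       rmsd = rmsd,
       transformed = sweep(Pr, 2, cq, `+`),
       degenerate = degenerate)
}

#' Apply a rigid transform to coordinates
#'
#' @param X n x 3 matrix (rows with NA pass through unchanged).
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 vector.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(X, rotation, translation) {
  X <- as.matrix(X)
  ok <- !is.na(X[, 1L])
  X[ok, ] <- sweep(X[ok, , drop = FALSE] %*% t(rotation), 2, translation, `+`)
  X
}

# Ideal C-beta from backbone N/CA/C using fixed tetrahedral internal
# geometry (the standard pseudo-CB construction; 1.53 A effective bond).
ideal_cb <- function(n, ca, c) {
  b <- ca - n
  g <- c - ca
  a <- cross3(b, g)
  ca + (-0.58273431 * a + 0.56802827 * b - 0.54067466 * g)
}

# Signed dihedral angle p1-p2-p3-p4 in degrees.
dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

cross_rows <- function(A, B) {
  cbind(A[, 2L] * B[, 3L] - A[, 3L] * B[, 2L],
        A[, 3L] * B[, 1L] - A[, 1L] * B[, 3L],
        A[, 1L] * B[, 2L] - A[, 2L] * B[, 1L])
}

# Classify per-residue local geometry from the CA trace using CA virtual
# torsions (CA i-1..i+2) and the CA(i)-CA(i+3) distance. Returns a vector
# of "H"/"E"/"L" with NA at positions where the torsion is undefined.
# Fully vectorised: it sits inside the Monte Carlo scoring loop.
classify_ss_ca <- function(ca) {
  n <- nrow(ca)
  out <- rep(NA_character_, n)
  if (n < 4L) return(out)
  i <- 2:(n - 2L)
  p1 <- ca[i - 1L, , drop = FALSE]; p2 <- ca[i, , drop = FALSE]
  p3 <- ca[i + 1L, , drop = FALSE]; p4 <- ca[i + 2L, , drop = FALSE]
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross_rows(b1, b2); n2 <- cross_rows(b2, b3)
  b2u <- b2 / pmax(sqrt(rowSums(b2^2)), 1e-12)
  m1 <- cross_rows(n1, b2u)
  th <- atan2(rowSums(m1 * n2), rowSums(n1 * n2)) * 180 / pi
  d13 <- rep(NA_real_, length(i))
  ok3 <- i + 3L <= n
  d13[ok3] <- sqrt(rowSums((ca[i[ok3] + 3L, , drop = FALSE] -
                            ca[i[ok3], , drop = FALSE])^2))
  cls <- rep("L", length(i))
  cls[!is.na(th) & th > 20 & th < 80 & (is.na(d13) | d13 < 7)] <- "H"
  cls[!is.na(th) & abs(th) > 140 & (is.na(d13) | d13 > 8)] <- "E"
  cls[is.na(th)] <- NA_character_
  out[i] <- cls
  out
}
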