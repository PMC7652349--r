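# Independent oracles, kept free of the implementation paths they check.

# Quaternion (Horn) superposition RMSD: maximal eigenvalue of the 4x4 key
# matrix built from the correlation of the centred coordinate sets.
quaternion_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  M <- crossprod(Pc, Qc)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       Syy - Sxx - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       Szz - Sxx - Syy),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  e <- sum(Pc^2) + sum(Qc^2) - 2 * lam
  sqrt(max(e, 0) / nrow(P))
}

# random proper rotation matrix
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# regex-based span oracle, independent of topology_to_span's run scanning
span_oracle <- function(topo) {
  m <- gregexpr("M+", topo)[[1]]
  if (m[1] == -1) return(NULL)
  cbind(start = as.integer(m), end = as.integer(m) + attr(m, "match.length") - 1L)
}

# brute-force per-column identity count
identity_oracle <- function(row_i, row_j) {
  a <- strsplit(row_i, "")[[1]]
  b <- strsplit(row_j, "")[[1]]
  n_both <- 0; n_same <- 0
  for (k in seq_along(a)) {
    if (a[k] != "-" && b[k] != "-") {
      n_both <- n_both + 1
      if (a[k] == b[k]) n_same <- n_same + 1
    }
  }
  if (n_both == 0) return(NA_real_)
  100 * n_same / n_both
}

random_aa_string <- function(n) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y"), n, TRUE),
        collapse = "")
}
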