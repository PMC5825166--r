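#' Anisotropic network model of C-alpha coordinates
#'
#' Builds the 3N x 3N ANM Hessian with a distance-dependent spring constant
#' and diagonalizes it. For a contacting pair (i, j) at distance d the
#' off-diagonal 3 x 3 superblock is -gamma(d)/d^2 * r r^T (r the
#' inter-bead vector); diagonal superblocks are the negated sums of the
#' row's off-diagonals, so each Hessian row sums to zero across
#' superblocks (translation invariance).
#'
#' @param xyz N x 3 C-alpha coordinates (Angstrom).
#' @param cutoff contact cutoff in Angstrom (default 15, inclusive).
#' @param gamma spring-constant function of distance; the default
#'   `gamma(d) = (d0/d)^2` with `d0 = 1` makes closer contacts stiffer.
#' @return object of class `anm`: `xyz`, `cutoff`, `hessian`, `values`
#'   (eigenvalues ascending), `vectors` (columns match `values`),
#'   `zero_modes` (indices of numerically zero modes).
#' @export
build_anm <- function(xyz, cutoff = 15, gamma = function(d) 1 / d^2) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (n < 2) stop("degeneracy error: need at least 2 beads")
  # the two-bead dimer is a well-defined special case (one stretch mode);
  # larger collinear systems have no transverse restoring force
  if (n > 2 && sum(svd(sweep(xyz, 2, colMeans(xyz)))$d > 1e-8) < 2)
    stop("degeneracy error: collinear bead geometry")
  D <- as.matrix(stats::dist(xyz))
  H <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- D[i, j]
      if (d > cutoff || d == 0) next
      r <- xyz[j, ] - xyz[i, ]
      blk <- -(gamma(d) / d^2) * tcrossprod(r)
      bi <- (3 * i - 2):(3 * i); bj <- (3 * j - 2):(3 * j)
      H[bi, bj] <- blk
      H[bj, bi] <- blk
      H[bi, bi] <- H[bi, bi] - blk
      H[bj, bj] <- H[bj, bj] - blk
    }
  }
  e <- eigen(H, symmetric = TRUE)
  values <- rev(e$values)
  vectors <- e$vectors[, rev(seq_len(3 * n)), drop = FALSE]
  zero <- which(values < 1e-8 * max(values))
  if (length(zero) > 6)
    warning("disconnected contact graph: ", length(zero), " zero modes")
  structure(list(xyz = xyz, cutoff = cutoff, gamma = gamma, hessian = H,
                 values = values, vectors = vectors, zero_modes = zero),
            class = "anm")
}

#' @export
print.anm <- function(x, ...) {
  cat("anm: ", nrow(x$xyz), " beads, cutoff ", x$cutoff, " A, ",
      length(x$zero_modes), " zero modes\n", sep = "")
  invisible(x)
}

#' Select the low-frequency modes carrying 80% of the variance
#'
#' Mode variance is proportional to 1/lambda over the strictly positive
#' modes; modes are taken in ascending-lambda order until the cumulative
#' variance fraction reaches `fraction`.
#'
#' @param m an [build_anm] model.
#' @param fraction cumulative variance target (default 0.8).
#' @return integer vector of mode indices (into `m$values`).
#' @export
select_modes_80 <- function(m, fraction = 0.8) {
  nz <- setdiff(seq_along(m$values), m$zero_modes)
  v <- 1 / m$values[nz]
  cf <- cumsum(v) / sum(v)
  nz[seq_len(which(cf >= fraction)[1])]
}

#' Per-residue summed square fluctuations
#'
#' `flucs(i) = sum_k (1/lambda_k) |v_k(i)|^2` over the selected modes,
#' `v_k(i)` the 3-vector of mode k at residue i.
#'
#' @param m an [build_anm] model.
#' @param modes mode indices (must be non-zero modes).
#' @return numeric vector of length N (arbitrary units, >= 0).
#' @export
square_fluctuations <- function(m, modes = select_modes_80(m)) {
  if (any(modes %in% m$zero_modes)) stop("modes must exclude zero modes")
  n <- nrow(m$xyz)
  V <- m$vectors[, modes, drop = FALSE]
  W <- sweep(V^2, 2, m$values[modes], "/")
  rs <- rowSums(W)
  rs[seq(1, 3 * n, 3)] + rs[seq(2, 3 * n, 3)] + rs[seq(3, 3 * n, 3)]
}

#' Trim chain termini and z-score a fluctuation profile
#'
#' Drops `trim` residues at each end (the termini dominate raw elastic
#' network fluctuations) and z-scores the remainder.
#'
#' @param f per-residue fluctuation values in chain order.
#' @param trim residues removed per terminus (default 5).
#' @return object of class `fluctuation_profile`: `raw` (input), `kept`
#'   (indices retained), `normalized` (z-scores over `kept`).
#' @export
normalize_fluctuations <- function(f, trim = 5) {
  f <- as.numeric(f)
  if (length(f) <= 2 * trim)
    stop("trim error: chain too short for ", trim, "+", trim, " trimming")
  kept <- (trim + 1):(length(f) - trim)
  structure(list(raw = f, kept = kept,
                 normalized = normalize_profile(f[kept]), trim = trim),
            class = "fluctuation_profile")
}

#' Residue-residue cross-correlation matrix
#'
#' `C_ij = sum_k (1/lambda_k) v_k(i).v_k(j)` normalized by
#' `sqrt(C_ii C_jj)` over the same mode set; entries lie in \[-1, 1\] with
#' unit diagonal.
#'
#' @param m an [build_anm] model.
#' @param modes mode indices.
#' @return N x N symmetric matrix.
#' @export
cross_correlation <- function(m, modes = select_modes_80(m)) {
  if (any(modes %in% m$zero_modes)) stop("modes must exclude zero modes")
  n <- nrow(m$xyz)
  U <- sweep(m$vectors[, modes, drop = FALSE], 2,
             sqrt(m$values[modes]), "/")
  C <- tcrossprod(U[seq(1, 3 * n, 3), , drop = FALSE]) +
       tcrossprod(U[seq(2, 3 * n, 3), , drop = FALSE]) +
       tcrossprod(U[seq(3, 3 * n, 3), , drop = FALSE])
  dn <- sqrt(diag(C))
  C <- C / tcrossprod(dn)
  C[C > 1] <- 1; C[C < -1] <- -1
  C
}

#' Rv coefficient between two symmetric matrices
#'
#' A matrix-level generalization of the Pearson correlation:
#' `Rv = trace(AB) / sqrt(trace(AA) trace(BB))`.
#'
#' @param A,B symmetric matrices of equal size.
#' @return scalar; 1 when the matrices are proportional.
#' @export
rv_coefficient <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) stop("shape error: matrices differ in size")
  na <- sum(A * A); nb <- sum(B * B)
  if (na == 0 || nb == 0) stop("undefined error: zero matrix")
  sum(A * B) / sqrt(na * nb)
}

#' Fraction of strongly coupled residue pairs
#'
#' Fraction of off-diagonal unordered pairs with `|C_ij| >= threshold`.
#'
#' @param C a cross-correlation matrix.
#' @param threshold coupling threshold (default 0.7, inclusive).
#' @return fraction in \[0, 1\].
#' @export
coupling_fraction <- function(C, threshold = 0.7) {
  ut <- C[upper.tri(C)]
  if (length(ut) == 0) return(0)
  mean(abs(ut) >= threshold)
}
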