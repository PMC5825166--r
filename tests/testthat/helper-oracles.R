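# Independent oracles used across the suite. Each one recomputes the
# quantity by a different route than the package (series summation,
# numeric differentiation, exhaustive enumeration, direct search).

# communicability centrality by truncated walk summation: sum_k (A^k)_ii/k!
oracle_communicability <- function(A, kmax = 30) {
  n <- nrow(A)
  out <- diag(n)          # k = 0 term
  P <- diag(n)
  for (k in 1:kmax) {
    P <- P %*% A
    out <- out + P / factorial(k)
  }
  diag(out)
}

# ENM energy E = 1/2 sum_contacts gamma(d0) (d - d0)^2 and its numeric
# Hessian by central differences
enm_energy <- function(x, x0, cutoff = 15, gamma = function(d) 1 / d^2) {
  n <- nrow(x0)
  D0 <- as.matrix(dist(x0))
  e <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (D0[i, j] > cutoff) next
    d <- sqrt(sum((x[i, ] - x[j, ])^2))
    e <- e + 0.5 * gamma(D0[i, j]) * (d - D0[i, j])^2
  }
  e
}

oracle_numeric_hessian <- function(x0, cutoff = 15,
                                   gamma = function(d) 1 / d^2,
                                   h = 1e-4) {
  n3 <- 3 * nrow(x0)
  H <- matrix(0, n3, n3)
  flat <- function(v) matrix(v, ncol = 3, byrow = TRUE)
  v0 <- as.numeric(t(x0))
  for (a in seq_len(n3)) for (b in a:n3) {
    vpp <- v0; vpp[a] <- vpp[a] + h; vpp[b] <- vpp[b] + h
    vpm <- v0; vpm[a] <- vpm[a] + h; vpm[b] <- vpm[b] - h
    vmp <- v0; vmp[a] <- vmp[a] - h; vmp[b] <- vmp[b] + h
    vmm <- v0; vmm[a] <- vmm[a] - h; vmm[b] <- vmm[b] - h
    H[a, b] <- H[b, a] <-
      (enm_energy(flat(vpp), x0, cutoff, gamma) -
       enm_energy(flat(vpm), x0, cutoff, gamma) -
       enm_energy(flat(vmp), x0, cutoff, gamma) +
       enm_energy(flat(vmm), x0, cutoff, gamma)) / (4 * h^2)
  }
  H
}

# GDT by exhaustive enumeration over all residue subsets of size >= 4:
# superpose on the subset, count residues within the cutoff
oracle_gdt <- function(xa, xb, cutoff = 4) {
  n <- nrow(xa)
  best <- 0L
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) < 4) next
    sup <- tryCatch(kabsch_superpose(xa[idx, , drop = FALSE],
                                     xb[idx, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(sup)) next
    d <- sqrt(rowSums((xa - apply_superposition(sup, xb))^2))
    best <- max(best, sum(d <= cutoff))
  }
  100 * best / n
}

# KS D statistic by direct ECDF evaluation at every pooled point
oracle_ks_d <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# best-fit RMSD by rotation grid search plus Nelder-Mead refinement,
# never using the package's Kabsch path
oracle_min_rmsd <- function(xa, xb, coarse = 10) {
  A <- sweep(xa, 2, colMeans(xa))
  B <- sweep(xb, 2, colMeans(xb))
  rotmat <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
    Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(mean(rowSums((A - B %*% rotmat(ang))^2)))
  step <- coarse * pi / 180
  grid <- expand.grid(a = seq(0, 2 * pi - step, by = step),
                      b = seq(0, pi, by = step),
                      c = seq(0, 2 * pi - step, by = step))
  vals <- apply(grid, 1, obj)
  start <- as.numeric(grid[which.min(vals), ])
  opt <- optim(start, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 5000))
  opt$value
}

# a reproducible proper rotation for fixtures
rotation_about_axis_test <- function(seed) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0.2, 2.5)
  c_ <- cos(ang); s_ <- sin(ang)
  c_ * diag(3) + s_ * rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]),
                            c(-ax[2], ax[1], 0)) + (1 - c_) * tcrossprod(ax)
}

# ideal helix C-alpha trace (rise 1.5 A, 100 deg/residue, 3.8 A spacing)
helix_coords <- function(n) {
  theta <- (seq_len(n) - 1) * 100 * pi / 180
  radius <- sqrt(3.8^2 - 1.5^2) / (2 * sin(50 * pi / 180))
  cbind(radius * cos(theta), radius * sin(theta), 1.5 * (seq_len(n) - 1))
}

# minimal hand-built PDB text
pdb_text <- function(lines) paste(c(lines, "END"), collapse = "\n")

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1, elem = substr(name, 1, 1),
                          record = "ATOM", alt = " ") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, alt, resname, chain, resno, x, y, z,
          occ, 0, elem)
}

# three-residue glycine strand along x, CA spacing 3.8 A
tiny_pdb <- function() {
  pdb_text(vapply(1:3, function(i)
    pdb_atom_line(i, "CA", "GLY", "A", i, 3.8 * (i - 1), 0, 0),
    character(1)))
}
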