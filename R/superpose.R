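#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of `xb` onto `xa` by SVD of the covariance
#' matrix, with the reflection branch excluded so the rotation is proper
#' (determinant +1).
#'
#' @param xa,xb N x 3 coordinate matrices in 1:1 correspondence (Angstrom).
#' @return object of class `superposition`: list with `rotation` (3 x 3),
#'   `translation` (length 3) and `rmsd`; the fitted coordinates are
#'   `xb %*% rotation + translation` (rows).
#' @export
kabsch_superpose <- function(xa, xb) {
  xa <- as.matrix(xa); xb <- as.matrix(xb)
  if (!all(dim(xa) == dim(xb)) || ncol(xa) != 3)
    stop("coordinate sets must be N x 3 and congruent")
  n <- nrow(xa)
  if (n < 3) stop("degenerate-geometry error: need at least 3 points")
  ca <- colMeans(xa); cb <- colMeans(xb)
  A <- sweep(xa, 2, ca); B <- sweep(xb, 2, cb)
  if (sum(svd(A)$d > 1e-8) < 2 || sum(svd(B)$d > 1e-8) < 2)
    stop("degenerate-geometry error: collinear points")
  sv <- svd(t(B) %*% A)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  tr <- ca - as.numeric(cb %*% R)
  fitted <- B %*% R
  rmsd <- sqrt(mean(rowSums((A - fitted)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd),
            class = "superposition")
}

#' Apply a superposition to coordinates
#' @param sup a [kabsch_superpose] result.
#' @param x N x 3 coordinates.
#' @return transformed N x 3 coordinates.
#' @export
apply_superposition <- function(sup, x)
  sweep(as.matrix(x) %*% sup$rotation, 2, sup$translation, "+")

#' GDT score by the seed-extend heuristic
#'
#' Percentage of residues that fit simultaneously within `cutoff` Angstrom
#' of their partners under a single rigid superposition. Every contiguous
#' seed window of lengths 4, N/4, N/2 and N is superposed, then the
#' included set (residues within the cutoff) is iteratively re-superposed
#' until stable (at most 20 rounds); the best set wins, ties broken by
#' larger set then lower RMSD over the included set. Two refinements
#' harden the search: a shrink pass drops the worst-fitting residue from
#' the full set, and chains of at most 12 residues additionally seed from
#' every 4-residue combination (exhaustive at the sizes where that is
#' affordable).
#'
#' @param xa,xb mapped C-alpha coordinate matrices (N x 3).
#' @param cutoff distance cutoff in Angstrom (default 4, inclusive).
#' @return score in \[0, 100\].
#' @export
gdt_score <- function(xa, xb, cutoff = 4) {
  xa <- as.matrix(xa); xb <- as.matrix(xb)
  n <- nrow(xa)
  if (n < 4) stop("too-short error: GDT needs at least 4 residues")
  lens <- sort(unique(pmax(4L, c(4L, n %/% 4L, n %/% 2L, n))))
  lens <- lens[lens <= n]
  seeds <- list()
  for (L in lens)
    for (st in seq_len(n - L + 1L))
      seeds[[length(seeds) + 1L]] <- st:(st + L - 1L)
  # on very short chains every 4-residue combination is an affordable
  # seed, making the search exhaustive at the sizes where that is cheap
  if (n <= 12)
    seeds <- c(seeds, utils::combn(n, 4, simplify = FALSE))
  best_n <- 0L; best_rmsd <- Inf
  for (seed_idx in seeds) {
    {
      idx <- seed_idx
      for (iter in seq_len(20L)) {
        sup <- tryCatch(kabsch_superpose(xa[idx, , drop = FALSE],
                                         xb[idx, , drop = FALSE]),
                        error = function(e) NULL)
        if (is.null(sup)) break
        d <- sqrt(rowSums((xa - apply_superposition(sup, xb))^2))
        inc <- which(d <= cutoff)
        if (length(inc) >= 1) {   # every iterate is a candidate score
          rmsd_inc <- sqrt(mean(d[inc]^2))
          if (length(inc) > best_n ||
              (length(inc) == best_n && rmsd_inc < best_rmsd)) {
            best_n <- length(inc); best_rmsd <- rmsd_inc
          }
        }
        if (length(inc) < 3) break
        if (length(inc) == length(idx) && all(inc == idx)) break
        idx <- inc
      }
    }
  }
  # shrink pass: from the full set, repeatedly drop the worst-fitting
  # residue; catches fit sets no contiguous seed extends to
  idx <- seq_len(n)
  while (length(idx) >= 4) {
    sup <- tryCatch(kabsch_superpose(xa[idx, , drop = FALSE],
                                     xb[idx, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(sup)) break
    d <- sqrt(rowSums((xa - apply_superposition(sup, xb))^2))
    inc <- which(d <= cutoff)
    if (length(inc) > best_n ||
        (length(inc) == best_n && sqrt(mean(d[inc]^2)) < best_rmsd)) {
      best_n <- length(inc); best_rmsd <- sqrt(mean(d[inc]^2))
    }
    idx <- idx[-which.max(d[idx])]
  }
  100 * best_n / n
}

#' Per-residue deviation profile of a superposed pair
#'
#' Superposes the mapped C-alpha sets globally (Kabsch), records the
#' per-residue C-alpha distance, global RMSD, GDT and the residues flagged
#' by the two-sigma rule.
#'
#' @param xa,xb mapped C-alpha coordinates (N x 3).
#' @param gdt_cutoff GDT distance cutoff (Angstrom).
#' @return object of class `deviation_profile`: `distances`, `mean`, `sd`
#'   (population), `flagged` (indices into the mapped set), `regions`
#'   (contiguous runs), `rmsd`, `gdt`, `gdt_complement` (100 - GDT).
#' @export
deviation_profile <- function(xa, xb, gdt_cutoff = 4) {
  sup <- kabsch_superpose(xa, xb)
  d <- sqrt(rowSums((as.matrix(xa) - apply_superposition(sup, xb))^2))
  fl <- significant_regions(d)
  gdt <- gdt_score(xa, xb, cutoff = gdt_cutoff)
  structure(list(distances = d, mean = mean(d),
                 sd = sqrt(mean((d - mean(d))^2)),
                 flagged = fl$flagged, regions = fl$regions,
                 rmsd = sup$rmsd, gdt = gdt, gdt_complement = 100 - gdt,
                 superposition = sup),
            class = "deviation_profile")
}

#' Locally deviating residues by the two-sigma rule
#'
#' A residue is flagged iff its distance exceeds the mean of the distance
#' distribution by more than twice the (population) standard deviation.
#'
#' @param distances per-residue C-alpha distances after superposition.
#' @return list with `flagged` (indices) and `regions` (data.frame of
#'   contiguous runs with columns `start`, `end`).
#' @export
significant_regions <- function(distances) {
  d <- as.numeric(distances)
  if (length(d) < 2) stop("need at least 2 mapped residues")
  mu <- mean(d)
  sdev <- sqrt(mean((d - mu)^2))
  # 1e-6 A floor: distances below coordinate precision are physically zero
  flagged <- which(d > mu + 2 * sdev & d > 1e-6)
  regions <- if (length(flagged) == 0) {
    data.frame(start = integer(0), end = integer(0))
  } else {
    brk <- c(0, which(diff(flagged) > 1), length(flagged))
    data.frame(start = flagged[brk[-length(brk)] + 1],
               end = flagged[brk[-1]])
  }
  list(flagged = flagged, regions = regions)
}

#' Classify a pair by where its deviating regions fall
#'
#' @param flagged residue indices flagged by [significant_regions] (on the
#'   common-domain index space).
#' @param interface residue indices of the domain-domain interface on the
#'   same index space (or an `interface_set`, whose `residues` are used).
#' @return one of `"interface-only"`, `"non-interface-only"`, `"both"`,
#'   `"none"`.
#' @export
classify_pair <- function(flagged, interface) {
  if (inherits(interface, "interface_set")) interface <- interface$residues
  flagged <- as.integer(flagged)
  if (length(flagged) == 0) return("none")
  inside <- flagged %in% interface
  if (all(inside)) "interface-only"
  else if (!any(inside)) "non-interface-only"
  else "both"
}
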