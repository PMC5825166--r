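#' C-alpha contact network
#'
#' Undirected, unweighted network with one node per residue and an edge
#' wherever the C-alpha distance is less than or equal to `cutoff`.
#'
#' @param s a [protstruct].
#' @param cutoff contact cutoff in Angstrom (default 5, inclusive).
#' @return object of class `contact_network`: list with `adjacency`
#'   (symmetric 0/1 matrix, zero diagonal), `cutoff` and `resindex`.
#' @export
build_network <- function(s, cutoff = 5) {
  xyz <- ca_coords(s)
  if (nrow(xyz) == 0) stop("empty-structure error: no CA atoms")
  D <- as.matrix(stats::dist(xyz))
  A <- (D <= cutoff) * 1
  diag(A) <- 0
  dimnames(A) <- NULL
  structure(list(adjacency = A, cutoff = cutoff,
                 resindex = attr(xyz, "resindex")),
            class = "contact_network")
}

#' Communicability centrality
#'
#' The factorial-weighted sum of closed walks of all lengths through each
#' node: the diagonal of the matrix exponential of the adjacency, computed
#' by eigendecomposition of the symmetric adjacency matrix.
#'
#' @param g a [build_network] result (or a symmetric 0/1 adjacency matrix).
#' @return numeric vector of raw centralities (each >= 1).
#' @export
communicability_centrality <- function(g) {
  A <- if (inherits(g, "contact_network")) g$adjacency else as.matrix(g)
  if (nrow(A) == 0) stop("empty network")
  e <- eigen(A, symmetric = TRUE)
  as.numeric((e$vectors^2) %*% exp(e$values))
}

#' Z-score normalization of a centrality (or any) profile
#'
#' @param x numeric vector.
#' @return z-scored vector (mean 0, sd 1); all zeros with a warning when
#'   the input is constant.
#' @export
normalize_profile <- function(x) {
  x <- as.numeric(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    warning("constant profile: z-scores undefined, returning zeros")
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

#' Residues whose normalized centrality differs between pair members
#'
#' @param md_norm,id_norm normalized centrality vectors for the two pair
#'   members, indexed by each structure's residue order.
#' @param mapping a [map_common_domain] result aligning the two.
#' @param threshold flag residues with absolute difference strictly greater
#'   than this (default 1.5).
#' @return data.frame with one row per mapped pair: `res_a`, `res_b`,
#'   `delta` (md - id), `flagged`.
#' @export
centrality_difference <- function(md_norm, id_norm, mapping,
                                  threshold = 1.5) {
  p <- mapping$pairs
  if (max(p[, 1]) > length(md_norm) || max(p[, 2]) > length(id_norm))
    stop("mapping error: mapped residue outside profile range")
  delta <- md_norm[p[, 1]] - id_norm[p[, 2]]
  data.frame(res_a = p[, 1], res_b = p[, 2], delta = delta,
             flagged = abs(delta) > threshold)
}
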