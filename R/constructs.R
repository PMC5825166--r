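#' Amputated-domain control construct
#'
#' In-silico removal of the tethered domains: keeps exactly the common
#' domain residues of the multi-domain structure with coordinates
#' unchanged (control construct for crystal-packing effects on dynamics).
#'
#' @param md multi-domain [protstruct].
#' @param common [domain_def] of the common domain.
#' @return a [protstruct] (the AD construct).
#' @export
amputate <- function(md, common) {
  out <- extract_domain(md, common)
  out$id <- paste0(md$id, ":AD")
  out
}

#' Swapped-domain control construct
#'
#' Rigidly superposes the isolated domain onto the multi-domain member's
#' common domain (Kabsch on mapped C-alpha) and replaces the common domain
#' in place, leaving the tethered domains untouched. The result matches
#' the multi-domain member in sequence and numbering over mutually
#' resolved residues.
#'
#' @param md multi-domain [protstruct].
#' @param id_ isolated-domain [protstruct].
#' @param m [map_common_domain] result mapping `extract_domain(md, common)`
#'   to `id_`.
#' @param common [domain_def] of the common domain within `md`.
#' @return a [protstruct] (the swapped construct).
#' @export
swap_common_domain <- function(md, id_, m, common) {
  dom_idx <- domain_residue_indices(md, common)
  md_idx <- dom_idx[m$pairs[, 1]]
  id_idx <- m$pairs[, 2]
  if (length(md_idx) < 3) stop("need at least 3 mapped residues")
  ca_md <- ca_coords(md, strict = FALSE)
  ca_id <- ca_coords(id_, strict = FALSE)
  ra <- match(md_idx, attr(ca_md, "resindex"))
  rb <- match(id_idx, attr(ca_id, "resindex"))
  if (anyNA(ra) || anyNA(rb)) stop("mapped residue lacks a CA atom")
  sup <- kabsch_superpose(ca_md[ra, , drop = FALSE],
                          ca_id[rb, , drop = FALSE])
  idat <- id_$atoms
  idat[, c("x", "y", "z")] <-
    apply_superposition(sup, as.matrix(idat[, c("x", "y", "z")]))
  # rebuild in md residue order: uncommon residues keep their atoms,
  # mapped common residues take the transformed id atoms under md numbering
  parts <- vector("list", n_residues(md))
  for (k in seq_len(n_residues(md))) {
    if (!k %in% dom_idx) {
      parts[[k]] <- md$atoms[md$atoms$resindex == k, , drop = FALSE]
    } else {
      hit <- match(k, md_idx)
      if (is.na(hit)) next  # not mutually resolved: dropped
      blk <- idat[idat$resindex == id_idx[hit], , drop = FALSE]
      blk$chain <- md$residues$chain[k]
      blk$resno <- md$residues$resno[k]
      blk$ins <- md$residues$ins[k]
      parts[[k]] <- blk
    }
  }
  at <- do.call(rbind, parts)
  out <- protstruct(at[, setdiff(names(at), "resindex")],
                    id = paste0(md$id, ":swapped"))
  attr(out, "superposition") <- sup
  out
}

#' Homolog chimera with junction-clash trimming
#'
#' Grafts a single-domain protein into a multi-domain scaffold: the single
#' domain is rigidly superposed onto the multi-domain member's homologous
#' domain, that domain is excised, and the transformed single domain is
#' ligated in. While any atom pair between the two parents is closer than
#' `clash` Angstrom, one residue is removed from a junction terminus,
#' alternating sides starting with the N-terminal side of the downstream
#' parent, up to `max_trim` residues per side. Passing several graft sites
#' (gene-duplicated repeats) grafts the single domain into each.
#'
#' @param single single-domain [protstruct].
#' @param multi multi-domain [protstruct].
#' @param grafts list of graft sites, each a list with `domain` (a
#'   [domain_def] on `multi`, contiguous) and `mapping` (a
#'   [map_common_domain] result from `single` to
#'   `extract_domain(multi, domain)`, homolog mode); a single site may be
#'   passed directly.
#' @param clash heavy-atom clash threshold in Angstrom (default 2).
#' @param max_trim maximum residues removed per junction side (default 9).
#' @return list with `structure` (the chimera, residues renumbered 1..N)
#'   and `record` (construct kind, junction trims, per-residue provenance).
#' @export
build_chimera <- function(single, multi, grafts, clash = 2.0, max_trim = 9) {
  if (!is.null(grafts$domain)) grafts <- list(grafts)
  site_idx <- lapply(grafts, function(g) {
    idx <- domain_residue_indices(multi, g$domain)
    if (!all(diff(idx) == 1))
      stop("chimera grafting requires a contiguous homologous domain")
    if (nrow(g$mapping$pairs) < 0.5 * n_residues(single))
      stop("homolog mapping covers <50% of the single-domain protein")
    idx
  })
  ord <- order(vapply(site_idx, min, integer(1)))
  grafts <- grafts[ord]; site_idx <- site_idx[ord]

  ca_m <- ca_coords(multi, strict = FALSE)
  ca_s <- ca_coords(single, strict = FALSE)

  # parts: alternating multi segments and transformed single copies
  parts <- list(); kinds <- character(0)
  pos <- 1L
  nres <- n_residues(multi)
  for (gi in seq_along(grafts)) {
    idx <- site_idx[[gi]]
    if (pos < min(idx)) {
      parts <- c(parts, list(pos:(min(idx) - 1L))); kinds <- c(kinds, "multi")
    }
    g <- grafts[[gi]]
    s_idx <- g$mapping$pairs[, 1]
    m_idx <- idx[g$mapping$pairs[, 2]]
    rs <- match(s_idx, attr(ca_s, "resindex"))
    rm_ <- match(m_idx, attr(ca_m, "resindex"))
    ok <- !is.na(rs) & !is.na(rm_)
    if (sum(ok) < 3) stop("superposition degeneracy: <3 mapped CA")
    sup <- kabsch_superpose(ca_m[rm_[ok], , drop = FALSE],
                            ca_s[rs[ok], , drop = FALSE])
    sat <- single$atoms
    sat[, c("x", "y", "z")] <-
      apply_superposition(sup, as.matrix(sat[, c("x", "y", "z")]))
    parts <- c(parts, list(sat)); kinds <- c(kinds, "single")
    pos <- max(idx) + 1L
  }
  if (pos <= nres) { parts <- c(parts, list(pos:nres)); kinds <- c(kinds, "multi") }

  # per-part residue index lists (into each parent) for trimming
  part_res <- lapply(seq_along(parts), function(i) {
    if (kinds[i] == "multi") parts[[i]] else unique(parts[[i]]$resindex)
  })
  junctions <- which(diff(match(kinds, c("multi", "single"))) != 0)
  trims <- matrix(0L, nrow = length(junctions), ncol = 2,
                  dimnames = list(NULL, c("upstream", "downstream")))
  turn <- rep(2L, length(junctions))  # start on downstream N-terminal side

  part_atoms <- function(i, keep) {
    if (kinds[i] == "multi")
      multi$atoms[multi$atoms$resindex %in% keep, , drop = FALSE]
    else parts[[i]][parts[[i]]$resindex %in% keep, , drop = FALSE]
  }
  clash_pairs <- function() {
    # min distance between atoms of different parents
    worst <- NULL; wd <- Inf
    for (i in seq_along(parts)) for (j in seq_along(parts)) {
      if (j <= i || kinds[i] == kinds[j]) next
      ai <- part_atoms(i, part_res[[i]]); aj <- part_atoms(j, part_res[[j]])
      if (nrow(ai) == 0 || nrow(aj) == 0) next
      xi <- as.matrix(ai[, c("x", "y", "z")])
      xj <- as.matrix(aj[, c("x", "y", "z")])
      d2 <- outer(rowSums(xi^2), rowSums(xj^2), "+") - 2 * xi %*% t(xj)
      md2 <- min(d2)
      if (md2 < wd^2) {
        wd <- sqrt(max(md2, 0))
        w <- which(d2 == md2, arr.ind = TRUE)[1, ]
        worst <- (xi[w[1], ] + xj[w[2], ]) / 2
      }
    }
    list(dist = wd, at = worst)
  }

  repeat {
    cp <- clash_pairs()
    if (cp$dist >= clash) break
    # junction nearest the worst clash (by its flanking terminal CA)
    jd <- vapply(seq_along(junctions), function(k) {
      i <- junctions[k]
      up <- part_res[[i]]; dn <- part_res[[i + 1]]
      if (length(up) == 0 || length(dn) == 0) return(Inf)
      a1 <- part_atoms(i, up[length(up)]); a2 <- part_atoms(i + 1, dn[1])
      min(sqrt(colSums((t(as.matrix(a1[, c("x", "y", "z")])) - cp$at)^2)),
          sqrt(colSums((t(as.matrix(a2[, c("x", "y", "z")])) - cp$at)^2)))
    }, numeric(1))
    k <- which.min(jd)
    side <- turn[k]
    other <- 3L - side
    if (trims[k, side] >= max_trim) side <- other
    if (trims[k, side] >= max_trim)
      stop("chimera-failure error: clash unresolvable within max_trim")
    i <- junctions[k]
    if (side == 1L) {  # upstream C-terminal residue
      part_res[[i]] <- part_res[[i]][-length(part_res[[i]])]
    } else {           # downstream N-terminal residue
      part_res[[i + 1]] <- part_res[[i + 1]][-1]
    }
    trims[k, side] <- trims[k, side] + 1L
    turn[k] <- other
  }

  at_list <- lapply(seq_along(parts), function(i) {
    a <- part_atoms(i, part_res[[i]])
    a$parent <- if (kinds[i] == "multi") multi$id else single$id
    a$part <- i
    a
  })
  at <- do.call(rbind, at_list)
  # renumber sequentially, record provenance
  okey <- paste(at$part, at$chain, at$resno, at$ins, sep = ":")
  newno <- match(okey, unique(okey))
  prov <- data.frame(resno = unique(newno),
                     parent = at$parent[!duplicated(okey)],
                     parent_resno = at$resno[!duplicated(okey)],
                     parent_chain = at$chain[!duplicated(okey)])
  at$resno <- newno; at$chain <- "A"; at$ins <- ""
  out <- protstruct(at[, c("chain", "resno", "ins", "resname", "atom",
                           "element", "x", "y", "z", "occ")],
                    id = paste0(single$id, "-", multi$id, ":chimera"))
  record <- list(kind = "chimera",
                 sources = c(single = single$id, multi = multi$id),
                 junction_trims = as.data.frame(trims),
                 provenance = prov)
  list(structure = out, record = record)
}
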