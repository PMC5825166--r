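ca_structure <- function(xyz, resnames, id, chain = "A",
                         resno = seq_len(nrow(xyz))) {
  protstruct(data.frame(chain = chain, resno = resno, ins = "",
                        resname = resnames, atom = "CA", element = "C",
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1,
                        stringsAsFactors = FALSE), id = id)
}

random_sequence <- function(n) sample(bio3d::aa123(AA20), n, replace = TRUE)

#' Generate a synthetic single-domain C-alpha structure
#'
#' Helix mode uses ideal helical parameters (rise 1.5 Angstrom, 100
#' degrees per residue, radius chosen so consecutive C-alphas are 3.8
#' Angstrom apart). Coil mode is a seeded compact self-avoiding walk:
#' step 3.8 Angstrom, no two non-adjacent C-alphas closer than 4
#' Angstrom, confined to a sphere so the domain is globular.
#'
#' @param n number of residues (>= 12).
#' @param geometry `"coil"` (default) or `"helix"`.
#' @param seed RNG seed (mandatory; the generator is deterministic).
#' @return a [protstruct] C-alpha trace with a random sequence.
#' @export
make_domain <- function(n, geometry = c("coil", "helix"), seed) {
  geometry <- match.arg(geometry)
  if (n < 12) stop("domain size must be >= 12")
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  if (geometry == "helix") {
    theta <- (seq_len(n) - 1) * 100 * pi / 180
    rise <- 1.5
    radius <- sqrt(3.8^2 - rise^2) / (2 * sin(50 * pi / 180))
    xyz <- cbind(radius * cos(theta), radius * sin(theta),
                 rise * (seq_len(n) - 1))
  } else {
    rmax <- 3.3 * n^(1 / 3) + 3
    step <- 3.8
    for (attempt in 1:50) {
      xyz <- matrix(NA_real_, n, 3)
      xyz[1, ] <- c(0, 0, 0)
      ok <- TRUE
      for (i in 2:n) {
        placed <- FALSE
        for (try in 1:200) {
          u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
          cand <- xyz[i - 1, ] + step * u
          if (sqrt(sum(cand^2)) > rmax) next
          if (i > 2) {
            d <- sqrt(colSums((t(xyz[1:(i - 2), , drop = FALSE]) - cand)^2))
            if (min(d) < 4) next
          }
          xyz[i, ] <- cand; placed <- TRUE; break
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) break
    }
    if (!ok) stop("generation error: self-avoiding walk failed")
  }
  ca_structure(xyz, random_sequence(n), id = paste0("synth-", geometry))
}

#' Specification for a synthetic multi-domain / isolated-domain pair
#'
#' @param domain_sizes residue counts, first entry is the common domain
#'   (each >= 12).
#' @param geometry `"coil"` or `"helix"` (recycled over domains).
#' @param linker_length residues in each inter-domain linker.
#' @param interface_contacts target number of cross-domain C-alpha contact
#'   pairs (placement accepts within 20 percent; 0 means well separated).
#' @param noise_sd coordinate noise sd in Angstrom applied independently
#'   to both members.
#' @param hinge optional list(`domain` = index, `angle` = degrees): rigid
#'   rotation of that domain about a random axis through its linker end.
#' @param truncations residues removed from the isolated member's
#'   N- and C-terminus, `c(n, c)`.
#' @param seed mandatory RNG seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(domain_sizes = c(60, 50), geometry = "coil",
                           linker_length = 4, interface_contacts = 12,
                           noise_sd = 0.2, hinge = NULL,
                           truncations = c(0, 0), seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (any(domain_sizes < 12)) stop("domain sizes must be >= 12")
  if (noise_sd < 0) stop("noise sd must be >= 0")
  structure(list(domain_sizes = domain_sizes,
                 geometry = rep(geometry, length.out = length(domain_sizes)),
                 linker_length = linker_length,
                 interface_contacts = interface_contacts,
                 noise_sd = noise_sd, hinge = hinge,
                 truncations = truncations, seed = seed),
            class = "synthetic_spec")
}

rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  c_ * diag(3) + s_ * rbind(c(0, -u[3], u[2]), c(u[3], 0, -u[1]),
                            c(-u[2], u[1], 0)) + (1 - c_) * tcrossprod(u)
}

count_interface_contacts <- function(xa, xb, cutoff = 6) {
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  sum(d2 <= cutoff^2)
}

#' Generate a synthetic multi-domain / isolated-domain structure pair
#'
#' The multi-domain member (MD) is the common domain plus tethered
#' domain(s) joined by linkers, the tethered domain translated along a
#' seeded direction until the cross-domain C-alpha contact count (6
#' Angstrom criterion, matching the interface definition with the
#' generator's effective C-alpha radius) is within 20 percent of the
#' target. The isolated member (ID) is the common domain alone with an
#' independent noise draw and optional terminal truncation.
#'
#' @param spec a [synthetic_spec].
#' @return list with `md`, `id` ([protstruct]s), `common` (a [domain_def]
#'   on `md`), and `truth` (interface residues of the common domain,
#'   placement geometry, seeds).
#' @export
make_multidomain <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  seeds <- sample.int(2^31 - 10, length(spec$domain_sizes) + 3)
  doms <- lapply(seq_along(spec$domain_sizes), function(i)
    make_domain(spec$domain_sizes[i], spec$geometry[i], seed = seeds[i]))
  common_xyz <- ca_coords(doms[[1]])
  common_xyz <- sweep(common_xyz, 2, colMeans(common_xyz))

  placed <- list(common_xyz)
  set.seed(seeds[length(seeds) - 2])
  for (k in 2:length(doms)) {
    dx <- ca_coords(doms[[k]])
    dx <- sweep(dx, 2, colMeans(dx))
    target <- spec$interface_contacts
    lo <- ceiling(0.8 * target); hi <- floor(1.2 * target)
    done <- FALSE
    for (try in 1:20) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      offs <- seq(80, 8, by = -0.25)
      for (D in offs) {
        cand <- sweep(dx, 2, D * u, "+")
        cnt <- count_interface_contacts(placed[[1]], cand)
        if (target == 0) {
          mind2 <- min(outer(rowSums(placed[[1]]^2), rowSums(cand^2), "+") -
                         2 * placed[[1]] %*% t(cand))
          if (sqrt(max(mind2, 0)) <= 10) break
          keep <- cand; done <- TRUE
        } else {
          if (cnt > hi) break
          if (cnt >= lo) { keep <- cand; done <- TRUE; break }
        }
      }
      if (done) break
    }
    if (!done) stop("placement error: interface contact target unreachable")
    placed[[k]] <- keep
  }

  # assemble MD: common, then for each extra domain a straight linker
  atoms_xyz <- placed[[1]]
  resnames <- doms[[1]]$residues$resname
  dom_ranges <- list(c(1, nrow(placed[[1]])))
  for (k in 2:length(placed)) {
    a <- atoms_xyz[nrow(atoms_xyz), ]
    b <- placed[[k]][1, ]
    L <- spec$linker_length
    if (L > 0) {
      frac <- seq_len(L) / (L + 1)
      link <- t(vapply(frac, function(f) a + f * (b - a), numeric(3)))
      atoms_xyz <- rbind(atoms_xyz, link)
      resnames <- c(resnames, random_sequence(L))
    }
    st <- nrow(atoms_xyz) + 1
    atoms_xyz <- rbind(atoms_xyz, placed[[k]])
    resnames <- c(resnames, doms[[k]]$residues$resname)
    dom_ranges[[k]] <- c(st, nrow(atoms_xyz))
  }

  # optional hinge rotation of a named domain (about its first residue)
  if (!is.null(spec$hinge)) {
    rg <- dom_ranges[[spec$hinge$domain]]
    idx <- rg[1]:rg[2]
    set.seed(seeds[length(seeds) - 1] + 7)
    ax <- stats::rnorm(3)
    R <- rotation_about_axis(ax, spec$hinge$angle * pi / 180)
    pivot <- atoms_xyz[rg[1], ]
    atoms_xyz[idx, ] <- sweep(sweep(atoms_xyz[idx, , drop = FALSE], 2,
                                    pivot) %*% R, 2, pivot, "+")
  }

  # ground-truth interface on noiseless coordinates
  n_common <- spec$domain_sizes[1]
  iface_common <- integer(0)
  for (k in 2:length(placed)) {
    rg <- dom_ranges[[k]]
    d2 <- outer(rowSums(atoms_xyz[1:n_common, , drop = FALSE]^2),
                rowSums(atoms_xyz[rg[1]:rg[2], , drop = FALSE]^2), "+") -
      2 * atoms_xyz[1:n_common, , drop = FALSE] %*%
        t(atoms_xyz[rg[1]:rg[2], , drop = FALSE])
    iface_common <- union(iface_common, which(rowSums(d2 <= 36) > 0))
  }
  id_xyz <- atoms_xyz[1:n_common, , drop = FALSE]

  set.seed(seeds[length(seeds)])
  md_xyz <- atoms_xyz + matrix(stats::rnorm(length(atoms_xyz),
                                            sd = spec$noise_sd),
                               ncol = 3)
  id_xyz <- id_xyz + matrix(stats::rnorm(length(id_xyz),
                                         sd = spec$noise_sd), ncol = 3)
  keep_id <- seq_len(n_common)
  tr <- spec$truncations
  if (tr[1] > 0) keep_id <- keep_id[-seq_len(tr[1])]
  if (tr[2] > 0) keep_id <- keep_id[seq_len(length(keep_id) - tr[2])]

  md <- ca_structure(md_xyz, resnames, id = "synth-MD")
  id_ <- ca_structure(id_xyz[keep_id, , drop = FALSE],
                      resnames[keep_id], id = "synth-ID",
                      resno = keep_id)
  common <- domain_def("common", data.frame(chain = "A", start = 1,
                                            end = n_common))
  list(md = md, id = id_, common = common,
       truth = list(interface = sort(iface_common),
                    dom_ranges = dom_ranges, seeds = seeds,
                    noiseless_md = atoms_xyz))
}

#' Rigidly displace a region and add coordinate noise
#'
#' Creates a known locally deviating region: the region's residues are
#' displaced by `displacement` Angstrom along a seeded random direction,
#' then Gaussian noise is added to every coordinate.
#'
#' @param s a [protstruct].
#' @param region residue indices to displace.
#' @param displacement displacement magnitude in Angstrom.
#' @param noise_sd noise sd in Angstrom.
#' @param seed RNG seed.
#' @return list with `structure` (perturbed copy) and `deviation`
#'   (per-residue true displacement distance before noise).
#' @export
perturb <- function(s, region, displacement, noise_sd, seed) {
  if (missing(seed)) stop("seed is mandatory")
  region <- as.integer(region)
  if (any(region < 1 | region > n_residues(s)))
    stop("region outside structure")
  set.seed(seed)
  u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
  at <- s$atoms
  sel <- at$resindex %in% region
  at[sel, c("x", "y", "z")] <- sweep(as.matrix(at[sel, c("x", "y", "z")]),
                                     2, displacement * u, "+")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  at[, c("x", "y", "z")] <- xyz + matrix(stats::rnorm(length(xyz),
                                                      sd = noise_sd),
                                         ncol = 3)
  dev <- rep(0, n_residues(s))
  dev[region] <- displacement
  out <- protstruct(at[, setdiff(names(at), "resindex")],
                    id = paste0(s$id, ":perturbed"))
  list(structure = out, deviation = dev)
}
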