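AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Kyte-Doolittle hydropathy, the basis of the default contact potential
KD_HYDROPATHY <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                   Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                   L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                   S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Pairwise amino-acid contact potential
#'
#' The default is a hydrophobicity-product table: with
#' `q = (hydropathy + 4.5) / 9` in \[0, 1\], the contact energy is
#' `e(a, b) = -q_a q_b`, so hydrophobic-hydrophobic contacts are most
#' favourable (the dominant mode of statistical contact potentials). Any
#' symmetric 20 x 20 matrix with one-letter dimnames can be used instead.
#'
#' @param name potential name; only `"hydrophobicity"` is shipped.
#' @return 20 x 20 symmetric numeric matrix, dimnames the one-letter codes.
#' @export
contact_potential <- function(name = "hydrophobicity") {
  if (name != "hydrophobicity") stop("unknown potential: ", name)
  q <- (KD_HYDROPATHY + 4.5) / 9
  -outer(q, q)
}

#' Sequence-distant C-alpha contacts of a structure
#'
#' Unordered residue pairs separated by at least 2 positions in sequence
#' with C-alpha distance at most `cutoff` Angstrom (inclusive).
#'
#' @param s a [protstruct].
#' @param cutoff contact cutoff (default 5).
#' @return data.frame with columns `i`, `j` (residue indices, i < j) and
#'   `dist`.
#' @export
contact_list <- function(s, cutoff = 5) {
  if (n_residues(s) == 0)
    return(data.frame(i = integer(0), j = integer(0), dist = numeric(0)))
  xyz <- ca_coords(s)
  ri <- attr(xyz, "resindex")
  D <- as.matrix(stats::dist(xyz))
  hit <- which(upper.tri(D) & D <= cutoff, arr.ind = TRUE)
  sep <- abs(ri[hit[, 2]] - ri[hit[, 1]])
  hit <- hit[sep >= 2, , drop = FALSE]
  data.frame(i = ri[hit[, 1]], j = ri[hit[, 2]],
             dist = D[hit[, , drop = FALSE]])
}

# contact energy: potential entry scaled by an inverse-square distance
# weight (reference 4 A) plus an optional contact-count burial term
contact_energy <- function(aa_i, aa_j, d, pot, burial_i = 0, burial_j = 0,
                           burial_weight = 0) {
  e <- pot[cbind(aa_i, aa_j)] * (4 / d)^2
  if (burial_weight != 0)
    e <- e + burial_weight * pot[cbind(aa_i, aa_j)] *
      (burial_i + burial_j) / 2
  unname(e)
}

#' Frustration index of a native energy against a decoy ensemble
#'
#' The Z-score `(mean(decoys) - native) / sd(decoys)` (sample sd), signed
#' so that a native more stable (lower energy) than the decoys gives a
#' positive index.
#'
#' @param e_native native energy.
#' @param e_decoys decoy energies (>= 2 values with non-zero spread).
#' @return scalar index.
#' @export
frustration_index <- function(e_native, e_decoys) {
  if (length(e_decoys) < 2)
    stop("undefined-index error: need at least 2 decoys")
  s <- stats::sd(e_decoys)
  if (!is.finite(s) || s == 0)
    stop("undefined-index error: zero decoy energy spread")
  (mean(e_decoys) - e_native) / s
}

#' Mutational decoy energies of a contact
#'
#' Energies of the contact under amino-acid pair substitutions with all
#' structural parameters fixed. When `n >= 400` all 20 x 20 pairs are
#' enumerated (native pair included once); otherwise `n` pairs are sampled
#' reproducibly from `seed`.
#'
#' @param contact one-row data.frame (or list) with `aa_i`, `aa_j`, `dist`
#'   and optional `burial_i`, `burial_j`.
#' @param pot contact potential matrix.
#' @param n decoy budget (default 1000 => exhaustive).
#' @param seed RNG seed (used only when sampling).
#' @param burial_weight burial term weight (default 0, off).
#' @return numeric vector of decoy energies.
#' @export
decoys_mutational <- function(contact, pot, n = 1000, seed = 1,
                              burial_weight = 0) {
  bi <- if (is.null(contact$burial_i)) 0 else contact$burial_i
  bj <- if (is.null(contact$burial_j)) 0 else contact$burial_j
  if (n >= 400) {
    grid <- expand.grid(a = AA20, b = AA20, stringsAsFactors = FALSE)
  } else {
    set.seed(seed)
    grid <- data.frame(a = sample(AA20, n, replace = TRUE),
                       b = sample(AA20, n, replace = TRUE))
  }
  contact_energy(grid$a, grid$b, contact$dist, pot,
                 bi, bj, burial_weight)
}

# empirical structural contexts: contact distances and residue burials
resample_contexts <- function(s, n, seed, cutoff = 5) {
  if (n_residues(s) < 10)
    stop("resample error: structure too small (<10 residues)")
  cl <- contact_list(s, cutoff)
  if (nrow(cl) == 0) stop("resample error: no contacts to sample from")
  burial <- tabulate(c(cl$i, cl$j), nbins = n_residues(s))
  set.seed(seed)
  data.frame(dist = sample(cl$dist, n, replace = TRUE),
             burial_i = sample(burial, n, replace = TRUE),
             burial_j = sample(burial, n, replace = TRUE))
}

#' Configurational decoy energies of a contact
#'
#' Energies of the native residue pair evaluated in `n` structural
#' contexts resampled from the structure's own empirical distribution of
#' contact distances and residue burial counts (the configurations a
#' contact can take during folding).
#'
#' @param contact one-row data.frame (or list) with `aa_i`, `aa_j`.
#' @param s the [protstruct] supplying the empirical context distribution.
#' @param pot contact potential matrix.
#' @param n number of decoys (default 1000).
#' @param seed RNG seed.
#' @param burial_weight burial term weight (default 0).
#' @param cutoff contact cutoff used for the empirical distribution.
#' @return numeric vector of decoy energies.
#' @export
decoys_configurational <- function(contact, s, pot, n = 1000, seed = 1,
                                   burial_weight = 0, cutoff = 5) {
  ctx <- resample_contexts(s, n, seed, cutoff)
  contact_energy(rep(contact$aa_i, n), rep(contact$aa_j, n), ctx$dist,
                 pot, ctx$burial_i, ctx$burial_j, burial_weight)
}

#' Single-residue-level frustration (SRLF)
#'
#' The native energy is the sum over the residue's contacts; the decoys
#' are the 19 alternative amino-acid identities with every contact
#' re-scored (exhaustive). The index is the decoy Z-score of
#' [frustration_index].
#'
#' @param residue residue index into `s`.
#' @param s a [protstruct].
#' @param pot contact potential.
#' @param cutoff contact cutoff (default 5).
#' @param burial_weight burial term weight (default 0).
#' @return scalar index; errors if the residue has no contacts or the
#'   identities are isoenergetic.
#' @export
srlf <- function(residue, s, pot, cutoff = 5, burial_weight = 0) {
  cl <- contact_list(s, cutoff)
  burial <- tabulate(c(cl$i, cl$j), nbins = n_residues(s))
  mine <- cl[cl$i == residue | cl$j == residue, , drop = FALSE]
  if (nrow(mine) == 0)
    stop("undefined-index error: residue ", residue, " has no contacts")
  seqs <- structure_sequence(s)
  partner <- ifelse(mine$i == residue, mine$j, mine$i)
  total_energy <- function(aa)
    sum(contact_energy(rep(aa, nrow(mine)), seqs[partner], mine$dist, pot,
                       burial[residue], burial[partner], burial_weight))
  native_aa <- seqs[residue]
  if (!native_aa %in% AA20)
    stop("undefined-index error: non-standard residue identity")
  e_native <- total_energy(native_aa)
  e_decoys <- vapply(setdiff(AA20, native_aa), total_energy, numeric(1))
  frustration_index(e_native, e_decoys)
}

#' Classify a frustration index
#'
#' Minimal if the index is strictly greater than 0.78, high if strictly
#' less than -1, neutral otherwise (boundaries inclusive to neutral).
#'
#' @param index numeric vector of frustration indices.
#' @return character vector in `{"minimal", "neutral", "high"}` (`NA` for
#'   non-finite input).
#' @export
classify_frustration <- function(index) {
  out <- ifelse(index > 0.78, "minimal",
                ifelse(index < -1, "high", "neutral"))
  out[!is.finite(index)] <- NA_character_
  out
}

#' Full frustration profile of a structure
#'
#' Per-residue SRLF with class labels, and per-contact mutational and
#' configurational indices with class labels. Items whose decoy ensembles
#' have zero spread (or residues without contacts) are reported with `NA`
#' index and class `"undefined"`.
#'
#' @param s a [protstruct].
#' @param pot contact potential (default [contact_potential]).
#' @param cutoff contact cutoff (default 5).
#' @param n_decoys configurational decoy count (default 1000).
#' @param seed RNG seed for configurational decoys.
#' @param burial_weight burial term weight (default 0).
#' @return object of class `frustration_profile`: `residues` data.frame
#'   (`residue`, `srlf`, `class`), `contacts` data.frame (`i`, `j`,
#'   `dist`, `mfi`, `mfi_class`, `cfi`, `cfi_class`), `seed`, `n_decoys`.
#' @export
frustration_profile <- function(s, pot = contact_potential(), cutoff = 5,
                                n_decoys = 1000, seed = 1,
                                burial_weight = 0) {
  cl <- contact_list(s, cutoff)
  seqs <- structure_sequence(s)
  burial <- tabulate(c(cl$i, cl$j), nbins = n_residues(s))
  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  res <- data.frame(residue = seq_len(n_residues(s)), srlf = NA_real_)
  for (r in res$residue)
    res$srlf[res$residue == r] <-
      safe(srlf(r, s, pot, cutoff, burial_weight))
  res$class <- classify_frustration(res$srlf)
  res$class[is.na(res$srlf)] <- "undefined"

  mfi <- cfi <- rep(NA_real_, nrow(cl))
  if (nrow(cl) > 0) {
    ctx_ok <- n_residues(s) >= 10
    for (k in seq_len(nrow(cl))) {
      co <- list(aa_i = seqs[cl$i[k]], aa_j = seqs[cl$j[k]],
                 dist = cl$dist[k],
                 burial_i = burial[cl$i[k]], burial_j = burial[cl$j[k]])
      if (co$aa_i %in% AA20 && co$aa_j %in% AA20) {
        e_nat <- contact_energy(co$aa_i, co$aa_j, co$dist, pot,
                                co$burial_i, co$burial_j, burial_weight)
        mfi[k] <- safe(frustration_index(
          e_nat, decoys_mutational(co, pot, burial_weight = burial_weight)))
        if (ctx_ok)
          cfi[k] <- safe(frustration_index(
            e_nat, decoys_configurational(co, s, pot, n = n_decoys,
                                          seed = seed + k,
                                          burial_weight = burial_weight,
                                          cutoff = cutoff)))
      }
    }
  }
  contacts <- cbind(cl, mfi = mfi, mfi_class = classify_frustration(mfi),
                    cfi = cfi, cfi_class = classify_frustration(cfi))
  contacts$mfi_class[is.na(mfi)] <- "undefined"
  contacts$cfi_class[is.na(cfi)] <- "undefined"
  structure(list(residues = res, contacts = contacts, seed = seed,
                 n_decoys = n_decoys), class = "frustration_profile")
}

#' @export
print.frustration_profile <- function(x, ...) {
  cat("frustration_profile: ", nrow(x$residues), " residues, ",
      nrow(x$contacts), " contacts\n", sep = "")
  print(table(x$residues$class))
  invisible(x)
}
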