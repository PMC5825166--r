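#' Protein structure container
#'
#' A `protstruct` holds one polypeptide chain as an ordered atom table.
#' Residue order follows file order; the residue identity key is
#' (chain, residue number, insertion code).
#'
#' @param atoms data.frame with columns `chain`, `resno`, `ins`, `resname`,
#'   `atom`, `element`, `x`, `y`, `z`, `occ` (coordinates in Angstrom).
#' @param id text label for the structure.
#' @return An object of class `protstruct` with components `id`, `atoms`
#'   (atom table plus a `resindex` column) and `residues` (one row per
#'   residue, in file order).
#' @export
protstruct <- function(atoms, id = "structure") {
  need <- c("chain", "resno", "ins", "resname", "atom", "element",
            "x", "y", "z", "occ")
  if (!is.data.frame(atoms) || !all(need %in% names(atoms)))
    stop("atoms must be a data.frame with columns: ",
         paste(need, collapse = ", "))
  atoms <- as.data.frame(atoms)[, need]
  atoms$ins[is.na(atoms$ins)] <- ""
  key <- paste(atoms$chain, atoms$resno, atoms$ins, sep = ":")
  atoms$resindex <- match(key, unique(key))
  residues <- atoms[!duplicated(key),
                    c("chain", "resno", "ins", "resname", "resindex")]
  rownames(residues) <- NULL
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms, residues = residues),
            class = "protstruct")
}

#' @export
print.protstruct <- function(x, ...) {
  cat("protstruct '", x$id, "': ", nrow(x$residues), " residues, ",
      nrow(x$atoms), " atoms (chain ",
      paste(unique(x$residues$chain), collapse = ","), ")\n", sep = "")
  invisible(x)
}

#' Number of residues in a structure
#' @param s a `protstruct`.
#' @return integer count.
#' @export
n_residues <- function(s) nrow(s$residues)

#' Residue identity keys ("chain:resno:ins")
#' @param s a `protstruct`.
#' @return character vector, one key per residue in order.
#' @export
residue_keys <- function(s)
  paste(s$residues$chain, s$residues$resno, s$residues$ins, sep = ":")

#' C-alpha coordinates of a structure
#'
#' @param s a `protstruct`.
#' @param strict error if any residue lacks a CA atom (default TRUE, since
#'   every C-alpha-based operation requires one per residue).
#' @return numeric matrix N x 3 with a `resindex` attribute giving the
#'   residue index of each row.
#' @export
ca_coords <- function(s, strict = TRUE) {
  ca <- s$atoms[s$atoms$atom == "CA", ]
  ca <- ca[!duplicated(ca$resindex), ]
  if (strict && nrow(ca) < n_residues(s))
    stop("structure '", s$id, "': ", n_residues(s) - nrow(ca),
         " residue(s) lack a CA atom")
  m <- unname(as.matrix(ca[, c("x", "y", "z")]))
  attr(m, "resindex") <- ca$resindex
  m
}

#' One-letter amino-acid sequence of a structure
#' @param s a `protstruct`.
#' @return character vector of one-letter codes ("X" for non-standard).
#' @export
structure_sequence <- function(s) {
  aa <- bio3d::aa321(s$residues$resname)
  aa[is.na(aa) | aa == ""] <- "X"
  aa
}

#' Read a protein structure from PDB text or file
#'
#' Parses ATOM records of the first model. Heteroatoms and waters are
#' dropped; for alternate locations the highest-occupancy conformer is kept
#' (ties: first in file). Exactly one polypeptide chain is required unless
#' `chain` selects one.
#'
#' @param pdb path to a PDB file, or a character scalar of PDB-format text.
#' @param chain optional chain identifier to select from a multi-chain file.
#' @param id label for the returned structure (defaults to the file name).
#' @return a [protstruct].
#' @export
read_structure <- function(pdb, chain = NULL, id = NULL) {
  if (length(pdb) != 1L || !is.character(pdb))
    stop("pdb must be a single path or PDB text string")
  path <- pdb
  if (grepl("\n", pdb) || !file.exists(pdb)) {
    if (!grepl("\n", pdb)) stop("file not found: ", pdb)
    path <- tempfile(fileext = ".pdb")
    writeLines(pdb, path)
    on.exit(unlink(path))
    if (is.null(id)) id <- "structure"
  }
  if (is.null(id)) id <- sub("\\.pdb$", "", basename(path))
  raw <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("PDB parse error: ", conditionMessage(e)))
  a <- raw$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  if (nrow(a) == 0) stop("PDB parse error: no ATOM records")
  a$chain[is.na(a$chain)] <- " "
  chains <- unique(a$chain)
  if (!is.null(chain)) {
    if (!chain %in% chains) stop("chain '", chain, "' not present")
    a <- a[a$chain == chain, , drop = FALSE]
  } else if (length(chains) > 1) {
    stop("multi-chain structure (chains ", paste(chains, collapse = ","),
         "); pass chain= to select one")
  }
  a$insert[is.na(a$insert)] <- ""
  a$o[is.na(a$o)] <- 1
  a$alt[is.na(a$alt)] <- ""
  # altloc policy: per residue, keep atoms with no altloc plus the single
  # conformer whose summed occupancy is highest (ties: first in file)
  rkey <- paste(a$chain, a$resno, a$insert, sep = ":")
  keep <- rep(TRUE, nrow(a))
  for (k in unique(rkey[a$alt != ""])) {
    rows <- which(rkey == k & a$alt != "")
    occ <- vapply(split(a$o[rows], a$alt[rows]), sum, numeric(1))
    # preserve file order of alt codes for tie-breaking
    alts <- unique(a$alt[rows])
    occ <- occ[alts]
    best <- alts[which.max(occ)]
    keep[rows[a$alt[rows] != best]] <- FALSE
  }
  a <- a[keep, , drop = FALSE]
  elem <- a$elesy
  bad <- is.na(elem) | elem == ""
  if (any(bad)) # fall back to first letter of the atom name
    elem[bad] <- substr(gsub("[0-9 ]", "", a$elety[bad]), 1, 1)
  atoms <- data.frame(chain = a$chain, resno = a$resno, ins = a$insert,
                      resname = a$resid, atom = a$elety, element = elem,
                      x = a$x, y = a$y, z = a$z, occ = a$o,
                      stringsAsFactors = FALSE)
  s <- protstruct(atoms, id = id)
  if (!any(s$atoms$atom == "CA")) stop("PDB parse error: no CA atoms")
  s
}

#' Write a structure to a PDB file
#' @param s a [protstruct].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_structure <- function(s, file) {
  at <- s$atoms
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(at)),
                   resno = at$resno, resid = at$resname,
                   eleno = seq_len(nrow(at)), elety = at$atom,
                   chain = at$chain, insert = at$ins,
                   o = at$occ, b = rep(0, nrow(at)), elesy = at$element)
  invisible(file)
}

#' Domain definition by residue ranges
#'
#' @param id domain label.
#' @param segments data.frame with columns `chain`, `start`, `end`
#'   (1-based inclusive residue-number ranges, SCOPe style).
#' @return object of class `domaindef`.
#' @export
domain_def <- function(id, segments) {
  if (!is.data.frame(segments) ||
      !all(c("chain", "start", "end") %in% names(segments)))
    stop("segments must have columns chain, start, end")
  segments <- as.data.frame(segments)[, c("chain", "start", "end")]
  if (any(segments$end < segments$start))
    stop("definition error: segment end before start")
  # non-overlap within a chain
  for (ch in unique(segments$chain)) {
    sg <- segments[segments$chain == ch, , drop = FALSE]
    sg <- sg[order(sg$start), , drop = FALSE]
    if (nrow(sg) > 1 && any(sg$start[-1] <= sg$end[-nrow(sg)]))
      stop("definition error: overlapping segments in domain '", id, "'")
  }
  structure(list(id = id, segments = segments), class = "domaindef")
}

domain_residue_indices <- function(s, d) {
  res <- s$residues
  sel <- rep(FALSE, nrow(res))
  for (i in seq_len(nrow(d$segments))) {
    sg <- d$segments[i, ]
    hit <- res$chain == sg$chain & res$resno >= sg$start & res$resno <= sg$end
    if (!any(hit))
      stop("boundary error: segment ", sg$chain, ":", sg$start, "-", sg$end,
           " of domain '", d$id, "' matches no residue of '", s$id, "'")
    sel <- sel | hit
  }
  which(sel)
}

#' Extract a domain from a structure
#'
#' Returns the residues inside the definition's segments with original
#' numbering and coordinates preserved.
#'
#' @param s a [protstruct].
#' @param d a [domain_def].
#' @return a [protstruct] restricted to the domain.
#' @export
extract_domain <- function(s, d) {
  idx <- domain_residue_indices(s, d)
  at <- s$atoms[s$atoms$resindex %in% idx, , drop = FALSE]
  protstruct(at, id = paste0(s$id, ":", d$id))
}

complement_domain <- function(s, d) {
  idx <- setdiff(seq_len(n_residues(s)), domain_residue_indices(s, d))
  if (length(idx) == 0) stop("domain covers the whole structure")
  at <- s$atoms[s$atoms$resindex %in% idx, , drop = FALSE]
  protstruct(at, id = paste0(s$id, ":not-", d$id))
}

#' Map the common domain between two structures
#'
#' Global sequence alignment (match +1, mismatch -1, linear gap -2) of the
#' one-letter sequences. In `"identical"` mode only identical aligned
#' columns are mapped and an identity below `min_identity` is an error
#' (identical-domain pairs may differ only by short terminal extensions);
#' in `"homolog"` mode all aligned non-gap columns are mapped.
#'
#' @param a,b [protstruct] objects (single domains).
#' @param mode `"identical"` or `"homolog"`.
#' @param min_identity minimum identity fraction accepted in identical mode.
#' @return object of class `residue_mapping`: list with `pairs` (2-column
#'   matrix of residue indices in `a` and `b`, strictly increasing in both)
#'   and `identity` (fraction over aligned non-gap columns).
#' @export
map_common_domain <- function(a, b, mode = c("identical", "homolog"),
                              min_identity = 0.9) {
  mode <- match.arg(mode)
  sa <- structure_sequence(a)
  sb <- structure_sequence(b)
  ab <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V", "X")
  sm <- matrix(-1, length(ab), length(ab), dimnames = list(ab, ab))
  diag(sm) <- 1
  sm["X", "X"] <- 0
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(paste(sa, collapse = "")),
    Biostrings::AAString(paste(sb, collapse = "")),
    type = "global", substitutionMatrix = sm,
    gapOpening = 0, gapExtension = 2)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- cumsum(pa != "-")
  ib <- cumsum(pb != "-")
  col <- pa != "-" & pb != "-"
  same <- col & pa == pb
  identity <- if (any(col)) sum(same) / sum(col) else 0
  if (mode == "identical") {
    if (identity < min_identity)
      stop("pairing error: sequence identity ", sprintf("%.3f", identity),
           " below ", min_identity, " for '", a$id, "' vs '", b$id, "'")
    keep <- same
  } else keep <- col
  pairs <- cbind(a = ia[keep], b = ib[keep])
  structure(list(pairs = pairs, identity = identity, mode = mode),
            class = "residue_mapping")
}

#' @export
print.residue_mapping <- function(x, ...) {
  cat("residue_mapping: ", nrow(x$pairs), " aligned pairs, identity ",
      sprintf("%.3f", x$identity), " (", x$mode, " mode)\n", sep = "")
  invisible(x)
}

#' Van der Waals radii table
#'
#' Element-based radii (Angstrom) used by the interface criterion.
#' @return named numeric vector.
#' @export
vdw_radii <- function()
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)

atom_radius <- function(element, radii) {
  r <- radii[element]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Domain-domain interface residues
#'
#' A residue of either domain is an interface residue iff some atom pair
#' across the two domains is at a distance strictly less than the sum of the
#' atoms' van der Waals radii plus `margin`.
#'
#' @param s a [protstruct].
#' @param da,db [domain_def] objects; `db = NULL` uses the complement of
#'   `da` (all remaining residues of `s`).
#' @param radii named element-to-Angstrom radii table.
#' @param margin additive margin in Angstrom (default 0.5).
#' @return object of class `interface_set`: list with `residues` (residue
#'   indices of `s` in the set), `residues_a`, `residues_b`, and `contacts`
#'   (data.frame of atom pairs with distances).
#' @export
interface_residues <- function(s, da, db = NULL, radii = vdw_radii(),
                               margin = 0.5) {
  ia <- domain_residue_indices(s, da)
  ib <- if (is.null(db)) setdiff(seq_len(n_residues(s)), ia)
        else domain_residue_indices(s, db)
  if (length(intersect(ia, ib)) > 0)
    stop("definition error: overlapping domain definitions")
  at <- s$atoms
  aa <- at[at$resindex %in% ia, , drop = FALSE]
  bb <- at[at$resindex %in% ib, , drop = FALSE]
  if (nrow(aa) == 0 || nrow(bb) == 0)
    return(structure(list(residues = integer(0), residues_a = integer(0),
                          residues_b = integer(0),
                          contacts = data.frame()), class = "interface_set"))
  xa <- as.matrix(aa[, c("x", "y", "z")])
  xb <- as.matrix(bb[, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  d2[d2 < 0] <- 0
  dm <- sqrt(d2)
  thr <- outer(atom_radius(aa$element, radii),
               atom_radius(bb$element, radii), "+") + margin
  # strict inequality, robust to float rounding far below PDB precision
  hit <- which(dm < thr - 1e-9, arr.ind = TRUE)
  if (nrow(hit) == 0)
    return(structure(list(residues = integer(0), residues_a = integer(0),
                          residues_b = integer(0),
                          contacts = data.frame()), class = "interface_set"))
  contacts <- data.frame(
    res_a = aa$resindex[hit[, 1]], res_b = bb$resindex[hit[, 2]],
    atom_a = paste0(aa$chain[hit[, 1]], ":", aa$resno[hit[, 1]], ":",
                    aa$atom[hit[, 1]]),
    atom_b = paste0(bb$chain[hit[, 2]], ":", bb$resno[hit[, 2]], ":",
                    bb$atom[hit[, 2]]),
    dist = dm[hit], stringsAsFactors = FALSE)
  structure(list(residues = sort(unique(c(contacts$res_a, contacts$res_b))),
                 residues_a = sort(unique(contacts$res_a)),
                 residues_b = sort(unique(contacts$res_b)),
                 contacts = contacts), class = "interface_set")
}

#' Read a domain/functional-residue configuration file
#'
#' YAML or JSON with fields `structure` (path), `domains` (list of
#' `{id, segments: [[chain, start, end], ...]}`) and optional
#' `functional_residues` (residue numbers).
#'
#' @param path configuration file.
#' @return list with `structure`, `domains` (list of [domain_def]) and
#'   `functional_residues` (integer vector).
#' @export
read_domain_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path, simplifyVector = FALSE)
  doms <- lapply(cfg$domains, function(d) {
    seg <- do.call(rbind, lapply(d$segments, function(s)
      data.frame(chain = as.character(s[[1]]), start = as.integer(s[[2]]),
                 end = as.integer(s[[3]]), stringsAsFactors = FALSE)))
    domain_def(d$id, seg)
  })
  list(structure = cfg$structure, domains = doms,
       functional_residues = as.integer(unlist(cfg$functional_residues)))
}
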