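#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum of the ECDF difference; the p-value uses the
#' asymptotic Kolmogorov distribution with effective sample size
#' `n_x n_y / (n_x + n_y)`.
#'
#' @param x,y numeric samples (non-empty).
#' @return list with `statistic` (D) and `p.value`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties).
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return rho.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need equal lengths >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined error: constant input")
  unname(stats::cor(x, y, method = "spearman"))
}

#' Upper-quartile cutoff of a distribution
#'
#' 75th percentile by linear interpolation between order statistics
#' (type-7 convention).
#'
#' @param values numeric vector (>= 4 values).
#' @return upper quartile.
#' @export
quartile_cutoff <- function(values) {
  if (length(values) < 4) stop("need at least 4 values")
  unname(stats::quantile(values, 0.75, type = 7))
}

#' Analysis configuration with the pipeline's fixed thresholds
#'
#' @param network_cutoff C-alpha contact-network cutoff (Angstrom).
#' @param anm_cutoff ANM cutoff (Angstrom).
#' @param gdt_cutoff GDT distance cutoff (Angstrom).
#' @param interface_margin additive margin on the vdW-radii sum (Angstrom).
#' @param coc_threshold normalized-centrality difference flag threshold.
#' @param coupling_threshold cross-correlation coupling threshold.
#' @param rmsd_cutoff significant-deviation RMSD cutoff (Angstrom).
#' @param gdt_complement_cutoff significant-deviation 100-GDT cutoff.
#' @param trim residues trimmed per terminus before fluctuation z-scoring.
#' @param n_decoys configurational decoy count.
#' @param seed seed for all stochastic stages.
#' @param radii vdW radii table for interface detection (C-alpha-only
#'   synthetic structures use an enlarged effective radius).
#' @param potential frustration contact potential.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(network_cutoff = 5, anm_cutoff = 15,
                            gdt_cutoff = 4, interface_margin = 0.5,
                            coc_threshold = 1.5, coupling_threshold = 0.7,
                            rmsd_cutoff = 1, gdt_complement_cutoff = 5,
                            trim = 5, n_decoys = 1000, seed = 1,
                            radii = vdw_radii(),
                            potential = contact_potential()) {
  cfg <- list(network_cutoff = network_cutoff, anm_cutoff = anm_cutoff,
              gdt_cutoff = gdt_cutoff, interface_margin = interface_margin,
              coc_threshold = coc_threshold,
              coupling_threshold = coupling_threshold,
              rmsd_cutoff = rmsd_cutoff,
              gdt_complement_cutoff = gdt_complement_cutoff,
              trim = trim, n_decoys = n_decoys, seed = seed,
              radii = radii, potential = potential)
  num <- unlist(cfg[1:11])
  if (any(num <= 0)) stop("all thresholds must be positive")
  structure(cfg, class = "analysis_config")
}

restricted_z <- function(values, keep) {
  z <- rep(NA_real_, length(values))
  z[keep] <- normalize_profile(values[keep])
  z
}

#' Full comparative analysis of a tethered/isolated domain pair
#'
#' Runs the pipeline stages on the common domain of an MD/ID pair:
#' superposition and deviation profiling with two-sigma region detection
#' and interface-based categorization, contact-network communicability
#' comparison, ANM fluctuation / cross-correlation / Rv comparison, and
#' frustration class-change detection. Deterministic given the
#' configuration seed.
#'
#' @param md multi-domain member ([protstruct]).
#' @param id isolated member ([protstruct]).
#' @param common [domain_def] of the common domain within `md`; `NULL`
#'   when `md` is the domain itself (self/whole-structure comparison).
#' @param cfg an [analysis_config].
#' @param functional optional residue numbers (common-domain numbering)
#'   annotated in the report.
#' @param stages subset of `c("structure", "network", "dynamics",
#'   "frustration")` to run.
#' @param network_scope `"common"` builds networks on the common domain
#'   only (intra-domain rewiring); `"whole"` uses the full multi-domain
#'   network before restriction.
#' @return object of class `pair_report`.
#' @export
analyze_pair <- function(md, id, common = NULL, cfg = analysis_config(),
                         functional = NULL,
                         stages = c("structure", "network", "dynamics",
                                    "frustration"),
                         network_scope = c("common", "whole")) {
  network_scope <- match.arg(network_scope)
  if (is.null(common))
    common <- domain_def("common", data.frame(
      chain = md$residues$chain[1], start = min(md$residues$resno),
      end = max(md$residues$resno)))
  md_common <- extract_domain(md, common)
  mapping <- map_common_domain(md_common, id)
  dom_idx <- domain_residue_indices(md, common)
  has_tether <- length(dom_idx) < n_residues(md)
  pa <- mapping$pairs[, 1]; pb <- mapping$pairs[, 2]

  xa <- ca_coords(md_common); xb <- ca_coords(id)
  ia <- match(pa, attr(xa, "resindex")); ib <- match(pb, attr(xb, "resindex"))
  func_idx <- if (is.null(functional)) integer(0) else
    which(md_common$residues$resno %in% functional)

  report <- list(mapping = mapping, config = cfg, ids = c(md = md$id, id = id$id))

  iface_common <- integer(0)
  if (has_tether) {
    iface <- interface_residues(md, common, NULL, radii = cfg$radii,
                                margin = cfg$interface_margin)
    iface_common <- match(intersect(iface$residues, dom_idx), dom_idx)
    report$interface <- sort(iface_common)
  } else report$interface <- integer(0)

  if ("structure" %in% stages) {
    dev <- deviation_profile(xa[ia, , drop = FALSE], xb[ib, , drop = FALSE],
                             gdt_cutoff = cfg$gdt_cutoff)
    flagged_common <- pa[dev$flagged]
    report$structural <- list(
      rmsd = dev$rmsd, gdt = dev$gdt, gdt_complement = dev$gdt_complement,
      category = classify_pair(flagged_common, report$interface),
      significant = dev$rmsd > cfg$rmsd_cutoff ||
        dev$gdt_complement > cfg$gdt_complement_cutoff,
      profile = data.frame(
        res_common = pa, res_id = pb, distance = dev$distances,
        flagged = seq_along(pa) %in% dev$flagged,
        interface = pa %in% report$interface,
        functional = pa %in% func_idx),
      flagged = flagged_common, regions = dev$regions)
  }

  if ("network" %in% stages) {
    if (network_scope == "common") {
      coc_md_raw <- communicability_centrality(
        build_network(md_common, cfg$network_cutoff))
      norm_md <- normalize_profile(coc_md_raw)
    } else {
      coc_all <- communicability_centrality(
        build_network(md, cfg$network_cutoff))
      coc_md_raw <- coc_all[dom_idx]
      norm_md <- normalize_profile(coc_md_raw)
    }
    coc_id_raw <- communicability_centrality(
      build_network(id, cfg$network_cutoff))
    norm_id <- normalize_profile(coc_id_raw)
    tab <- centrality_difference(norm_md, norm_id, mapping,
                                 threshold = cfg$coc_threshold)
    tab$raw_md <- coc_md_raw[tab$res_a]
    tab$raw_id <- coc_id_raw[tab$res_b]
    tab$norm_md <- norm_md[tab$res_a]
    tab$norm_id <- norm_id[tab$res_b]
    report$network <- list(table = tab, n_flagged = sum(tab$flagged),
                           scope = network_scope)
  }

  if ("dynamics" %in% stages) {
    run_member <- function(s, common_residue_index) {
      m <- build_anm(ca_coords(s), cutoff = cfg$anm_cutoff)
      modes <- select_modes_80(m)
      fl <- square_fluctuations(m, modes)
      n <- length(fl)
      kept <- (cfg$trim + 1):(n - cfg$trim)
      list(model = m, modes = modes, fluc = fl,
           retained = intersect(kept, common_residue_index),
           cc = cross_correlation(m, modes))
    }
    mem_md <- run_member(md, dom_idx[pa])
    mem_id <- run_member(id, pb)
    z_md <- restricted_z(mem_md$fluc, mem_md$retained)
    z_id <- restricted_z(mem_id$fluc, mem_id$retained)
    both <- dom_idx[pa] %in% mem_md$retained & pb %in% mem_id$retained
    fluc_tab <- data.frame(
      res_common = pa[both], res_id = pb[both],
      md_norm = z_md[dom_idx[pa[both]]], id_norm = z_id[pb[both]],
      interface = pa[both] %in% report$interface,
      functional = pa[both] %in% func_idx)
    fluc_tab$delta <- fluc_tab$md_norm - fluc_tab$id_norm
    cc_md <- mem_md$cc[dom_idx[pa], dom_idx[pa], drop = FALSE]
    cc_id <- mem_id$cc[pb, pb, drop = FALSE]
    report$dynamics <- list(
      fluctuations = fluc_tab,
      cc_md = cc_md, cc_id = cc_id,
      rv = rv_coefficient(cc_md, cc_id),
      coupling_md = coupling_fraction(cc_md, cfg$coupling_threshold),
      coupling_id = coupling_fraction(cc_id, cfg$coupling_threshold))
  }

  if ("frustration" %in% stages) {
    fp_md <- frustration_profile(md_common, pot = cfg$potential,
                                 cutoff = cfg$network_cutoff,
                                 n_decoys = cfg$n_decoys, seed = cfg$seed)
    fp_id <- frustration_profile(id, pot = cfg$potential,
                                 cutoff = cfg$network_cutoff,
                                 n_decoys = cfg$n_decoys, seed = cfg$seed)
    srlf_tab <- data.frame(
      res_common = pa, res_id = pb,
      srlf_md = fp_md$residues$srlf[pa], class_md = fp_md$residues$class[pa],
      srlf_id = fp_id$residues$srlf[pb], class_id = fp_id$residues$class[pb])
    srlf_tab$changed <- srlf_tab$class_md != srlf_tab$class_id &
      srlf_tab$class_md != "undefined" & srlf_tab$class_id != "undefined"
    # contacts present (mapped) in both members
    a2b <- stats::setNames(pb, pa)
    cm <- fp_md$contacts
    key_id <- paste(fp_id$contacts$i, fp_id$contacts$j)
    mi <- a2b[as.character(cm$i)]; mj <- a2b[as.character(cm$j)]
    hit <- match(paste(pmin(mi, mj), pmax(mi, mj)), key_id)
    shared <- which(!is.na(hit))
    contact_tab <- data.frame(
      i = cm$i[shared], j = cm$j[shared],
      mfi_md = cm$mfi[shared], mfi_id = fp_id$contacts$mfi[hit[shared]],
      mfi_class_md = cm$mfi_class[shared],
      mfi_class_id = fp_id$contacts$mfi_class[hit[shared]],
      cfi_md = cm$cfi[shared], cfi_id = fp_id$contacts$cfi[hit[shared]],
      cfi_class_md = cm$cfi_class[shared],
      cfi_class_id = fp_id$contacts$cfi_class[hit[shared]])
    defined <- function(a, b) a != "undefined" & b != "undefined"
    contact_tab$mfi_changed <- contact_tab$mfi_class_md !=
      contact_tab$mfi_class_id &
      defined(contact_tab$mfi_class_md, contact_tab$mfi_class_id)
    contact_tab$cfi_changed <- contact_tab$cfi_class_md !=
      contact_tab$cfi_class_id &
      defined(contact_tab$cfi_class_md, contact_tab$cfi_class_id)
    report$frustration <- list(
      residues = srlf_tab, contacts = contact_tab,
      n_srlf_changes = sum(srlf_tab$changed, na.rm = TRUE),
      n_mfi_changes = sum(contact_tab$mfi_changed, na.rm = TRUE),
      n_cfi_changes = sum(contact_tab$cfi_changed, na.rm = TRUE))
  }

  structure(report, class = "pair_report")
}

#' @export
print.pair_report <- function(x, ...) {
  cat("pair_report:", x$ids["md"], "vs", x$ids["id"], "\n")
  if (!is.null(x$structural))
    cat(sprintf("  RMSD %.4f A  GDT %.2f  (100-GDT %.2f)  category: %s\n",
                x$structural$rmsd, x$structural$gdt,
                x$structural$gdt_complement, x$structural$category))
  if (!is.null(x$network))
    cat("  centrality flags:", x$network$n_flagged, "\n")
  if (!is.null(x$dynamics))
    cat(sprintf("  Rv %.4f  coupling MD %.4f  ID %.4f\n",
                x$dynamics$rv, x$dynamics$coupling_md,
                x$dynamics$coupling_id))
  if (!is.null(x$frustration))
    cat("  frustration class changes: SRLF", x$frustration$n_srlf_changes,
        " MFI", x$frustration$n_mfi_changes,
        " CFI", x$frustration$n_cfi_changes, "\n")
  invisible(x)
}

#' Comparative dynamics of a homologous single/multi-domain pair
#'
#' Grafts the single-domain protein into the multi-domain scaffold (the
#' chimera), runs ANM on all three, and compares normalized fluctuations
#' and cross-correlation sub-matrices at the functional residues. Only
#' mapped positions with identical amino acids in both homologs enter the
#' comparison.
#'
#' @param single single-domain [protstruct].
#' @param multi multi-domain [protstruct].
#' @param domain [domain_def] of the homologous domain within `multi`.
#' @param functional residue numbers of the functional residues in
#'   `multi`'s numbering.
#' @param cfg an [analysis_config].
#' @return object of class `homolog_report`: per-residue fluctuation
#'   table, functional-residue cross-correlation sub-matrices for all
#'   three structures, and Rv coefficients of single and chimera against
#'   the multi-domain member.
#' @export
analyze_homolog_pair <- function(single, multi, domain, functional,
                                 cfg = analysis_config()) {
  dom <- extract_domain(multi, domain)
  mapping <- map_common_domain(single, dom, mode = "homolog")
  dom_idx <- domain_residue_indices(multi, domain)
  seq_s <- structure_sequence(single)
  seq_d <- structure_sequence(dom)
  identical_pos <- seq_s[mapping$pairs[, 1]] == seq_d[mapping$pairs[, 2]]

  func_dom <- which(dom$residues$resno %in% functional)
  sel <- identical_pos & mapping$pairs[, 2] %in% func_dom
  if (!any(sel))
    stop("comparison error: no identical functional residues mapped")
  f_single <- mapping$pairs[sel, 1]
  f_dom <- mapping$pairs[sel, 2]
  f_multi <- dom_idx[f_dom]

  ch <- build_chimera(single, multi,
                      list(domain = domain, mapping = mapping))
  # functional residues in the chimera come from the grafted single parent
  prov <- ch$record$provenance
  single_keys <- paste(single$residues$chain[f_single],
                       single$residues$resno[f_single])
  prov_keys <- paste(prov$parent_chain, prov$parent_resno)
  f_chim <- prov$resno[prov$parent == single$id][
    match(single_keys, prov_keys[prov$parent == single$id])]
  if (anyNA(f_chim))
    stop("comparison error: functional residue trimmed from the chimera")

  run <- function(s) {
    m <- build_anm(ca_coords(s), cutoff = cfg$anm_cutoff)
    modes <- select_modes_80(m)
    fl <- square_fluctuations(m, modes)
    nf <- normalize_fluctuations(fl, trim = cfg$trim)
    z <- rep(NA_real_, length(fl)); z[nf$kept] <- nf$normalized
    list(z = z, cc = cross_correlation(m, modes))
  }
  r_single <- run(single); r_multi <- run(multi)
  r_chim <- run(ch$structure)

  fluc <- data.frame(
    res_multi = multi$residues$resno[f_multi],
    res_single = single$residues$resno[f_single],
    res_chimera = f_chim,
    multi = r_multi$z[f_multi], single = r_single$z[f_single],
    chimera = r_chim$z[f_chim])
  cc_m <- r_multi$cc[f_multi, f_multi, drop = FALSE]
  cc_s <- r_single$cc[f_single, f_single, drop = FALSE]
  cc_c <- r_chim$cc[f_chim, f_chim, drop = FALSE]
  structure(list(fluctuations = fluc, cc_multi = cc_m, cc_single = cc_s,
                 cc_chimera = cc_c,
                 rv_single_multi = rv_coefficient(cc_s, cc_m),
                 rv_chimera_multi = rv_coefficient(cc_c, cc_m),
                 chimera = ch, mapping = mapping),
            class = "homolog_report")
}

#' Write a pair report to disk
#'
#' Emits `summary.json` plus per-residue TSV tables (deviation,
#' centrality, fluctuations, frustration) and cross-correlation matrices
#' as TSV.
#'
#' @param report a [analyze_pair] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pair_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(md = unname(report$ids["md"]),
                  id = unname(report$ids["id"]),
                  identity = report$mapping$identity,
                  n_mapped = nrow(report$mapping$pairs))
  if (!is.null(report$structural)) {
    s <- report$structural
    summary$structural <- list(rmsd = round(s$rmsd, 4), gdt = round(s$gdt, 4),
                               gdt_complement = round(s$gdt_complement, 4),
                               category = s$category,
                               significant = s$significant)
    tsv(s$profile, "deviation.tsv")
  }
  if (!is.null(report$network)) {
    summary$network <- list(n_flagged = report$network$n_flagged,
                            scope = report$network$scope)
    tsv(report$network$table, "centrality.tsv")
  }
  if (!is.null(report$dynamics)) {
    d <- report$dynamics
    summary$dynamics <- list(rv = round(d$rv, 4),
                             coupling_md = round(d$coupling_md, 4),
                             coupling_id = round(d$coupling_id, 4))
    tsv(d$fluctuations, "fluctuations.tsv")
    tsv(as.data.frame(d$cc_md), "cc_md.tsv")
    tsv(as.data.frame(d$cc_id), "cc_id.tsv")
  }
  if (!is.null(report$frustration)) {
    f <- report$frustration
    summary$frustration <- list(n_srlf_changes = f$n_srlf_changes,
                                n_mfi_changes = f$n_mfi_changes,
                                n_cfi_changes = f$n_cfi_changes)
    tsv(f$residues, "srlf.tsv")
    tsv(f$contacts, "contacts.tsv")
  }
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
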