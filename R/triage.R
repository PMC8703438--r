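# Docking-model triage: a docked two-domain pose is eligible when (1) at
# least one exosite-3 residue of the Spacer domain lies on the interface and
# (2) none of the Spacer beta6-beta7 loop residues (default 621-623, which
# must stay free to bind the adjacent Cys domain) does.  Eligible models are
# ranked by their static-interface contact inventory, salt bridges weighted
# above hydrogen bonds.

#' Triage a docked complex model
#'
#' @param structure a single-conformation `complex_structure` with both
#'   domains
#' @param roles a `role_config` (validated against the structure)
#' @param chem a `chemistry_table` for the static contact inventory
#' @param interface_cutoff heavy-atom contact cutoff in Angstrom (default 5)
#' @param d_cut,a_cut,sb_cut detection criteria for the static inventory
#' @param model_id identifier carried into reports (default the structure's
#'   variable name)
#' @return object of class `triage_report`: list with `model_id`,
#'   `criterion_exosite3`, `criterion_loop_free`, `eligible`, `hbonds` and
#'   `saltbridges` (residue-pair data.frames), `n_hbonds`, `n_saltbridges`,
#'   `interface` (the interface residue pairs)
#' @export
triage_model <- function(structure, roles = role_config(),
                         chem = default_chemistry(), interface_cutoff = 5.0,
                         d_cut = 3.5, a_cut = 150, sb_cut = 4.0,
                         model_id = deparse(substitute(structure))) {
  stopifnot(inherits(structure, "complex_structure"))
  .require_domains(structure)
  validate_roles(structure, roles)
  iface <- interface_residues(structure = structure, cutoff = interface_cutoff)
  crit1 <- any(roles$exosite3_residues %in% iface$spacer_resno)
  crit2 <- !any(roles$triage_forbidden_residues %in% iface$spacer_resno)
  hb <- detect_hbonds_frame(structure = structure, chem = chem,
                            d_cut = d_cut, a_cut = a_cut)
  sb <- detect_saltbridges_frame(structure = structure, chem = chem,
                                 d_cut = sb_cut)
  hb_pairs <- unique(hb[, c("tsp8_resno", "tsp8_resid",
                            "spacer_resno", "spacer_resid")])
  sb_pairs <- unique(sb[, c("tsp8_resno", "tsp8_resid",
                            "spacer_resno", "spacer_resid")])
  structure(list(
    model_id = model_id,
    criterion_exosite3 = crit1, criterion_loop_free = crit2,
    eligible = crit1 && crit2,
    hbonds = hb_pairs, saltbridges = sb_pairs,
    n_hbonds = nrow(hb_pairs), n_saltbridges = nrow(sb_pairs),
    interface = iface), class = "triage_report")
}

#' @export
print.triage_report <- function(x, ...) {
  cat(sprintf(
    "triage_report '%s': exosite-3 on interface: %s; loop 621-623 free: %s; eligible: %s\n",
    x$model_id, x$criterion_exosite3, x$criterion_loop_free, x$eligible))
  cat(sprintf("  static interface: %d H-bond pairs, %d salt-bridge pairs\n",
              x$n_hbonds, x$n_saltbridges))
  invisible(x)
}

#' Rank triaged docking models
#'
#' Eligible models come first, ordered by descending salt-bridge count, then
#' descending H-bond count (salt bridges weigh more because they mark the
#' more stable static interfaces); ineligible models are appended in the
#' same order.  Remaining ties break deterministically by model id.
#'
#' @param reports list of `triage_report` objects (at least one)
#' @return the reports reordered; a summary data.frame is attached as
#'   attribute `"summary"`
#' @export
rank_models <- function(reports) {
  stopifnot(length(reports) >= 1L,
            all(vapply(reports, inherits, logical(1), "triage_report")))
  df <- data.frame(
    model_id = vapply(reports, `[[`, character(1), "model_id"),
    eligible = vapply(reports, `[[`, logical(1), "eligible"),
    n_saltbridges = vapply(reports, `[[`, integer(1), "n_saltbridges"),
    n_hbonds = vapply(reports, `[[`, integer(1), "n_hbonds"),
    stringsAsFactors = FALSE)
  ord <- order(-df$eligible, -df$n_saltbridges, -df$n_hbonds, df$model_id)
  out <- reports[ord]
  names(out) <- df$model_id[ord]
  summary <- df[ord, , drop = FALSE]
  summary$rank <- seq_len(nrow(summary))
  rownames(summary) <- NULL
  attr(out, "summary") <- summary
  out
}

#' Mutate residues of a complex structure
#'
#' Alanine truncation is supported for any structure: the side chain beyond
#' C-beta is removed (with its hydrogens), the residue renamed ALA and the
#' backbone left untouched.  Substitution to another residue type rebuilds
#' the side chain from the synthetic side-chain template library and is
#' available only for structures built by [build_template()] (which record
#' the local geometry needed for placement).
#'
#' @param structure a `complex_structure`
#' @param substitutions data.frame with columns `resno`, `to` (three-letter
#'   target, e.g. `"ALA"`) and optionally `chain`
#' @return the mutated `complex_structure`
#' @export
mutate_residues <- function(structure, substitutions) {
  stopifnot(inherits(structure, "complex_structure"),
            is.data.frame(substitutions),
            all(c("resno", "to") %in% names(substitutions)))
  atom <- structure$atom
  geom <- attr(structure, "template_geometry")
  for (k in seq_len(nrow(substitutions))) {
    rn <- substitutions$resno[k]
    to <- toupper(substitutions$to[k])
    rows <- which(atom$resno == rn)
    if (!is.null(substitutions$chain))
      rows <- rows[atom$chain[rows] == substitutions$chain[k]]
    if (length(rows) == 0L)
      stop("input error: residue ", rn, " not found")
    chain <- atom$chain[rows[1]]
    if (to == "ALA") {
      keep_heavy <- rows[atom$elety[rows] %in% c(.BB_NAMES, "CB") &
                           !atom$is_h[rows]]
      keep_h <- rows[atom$is_h[rows] & atom$bonded_heavy[rows] %in% keep_heavy]
      drop <- setdiff(rows, c(keep_heavy, keep_h))
      atom$resid[rows] <- "ALA"
      if (length(drop) > 0L) atom <- atom[-drop, , drop = FALSE]
    } else {
      kind <- switch(to, GLY = "GLY", ASN = "ASN", ASP = "ASP_HB",
                     LYS = "LYS",
                     stop("input error: unsupported target residue ", to))
      if (is.null(geom))
        stop("input error: template-based substitution requires a ",
             "generator-built structure; only ALA truncation is supported here")
      x0 <- geom$slot_x[[paste0(chain, rn)]]
      if (is.null(x0) || is.na(x0))
        stop("input error: no recorded geometry for residue ", chain, rn)
      mirror <- chain == "B"
      tmpl <- .res_template(kind)
      tmpl <- tmpl[!(tmpl$name %in% .BB_NAMES), , drop = FALSE]
      bb_rows <- rows[atom$elety[rows] %in% .BB_NAMES]
      drop <- setdiff(rows, bb_rows)
      atom$resid[rows] <- .resid_of_kind(kind)
      if (length(drop) > 0L) atom <- atom[-drop, , drop = FALSE]
      if (nrow(tmpl) > 0L) {
        new <- data.frame(
          eleno = max(atom$eleno) + seq_len(nrow(tmpl)),
          elety = tmpl$name, resid = .resid_of_kind(kind), chain = chain,
          resno = rn, x = tmpl$x + x0,
          y = if (mirror) 10 - tmpl$y else tmpl$y, z = tmpl$z,
          elesy = tmpl$elesy, stringsAsFactors = FALSE)
        insert_after <- max(which(atom$resno == rn & atom$chain == chain))
        atom <- rbind(atom[seq_len(insert_after), names(new)],
                      new,
                      if (insert_after < nrow(atom))
                        atom[(insert_after + 1L):nrow(atom), names(new)])
      }
    }
    # refresh row indices for the next substitution
    atom$is_h <- NULL; atom$domain <- NULL; atom$bonded_heavy <- NULL
    atom <- complex_structure(atom)$atom
  }
  out <- complex_structure(atom[, c("eleno", "elety", "resid", "chain",
                                    "resno", "x", "y", "z", "elesy")])
  attr(out, "template_geometry") <- geom
  out
}
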