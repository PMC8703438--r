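# Per-frame geometric detection of hydrogen bonds and salt bridges across
# the TSP8-Spacer interface, and pooling over a trajectory to residue-pair
# presence series and per-frame interface H-bond counts (N_HB).
#
# Criteria: an H-bond requires donor-acceptor distance < 3.5 A (strict) and
# donor-hydrogen-acceptor angle > 150 deg (strict); a salt bridge requires a
# side-chain carboxylate O of an acidic residue within 4 A (strict) of a
# side-chain N of a basic residue.  Only cross-domain pairs are evaluated.

# Candidate (donor heavy, hydrogen, acceptor) triples across the interface.
# Donors are heavy atoms listed in the chemistry table; each must carry at
# least one linked hydrogen, otherwise detection is impossible and we raise.
.hbond_candidates <- function(structure, chem) {
  .require_domains(structure)
  atom <- structure$atom
  don <- which(.chem_match(atom, chem$donor_atoms))
  acc <- which(.chem_match(atom, chem$acceptor_atoms))
  if (length(don) == 0L || length(acc) == 0L)
    return(data.frame(d = integer(), h = integer(), a = integer()))
  h_of <- split(which(atom$is_h), atom$bonded_heavy[atom$is_h])
  no_h <- don[!(as.character(don) %in% names(h_of))]
  if (length(no_h) > 0L) {
    i <- no_h[1]
    stop(sprintf(
      "chemistry error: donor atom %s of %s %s%d (serial %d) has no linked hydrogen",
      atom$elety[i], atom$resid[i], atom$chain[i], atom$resno[i], atom$eleno[i]))
  }
  dh <- do.call(rbind, lapply(don, function(d)
    cbind(d = d, h = h_of[[as.character(d)]])))
  # cross all donor-H pairs with all acceptors, keep cross-domain, drop
  # donor == acceptor atoms (possible for hydroxyls, same atom both roles)
  g <- expand.grid(i = seq_len(nrow(dh)), a = acc, KEEP.OUT.ATTRS = FALSE)
  d <- dh[g$i, "d"]; h <- dh[g$i, "h"]; a <- g$a
  keep <- atom$domain[d] != atom$domain[a]
  data.frame(d = d[keep], h = h[keep], a = a[keep])
}

.saltbridge_candidates <- function(structure, chem) {
  .require_domains(structure)
  atom <- structure$atom
  o <- which(.chem_match(atom, chem$acidic_O))
  n <- which(.chem_match(atom, chem$basic_N))
  if (length(o) == 0L || length(n) == 0L)
    return(data.frame(o = integer(), n = integer()))
  g <- expand.grid(o = o, n = n, KEEP.OUT.ATTRS = FALSE)
  keep <- atom$domain[g$o] != atom$domain[g$n]
  data.frame(o = g$o[keep], n = g$n[keep])
}

.pair_cols <- function(atom, i_tsp8_or_not, j) {
  # orient a (i, j) atom pair so the TSP8 residue comes first
  swap <- atom$domain[i_tsp8_or_not] != "TSP8"
  i2 <- ifelse(swap, j, i_tsp8_or_not)
  j2 <- ifelse(swap, i_tsp8_or_not, j)
  data.frame(
    tsp8_resno = atom$resno[i2], tsp8_resid = atom$resid[i2],
    spacer_resno = atom$resno[j2], spacer_resid = atom$resid[j2],
    stringsAsFactors = FALSE)
}

#' Detect interface hydrogen bonds in a single frame
#'
#' Emits one hit per (donor heavy atom, hydrogen, acceptor) triple with
#' donor-acceptor distance strictly below `d_cut` and donor-hydrogen-acceptor
#' angle strictly above `a_cut`.  Only cross-domain (TSP8 vs Spacer) triples
#' are evaluated; a donor heavy atom with no linked hydrogen raises a
#' chemistry error.
#'
#' @param frame n x 3 coordinate matrix (default: the structure's own
#'   coordinates)
#' @param structure a `complex_structure` with hydrogens present and linked
#' @param chem a `chemistry_table`
#' @param d_cut donor-acceptor distance cutoff in Angstrom (default 3.5)
#' @param a_cut donor-hydrogen-acceptor angle cutoff in degrees (default 150)
#' @return data.frame, one row per hit: atom serials of donor / hydrogen /
#'   acceptor, donor and acceptor residue identity, the residue pair oriented
#'   as (TSP8, Spacer), `distance` (donor-acceptor, Angstrom) and `angle`
#'   (degrees)
#' @export
detect_hbonds_frame <- function(frame = NULL, structure,
                                chem = default_chemistry(),
                                d_cut = 3.5, a_cut = 150) {
  stopifnot(inherits(structure, "complex_structure"), d_cut > 0,
            a_cut >= 0, a_cut <= 180)
  cand <- .hbond_candidates(structure, chem)
  if (is.null(frame)) frame <- coords(structure)
  frame <- as.matrix(frame)
  .eval_hbond_candidates(frame, structure, cand, d_cut, a_cut)
}

.eval_hbond_candidates <- function(frame, structure, cand, d_cut, a_cut) {
  atom <- structure$atom
  empty <- data.frame(
    donor_atom = integer(), hydrogen_atom = integer(), acceptor_atom = integer(),
    donor_resno = integer(), donor_resid = character(),
    acceptor_resno = integer(), acceptor_resid = character(),
    tsp8_resno = integer(), tsp8_resid = character(),
    spacer_resno = integer(), spacer_resid = character(),
    distance = numeric(), angle = numeric(), stringsAsFactors = FALSE)
  if (nrow(cand) == 0L) return(empty)
  dv <- frame[cand$d, , drop = FALSE] - frame[cand$a, , drop = FALSE]
  dist <- sqrt(rowSums(dv^2))
  sel <- dist < d_cut
  if (!any(sel)) return(empty)
  cand <- cand[sel, , drop = FALSE]; dist <- dist[sel]
  hd <- frame[cand$d, , drop = FALSE] - frame[cand$h, , drop = FALSE]
  ha <- frame[cand$a, , drop = FALSE] - frame[cand$h, , drop = FALSE]
  cosang <- rowSums(hd * ha) / (sqrt(rowSums(hd^2)) * sqrt(rowSums(ha^2)))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  sel <- ang > a_cut
  if (!any(sel)) return(empty)
  cand <- cand[sel, , drop = FALSE]; dist <- dist[sel]; ang <- ang[sel]
  out <- data.frame(
    donor_atom = atom$eleno[cand$d], hydrogen_atom = atom$eleno[cand$h],
    acceptor_atom = atom$eleno[cand$a],
    donor_resno = atom$resno[cand$d], donor_resid = atom$resid[cand$d],
    acceptor_resno = atom$resno[cand$a], acceptor_resid = atom$resid[cand$a],
    stringsAsFactors = FALSE)
  cbind(out, .pair_cols(atom, cand$d, cand$a),
        data.frame(distance = dist, angle = ang))
}

#' Detect interface salt bridges in a single frame
#'
#' One hit per cross-domain (side-chain carboxylate O, side-chain basic N)
#' atom pair with distance strictly below `d_cut`.  Backbone O and N are
#' never considered.
#'
#' @inheritParams detect_hbonds_frame
#' @param d_cut O-N distance cutoff in Angstrom (default 4.0)
#' @return data.frame, one row per hit: atom serials, residue identities,
#'   the (TSP8, Spacer) oriented pair and `distance`
#' @export
detect_saltbridges_frame <- function(frame = NULL, structure,
                                     chem = default_chemistry(), d_cut = 4.0) {
  stopifnot(inherits(structure, "complex_structure"), d_cut > 0)
  cand <- .saltbridge_candidates(structure, chem)
  if (is.null(frame)) frame <- coords(structure)
  frame <- as.matrix(frame)
  .eval_saltbridge_candidates(frame, structure, cand, d_cut)
}

.eval_saltbridge_candidates <- function(frame, structure, cand, d_cut) {
  atom <- structure$atom
  empty <- data.frame(
    acidic_atom = integer(), basic_atom = integer(),
    acidic_resno = integer(), acidic_resid = character(),
    basic_resno = integer(), basic_resid = character(),
    tsp8_resno = integer(), tsp8_resid = character(),
    spacer_resno = integer(), spacer_resid = character(),
    distance = numeric(), stringsAsFactors = FALSE)
  if (nrow(cand) == 0L) return(empty)
  dv <- frame[cand$o, , drop = FALSE] - frame[cand$n, , drop = FALSE]
  dist <- sqrt(rowSums(dv^2))
  sel <- dist < d_cut
  if (!any(sel)) return(empty)
  cand <- cand[sel, , drop = FALSE]; dist <- dist[sel]
  out <- data.frame(
    acidic_atom = atom$eleno[cand$o], basic_atom = atom$eleno[cand$n],
    acidic_resno = atom$resno[cand$o], acidic_resid = atom$resid[cand$o],
    basic_resno = atom$resno[cand$n], basic_resid = atom$resid[cand$n],
    stringsAsFactors = FALSE)
  cbind(out, .pair_cols(atom, cand$o, cand$n),
        data.frame(distance = dist))
}

#' Scan a trajectory for interface contacts
#'
#' Runs the per-frame H-bond and salt-bridge detectors over every frame
#' (optionally strided), pools atom-level hits to residue pairs (a pair is
#' present in a frame iff at least one atom-level hit links its two residues
#' that frame), and counts the interface N_HB per frame.
#'
#' @param traj an `md_trajectory`
#' @param chem a `chemistry_table`
#' @param d_cut,a_cut H-bond criteria (Angstrom, degrees)
#' @param sb_cut salt-bridge O-N cutoff (Angstrom)
#' @param stride analyse every `stride`-th frame (default 1: every frame)
#' @param nhb_level `"pair"` (default) counts distinct residue pairs with at
#'   least one H-bond hit per frame; `"atom"` counts distinct
#'   donor/hydrogen/acceptor triples
#' @return object of class `contact_scan`: list with `hbonds` and
#'   `saltbridges` (each a list of `contact_series`), `nhb` (integer vector,
#'   one entry per analysed frame), `n_frames`, `frames` (indices analysed)
#' @export
scan_trajectory <- function(traj, chem = default_chemistry(),
                            d_cut = 3.5, a_cut = 150, sb_cut = 4.0,
                            stride = 1L, nhb_level = c("pair", "atom")) {
  stopifnot(inherits(traj, "md_trajectory"), stride >= 1L)
  nhb_level <- match.arg(nhb_level)
  if (traj$n_frames < 1L) stop("input error: empty trajectory")
  structure <- traj$structure
  hb_cand <- .hbond_candidates(structure, chem)
  sb_cand <- .saltbridge_candidates(structure, chem)
  frames <- seq(1L, traj$n_frames, by = stride)
  n <- length(frames)
  hb_keys <- vector("list", n)
  sb_keys <- vector("list", n)
  nhb <- integer(n)
  for (k in seq_len(n)) {
    fr <- frame_coords(traj, frames[k])
    hb <- .eval_hbond_candidates(fr, structure, hb_cand, d_cut, a_cut)
    sb <- .eval_saltbridge_candidates(fr, structure, sb_cand, sb_cut)
    hb_keys[[k]] <- unique(paste(hb$tsp8_resno, hb$tsp8_resid,
                                 hb$spacer_resno, hb$spacer_resid, sep = "|"))
    sb_keys[[k]] <- unique(paste(sb$tsp8_resno, sb$tsp8_resid,
                                 sb$spacer_resno, sb$spacer_resid, sep = "|"))
    nhb[k] <- if (nhb_level == "pair") length(hb_keys[[k]]) else nrow(hb)
  }
  structure(list(
    hbonds = .pool_series(hb_keys, "hbond", n),
    saltbridges = .pool_series(sb_keys, "saltbridge", n),
    nhb = nhb, n_frames = n, frames = frames), class = "contact_scan")
}

.pool_series <- function(keys_per_frame, bond_type, n_frames) {
  all_keys <- sort(unique(unlist(keys_per_frame)))
  lapply(all_keys, function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    presence <- vapply(keys_per_frame, function(k) key %in% k, logical(1))
    contact_series(
      tsp8_resno = as.integer(parts[1]), tsp8_resid = parts[2],
      spacer_resno = as.integer(parts[3]), spacer_resid = parts[4],
      bond_type = bond_type, presence = presence)
  })
}

#' Per-frame presence record of one residue pair
#'
#' @param tsp8_resno,tsp8_resid,spacer_resno,spacer_resid the residue pair
#' @param bond_type `"hbond"` or `"saltbridge"`
#' @param presence logical vector, one entry per analysed frame
#' @return object of class `contact_series`
#' @export
contact_series <- function(tsp8_resno, tsp8_resid, spacer_resno, spacer_resid,
                           bond_type = c("hbond", "saltbridge"), presence) {
  bond_type <- match.arg(bond_type)
  presence <- as.logical(presence)
  if (length(presence) < 1L || anyNA(presence))
    stop("input error: presence vector must be non-empty logical")
  structure(list(
    tsp8_resno = as.integer(tsp8_resno), tsp8_resid = as.character(tsp8_resid),
    spacer_resno = as.integer(spacer_resno),
    spacer_resid = as.character(spacer_resid),
    bond_type = bond_type, presence = presence,
    n_frames = length(presence)), class = "contact_series")
}

#' @export
print.contact_series <- function(x, ...) {
  cat(sprintf("%s %s%d - %s%d: present %d/%d frames (%.3f)\n",
              x$bond_type, x$tsp8_resid, x$tsp8_resno,
              x$spacer_resid, x$spacer_resno,
              sum(x$presence), x$n_frames, mean(x$presence)))
  invisible(x)
}

#' @export
print.contact_scan <- function(x, ...) {
  cat("contact_scan:", length(x$hbonds), "H-bond pairs,",
      length(x$saltbridges), "salt-bridge pairs over", x$n_frames, "frames;",
      sprintf("mean N_HB %.2f\n", mean(x$nhb)))
  invisible(x)
}

#' Presence matrix of a contact scan
#'
#' @param scan a `contact_scan`
#' @param type `"hbond"` or `"saltbridge"`
#' @return logical matrix, one row per analysed frame, one column per
#'   residue pair (named `RES<i>-RES<j>`)
#' @export
presence_matrix <- function(scan, type = c("hbond", "saltbridge")) {
  type <- match.arg(type)
  series <- if (type == "hbond") scan$hbonds else scan$saltbridges
  if (length(series) == 0L)
    return(matrix(logical(), nrow = scan$n_frames, ncol = 0L))
  m <- vapply(series, function(s) s$presence, logical(scan$n_frames))
  m <- matrix(m, nrow = scan$n_frames)
  colnames(m) <- vapply(series, function(s)
    sprintf("%s%d-%s%d", s$tsp8_resid, s$tsp8_resno,
            s$spacer_resid, s$spacer_resno), character(1))
  m
}

#' Write per-frame contact hits of a trajectory to CSV
#'
#' One row per atom-level hit: frame, type, donor/acidic residue, acceptor/
#' basic residue, distance and (for H-bonds) angle.
#'
#' @inheritParams scan_trajectory
#' @param path output CSV file
#' @return `path`, invisibly
#' @export
write_hits_csv <- function(traj, path, chem = default_chemistry(),
                           d_cut = 3.5, a_cut = 150, sb_cut = 4.0) {
  stopifnot(inherits(traj, "md_trajectory"))
  structure <- traj$structure
  hb_cand <- .hbond_candidates(structure, chem)
  sb_cand <- .saltbridge_candidates(structure, chem)
  rows <- vector("list", traj$n_frames)
  for (i in seq_len(traj$n_frames)) {
    fr <- frame_coords(traj, i)
    hb <- .eval_hbond_candidates(fr, structure, hb_cand, d_cut, a_cut)
    sb <- .eval_saltbridge_candidates(fr, structure, sb_cand, sb_cut)
    parts <- list()
    if (nrow(hb) > 0L)
      parts$hb <- data.frame(
        frame = i, type = "hbond",
        tsp8 = paste0(hb$tsp8_resid, hb$tsp8_resno),
        spacer = paste0(hb$spacer_resid, hb$spacer_resno),
        distance = hb$distance, angle = hb$angle, stringsAsFactors = FALSE)
    if (nrow(sb) > 0L)
      parts$sb <- data.frame(
        frame = i, type = "saltbridge",
        tsp8 = paste0(sb$tsp8_resid, sb$tsp8_resno),
        spacer = paste0(sb$spacer_resid, sb$spacer_resno),
        distance = sb$distance, angle = NA_real_, stringsAsFactors = FALSE)
    rows[[i]] <- do.call(rbind, parts)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(frame = integer(), type = character(),
                      tsp8 = character(), spacer = character(),
                      distance = numeric(), angle = numeric())
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
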