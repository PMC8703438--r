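# Independent oracles and fixture builders used across the suite.

# Brute-force H-bond evaluator: walks every donor hydrogen and applies the
# geometric definition directly from the chemistry table, with no candidate
# caching or pre-filtering.  Returns a sorted character key per hit.
oracle_hbond_keys <- function(frame, structure, chem = default_chemistry(),
                              d_cut = 3.5, a_cut = 150) {
  atom <- structure$atom
  is_donor <- function(i) {
    atom$elety[i] %in% chem$donor_atoms[[".backbone"]] ||
      (!is.null(chem$donor_atoms[[atom$resid[i]]]) &&
         atom$elety[i] %in% chem$donor_atoms[[atom$resid[i]]])
  }
  is_acceptor <- function(i) {
    atom$elety[i] %in% chem$acceptor_atoms[[".backbone"]] ||
      (!is.null(chem$acceptor_atoms[[atom$resid[i]]]) &&
         atom$elety[i] %in% chem$acceptor_atoms[[atom$resid[i]]])
  }
  keys <- character()
  for (h in which(atom$is_h)) {
    d <- atom$bonded_heavy[h]
    if (is.na(d) || !is_donor(d)) next
    for (a in seq_len(nrow(atom))) {
      if (atom$is_h[a] || !is_acceptor(a)) next
      if (is.na(atom$domain[d]) || is.na(atom$domain[a])) next
      if (atom$domain[d] == atom$domain[a]) next
      dist <- sqrt(sum((frame[d, ] - frame[a, ])^2))
      if (dist >= d_cut) next
      v1 <- frame[d, ] - frame[h, ]; v2 <- frame[a, ] - frame[h, ]
      ang <- acos(min(1, max(-1, sum(v1 * v2) /
                               sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang > a_cut)
        keys <- c(keys, paste(atom$eleno[d], atom$eleno[h], atom$eleno[a]))
    }
  }
  sort(keys)
}

oracle_saltbridge_keys <- function(frame, structure,
                                   chem = default_chemistry(), d_cut = 4.0) {
  atom <- structure$atom
  in_map <- function(i, map) {
    !is.null(map[[atom$resid[i]]]) && atom$elety[i] %in% map[[atom$resid[i]]]
  }
  keys <- character()
  for (o in seq_len(nrow(atom))) {
    if (atom$is_h[o] || !in_map(o, chem$acidic_O)) next
    for (n in seq_len(nrow(atom))) {
      if (atom$is_h[n] || !in_map(n, chem$basic_N)) next
      if (is.na(atom$domain[o]) || is.na(atom$domain[n])) next
      if (atom$domain[o] == atom$domain[n]) next
      if (sqrt(sum((frame[o, ] - frame[n, ])^2)) < d_cut)
        keys <- c(keys, paste(atom$eleno[o], atom$eleno[n]))
    }
  }
  sort(keys)
}

# hit keys from the package detectors, matching the oracle key format
detector_hbond_keys <- function(frame, structure, ...) {
  h <- detect_hbonds_frame(frame, structure, ...)
  sort(paste(h$donor_atom, h$hydrogen_atom, h$acceptor_atom))
}

detector_saltbridge_keys <- function(frame, structure, ...) {
  s <- detect_saltbridges_frame(frame, structure, ...)
  sort(paste(s$acidic_atom, s$basic_atom))
}

# Quaternion-method (Horn) superposition RMSD: an independent route to the
# optimal-rigid-fit RMSD computed by superpose()'s SVD Kabsch solution.
quaternion_rmsd <- function(ref, mobile) {
  X <- sweep(mobile, 2, colMeans(mobile))
  Y <- sweep(ref, 2, colMeans(ref))
  S <- crossprod(X, Y)
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[3, 1] + S[1, 3]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (sum(X^2) + sum(Y^2) - 2 * lam) / nrow(X)))
}

# standard mixed fixture: one template with H-bond and salt-bridge pairs
make_mixed_template <- function(n_hb = 3L, n_sb = 2L, n_res = 30L,
                                p_occ = 0.5, n_frames = 50L, seed = 1L,
                                jitter_sd = 0.05) {
  n_pairs <- n_hb + n_sb
  stopifnot(n_pairs <= n_res)
  pairs <- data.frame(
    tsp8_resno = 1072L + seq_len(n_pairs) - 1L,
    spacer_resno = 556L + seq_len(n_pairs) - 1L,
    type = c(rep("hbond", n_hb), rep("saltbridge", n_sb)))
  schedule <- occupancy_schedule(pairs, p_occ)
  spec <- generator_spec(n_residues_per_domain = n_res, n_frames = n_frames,
                         seed = seed, jitter_sd = jitter_sd)
  list(template = build_template(spec, schedule), schedule = schedule,
       spec = spec, pairs = pairs)
}

# random conformations that straddle the detection thresholds: uniform
# displacement of every atom up to `amp` Angstrom
randomize_frame <- function(template, amp = 0.9) {
  x <- coords(template)
  x + matrix(runif(length(x), -amp, amp), nrow(x), 3)
}

# survival records in the shape select_key_residues() expects, built from a
# reference table's printed replicate columns
records_from_reference <- function(tab, bond_type) {
  agg <- lapply(seq_len(nrow(tab)), function(i)
    aggregate_replicates(c(tab$rep1[i], tab$rep2[i], tab$rep3[i])))
  data.frame(
    tsp8_resno = tab$tsp8_resno, tsp8_resid = tab$tsp8_resid,
    spacer_resno = tab$spacer_resno, spacer_resid = tab$spacer_resid,
    bond_type = bond_type,
    rep1 = tab$rep1, rep2 = tab$rep2, rep3 = tab$rep3,
    mean = vapply(agg, `[[`, numeric(1), "mean"),
    sem = vapply(agg, `[[`, numeric(1), "sem"),
    stringsAsFactors = FALSE)
}

# minimal hand-written PDB text helper
toy_pdb_lines <- function() {
  c(paste0("ATOM      1  N   GLY A1072       0.000   0.000   0.000",
           "  1.00  0.00           N"),
    paste0("ATOM      2  H   GLY A1072       1.000   0.000   0.000",
           "  1.00  0.00           H"),
    paste0("ATOM      3  O   GLY A1072       3.000   0.000   0.000",
           "  1.00  0.00           O"),
    "END")
}
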