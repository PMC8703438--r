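# Trajectory-level structural stability metrics: least-squares (Kabsch)
# superposition and RMSD series, Shrake-Rupley solvent accessible surface
# area and interface burial, and a simplified cross-domain nonbonded
# interaction energy (Lennard-Jones + Coulomb) with a CHARMM-style switching
# function between 10 and 12 Angstrom.

#' Default van der Waals radii by element
#'
#' Bondi-type radii (Angstrom) for the elements of standard protein atoms.
#' @return named numeric vector
#' @export
default_vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD of
#' `mobile` onto `ref` over the selected atoms (singular value
#' decomposition of the covariance matrix, with the determinant correction
#' that excludes reflections).
#'
#' @param ref,mobile n x 3 coordinate matrices with matching rows
#' @param selection optional integer indices of the atoms used for the fit
#'   and the deviation (default: all); at least 3 non-collinear atoms
#' @return list with `rotation` (3 x 3, to be applied as `x %*% rotation`),
#'   `translation` (length 3), `rmsd` (Angstrom, over the selection after
#'   the fit) and `aligned` (all mobile atoms transformed)
#' @export
superpose <- function(ref, mobile, selection = NULL) {
  ref <- as.matrix(ref); mobile <- as.matrix(mobile)
  stopifnot(ncol(ref) == 3L, ncol(mobile) == 3L, nrow(ref) == nrow(mobile))
  if (is.null(selection)) selection <- seq_len(nrow(ref))
  if (length(selection) < 3L)
    stop("geometry error: need at least 3 atoms to superpose")
  X <- mobile[selection, , drop = FALSE]
  Y <- ref[selection, , drop = FALSE]
  cm <- colMeans(X); cr <- colMeans(Y)
  Xc <- sweep(X, 2L, cm); Yc <- sweep(Y, 2L, cr)
  sv_x <- svd(Xc)$d
  if (sv_x[2] < 1e-8 * max(sv_x[1], 1e-12))
    stop("geometry error: selection is collinear")
  H <- crossprod(Xc, Yc)
  s <- svd(H)
  d <- sign(det(s$u) * det(s$v))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  aligned_sel <- Xc %*% R
  rmsd <- sqrt(mean(rowSums((aligned_sel - Yc)^2)))
  aligned <- sweep(sweep(mobile, 2L, cm) %*% R, 2L, cr, "+")
  list(rotation = R, translation = as.numeric(cr - cm %*% R), rmsd = rmsd,
       aligned = aligned)
}

.resolve_selection <- function(structure, selection) {
  if (is.numeric(selection)) return(as.integer(selection))
  sel <- match.arg(selection, c("calpha", "heavy", "all"))
  idx <- switch(sel,
    calpha = which(structure$atom$elety == "CA"),
    heavy = which(!structure$atom$is_h),
    all = seq_len(nrow(structure$atom)))
  if (length(idx) == 0L)
    stop("selection '", sel, "' matches no atoms")
  idx
}

#' Per-frame RMSD of a trajectory against a reference frame
#'
#' Each frame is superposed on the reference over the selection and the RMSD
#' is computed over the same selection.
#'
#' @param traj an `md_trajectory`
#' @param selection `"calpha"`, `"heavy"`, `"all"`, or integer atom indices
#' @param reference reference frame index (default 1, the initial state)
#' @return numeric vector of length `n_frames` (Angstrom)
#' @export
rmsd_series <- function(traj, selection = "calpha", reference = 1L) {
  stopifnot(inherits(traj, "md_trajectory"))
  idx <- .resolve_selection(traj$structure, selection)
  ref <- frame_coords(traj, reference)
  vapply(seq_len(traj$n_frames), function(i) {
    superpose(ref, frame_coords(traj, i), selection = idx)$rmsd
  }, numeric(1))
}

# deterministic golden-section spiral on the unit sphere
.sphere_points <- function(n) {
  i <- seq_len(n)
  z <- (2 * i - 1) / n - 1
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

# core Shrake-Rupley on raw coordinates; returns per-atom areas
.shrake_rupley <- function(xyz, radii, probe, n_points) {
  n <- nrow(xyz)
  pts <- .sphere_points(n_points)
  R <- radii + probe
  d2 <- .cross_dist2(xyz, xyz)
  area <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (R[i] + R)^2)
    nb <- nb[nb != i]
    sp <- sweep(pts * R[i], 2L, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
        (sp[, 3] - xyz[j, 3])^2
      exposed <- exposed & dj2 >= R[j]^2
      if (!any(exposed)) break
    }
    area[i] <- mean(exposed) * 4 * pi * R[i]^2
  }
  area
}

#' Solvent accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over every atom using a deterministic golden-section
#' spiral point set: the per-atom area is the exposed fraction of test
#' points times `4 * pi * (r + probe)^2`.  Hydrogens are excluded by default
#' (the convention of most SASA tools); include them via
#' `include_hydrogens = TRUE`.
#'
#' @param frame n x 3 coordinate matrix (default: the structure's own
#'   coordinates)
#' @param structure a `complex_structure`
#' @param radii named per-element radii (Angstrom), see
#'   [default_vdw_radii()]
#' @param probe probe radius in Angstrom (default 1.4, a water molecule)
#' @param n_points sphere test points per atom (default 960)
#' @param include_hydrogens logical (default FALSE)
#' @return object of class `sasa_result`: list with `atom_area` (0 for
#'   excluded atoms), `residue_area` (data.frame chain/resno/resid/area),
#'   `total`, `probe`, `n_points`
#' @export
sasa <- function(frame = NULL, structure, radii = default_vdw_radii(),
                 probe = 1.4, n_points = 960L, include_hydrogens = FALSE) {
  stopifnot(inherits(structure, "complex_structure"), probe >= 0,
            n_points >= 12L)
  if (is.null(frame)) frame <- coords(structure)
  frame <- as.matrix(frame)
  stopifnot(nrow(frame) == nrow(structure$atom))
  keep <- if (include_hydrogens) seq_len(nrow(frame)) else
    which(!structure$atom$is_h)
  elem <- structure$atom$elesy[keep]
  unknown <- setdiff(unique(elem), names(radii))
  if (length(unknown) > 0L)
    stop("radii error: no radius for element(s) ",
         paste(unknown, collapse = ", "))
  area_keep <- .shrake_rupley(frame[keep, , drop = FALSE],
                              radii[elem], probe, n_points)
  atom_area <- numeric(nrow(frame))
  atom_area[keep] <- area_keep
  res <- structure$residues
  res_area <- vapply(seq_len(nrow(res)), function(k)
    sum(atom_area[res$first[k]:res$last[k]]), numeric(1))
  structure(list(
    atom_area = atom_area,
    residue_area = data.frame(chain = res$chain, resno = res$resno,
                              resid = res$resid, area = res_area,
                              stringsAsFactors = FALSE),
    total = sum(atom_area), probe = probe, n_points = as.integer(n_points)),
    class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("sasa_result: total %.1f A^2 (probe %.1f A, %d points/atom)\n",
              x$total, x$probe, x$n_points))
  invisible(x)
}

#' Interface SASA of a two-domain complex
#'
#' Computes both quantities commonly called "interface SASA": the buried
#' area, `(SASA(TSP8 alone) + SASA(Spacer alone) - SASA(complex)) / 2`, and
#' the summed complex-state SASA of the interface residues (heavy-atom
#' contact definition, see [interface_residues()]).
#'
#' @inheritParams sasa
#' @param cutoff interface residue contact cutoff in Angstrom (default 5)
#' @return list with `buried_area`, `interface_residue_sasa`,
#'   `total_complex` (all Angstrom^2)
#' @export
interface_sasa <- function(frame = NULL, structure,
                           radii = default_vdw_radii(), probe = 1.4,
                           n_points = 960L, cutoff = 5.0) {
  stopifnot(inherits(structure, "complex_structure"))
  .require_domains(structure)
  if (is.null(frame)) frame <- coords(structure)
  frame <- as.matrix(frame)
  heavy <- !structure$atom$is_h
  elem <- structure$atom$elesy
  unknown <- setdiff(unique(elem[heavy]), names(radii))
  if (length(unknown) > 0L)
    stop("radii error: no radius for element(s) ",
         paste(unknown, collapse = ", "))
  part <- function(idx) {
    sum(.shrake_rupley(frame[idx, , drop = FALSE], radii[elem[idx]],
                       probe, n_points))
  }
  idx_a <- which(structure$atom$domain == "TSP8" & heavy)
  idx_b <- which(structure$atom$domain == "Spacer" & heavy)
  idx_ab <- which(heavy)
  total_complex <- part(idx_ab)
  buried <- (part(idx_a) + part(idx_b) - total_complex) / 2
  iface <- interface_residues(frame, structure, cutoff = cutoff)
  iface_res <- unique(c(paste("A", iface$tsp8_resno),
                        paste("B", iface$spacer_resno)))
  # residue-level SASA in the complex state
  sr <- sasa(frame, structure, radii = radii, probe = probe,
             n_points = n_points)
  ra <- sr$residue_area
  dom_chain <- ifelse(structure$residues$domain == "TSP8", "A", "B")
  in_iface <- paste(dom_chain, ra$resno) %in% iface_res
  list(buried_area = buried,
       interface_residue_sasa = sum(ra$area[in_iface]),
       total_complex = total_complex)
}

#' Nonbonded parameter set
#'
#' @param table data.frame with columns `resid` (residue name, `"*"` as a
#'   wildcard), `elety` (atom name), `charge` (e), `epsilon` (kcal/mol,
#'   Lennard-Jones well depth) and `rmin2` (Angstrom, half the Lennard-Jones
#'   minimum distance)
#' @param cutoff,switch_on nonbonded cutoff and switch-on distance in
#'   Angstrom (defaults 12 and 10)
#' @param dielectric relative dielectric constant (default 1)
#' @return object of class `nonbonded_params`
#' @export
nonbonded_params <- function(table, cutoff = 12, switch_on = 10,
                             dielectric = 1) {
  stopifnot(is.data.frame(table),
            all(c("resid", "elety", "charge", "epsilon", "rmin2") %in%
                  names(table)),
            cutoff > switch_on, switch_on > 0, dielectric > 0,
            all(table$epsilon >= 0))
  structure(list(table = table, cutoff = cutoff, switch_on = switch_on,
                 dielectric = dielectric), class = "nonbonded_params")
}

#' Read nonbonded parameters from a CSV or JSON file
#'
#' @param path file with columns/keys resid, elety, charge, epsilon, rmin2
#' @param ... passed to [nonbonded_params()]
#' @return a `nonbonded_params`
#' @export
read_nonbonded_params <- function(path, ...) {
  tab <- if (grepl("\\.json$", path, ignore.case = TRUE))
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  else read.csv(path, stringsAsFactors = FALSE)
  nonbonded_params(tab, ...)
}

#' Toy nonbonded parameters covering a structure
#'
#' Element-based Lennard-Jones parameters and simple formal charges
#' (carboxylate O of Asp/Glu -0.5 e each, Lys NZ +1 e, Arg NH1/NH2 +0.5 e)
#' for synthetic-structure tests and pipeline runs; not a forcefield.
#'
#' @param structure a `complex_structure`
#' @param ... passed to [nonbonded_params()]
#' @return a `nonbonded_params` covering every atom of `structure`
#' @export
toy_nonbonded_params <- function(structure, ...) {
  atom <- structure$atom
  key <- unique(paste(atom$resid, atom$elety, sep = "|"))
  parts <- do.call(rbind, strsplit(key, "|", fixed = TRUE))
  elem <- .element_from_name(parts[, 2])
  lj_eps <- c(C = 0.07, N = 0.20, O = 0.12, S = 0.45, H = 0.03)
  lj_rmin2 <- c(C = 2.00, N = 1.85, O = 1.70, S = 2.00, H = 0.60)
  charge <- numeric(length(key))
  charge[parts[, 1] %in% c("ASP", "GLU") &
           parts[, 2] %in% c("OD1", "OD2", "OE1", "OE2")] <- -0.5
  charge[parts[, 1] == "LYS" & parts[, 2] == "NZ"] <- 1.0
  charge[parts[, 1] == "ARG" & parts[, 2] %in% c("NH1", "NH2")] <- 0.5
  nonbonded_params(data.frame(
    resid = parts[, 1], elety = parts[, 2], charge = charge,
    epsilon = unname(lj_eps[elem]), rmin2 = unname(lj_rmin2[elem]),
    stringsAsFactors = FALSE), ...)
}

# CHARMM-style quadratic-cubic switching function, 1 below ron, 0 above roff
.switch_fn <- function(r, ron, roff) {
  s <- numeric(length(r))
  s[r <= ron] <- 1
  mid <- r > ron & r < roff
  if (any(mid)) {
    r2 <- r[mid]^2; ron2 <- ron^2; roff2 <- roff^2
    s[mid] <- (roff2 - r2)^2 * (roff2 + 2 * r2 - 3 * ron2) / (roff2 - ron2)^3
  }
  s
}

.COULOMB_K <- 332.0636  # kcal * Angstrom / (mol * e^2)

#' Cross-domain nonbonded interaction energy of a frame
#'
#' Sums switched Lennard-Jones and Coulomb terms over all TSP8 x Spacer atom
#' pairs: `vdw = eps_ij * ((rmin_ij/r)^12 - 2 (rmin_ij/r)^6)` with
#' `eps_ij = sqrt(eps_i eps_j)`, `rmin_ij = rmin2_i + rmin2_j` (CHARMM
#' combination rules), and `elec = 332.0636 q_i q_j / (dielectric * r)`.
#' Both terms are multiplied by a smooth switching function equal to 1 below
#' `switch_on`, 0 beyond `cutoff`.
#'
#' @param frame n x 3 coordinate matrix (default: the structure's own
#'   coordinates)
#' @param structure a `complex_structure` with both domains
#' @param params a `nonbonded_params` covering every atom
#' @return object of class `energy_breakdown`: list with `vdw`,
#'   `electrostatic`, `total` (kcal/mol)
#' @export
interaction_energy <- function(frame = NULL, structure, params) {
  stopifnot(inherits(structure, "complex_structure"),
            inherits(params, "nonbonded_params"))
  .require_domains(structure)
  if (is.null(frame)) frame <- coords(structure)
  frame <- as.matrix(frame)
  atom <- structure$atom
  tab <- params$table
  tab_key <- paste(tab$resid, tab$elety, sep = "|")
  atom_key <- paste(atom$resid, atom$elety, sep = "|")
  row <- match(atom_key, tab_key)
  wild <- is.na(row)
  if (any(wild)) {
    wrow <- match(paste("*", atom$elety[wild], sep = "|"), tab_key)
    row[wild] <- wrow
  }
  if (anyNA(row)) {
    miss <- unique(atom_key[is.na(row)])
    stop("parameter error: no nonbonded parameters for atom(s) ",
         paste(head(miss, 10L), collapse = ", "))
  }
  q <- tab$charge[row]; eps <- tab$epsilon[row]; rmin2 <- tab$rmin2[row]
  ia <- which(atom$domain == "TSP8"); ib <- which(atom$domain == "Spacer")
  d2 <- .cross_dist2(frame[ia, , drop = FALSE], frame[ib, , drop = FALSE])
  r <- sqrt(pmax(d2, 1e-12))
  within <- r < params$cutoff
  if (!any(within)) {
    out <- list(vdw = 0, electrostatic = 0, total = 0)
    class(out) <- "energy_breakdown"
    return(out)
  }
  idx <- which(within, arr.ind = TRUE)
  i <- ia[idx[, 1]]; j <- ib[idx[, 2]]; rij <- r[within]
  sw <- .switch_fn(rij, params$switch_on, params$cutoff)
  eps_ij <- sqrt(eps[i] * eps[j])
  rmin_ij <- rmin2[i] + rmin2[j]
  ratio6 <- (rmin_ij / rij)^6
  vdw <- sum(sw * eps_ij * (ratio6^2 - 2 * ratio6))
  elec <- sum(sw * .COULOMB_K * q[i] * q[j] / (params$dielectric * rij))
  out <- list(vdw = vdw, electrostatic = elec, total = vdw + elec)
  class(out) <- "energy_breakdown"
  out
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("interaction energy: vdW %.2f + elec %.2f = %.2f kcal/mol\n",
              x$vdw, x$electrostatic, x$total))
  invisible(x)
}

#' Per-condition summary of trajectory metrics
#'
#' For each condition, computes the time average of each requested metric per
#' replicate trajectory, then aggregates across replicates with
#' [aggregate_replicates()] (mean +/- SEM).
#'
#' @param trajs_by_condition named list: condition -> list of
#'   `md_trajectory` replicates
#' @param metrics subset of `"nhb"` (mean interface H-bond count),
#'   `"energy"` (mean cross-domain interaction energy, needs `params`),
#'   `"buried"` (mean buried interface area)
#' @param params a `nonbonded_params` (required for `"energy"`)
#' @param chem chemistry table for the H-bond scan
#' @param stride frame stride for the per-frame metrics (default 1)
#' @param n_points SASA point count for `"buried"` (default 240; burial is a
#'   difference of totals and converges faster than per-atom areas)
#' @return data.frame with columns `condition`, `metric`, `mean`, `sem` and
#'   one `rep<i>` column per replicate
#' @export
metric_summary <- function(trajs_by_condition,
                           metrics = c("nhb"), params = NULL,
                           chem = default_chemistry(), stride = 1L,
                           n_points = 240L) {
  stopifnot(is.list(trajs_by_condition), length(trajs_by_condition) >= 1L)
  metrics <- match.arg(metrics, c("nhb", "energy", "buried"),
                       several.ok = TRUE)
  if ("energy" %in% metrics && is.null(params))
    stop("metric 'energy' requires nonbonded params")
  rows <- list()
  for (cond in names(trajs_by_condition)) {
    trajs <- trajs_by_condition[[cond]]
    stopifnot(all(vapply(trajs, inherits, logical(1), "md_trajectory")))
    per_rep <- lapply(trajs, function(tr) {
      frames <- seq(1L, tr$n_frames, by = stride)
      out <- c()
      if ("nhb" %in% metrics) {
        sc <- scan_trajectory(tr, chem = chem, stride = stride)
        out["nhb"] <- mean(sc$nhb)
      }
      if ("energy" %in% metrics)
        out["energy"] <- mean(vapply(frames, function(i)
          interaction_energy(frame_coords(tr, i), tr$structure,
                             params)$total, numeric(1)))
      if ("buried" %in% metrics)
        out["buried"] <- mean(vapply(frames, function(i)
          interface_sasa(frame_coords(tr, i), tr$structure,
                         n_points = n_points)$buried_area, numeric(1)))
      out
    })
    for (m in metrics) {
      vals <- vapply(per_rep, `[[`, numeric(1), m)
      agg <- if (length(vals) >= 2L) {
        s <- sqrt(sum((vals - mean(vals))^2) / length(vals))
        list(mean = mean(vals), sem = s / sqrt(length(vals)))
      } else list(mean = vals, sem = 0)
      row <- data.frame(condition = cond, metric = m, mean = agg$mean,
                        sem = agg$sem, stringsAsFactors = FALSE)
      for (r in seq_along(vals)) row[[paste0("rep", r)]] <- vals[r]
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
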