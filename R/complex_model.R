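# Structure / trajectory data model and PDB I/O.
#
# A complex_structure holds an atom table (one row per atom, bio3d-like
# columns) plus derived annotation: per-atom domain membership (TSP8/Spacer),
# hydrogen -> parent heavy atom links, and a residue index.  Coordinates of a
# single conformation live in the atom table; trajectory frames are stored
# separately as an (n_frames x 3*n_atoms) matrix in bio3d xyz convention.

# Default domain rule: author numbering of the ADAMTS13 TSP8-Spacer complex.
.TSP8_RANGE <- 1072:1131
.SPACER_RANGE <- 556:682

.EXOSITE3_DEFAULT <- c(568L, 592L, 660L, 661L, 665L)
.EXOSITE4_DEFAULT <- c(634L, 635L, 636L, 639L)
.TSP8_KEY_DEFAULT <- c(1075L, 1090L, 1095L, 1130L)
.FORBIDDEN_DEFAULT <- c(621L, 622L, 623L)

.element_from_name <- function(elety) {
  # first alphabetic character of the atom name; covers standard PDB protein
  # atoms (no two-letter protein elements other than explicit elesy)
  stripped <- sub("^[0-9']*", "", elety)
  toupper(substr(stripped, 1, 1))
}

.assign_domain <- function(resno) {
  domain <- rep(NA_character_, length(resno))
  domain[resno %in% .TSP8_RANGE] <- "TSP8"
  domain[resno %in% .SPACER_RANGE] <- "Spacer"
  domain
}

#' Build a complex structure from an atom table
#'
#' Validates the atom table, assigns TSP8/Spacer domain membership by residue
#' number (TSP8: 1072-1131, Spacer: 556-682; other residues are left
#' unassigned and only rejected by operations that need domains), links each
#' hydrogen to its nearest heavy atom within 1.2 Angstrom, and builds a
#' residue index.
#'
#' @param atom data.frame with columns `eleno`, `elety`, `resid`, `chain`,
#'   `resno`, `x`, `y`, `z` and optionally `elesy` (element symbol).
#' @param exosite3,exosite4 integer residue numbers of the two Spacer-side
#'   exosites; defaults are the canonical sets (568/592/660/661/665 and
#'   634/635/636/639) intersected with the residues present.
#' @return An object of class `complex_structure`: list with elements
#'   `atom` (augmented atom table with `elesy`, `domain`, `is_h`,
#'   `bonded_heavy` columns), `residues` (one row per residue with atom index
#'   range), `exosite3`, `exosite4`.
#' @export
complex_structure <- function(atom, exosite3 = NULL, exosite4 = NULL) {
  required <- c("eleno", "elety", "resid", "chain", "resno", "x", "y", "z")
  missing_cols <- setdiff(required, names(atom))
  if (length(missing_cols) > 0L)
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atom) == 0L)
    stop("format error: no atoms")
  xyz <- as.matrix(atom[, c("x", "y", "z")])
  if (!all(is.finite(xyz)))
    stop("non-finite coordinates in atom table")
  if (any(atom$resno <= 0L))
    stop("residue numbers must be positive")

  if (is.null(atom$elesy) || all(is.na(atom$elesy)) || all(atom$elesy == "")) {
    atom$elesy <- .element_from_name(atom$elety)
  } else {
    blank <- is.na(atom$elesy) | atom$elesy == ""
    atom$elesy[blank] <- .element_from_name(atom$elety[blank])
  }
  atom$is_h <- atom$elesy == "H"
  atom$domain <- .assign_domain(atom$resno)

  atom$bonded_heavy <- NA_integer_
  h_idx <- which(atom$is_h)
  heavy_idx <- which(!atom$is_h)
  if (length(h_idx) > 0L && length(heavy_idx) == 0L)
    stop("annotation error: structure contains only hydrogens")
  for (i in h_idx) {
    d2 <- (xyz[heavy_idx, 1] - xyz[i, 1])^2 +
      (xyz[heavy_idx, 2] - xyz[i, 2])^2 +
      (xyz[heavy_idx, 3] - xyz[i, 3])^2
    j <- which.min(d2)
    if (d2[j] >= 1.2^2)
      stop(sprintf(
        "annotation error: hydrogen %s %s%d %s (serial %d) has no heavy atom within 1.2 A",
        atom$elety[i], atom$chain[i], atom$resno[i], atom$resid[i], atom$eleno[i]))
    atom$bonded_heavy[i] <- heavy_idx[j]
  }

  res_key <- paste(atom$chain, atom$resno, atom$resid)
  first <- !duplicated(res_key)
  residues <- data.frame(
    chain = atom$chain[first], resno = atom$resno[first],
    resid = atom$resid[first], domain = atom$domain[first],
    stringsAsFactors = FALSE)
  residues$first <- match(unique(res_key), res_key)
  residues$last <- c(residues$first[-1] - 1L, nrow(atom))

  spacer_res <- residues$resno[residues$domain %in% "Spacer"]
  if (is.null(exosite3)) exosite3 <- intersect(.EXOSITE3_DEFAULT, spacer_res)
  if (is.null(exosite4)) exosite4 <- intersect(.EXOSITE4_DEFAULT, spacer_res)
  bad3 <- setdiff(exosite3, spacer_res)
  bad4 <- setdiff(exosite4, spacer_res)
  if (length(bad3) > 0L || length(bad4) > 0L)
    stop("exosite residues not found in the Spacer domain: ",
         paste(sort(c(bad3, bad4)), collapse = ", "))

  structure(
    list(atom = atom, residues = residues,
         exosite3 = as.integer(exosite3), exosite4 = as.integer(exosite4)),
    class = "complex_structure")
}

#' @export
print.complex_structure <- function(x, ...) {
  dom <- table(factor(x$residues$domain, levels = c("TSP8", "Spacer")))
  cat("complex_structure:", nrow(x$atom), "atoms,",
      nrow(x$residues), "residues",
      sprintf("(TSP8 %d, Spacer %d)\n", dom[["TSP8"]], dom[["Spacer"]]))
  invisible(x)
}

#' Coordinates of a structure as an n x 3 matrix
#' @param structure a `complex_structure`
#' @return numeric matrix with one row per atom (Angstrom)
#' @export
coords <- function(structure) {
  stopifnot(inherits(structure, "complex_structure"))
  as.matrix(structure$atom[, c("x", "y", "z")])
}

# light validation of ATOM/HETATM records so format errors carry line numbers
.validate_pdb_lines <- function(lines) {
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec))
    stop("format error: no ATOM/HETATM records")
  idx <- which(rec)
  bad_len <- idx[nchar(lines[idx]) < 54]
  if (length(bad_len) > 0L)
    stop(sprintf("format error: truncated ATOM/HETATM record at line %d", bad_len[1]))
  xyz_txt <- cbind(substr(lines[idx], 31, 38), substr(lines[idx], 39, 46),
                   substr(lines[idx], 47, 54))
  suppressWarnings(num <- matrix(as.numeric(xyz_txt), ncol = 3))
  bad <- idx[!stats::complete.cases(num)]
  if (length(bad) > 0L)
    stop(sprintf("format error: unparseable coordinates at line %d", bad[1]))
  icode <- substr(lines[idx], 27, 27)
  if (any(icode != " "))
    stop(sprintf("format error: insertion code at line %d not supported",
                 idx[which(icode != " ")[1]]))
  invisible(TRUE)
}

#' Read a protein complex from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d), keeps alternate location 'A' or
#' blank only, rejects insertion codes, and annotates the result: domain
#' membership by residue number and hydrogen-to-heavy-atom links (nearest
#' heavy atom within 1.2 Angstrom; a hydrogen with no such neighbour is an
#' error).  Hydrogens are required downstream for hydrogen-bond detection and
#' are never built by this package; structures lacking them are rejected at
#' detection time with a clear error.
#'
#' @param path PDB file path.
#' @param exosite3,exosite4 optional exosite residue numbers, see
#'   [complex_structure()].
#' @return a `complex_structure`
#' @export
read_pdb <- function(path, exosite3 = NULL, exosite4 = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  .validate_pdb_lines(readLines(path, warn = FALSE))
  pdb <- bio3d::read.pdb(path, rm.alt = TRUE, verbose = FALSE)
  atom <- pdb$atom[, c("eleno", "elety", "resid", "chain", "resno",
                       "x", "y", "z", "elesy")]
  atom$chain[is.na(atom$chain)] <- " "
  complex_structure(atom, exosite3 = exosite3, exosite4 = exosite4)
}

.pdb_format_atom <- function(atom, xyz) {
  # xyz: n x 3 matrix for this model
  name <- ifelse(nchar(atom$elety) < 4L & nchar(atom$elesy) == 1L,
                 sprintf(" %-3s", atom$elety), sprintf("%-4s", atom$elety))
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          atom$eleno %% 100000L, name, atom$resid, atom$chain, atom$resno,
          xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, atom$elesy)
}

#' Write a structure (or one conformation of it) to a PDB file
#'
#' @param structure a `complex_structure`
#' @param path output file
#' @param xyz optional n x 3 coordinate matrix overriding the structure's own
#'   coordinates
#' @return `path`, invisibly
#' @export
write_pdb <- function(structure, path, xyz = NULL) {
  stopifnot(inherits(structure, "complex_structure"))
  if (is.null(xyz)) xyz <- coords(structure)
  xyz <- as.matrix(xyz)
  stopifnot(nrow(xyz) == nrow(structure$atom), ncol(xyz) == 3L)
  writeLines(c(.pdb_format_atom(structure$atom, xyz), "END"), path)
  invisible(path)
}

#' A trajectory over a fixed atom table
#'
#' @param structure the `complex_structure` whose atoms the frames follow
#' @param xyz numeric matrix, one row per frame, 3*n_atoms columns in bio3d
#'   xyz order (x1, y1, z1, x2, ...)
#' @param frame_interval time between saved frames in ps
#' @return object of class `md_trajectory` with elements `structure`, `xyz`,
#'   `frame_interval`, `n_frames`
#' @export
trajectory <- function(structure, xyz, frame_interval = 1) {
  stopifnot(inherits(structure, "complex_structure"))
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nrow(structure$atom))
    stop("trajectory error: frames have ", ncol(xyz) / 3,
         " atoms but structure has ", nrow(structure$atom))
  if (nrow(xyz) < 1L) stop("trajectory error: no frames")
  if (!all(is.finite(xyz))) stop("trajectory error: non-finite coordinates")
  structure(list(structure = structure, xyz = xyz,
                 frame_interval = frame_interval, n_frames = nrow(xyz)),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("md_trajectory:", x$n_frames, "frames x", nrow(x$structure$atom),
      "atoms,", x$frame_interval, "ps/frame\n")
  invisible(x)
}

#' Extract one frame of a trajectory as an n x 3 matrix
#' @param traj an `md_trajectory`
#' @param i frame index (1-based)
#' @return numeric n x 3 matrix
#' @export
frame_coords <- function(traj, i) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (i < 1L || i > traj$n_frames) stop("frame index out of range: ", i)
  matrix(traj$xyz[i, ], ncol = 3L, byrow = TRUE)
}

#' Read a multi-model PDB trajectory
#'
#' Every MODEL must contain the same atoms (name + chain + residue) as
#' `structure`, in the same order; a mismatch is reported with the offending
#' model number.  Frames are ordered by MODEL number.
#'
#' @param path multi-model PDB file
#' @param structure the reference `complex_structure`
#' @param frame_interval ps per saved frame (metadata only)
#' @return an `md_trajectory`
#' @export
read_trajectory <- function(path, structure, frame_interval = 1) {
  stopifnot(inherits(structure, "complex_structure"))
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  .validate_pdb_lines(lines)
  n_expect <- nrow(structure$atom)
  model_starts <- grep("^MODEL", lines)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (length(model_starts) > 0L) {
    model_no <- as.integer(sub("^MODEL\\s+", "", lines[model_starts]))
    block <- findInterval(which(is_atom), model_starts)
    counts <- tabulate(block, nbins = length(model_starts))
    bad <- which(counts != n_expect)
    if (length(bad) > 0L)
      stop(sprintf(
        "trajectory error: model %d has %d atoms, expected %d",
        model_no[bad[1]], counts[bad[1]], n_expect))
  } else if (sum(is_atom) != n_expect) {
    stop(sprintf("trajectory error: model 1 has %d atoms, expected %d",
                 sum(is_atom), n_expect))
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = TRUE, verbose = FALSE)
  atom <- pdb$atom
  atom$chain[is.na(atom$chain)] <- " "
  same <- atom$elety == structure$atom$elety &
    atom$chain == structure$atom$chain &
    atom$resno == structure$atom$resno &
    atom$resid == structure$atom$resid
  if (!all(same))
    stop("trajectory error: atom identity mismatch at atom ",
         which(!same)[1], " (", atom$elety[which(!same)[1]], ")")
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  trajectory(structure, unclass(xyz), frame_interval = frame_interval)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj an `md_trajectory`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "md_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(traj$n_frames)) {
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(.pdb_format_atom(traj$structure$atom, frame_coords(traj, i)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

.require_domains <- function(structure) {
  if (any(is.na(structure$atom$domain)))
    stop("configuration error: residues without TSP8/Spacer domain assignment: ",
         paste(head(unique(structure$atom$resno[is.na(structure$atom$domain)])),
               collapse = ", "))
  if (!all(c("TSP8", "Spacer") %in% structure$atom$domain))
    stop("configuration error: structure must contain both TSP8 and Spacer domains")
}

#' Interface residue pairs of a two-domain complex
#'
#' A (TSP8 residue, Spacer residue) pair is on the interface if any pair of
#' heavy atoms across the two domains is closer than `cutoff`.
#'
#' @param frame n x 3 coordinate matrix (defaults to the structure's own
#'   coordinates)
#' @param structure a `complex_structure` with both domains assigned
#' @param cutoff heavy-atom minimum distance in Angstrom (default 5.0, a
#'   common contact definition)
#' @return data.frame with columns `tsp8_resno`, `tsp8_resid`,
#'   `spacer_resno`, `spacer_resid`, `min_dist`
#' @export
interface_residues <- function(frame = NULL, structure, cutoff = 5.0) {
  stopifnot(inherits(structure, "complex_structure"), cutoff > 0)
  .require_domains(structure)
  if (is.null(frame)) frame <- coords(structure)
  frame <- as.matrix(frame)
  stopifnot(nrow(frame) == nrow(structure$atom))
  a_idx <- which(structure$atom$domain == "TSP8" & !structure$atom$is_h)
  b_idx <- which(structure$atom$domain == "Spacer" & !structure$atom$is_h)
  d2 <- .cross_dist2(frame[a_idx, , drop = FALSE], frame[b_idx, , drop = FALSE])
  hit <- which(d2 < cutoff^2, arr.ind = TRUE)
  empty <- data.frame(tsp8_resno = integer(), tsp8_resid = character(),
                      spacer_resno = integer(), spacer_resid = character(),
                      min_dist = numeric(), stringsAsFactors = FALSE)
  if (nrow(hit) == 0L) return(empty)
  ai <- a_idx[hit[, 1]]; bi <- b_idx[hit[, 2]]
  key <- paste(structure$atom$resno[ai], structure$atom$resno[bi])
  dmin <- tapply(sqrt(d2[hit]), key, min)
  first <- !duplicated(key)
  out <- data.frame(
    tsp8_resno = structure$atom$resno[ai][first],
    tsp8_resid = structure$atom$resid[ai][first],
    spacer_resno = structure$atom$resno[bi][first],
    spacer_resid = structure$atom$resid[bi][first],
    stringsAsFactors = FALSE)
  out$min_dist <- as.numeric(dmin[match(key[first], names(dmin))])
  out[order(out$tsp8_resno, out$spacer_resno), , drop = FALSE]
}

# squared distances between rows of a (n x 3) and rows of b (m x 3)
.cross_dist2 <- function(a, b) {
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
}

#' Role configuration for triage and key-residue analysis
#'
#' @param exosite3_residues,exosite4_residues Spacer-side exosite residue
#'   numbers (defaults: 568/592/660/661/665 and 634/635/636/639)
#' @param tsp8_key_residues TSP8-side key residues (default
#'   1075/1090/1095/1130)
#' @param triage_forbidden_residues Spacer loop residues that must stay off
#'   the interface during docking-model triage (default 621/622/623)
#' @return object of class `role_config`
#' @export
role_config <- function(exosite3_residues = .EXOSITE3_DEFAULT,
                        exosite4_residues = .EXOSITE4_DEFAULT,
                        tsp8_key_residues = .TSP8_KEY_DEFAULT,
                        triage_forbidden_residues = .FORBIDDEN_DEFAULT) {
  ex3 <- as.integer(exosite3_residues); ex4 <- as.integer(exosite4_residues)
  if (length(intersect(ex3, ex4)) > 0L)
    stop("exosite-3 and exosite-4 sets must be disjoint")
  structure(list(exosite3_residues = ex3, exosite4_residues = ex4,
                 tsp8_key_residues = as.integer(tsp8_key_residues),
                 triage_forbidden_residues = as.integer(triage_forbidden_residues)),
            class = "role_config")
}

#' Read a role configuration from a JSON file
#'
#' Expected keys: `exosite3`, `exosite4`, `tsp8_key`, `forbidden`.
#' @param path JSON file
#' @return a `role_config`
#' @export
read_role_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  role_config(
    exosite3_residues = x$exosite3 %||% .EXOSITE3_DEFAULT,
    exosite4_residues = x$exosite4 %||% .EXOSITE4_DEFAULT,
    tsp8_key_residues = x$tsp8_key %||% .TSP8_KEY_DEFAULT,
    triage_forbidden_residues = x$forbidden %||% .FORBIDDEN_DEFAULT)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Check that every role residue resolves to exactly one residue
#'
#' @param structure a `complex_structure`
#' @param roles a `role_config`
#' @return `TRUE` invisibly; raises on any unresolved or ambiguous residue
#' @export
validate_roles <- function(structure, roles) {
  stopifnot(inherits(structure, "complex_structure"),
            inherits(roles, "role_config"))
  res <- structure$residues
  check <- function(resnos, domain, what) {
    for (r in resnos) {
      n <- sum(res$resno == r & res$domain %in% domain)
      if (n == 0L) stop(what, " residue ", r, " not found in the ", domain, " domain")
      if (n > 1L) stop(what, " residue ", r, " is ambiguous (", n, " matches)")
    }
  }
  check(roles$exosite3_residues, "Spacer", "exosite-3")
  check(roles$exosite4_residues, "Spacer", "exosite-4")
  check(roles$tsp8_key_residues, "TSP8", "TSP8 key")
  check(roles$triage_forbidden_residues, "Spacer", "forbidden-loop")
  invisible(TRUE)
}

#' Donor/acceptor and charged-group chemistry of the standard amino acids
#'
#' Backbone N donates (through its amide hydrogen) and backbone O accepts for
#' every residue.  Side chains follow the conventional geometric H-bond
#' table: Ser/Thr/Tyr hydroxyls donate and accept; Asn/Gln/Arg/Lys/Trp/His
#' side-chain N-H donate; Asp/Glu/Asn/Gln side-chain O accept; His ring N
#' accept (His is treated as both donor and acceptor so either protonation
#' variant is covered).  Salt-bridge groups are the side-chain carboxylate O
#' of Asp/Glu and the side-chain N of Arg/Lys/His.
#'
#' @return object of class `chemistry_table` with elements `donor_atoms`,
#'   `acceptor_atoms`, `acidic_O`, `basic_N` (each a list mapping residue
#'   name to atom names; the special entry `.backbone` applies to all
#'   residues)
#' @export
default_chemistry <- function() {
  his <- c("HSD", "HSE", "HSP", "HIS")  # CHARMM protonation variants
  donor <- list(
    `.backbone` = "N",
    SER = "OG", THR = "OG1", TYR = "OH",
    ASN = "ND2", GLN = "NE2",
    ARG = c("NE", "NH1", "NH2"), LYS = "NZ", TRP = "NE1")
  for (h in his) donor[[h]] <- c("ND1", "NE2")
  acceptor <- list(
    `.backbone` = c("O", "OXT"),
    SER = "OG", THR = "OG1", TYR = "OH",
    ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
    ASN = "OD1", GLN = "OE1")
  for (h in his) acceptor[[h]] <- c("ND1", "NE2")
  basic <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ")
  for (h in his) basic[[h]] <- c("ND1", "NE2")
  chem <- structure(list(
    donor_atoms = donor, acceptor_atoms = acceptor,
    acidic_O = list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2")),
    basic_N = basic), class = "chemistry_table")
  .validate_chemistry(chem)
  chem
}

.validate_chemistry <- function(chem) {
  if (!all(c("ASP", "GLU") %in% names(chem$acidic_O)))
    stop("chemistry table must list Asp and Glu carboxylate oxygens")
  if (!all(c("ARG", "LYS") %in% names(chem$basic_N)) ||
      !any(c("HIS", "HSD") %in% names(chem$basic_N)))
    stop("chemistry table must list Arg/Lys/His side-chain nitrogens")
  invisible(TRUE)
}

# atom rows matching a chemistry map (list resid -> atom names, with
# .backbone applying to every residue)
.chem_match <- function(atom, map) {
  hit <- rep(FALSE, nrow(atom))
  bb <- map[[".backbone"]]
  if (!is.null(bb)) hit <- hit | atom$elety %in% bb
  for (res in setdiff(names(map), ".backbone")) {
    hit <- hit | (atom$resid == res & atom$elety %in% map[[res]])
  }
  hit & !atom$is_h
}
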