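# Synthetic two-domain complexes and replicate trajectories with programmed
# per-pair bond occupancies.  The generator stands in for an MD engine: it
# emulates two rigid mini-domains in contact, a set of interface donor-
# acceptor (H-bond) and acid-base (salt-bridge) residue pairs each switching
# between a bonded and a broken pose by a per-frame Bernoulli (or Markov)
# draw, plus Gaussian positional jitter.  The draws are returned as a ground
# truth matrix so detector and survival-ratio recovery can be tested against
# known occupancies.
#
# Geometry: the TSP8-like chain backbone lies at y = 0 and the Spacer-like
# chain at y = 10 (Angstrom); each scheduled pair occupies one x "slot"
# (7 A apart) where the partnered side chains reach across the interface.
# Bonded poses satisfy the detection criteria with margin (H-bond:
# donor-acceptor 2.9 A, donor-H-acceptor 180 deg; salt bridge: O-N 3.2 A);
# the broken pose displaces the acceptor-bearing side chain 2 A along the
# donor->acceptor axis, taking the donor-acceptor distance to 4.9 A.

.BB_NAMES <- c("N", "H", "CA", "C", "O")

# local residue templates: columns name, element, x, y, z; +y points toward
# the interface.  The Spacer-like chain is mirrored (y -> 10 - y).
.res_template <- function(kind) {
  bb <- data.frame(
    name = .BB_NAMES, elesy = c("N", "H", "C", "C", "O"),
    x = c(0, 0, 1.1, 2.2, 2.3), y = c(0, -1, 0.9, 0.3, -0.8), z = 0,
    stringsAsFactors = FALSE)
  side <- switch(kind,
    GLY = NULL,
    # H-bond donor: amide N-H aimed straight at the interface
    ASN = data.frame(name = c("CB", "ND2", "HD21"),
                     elesy = c("C", "N", "H"),
                     x = c(1.1, 0, 0), y = c(2.2, 3.55, 4.55), z = 0,
                     stringsAsFactors = FALSE),
    # H-bond acceptor: carboxylate O at 6.45 after mirroring (D-A 2.9)
    ASP_HB = data.frame(name = c("CB", "OD1", "OD2"),
                        elesy = c("C", "O", "O"),
                        x = c(1.1, 0, 0.9), y = c(2.2, 3.55, 3.3), z = 0,
                        stringsAsFactors = FALSE),
    # salt-bridge acid: O at 6.6 after mirroring (O-N 3.2)
    ASP_SB = data.frame(name = c("CB", "OD1", "OD2"),
                        elesy = c("C", "O", "O"),
                        x = c(1.1, 0, 0.9), y = c(2.2, 3.4, 3.15), z = 0,
                        stringsAsFactors = FALSE),
    # salt-bridge base: NZ reaching to 3.4; HZ1 perpendicular so the pair
    # never doubles as a geometric H-bond (D-H-A angle ~73 deg)
    LYS = data.frame(name = c("CB", "NZ", "HZ1"),
                     elesy = c("C", "N", "H"),
                     x = c(1.1, 0, 0), y = c(2.2, 3.4, 3.4), z = c(0, 0, 1),
                     stringsAsFactors = FALSE),
    stop("unknown residue template: ", kind))
  rbind(bb, side)
}

.resid_of_kind <- function(kind) sub("_(HB|SB)$", "", kind)

#' Generator specification
#'
#' @param n_residues_per_domain residues per domain; a single count used for
#'   both chains or a length-2 vector `c(tsp8, spacer)`.  The TSP8-like chain
#'   is numbered from 1072 (max 60 residues), the Spacer-like chain from 556
#'   (max 127), so generated structures follow the package's standard domain
#'   numbering.
#' @param n_frames frames per trajectory
#' @param frame_interval ps per saved frame (metadata)
#' @param jitter_sd Gaussian positional jitter, Angstrom (default 0.05)
#' @param seed integer seed; replicates use `seed`, `seed + 1`, `seed + 2`
#' @param replicates number of replicate trajectories (default 3)
#' @return object of class `generator_spec`
#' @export
generator_spec <- function(n_residues_per_domain = 10L, n_frames = 200L,
                           frame_interval = 10, jitter_sd = 0.05,
                           seed = 1L, replicates = 3L) {
  n <- as.integer(n_residues_per_domain)
  if (length(n) == 1L) n <- c(n, n)
  stopifnot(length(n) == 2L, all(n >= 1L), n_frames >= 1L, jitter_sd >= 0,
            replicates >= 1L)
  if (n[1] > 60L) stop("TSP8-like chain limited to 60 residues (1072-1131)")
  if (n[2] > 127L) stop("Spacer-like chain limited to 127 residues (556-682)")
  structure(list(n_residues_per_domain = n, n_frames = as.integer(n_frames),
                 frame_interval = frame_interval, jitter_sd = jitter_sd,
                 seed = as.integer(seed), replicates = as.integer(replicates)),
            class = "generator_spec")
}

#' Programmed occupancy schedule
#'
#' @param pairs data.frame with columns `tsp8_resno`, `spacer_resno`, `type`
#'   (`"hbond"` or `"saltbridge"`); each residue may appear in at most one
#'   pair
#' @param p_occ per-pair occupancy probability in `[0, 1]` (recycled)
#' @param correlation `NULL` for i.i.d. per-frame draws, or
#'   `list(flip = r)` for a two-state Markov chain started at its stationary
#'   distribution with on->off rate `r` per frame (the off->on rate is
#'   derived so the stationary occupancy stays `p_occ`)
#' @return object of class `occupancy_schedule`
#' @export
occupancy_schedule <- function(pairs, p_occ, correlation = NULL) {
  stopifnot(is.data.frame(pairs),
            all(c("tsp8_resno", "spacer_resno", "type") %in% names(pairs)))
  if (!all(pairs$type %in% c("hbond", "saltbridge")))
    stop("pair type must be 'hbond' or 'saltbridge'")
  p_occ <- rep_len(as.numeric(p_occ), nrow(pairs))
  if (any(p_occ < 0 | p_occ > 1)) stop("p_occ must lie in [0, 1]")
  if (anyDuplicated(pairs$tsp8_resno) || anyDuplicated(pairs$spacer_resno))
    stop("each residue may appear in at most one scheduled pair")
  if (!is.null(correlation)) {
    stopifnot(is.list(correlation), is.numeric(correlation$flip),
              correlation$flip > 0, correlation$flip <= 1)
  }
  pairs$p_occ <- p_occ
  structure(list(pairs = pairs, correlation = correlation),
            class = "occupancy_schedule")
}

#' Build a synthetic two-domain template complex
#'
#' Two chains (A: TSP8-like, numbered from 1072; B: Spacer-like, numbered
#' from 556) of glycine filler residues with explicit hydrogens.  Each
#' scheduled H-bond pair is realised as an Asn donor (chain A) facing an Asp
#' acceptor (chain B) with donor-acceptor distance 2.9 Angstrom and a linear
#' donor-H-acceptor geometry; each salt-bridge pair as a Lys (chain A) facing
#' an Asp (chain B) with carboxylate-O to NZ distance 3.2 Angstrom.
#'
#' @param spec a `generator_spec`
#' @param schedule an `occupancy_schedule`; pair residues must exist in the
#'   template
#' @return a `complex_structure` carrying a `template_geometry` attribute
#'   used by [generate_trajectory()] and [mutate_residues()]
#' @export
build_template <- function(spec, schedule = occupancy_schedule(
                             data.frame(tsp8_resno = integer(),
                                        spacer_resno = integer(),
                                        type = character()), numeric())) {
  stopifnot(inherits(spec, "generator_spec"),
            inherits(schedule, "occupancy_schedule"))
  n <- spec$n_residues_per_domain
  resno_a <- 1072L + seq_len(n[1]) - 1L
  resno_b <- 556L + seq_len(n[2]) - 1L
  pairs <- schedule$pairs
  if (!all(pairs$tsp8_resno %in% resno_a) ||
      !all(pairs$spacer_resno %in% resno_b))
    stop("scheduled pair residues do not fit within the template residue counts")

  n_slots <- max(n)
  if (nrow(pairs) > min(n))
    stop("more scheduled pairs than residues in the smaller domain")
  # scheduled pairs occupy the first slots; filler residues take the rest
  slot_a <- rep(NA_integer_, n[1]); slot_b <- rep(NA_integer_, n[2])
  if (nrow(pairs) > 0L) {
    slot_a[match(pairs$tsp8_resno, resno_a)] <- seq_len(nrow(pairs))
    slot_b[match(pairs$spacer_resno, resno_b)] <- seq_len(nrow(pairs))
  }
  slot_a[is.na(slot_a)] <- setdiff(seq_len(n_slots), slot_a)[seq_len(sum(is.na(slot_a)))]
  slot_b[is.na(slot_b)] <- setdiff(seq_len(n_slots), slot_b)[seq_len(sum(is.na(slot_b)))]

  kind_a <- rep("GLY", n[1]); kind_b <- rep("GLY", n[2])
  if (nrow(pairs) > 0L) {
    ia <- match(pairs$tsp8_resno, resno_a); ib <- match(pairs$spacer_resno, resno_b)
    kind_a[ia] <- ifelse(pairs$type == "hbond", "ASN", "LYS")
    kind_b[ib] <- ifelse(pairs$type == "hbond", "ASP_HB", "ASP_SB")
  }

  build_chain <- function(chain, resno, kind, slot, mirror) {
    parts <- lapply(seq_along(resno), function(i) {
      tmpl <- .res_template(kind[i])
      x <- tmpl$x + 7.0 * (slot[i] - 1L)
      y <- if (mirror) 10 - tmpl$y else tmpl$y
      data.frame(elety = tmpl$name, elesy = tmpl$elesy,
                 resid = .resid_of_kind(kind[i]), chain = chain,
                 resno = resno[i], x = x, y = y, z = tmpl$z,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, parts)
  }
  atom <- rbind(build_chain("A", resno_a, kind_a, slot_a, FALSE),
                build_chain("B", resno_b, kind_b, slot_b, TRUE))
  atom$eleno <- seq_len(nrow(atom))
  atom <- atom[, c("eleno", "elety", "resid", "chain", "resno",
                   "x", "y", "z", "elesy")]

  xyz <- as.matrix(atom[, c("x", "y", "z")])
  d2 <- .cross_dist2(xyz, xyz)
  diag(d2) <- Inf
  if (min(d2) < 0.8^2) {
    w <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
    stop(sprintf("construction error: atoms %d and %d overlap (%.2f A)",
                 w[1], w[2], sqrt(min(d2))))
  }

  tmpl <- complex_structure(atom)
  attr(tmpl, "template_geometry") <- list(
    slot_x = stats::setNames(7.0 * (c(slot_a, slot_b) - 1L),
                             paste0(c(rep("A", n[1]), rep("B", n[2])),
                                    c(resno_a, resno_b))),
    interface_y = 10, pairs = pairs)
  tmpl
}

# per-pair probe atoms used for ground-truth validation and the broken pose
.pair_atoms <- function(template, pairs) {
  atom <- template$atom
  lapply(seq_len(nrow(pairs)), function(s) {
    a <- which(atom$chain == "A" & atom$resno == pairs$tsp8_resno[s])
    b <- which(atom$chain == "B" & atom$resno == pairs$spacer_resno[s])
    side_b <- b[!(atom$elety[b] %in% .BB_NAMES)]
    if (pairs$type[s] == "hbond") {
      d <- a[atom$elety[a] == "ND2"]; h <- a[atom$elety[a] == "HD21"]
      acc <- b[atom$elety[b] == "OD1"]
      list(type = "hbond", donor = d, hydrogen = h, acceptor = acc,
           displace = side_b)
    } else {
      nz <- a[atom$elety[a] == "NZ"]; o <- b[atom$elety[b] == "OD1"]
      list(type = "saltbridge", donor = nz, acceptor = o, displace = side_b)
    }
  })
}

#' Generate a synthetic trajectory with programmed bond occupancies
#'
#' For every frame and scheduled pair, a Bernoulli(`p_occ`) draw (or a
#' stationary two-state Markov step when the schedule requests correlation)
#' selects the bonded pose or the broken pose (acceptor-bearing side chain
#' displaced 2 Angstrom along the donor->acceptor axis); Gaussian jitter of
#' sd `spec$jitter_sd` is then added to every atom.  Identical
#' (seed, spec, schedule) inputs give identical output.
#'
#' @param template a structure from [build_template()]
#' @param schedule the `occupancy_schedule` used to build the template
#' @param spec a `generator_spec`
#' @param seed seed for this trajectory (default `spec$seed`)
#' @return object of class `synthetic_run`: list with `trajectory` (an
#'   `md_trajectory`), `ground_truth` (n_frames x n_pairs logical matrix of
#'   the programmed draws), `schedule`, `spec`, `seed`
#' @export
generate_trajectory <- function(template, schedule, spec, seed = spec$seed) {
  stopifnot(inherits(template, "complex_structure"),
            inherits(schedule, "occupancy_schedule"),
            inherits(spec, "generator_spec"))
  geom <- attr(template, "template_geometry")
  if (is.null(geom)) stop("template must come from build_template()")
  pairs <- schedule$pairs
  n_pairs <- nrow(pairs)
  n_frames <- spec$n_frames
  n_atoms <- nrow(template$atom)
  probes <- .pair_atoms(template, pairs)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  present <- matrix(TRUE, n_frames, n_pairs)
  for (p in seq_len(n_pairs)) {
    pr <- pairs$p_occ[p]
    if (is.null(schedule$correlation)) {
      present[, p] <- runif(n_frames) < pr
    } else {
      r_off <- schedule$correlation$flip          # P(on -> off)
      r_on <- if (pr >= 1) 1 else r_off * pr / (1 - pr)  # P(off -> on)
      if (r_on > 1) stop("flip rate incompatible with p_occ ", pr)
      s <- logical(n_frames)
      s[1] <- runif(1) < pr
      if (n_frames > 1L) {
        u <- runif(n_frames - 1L)
        for (f in 2L:n_frames)
          s[f] <- if (s[f - 1L]) u[f - 1L] >= r_off else u[f - 1L] < r_on
      }
      present[, p] <- s
    }
  }

  base <- as.numeric(t(coords(template)))  # bio3d xyz order
  xyz <- matrix(base, nrow = n_frames, ncol = 3L * n_atoms, byrow = TRUE)
  for (p in seq_len(n_pairs)) {
    broken <- which(!present[, p])
    if (length(broken) == 0L) next
    ycols <- 3L * (probes[[p]]$displace - 1L) + 2L  # displace along +y (D->A axis)
    xyz[broken, ycols] <- xyz[broken, ycols] + 2.0
  }
  if (spec$jitter_sd > 0)
    xyz <- xyz + matrix(rnorm(n_frames * 3L * n_atoms, sd = spec$jitter_sd),
                        n_frames, 3L * n_atoms)

  if (n_pairs > 0L)
    colnames(present) <- sprintf("%s-%s", pairs$tsp8_resno, pairs$spacer_resno)
  run <- structure(list(
    trajectory = trajectory(template, xyz, frame_interval = spec$frame_interval),
    ground_truth = present, schedule = schedule, spec = spec,
    seed = as.integer(seed)), class = "synthetic_run")
  .check_programmed_geometry(run, probes)
  run
}

# warn if jitter breaks the bonded-pose criteria in > 1% of programmed-
# present frames (measured directly on the probe atoms)
.check_programmed_geometry <- function(run, probes) {
  xyz <- run$trajectory$xyz
  pairs <- run$schedule$pairs
  bad <- 0L; tot <- 0L
  at <- function(i) xyz[, 3L * (i - 1L) + 1:3, drop = FALSE]
  for (p in seq_len(nrow(pairs))) {
    on <- run$ground_truth[, p]
    if (!any(on)) next
    pr <- probes[[p]]
    d <- at(pr$donor)[on, , drop = FALSE]
    a <- at(pr$acceptor)[on, , drop = FALSE]
    dist <- sqrt(rowSums((d - a)^2))
    if (pr$type == "hbond") {
      h <- at(pr$hydrogen)[on, , drop = FALSE]
      hd <- d - h; ha <- a - h
      ang <- acos(pmin(1, pmax(-1, rowSums(hd * ha) /
                                 sqrt(rowSums(hd^2) * rowSums(ha^2))))) * 180 / pi
      viol <- dist >= 3.5 | ang <= 150
    } else {
      viol <- dist >= 4.0
    }
    bad <- bad + sum(viol); tot <- tot + sum(on)
  }
  if (tot > 0L && bad / tot > 0.01)
    warning(sprintf(
      "generator warning: jitter violates bonded-pose criteria in %.2f%% of programmed-present frames",
      100 * bad / tot))
  invisible(bad / max(tot, 1L))
}

#' @export
print.synthetic_run <- function(x, ...) {
  cat("synthetic_run: seed", x$seed, "-", x$trajectory$n_frames, "frames,",
      nrow(x$schedule$pairs), "scheduled pairs\n")
  invisible(x)
}

#' Generate replicate trajectories
#'
#' Replicate r uses seed `spec$seed + r - 1` (recorded in each run).
#'
#' @inheritParams generate_trajectory
#' @return list of `synthetic_run`, length `spec$replicates`
#' @export
generate_replicates <- function(template, schedule, spec) {
  lapply(seq_len(spec$replicates) - 1L, function(r)
    generate_trajectory(template, schedule, spec, seed = spec$seed + r))
}

#' Generate a synthetic interface H-bond count series
#'
#' I.i.d. rounded Gaussian counts truncated at zero, reproducible by seed;
#' used as input for [fit_gaussian()].
#'
#' @param mean,sd mean and standard deviation of the underlying Gaussian
#' @param n_frames series length (at least 100)
#' @param seed integer seed
#' @return integer vector of length `n_frames`
#' @export
generate_nhb_series <- function(mean, sd, n_frames, seed) {
  if (mean < 0) stop("parameter error: mean must be non-negative")
  stopifnot(sd > 0, n_frames >= 100L)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  as.integer(pmax(0, round(rnorm(n_frames, mean, sd))))
}

#' Write a synthetic run to disk
#'
#' Writes the trajectory as a multi-model PDB, the ground truth as a long CSV
#' (frame, pair, present) and a JSON metadata file recording spec, schedule
#' and seed.
#'
#' @param run a `synthetic_run`
#' @param dir output directory (created if needed)
#' @param prefix file name prefix (default `"synthetic"`)
#' @return named character vector of the files written, invisibly
#' @export
write_synthetic_dataset <- function(run, dir, prefix = "synthetic") {
  stopifnot(inherits(run, "synthetic_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    trajectory = file.path(dir, paste0(prefix, "_traj.pdb")),
    ground_truth = file.path(dir, paste0(prefix, "_truth.csv")),
    metadata = file.path(dir, paste0(prefix, "_meta.json")))
  write_trajectory(run$trajectory, paths[["trajectory"]])
  gt <- run$ground_truth
  long <- data.frame(
    frame = rep(seq_len(nrow(gt)), times = ncol(gt)),
    pair = rep(colnames(gt), each = nrow(gt)),
    type = rep(run$schedule$pairs$type, each = nrow(gt)),
    present = as.integer(gt))
  write.csv(long, paths[["ground_truth"]], row.names = FALSE)
  meta <- list(seed = run$seed, spec = unclass(run$spec),
               schedule = list(pairs = run$schedule$pairs,
                               correlation = run$schedule$correlation))
  jsonlite::write_json(meta, paths[["metadata"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
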