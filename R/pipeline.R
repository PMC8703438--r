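# End-to-end pipeline: synthetic generation (or trajectory files) ->
# contact scan -> survival statistics -> classification -> key residues ->
# report files, with a JSON manifest recording inputs, thresholds and seeds.

#' Pipeline configuration
#'
#' Each condition is either synthetic (`pairs` + `p_occ`: an occupancy
#' schedule realised by the generator) or file-based (`structure`: a PDB
#' path, `trajectories`: multi-model PDB paths, one per replicate).
#'
#' @param conditions named list of condition descriptions (see details)
#' @param outdir output directory
#' @param replicates replicate count for synthetic conditions (default 3)
#' @param n_frames frames per synthetic trajectory (default 200)
#' @param jitter_sd generator jitter in Angstrom (default 0.05)
#' @param frame_interval ps per frame (default 10)
#' @param seed base seed; condition c, replicate r uses
#'   `seed + (c-1)*replicates + (r-1)`
#' @param thresholds list of detection/reporting thresholds; defaults:
#'   `hbond_d` 3.5, `hbond_a` 150, `saltbridge_d` 4.0, `interface` 5.0,
#'   `reporting` 0.10, `key` 0.30
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(conditions, outdir, replicates = 3L,
                            n_frames = 200L, jitter_sd = 0.05,
                            frame_interval = 10, seed = 1L,
                            thresholds = list()) {
  stopifnot(is.list(conditions), length(conditions) >= 1L)
  if (is.null(names(conditions)) || any(names(conditions) == ""))
    stop("config error: every condition must be named")
  if (replicates < 1L)
    stop("config error: replicate count must be at least 1")
  if (n_frames < 1L) stop("config error: n_frames must be at least 1")
  def <- list(hbond_d = 3.5, hbond_a = 150, saltbridge_d = 4.0,
              interface = 5.0, reporting = 0.10, key = 0.30)
  thresholds <- utils::modifyList(def, thresholds)
  if (any(unlist(thresholds) <= 0))
    stop("config error: thresholds must be positive")
  for (nm in names(conditions)) {
    cond <- conditions[[nm]]
    synthetic <- !is.null(cond$pairs)
    file_based <- !is.null(cond$trajectories)
    if (synthetic == file_based)
      stop("config error: condition '", nm,
           "' must have either pairs (synthetic) or trajectories (files)")
    if (synthetic) {
      stopifnot(is.data.frame(as.data.frame(cond$pairs)))
      if (is.null(cond$p_occ))
        stop("config error: condition '", nm, "' lacks p_occ")
    } else if (is.null(cond$structure)) {
      stop("config error: condition '", nm, "' lacks a structure path")
    }
  }
  structure(list(conditions = conditions, outdir = outdir,
                 replicates = as.integer(replicates),
                 n_frames = as.integer(n_frames), jitter_sd = jitter_sd,
                 frame_interval = frame_interval, seed = as.integer(seed),
                 thresholds = thresholds), class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#'
#' The JSON round-trips losslessly through [read_pipeline_config()].
#'
#' @param config a `pipeline_config`
#' @param path JSON file
#' @return `path` (write) or a `pipeline_config` (read)
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in names(x$conditions)) {
    if (!is.null(x$conditions[[nm]]$pairs))
      x$conditions[[nm]]$pairs <- as.data.frame(x$conditions[[nm]]$pairs)
  }
  pipeline_config(conditions = x$conditions, outdir = x$outdir,
                  replicates = x$replicates, n_frames = x$n_frames,
                  jitter_sd = x$jitter_sd, frame_interval = x$frame_interval,
                  seed = x$seed, thresholds = x$thresholds)
}

.stage <- function(stage, cond, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed for condition '", cond,
         "': ", conditionMessage(e), call. = FALSE))
}

#' Run the full interface-analysis pipeline
#'
#' For every condition: obtain replicate trajectories (from the synthetic
#' generator or from files), scan them for interface H-bonds and salt
#' bridges, compute survival records, classify, apply the reporting filter,
#' select key residues on the TSP8 side, and write per-condition CSV tables
#' plus a JSON manifest.  Outputs are deterministic for a fixed
#' configuration: a rerun reproduces them byte for byte.
#'
#' @param config a `pipeline_config`
#' @return invisibly, a named list per condition with `records` (H-bond and
#'   salt-bridge survival records), `tables` (filtered report tables),
#'   `key_residues`, `scans`, `seeds`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  th <- config$thresholds
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  manifest <- list(package = "ifacemd",
                   version = as.character(utils::packageVersion("ifacemd")),
                   seed = config$seed, thresholds = th, conditions = list())
  for (ci in seq_along(config$conditions)) {
    nm <- names(config$conditions)[ci]
    cond <- config$conditions[[ci]]
    seeds <- config$seed + (ci - 1L) * config$replicates +
      seq_len(config$replicates) - 1L
    if (!is.null(cond$pairs)) {
      pairs <- as.data.frame(cond$pairs)
      schedule <- .stage("schedule", nm,
                         occupancy_schedule(pairs, cond$p_occ))
      n_a <- max(pairs$tsp8_resno) - 1072L + 1L
      n_b <- max(pairs$spacer_resno) - 556L + 1L
      spec <- generator_spec(
        n_residues_per_domain = c(max(n_a, 2L), max(n_b, 2L)),
        n_frames = config$n_frames, frame_interval = config$frame_interval,
        jitter_sd = config$jitter_sd, seed = seeds[1],
        replicates = config$replicates)
      template <- .stage("build_template", nm, build_template(spec, schedule))
      trajs <- lapply(seeds, function(s)
        .stage("generate", nm,
               generate_trajectory(template, schedule, spec,
                                   seed = s))$trajectory)
      inputs <- list(mode = "synthetic", pairs = pairs, p_occ = cond$p_occ)
    } else {
      structure_ <- .stage("read_pdb", nm, read_pdb(cond$structure))
      trajs <- lapply(cond$trajectories, function(p)
        .stage("read_trajectory", nm, read_trajectory(p, structure_)))
      seeds <- integer(0)
      inputs <- list(mode = "files", structure = cond$structure,
                     trajectories = cond$trajectories)
    }
    scans <- lapply(trajs, function(tr)
      .stage("scan_trajectory", nm,
             scan_trajectory(tr, d_cut = th$hbond_d, a_cut = th$hbond_a,
                             sb_cut = th$saltbridge_d)))
    hb_rec <- .stage("survival", nm, survival_records(scans, "hbond"))
    sb_rec <- .stage("survival", nm, survival_records(scans, "saltbridge"))
    hb_tab <- reporting_filter(hb_rec, th$reporting)
    sb_tab <- reporting_filter(sb_rec, th$reporting)
    keys <- select_key_residues(rbind(hb_rec, sb_rec), side = "TSP8",
                                threshold = th$key)
    f_hb <- file.path(config$outdir, paste0(nm, "_hbond_table.csv"))
    f_sb <- file.path(config$outdir, paste0(nm, "_saltbridge_table.csv"))
    f_key <- file.path(config$outdir, paste0(nm, "_key_residues.json"))
    write.csv(hb_tab, f_hb, row.names = FALSE)
    write.csv(sb_tab, f_sb, row.names = FALSE)
    jsonlite::write_json(
      list(side = keys$side, threshold = keys$threshold,
           residues = keys$residues),
      f_key, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest$conditions[[nm]] <- list(
      inputs = inputs, seeds = seeds, replicates = length(trajs),
      n_frames = trajs[[1]]$n_frames,
      outputs = c(f_hb, f_sb, f_key),
      n_hbond_pairs = nrow(hb_rec), n_saltbridge_pairs = nrow(sb_rec),
      key_residues = keys$residues)
    results[[nm]] <- list(records = list(hbond = hb_rec, saltbridge = sb_rec),
                          tables = list(hbond = hb_tab, saltbridge = sb_tab),
                          key_residues = keys, scans = scans, seeds = seeds)
    message(sprintf(
      "[%s] %d replicates x %d frames: %d H-bond pairs, %d salt-bridge pairs, key residues: %s",
      nm, length(trajs), trajs[[1]]$n_frames, nrow(hb_rec), nrow(sb_rec),
      paste(keys$residues, collapse = ",")))
  }
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  invisible(results)
}
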