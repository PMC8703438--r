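# Docking-model triage, mutation, pipeline orchestration and the CLI.

toy_roles <- role_config(exosite3_residues = 568L, exosite4_residues = 634L,
                         tsp8_key_residues = 1075L,
                         triage_forbidden_residues = c(621L, 622L, 623L))

# a docked-model fixture with designed static contacts; spacer partners are
# chosen so residue 568 (exosite-3 analog) sits on the interface and the
# 621-623 loop stays free unless requested
make_model <- function(n_hb, n_sb, touch_forbidden = FALSE) {
  spacer <- c(568L, 634L, 560L + seq_len(max(0, n_hb + n_sb - 2L)) - 1L)
  if (touch_forbidden) spacer[1] <- 622L
  pairs <- data.frame(
    tsp8_resno = 1072L + seq_len(n_hb + n_sb) - 1L,
    spacer_resno = spacer[seq_len(n_hb + n_sb)],
    type = c(rep("hbond", n_hb), rep("saltbridge", n_sb)))
  spec <- generator_spec(n_residues_per_domain = c(12L, 79L), n_frames = 1L)
  build_template(spec, occupancy_schedule(pairs, 1))
}

test_that("triage criteria gate on exosite-3 presence and a free loop", {
  a <- triage_model(make_model(7L, 3L), roles = toy_roles, model_id = "A")
  expect_true(a$criterion_exosite3)
  expect_true(a$criterion_loop_free)
  expect_true(a$eligible)
  expect_equal(c(a$n_hbonds, a$n_saltbridges), c(7L, 3L))
  bad <- triage_model(make_model(3L, 0L, touch_forbidden = TRUE),
                      roles = toy_roles, model_id = "bad")
  expect_false(bad$criterion_loop_free)
  expect_false(bad$eligible)
  # exosite-3 criterion fails when no exosite residue touches the interface
  lone <- triage_model(make_model(0L, 0L), roles = toy_roles)
  expect_false(lone$criterion_exosite3)
})

test_that("model ranking puts the richer static interface first", {
  a <- triage_model(make_model(7L, 3L), roles = toy_roles, model_id = "A")
  b <- triage_model(make_model(5L, 0L), roles = toy_roles, model_id = "B")
  ranked <- rank_models(list(b, a))
  expect_equal(names(ranked), c("A", "B"))
  expect_true(all(attr(ranked, "summary")$eligible))
  # an ineligible model never outranks an eligible one
  rich_bad <- triage_model(make_model(6L, 3L, touch_forbidden = TRUE),
                           roles = toy_roles, model_id = "richbad")
  poor_ok <- triage_model(make_model(1L, 0L), roles = toy_roles,
                          model_id = "poorok")
  ranked2 <- rank_models(list(rich_bad, poor_ok))
  expect_equal(names(ranked2), c("poorok", "richbad"))
  # deterministic tie-break by model id
  a2 <- triage_model(make_model(7L, 3L), roles = toy_roles, model_id = "A2")
  expect_equal(names(rank_models(list(a2, a))), c("A", "A2"))
})

test_that("alanine mutation truncates side chains and kills designed bonds", {
  fx <- make_mixed_template(n_hb = 2L, n_sb = 2L, n_res = 8L)
  tmpl <- fx$template
  expect_gt(nrow(detect_saltbridges_frame(structure = tmpl)), 0L)
  key_analogs <- fx$pairs$tsp8_resno
  mut <- mutate_residues(tmpl, data.frame(resno = key_analogs, to = "ALA"))
  expect_true(all(mut$atom$resid[mut$atom$resno %in% key_analogs] == "ALA"))
  expect_equal(nrow(detect_saltbridges_frame(structure = mut)), 0L)
  expect_equal(nrow(detect_hbonds_frame(structure = mut)), 0L)
  expect_error(mutate_residues(tmpl, data.frame(resno = 9999L, to = "ALA")),
               "not found")
})

test_that("Arg to Ala removes every basic side-chain nitrogen", {
  atom <- data.frame(
    eleno = 1:8,
    elety = c("N", "H", "CA", "C", "O", "NE", "NH1", "NH2"),
    resid = "ARG", chain = "A", resno = 1075L,
    x = c(0, 0, 1.1, 2.2, 2.3, 0.3, 1.0, -0.6),
    y = c(0, -1, 0.9, 0.3, -0.8, 2.2, 3.2, 3.2), z = 0,
    elesy = c("N", "H", "C", "C", "O", "N", "N", "N"))
  s <- complex_structure(atom)
  mut <- mutate_residues(s, data.frame(resno = 1075L, to = "ALA"))
  expect_false(any(mut$atom$elety %in% c("NE", "NH1", "NH2")))
  expect_true(all(c("N", "CA", "C", "O") %in% mut$atom$elety))
  expect_equal(unique(mut$atom$resid), "ALA")
})

test_that("template-library substitutions rebuild functional side chains", {
  fx <- make_mixed_template(n_hb = 1L, n_sb = 1L, n_res = 6L)
  # swap the salt-bridge Lys analog for an Asn (donor) side chain
  lys <- fx$pairs$tsp8_resno[fx$pairs$type == "saltbridge"]
  sw <- mutate_residues(fx$template, data.frame(resno = lys, to = "ASN"))
  expect_true("ND2" %in% sw$atom$elety[sw$atom$resno == lys])
  expect_false("NZ" %in% sw$atom$elety[sw$atom$resno == lys])
  # the old salt bridge is gone
  expect_equal(nrow(detect_saltbridges_frame(structure = sw)), 0L)
  # swaps need recorded template geometry
  plain <- complex_structure(fx$template$atom[, c(
    "eleno", "elety", "resid", "chain", "resno", "x", "y", "z", "elesy")])
  expect_error(mutate_residues(plain, data.frame(resno = lys, to = "ASN")),
               "generator-built")
})

test_that("mutating all key-residue analogs empties the key-residue report", {
  pairs <- data.frame(tsp8_resno = c(1075L, 1090L, 1095L, 1130L),
                      spacer_resno = c(634L, 660L, 635L, 636L),
                      type = c("hbond", "saltbridge", "hbond", "hbond"))
  sch <- occupancy_schedule(pairs, p_occ = c(0.8, 0.6, 0.9, 0.6))
  spec <- generator_spec(n_residues_per_domain = c(60L, 110L),
                         n_frames = 100L, seed = 31L)
  tmpl <- build_template(spec, sch)
  scans <- lapply(generate_replicates(tmpl, sch, spec),
                  function(r) scan_trajectory(r$trajectory))
  rec <- rbind(survival_records(scans, "hbond"),
               survival_records(scans, "saltbridge"))
  expect_setequal(select_key_residues(rec, "TSP8")$residues,
                  c(1075L, 1090L, 1095L, 1130L))
  # now truncate the four analogs: all designed interactions disappear
  mut <- mutate_residues(tmpl, data.frame(resno = pairs$tsp8_resno,
                                          to = "ALA"))
  empty_sch <- occupancy_schedule(
    data.frame(tsp8_resno = integer(), spacer_resno = integer(),
               type = character()), numeric())
  mut_scans <- lapply(generate_replicates(mut, empty_sch, spec),
                      function(r) scan_trajectory(r$trajectory))
  mut_rec <- rbind(survival_records(mut_scans, "hbond"),
                   survival_records(mut_scans, "saltbridge"))
  expect_length(select_key_residues(mut_rec, "TSP8")$residues, 0L)
  expect_equal(sum(mut_rec$bond_type == "saltbridge"), 0L)
})

test_that("the pipeline is deterministic and writes a faithful manifest", {
  pairs <- data.frame(tsp8_resno = c(1075L, 1077L), spacer_resno = c(557L, 559L),
                      type = c("hbond", "saltbridge"))
  make_cfg <- function(outdir)
    pipeline_config(conditions = list(
      WT = list(pairs = pairs, p_occ = c(0.8, 0.6)),
      Mut = list(pairs = pairs, p_occ = c(0.1, 0.05))),
      outdir = outdir, n_frames = 60L, seed = 5L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  res1 <- run_pipeline(make_cfg(d1))
  res2 <- run_pipeline(make_cfg(d2))
  for (f in c("WT_hbond_table.csv", "WT_saltbridge_table.csv",
              "Mut_hbond_table.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  man <- jsonlite::read_json(file.path(d1, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$conditions$WT$replicates, 3L)
  expect_equal(man$conditions$WT$seeds, c(5L, 6L, 7L))
  expect_equal(man$conditions$Mut$seeds, c(8L, 9L, 10L))
  expect_equal(man$seed, 5L)
  # occupancies separate the two conditions
  expect_true(1075L %in% res1$WT$key_residues$residues)
  expect_length(res1$Mut$key_residues$residues, 0L)
})

test_that("configuration errors are raised before any computation", {
  pairs <- data.frame(tsp8_resno = 1075L, spacer_resno = 557L, type = "hbond")
  expect_error(pipeline_config(list(WT = list(pairs = pairs, p_occ = 1)),
                               tempdir(), replicates = 0L), "config error")
  expect_error(pipeline_config(list(list(pairs = pairs, p_occ = 1)),
                               tempdir()), "config error")
  expect_error(pipeline_config(list(WT = list()), tempdir()), "config error")
  cfg <- pipeline_config(list(WT = list(pairs = pairs, p_occ = 1)),
                         tempdir(), thresholds = list(reporting = 0.2))
  f <- withr::local_tempfile(fileext = ".json")
  write_pipeline_config(cfg, f)
  back <- read_pipeline_config(f)
  expect_equal(back$thresholds, cfg$thresholds)
  expect_equal(back$conditions$WT$pairs, cfg$conditions$WT$pairs)
  expect_equal(back$seed, cfg$seed)
})

test_that("the command line drives generate, triage and run", {
  d <- withr::local_tempdir()
  # generate
  pairs_csv <- file.path(d, "pairs.csv")
  write.csv(data.frame(tsp8_resno = c(1073L, 1074L), spacer_resno = c(557L, 558L),
                       type = c("hbond", "saltbridge"), p_occ = c(0.9, 0.7)),
            pairs_csv, row.names = FALSE)
  gen_dir <- file.path(d, "gen")
  expect_equal(ifacemd_main(c("generate", "--pairs", pairs_csv, "--out",
                              gen_dir, "--n-frames", "10", "--seed", "3",
                              "--replicates", "2")), 0L)
  expect_true(file.exists(file.path(gen_dir, "replicate2_traj.pdb")))
  # triage over written PDB models
  roles_json <- file.path(d, "roles.json")
  jsonlite::write_json(list(exosite3 = 568L, exosite4 = 634L,
                            tsp8_key = 1075L, forbidden = c(621L, 622L, 623L)),
                       roles_json, auto_unbox = TRUE)
  pa <- file.path(d, "modelA.pdb"); pb <- file.path(d, "modelB.pdb")
  write_pdb(make_model(7L, 3L), pa)
  write_pdb(make_model(5L, 0L), pb)
  rep_json <- file.path(d, "triage.json")
  expect_equal(suppressMessages(
    ifacemd_main(c("triage", "--out", rep_json, pa, pb, "--roles",
                   roles_json))), 0L)
  tri <- jsonlite::read_json(rep_json, simplifyVector = TRUE)
  expect_equal(tri$model_id[1], "modelA")
  # full pipeline from a config file
  cfg <- pipeline_config(list(WT = list(
    pairs = data.frame(tsp8_resno = 1073L, spacer_resno = 557L,
                       type = "hbond"), p_occ = 0.8)),
    outdir = file.path(d, "out"), n_frames = 20L, seed = 2L)
  cfg_json <- file.path(d, "config.json")
  write_pipeline_config(cfg, cfg_json)
  expect_equal(suppressMessages(
    ifacemd_main(c("run", "--config", cfg_json))), 0L)
  expect_true(file.exists(file.path(d, "out", "manifest.json")))
  # unknown commands and missing options fail cleanly
  expect_equal(suppressMessages(ifacemd_main("frobnicate")), 1L)
  expect_equal(suppressMessages(ifacemd_main(c("scan", "--out", "x"))), 1L)
})
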