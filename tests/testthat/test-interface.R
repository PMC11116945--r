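test_that("community tables round-trip through delimited text", {
  sd1 <- generate_study_design(seed = 21)
  dir <- withr::local_tempdir()
  write_community(sd1$community, dir, prefix = "rt", env = sd1$env)
  back <- read_community(file.path(dir, "rt_counts.csv"),
                         file.path(dir, "rt_samples.csv"),
                         file.path(dir, "rt_genera.csv"),
                         file.path(dir, "rt_env.csv"))
  expect_equal(back$community$counts, sd1$community$counts)
  expect_equal(back$community$genus_meta, sd1$community$genus_meta,
               ignore_attr = TRUE)
  expect_equal(back$env$SM, sd1$env$SM, tolerance = 1e-10)
})

test_that("malformed inputs fail with addressed messages", {
  tab <- toy_community(matrix(c(1, 2, 0, 3), 2))
  dir <- withr::local_tempdir()
  write_community(tab, dir, prefix = "bad")
  counts <- file.path(dir, "bad_counts.csv")

  # negative count
  txt <- readLines(counts)
  txt[2] <- sub("^s1,1", "s1,-1", txt[2])
  writeLines(txt, counts)
  expect_error(read_community(counts, file.path(dir, "bad_samples.csv"),
                              file.path(dir, "bad_genera.csv")),
               "negative count.*g1")

  # non-numeric count
  txt[2] <- sub("^s1,-?1", "s1,abc", txt[2])
  writeLines(txt, counts)
  expect_error(read_community(counts, file.path(dir, "bad_samples.csv"),
                              file.path(dir, "bad_genera.csv")),
               "non-numeric")

  # env table missing a sample
  write_community(tab, dir, prefix = "ok",
                  env = data.frame(sample_id = "s1", SM = 1))
  expect_error(read_community(file.path(dir, "ok_counts.csv"),
                              file.path(dir, "ok_samples.csv"),
                              file.path(dir, "ok_genera.csv"),
                              file.path(dir, "ok_env.csv")),
               "s2")
})

test_that("run configuration validates paths and fills defaults", {
  dir <- withr::local_tempdir()
  sd1 <- generate_study_design(seed = 2)
  write_community(sd1$community, dir, prefix = "cfg", env = sd1$env)
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(list(counts = file.path(dir, "cfg_counts.csv"),
                        samples = file.path(dir, "cfg_samples.csv"),
                        genera = file.path(dir, "cfg_genera.csv"),
                        env = file.path(dir, "cfg_env.csv"),
                        n_sims_ems = 50), cfg_path)
  cfg <- read_run_config(cfg_path)
  expect_equal(cfg$n_sims_ems, 50)
  expect_equal(cfg$alpha, 0.05)          # default filled
  expect_equal(cfg$geo_mode, "great_circle")

  yaml::write_yaml(list(counts = file.path(dir, "nope.csv"),
                        samples = file.path(dir, "cfg_samples.csv"),
                        genera = file.path(dir, "cfg_genera.csv"),
                        env = file.path(dir, "cfg_env.csv")), cfg_path)
  expect_error(read_run_config(cfg_path), "does not exist")
})

test_that("the full pipeline yields one EMS row per analysis unit", {
  sd1 <- generate_study_design(seed = 31)
  dir <- withr::local_tempdir()
  res <- suppressWarnings(
    run_all(sd1$community, sd1$env, out_dir = dir,
            n_sims_ems = 40, n_sims_cooc = 40, n_perm_mantel = 99,
            seed = 4, by_trophic_group = FALSE,
            n_trees_importance = 100, n_perms_importance = 15))
  # 12 local units (4 sites x 3 covers) + 3 regional units
  expect_equal(nrow(res$ems) + length(res$skipped), 15)
  expect_equal(nrow(res$mantel), nrow(res$ems))
  expect_true(all(res$cooccurrence$group == "all"))
  expect_equal(sort(unique(res$importance$unit)),
               sort(paste("regional", unique(sd1$community$sample_meta$land_cover),
                          sep = "/")))
  expect_true(file.exists(file.path(dir, "ems_report.csv")))
  expect_true(file.exists(file.path(dir, "run_log.yaml")))

  # configuration errors precede computation
  expect_error(run_all(sd1$community, sd1$env,
                       land_cover_set = c("farmland", "swamp")),
               "unknown land cover")
})

test_that("repeated runs with one seed are identical", {
  sd1 <- generate_study_design(seed = 13)
  sub <- subset_community(sd1$community, "woodland", "regional")
  a <- ems_pipeline(sub, n_sims = 30, seed = 6)
  b <- ems_pipeline(sub, n_sims = 30, seed = 6)
  expect_identical(ems_report(list(u = a)), ems_report(list(u = b)))
  ca <- cooccurrence_analysis(sub, n_sims = 30, seed = 6)
  cb <- cooccurrence_analysis(sub, n_sims = 30, seed = 6)
  expect_identical(ca$null$values, cb$null$values)
})
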