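test_that("an empty config document yields all defaults", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", f)
  cfg <- load_config(f)
  expect_equal(cfg$pool_fraction, run_config()$pool_fraction)
  expect_equal(cfg$spin_up_days, run_config()$spin_up_days)
  expect_equal(cfg$eps$eps_keratin, 15)
})

test_that("config overrides are applied and unknown keys rejected by name", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("pool_fraction: 0.55", "eps:", "  eps_keratin: 14"), f)
  cfg <- load_config(f)
  expect_equal(cfg$pool_fraction, 0.55)
  expect_equal(cfg$eps$eps_keratin, 14)

  f2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("eps:\n  epz_keratin: 14", f2)
  expect_error(load_config(f2), "epz_keratin")

  f3 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("pool_fractionn: 0.5", f3)
  expect_error(load_config(f3), "pool_fractionn")

  expect_error(load_config(tempfile()), "not found")
})

test_that("coefficient sets carry provenance and reject unknown overrides", {
  co <- default_coefficients()
  expect_true(all(vapply(co, function(s) nzchar(s$provenance), logical(1))))
  expect_error(default_coefficients(list(ventilation = list(x = 1))),
               "ventilation")
  co2 <- default_coefficients(list(respiration = list(vent_ref_m3_per_d = 99)))
  expect_equal(co2$respiration$vent_ref_m3_per_d, 99)
})

test_that("driver tables round-trip through CSV with value equality", {
  d <- gen_drivers(40, seed = 9)
  dir <- withr::local_tempdir()
  cfg <- run_config(seed = 9L)
  write_driver_tables(d, dir, cfg)
  back <- read_driver_tables(dir)
  for (tab in c("weather", "isotopes", "calendar", "leaf_diurnal")) {
    expect_equal(back[[tab]], d[[tab]], tolerance = 1e-12, ignore_attr = TRUE)
  }
  # config hash recorded in the comment header
  header <- readLines(file.path(dir, "weather.csv"), n = 3)
  expect_true(any(grepl(paste0("# config_hash: ", config_hash(cfg)), header)))
  expect_true(any(grepl("# seed: 9", header)))

  expect_error(read_driver_tables(withr::local_tempdir()), "missing driver")
})

test_that("a simulation on read-back drivers reproduces the in-memory run", {
  d <- gen_drivers(60, seed = 4)
  dir <- withr::local_tempdir()
  write_driver_tables(d, dir)
  sim1 <- simulate_body_water(d)
  sim2 <- simulate_body_water(read_driver_tables(dir))
  expect_equal(sim2$d_bw, sim1$d_bw, tolerance = 1e-12)
})

cli_path <- function() {
  p <- system.file("exec", "isocow", package = "isocow")
  if (!nzchar(p)) p <- file.path(testthat::test_path("..", ".."), "exec", "isocow")
  normalizePath(p)
}

run_cli <- function(...) {
  rscript <- file.path(R.home("bin"), "Rscript")
  suppressWarnings(system2(rscript, c(cli_path(), ...),
                           stdout = TRUE, stderr = TRUE))
}

test_that("cli generate is reproducible for a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  out1 <- run_cli("generate", "--seed", "3", "--n-days", "80", "--out", d1)
  out2 <- run_cli("generate", "--seed", "3", "--n-days", "80", "--out", d2)
  expect_null(attr(out1, "status"))
  expect_null(attr(out2, "status"))
  for (f in c("weather.csv", "isotopes.csv", "calendar.csv",
              "leaf_diurnal.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("cli simulate writes the daily table and rejects misaligned drivers", {
  drv <- withr::local_tempdir()
  run <- withr::local_tempdir()
  run_cli("generate", "--seed", "1", "--n-days", "80", "--out", drv)
  out <- run_cli("simulate", "--drivers", drv, "--out", run)
  expect_null(attr(out, "status"))
  sim <- read_table(file.path(run, "simulation.csv"))
  expect_equal(nrow(sim), 80)
  expect_true(all(c("d_bw", "m_residual_water", "d_keratin") %in% names(sim)))

  # truncate the calendar -> aligned-length error, nonzero exit
  cal <- readLines(file.path(drv, "calendar.csv"))
  writeLines(cal[-length(cal)], file.path(drv, "calendar.csv"))
  bad <- run_cli("simulate", "--drivers", drv, "--out", run)
  expect_equal(attr(bad, "status"), 1L)
  expect_true(any(grepl("aligned", bad)))
})

test_that("cli end-to-end run writes all table kinds", {
  drv <- withr::local_tempdir()
  run <- withr::local_tempdir()
  run_cli("generate", "--seed", "2", "--n-days", "400", "--out", drv)
  run_cli("hair", "--drivers", drv, "--out", run)
  run_cli("attribute", "--drivers", drv, "--out", run)
  expect_true(file.exists(file.path(run, "hair_segments.csv")))
  expect_true(file.exists(file.path(run, "isoflux.csv")))
  expect_true(file.exists(file.path(run, "variance_attribution.csv")))
  seg <- read_table(file.path(run, "hair_segments.csv"))
  expect_true(all(seg$end_day - seg$start_day > 13))
  iso <- read_table(file.path(run, "isoflux.csv"))
  expect_equal(as.numeric(tapply(iso$contribution, iso$period, sum)),
               rep(100, 3), tolerance = 1e-9)
})
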