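make_batch_file <- function(dir, n = 2, noise = 0.02, seed = 5) {
  sds <- noise_sds_for("exponential", frac = max(noise, 1e-6))
  spec <- synthetic_spec("exponential", noise_sds = if (noise > 0) sds else 0,
                         seed = seed)
  batch <- generate_batch(n, spec, jitter = list(mu = c(0.4, 0.8)), dir = dir)
  list(batch = batch, sds = sds)
}

test_that("a full run writes the five artifacts per experiment plus aggregates", {
  dir <- withr::local_tempdir()
  b <- make_batch_file(dir, n = 2)
  out <- file.path(dir, "out")
  res <- run_experiments(b$batch$data_path, model = "exponential", sds = b$sds,
                         mc_iterations = 10, seed = 7, output_dir = out)
  expect_length(res$fits, 2L)
  expect_identical(res$failures, character(0))
  for (exp in c("exp_001", "exp_002")) {
    d <- file.path(out, exp)
    expect_true(all(file.exists(file.path(d, c("results.tsv", "stats.txt",
                                               "config.yaml", "plot.pdf",
                                               "plot.svg", "exflux.log")))))
    expect_gt(file.size(file.path(d, "plot.svg")), 0)
  }
  agg <- read_results_tsv(file.path(out, "results.tsv"))
  expect_identical(nrow(agg), 8L)           # 2 experiments x 4 parameters
  expect_setequal(unique(agg$experiment), c("exp_001", "exp_002"))
  log_lines <- readLines(file.path(out, "exflux.log"))
  expect_true(any(grepl("exflux", log_lines)))
  expect_true(any(grepl("objective", log_lines)))
})

test_that("replaying the emitted configuration reproduces the results file bitwise", {
  dir <- withr::local_tempdir()
  b <- make_batch_file(dir, n = 2)
  out1 <- file.path(dir, "run1")
  run_experiments(b$batch$data_path, model = "exponential", sds = b$sds,
                  mc_iterations = 20, seed = 11, output_dir = out1)
  cfg <- read_run_config(file.path(out1, "config.yaml"))
  out2 <- file.path(dir, "run2")
  run_experiments(b$batch$data_path, config = cfg, output_dir = out2)
  f1 <- readBin(file.path(out1, "results.tsv"), "raw", file.size(file.path(out1, "results.tsv")))
  f2 <- readBin(file.path(out2, "results.tsv"), "raw", file.size(file.path(out2, "results.tsv")))
  expect_identical(f1, f2)
})

test_that("a failing experiment is skipped while the others complete", {
  dir <- withr::local_tempdir()
  b <- make_batch_file(dir, n = 2)
  # sabotage experiment 1: only one glc observation left
  lines <- readLines(b$batch$data_path)
  header <- strsplit(lines[1], "\t")[[1]]
  glc_col <- which(header == "glc")
  for (i in 3:13) {    # rows 2..13 are exp_001; keep one glc value
    cells <- strsplit(lines[i], "\t")[[1]]
    cells[glc_col] <- ""
    lines[i] <- paste(cells, collapse = "\t")
  }
  writeLines(lines, b$batch$data_path)
  out <- file.path(dir, "out")
  res <- run_experiments(b$batch$data_path, model = "exponential", sds = b$sds,
                         mc_iterations = 0, seed = 3, output_dir = out)
  expect_identical(res$failures, "exp_001")
  expect_named(res$fits, "exp_002")
  expect_true(file.exists(file.path(out, "exp_002", "results.tsv")))
  expect_true(any(grepl("FAILED", readLines(file.path(out, "exflux.log")))))
})

test_that("model comparison ranks the generating model first on strongly degrading data", {
  dir <- withr::local_tempdir()
  truth <- c(X0 = 0.02, mu = 0.6, glc_0 = 20, q_glc = -2, k_glc = 0.3)
  sds <- noise_sds_for("exponential_degradation", truth)
  g <- generate_dataset(synthetic_spec("exponential_degradation", truth,
                                       noise_sds = sds, seed = 9))
  path <- file.path(dir, "d.tsv")
  readr::write_tsv(g$data, path)
  out <- file.path(dir, "cmp")
  res <- compare_models(path, c("exponential", "exponential_degradation"),
                        sds = sds, seed = 9, output_dir = out)
  rk <- res$rankings
  expect_identical(rk$model[1], "exponential_degradation")
  expect_equal(rk$delta_aic[1], 0)
  expect_true(file.exists(file.path(out, "experiment", "ranking.tsv")))
  expect_true(file.exists(file.path(out, "experiment", "exponential", "results.tsv")))
  expect_error(compare_models(path, "exponential", sds = sds),
               class = "exflux_input_error")
})

test_that("a noiseless synthetic batch is recovered within 1% end to end", {
  dir <- withr::local_tempdir()
  spec <- synthetic_spec("exponential", noise_sds = 0, seed = 15)
  batch <- generate_batch(50, spec,
                          jitter = list(mu = c(0.3, 0.9), q_glc = c(-6, -2),
                                        X0 = c(0.01, 0.1)),
                          dir = dir)
  out <- file.path(dir, "out")
  res <- run_experiments(batch$data_path, model = "exponential",
                         sds = noise_sds_for("exponential"),
                         mc_iterations = 0, seed = 20, output_dir = out)
  expect_length(res$fits, 50L)
  merged <- dplyr::inner_join(res$results, batch$truth,
                              by = c("experiment", "parameter"))
  rel_err <- abs(merged$optimal - merged$value) / abs(merged$value)
  expect_lt(max(rel_err), 0.01)
})

test_that("the command-line interface lists models, runs, and signals usage errors", {
  cli <- system.file("cli", "exflux.R", package = "exflux")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")

  lm <- system2(rscript, c(cli, "--list-models"), stdout = TRUE)
  expect_identical(attr(lm, "status"), NULL)   # exit 0
  expect_true(all(c("exponential", "monod") %in% lm))

  bad <- suppressWarnings(system2(rscript, c(cli, "--model", "exponential"),
                                  stdout = TRUE, stderr = TRUE))
  expect_identical(attr(bad, "status"), 2L)    # --data missing -> usage error

  dir <- withr::local_tempdir()
  b <- make_batch_file(dir, n = 1)
  out <- file.path(dir, "cli_out")
  ok <- suppressWarnings(system2(
    rscript,
    c(cli, "--data", b$batch$data_path, "--model", "exponential",
      "--sd", sprintf("X=%.6f,glc=%.6f", b$sds[["X"]], b$sds[["glc"]]),
      "--mc", "5", "--seed", "4", "--output", out),
    stdout = TRUE, stderr = TRUE))
  expect_identical(attr(ok, "status"), NULL)
  expect_true(file.exists(file.path(out, "exp_001", "plot.pdf")))
  expect_true(file.exists(file.path(out, "results.tsv")))
})
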