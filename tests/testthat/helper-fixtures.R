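# shared fixtures: the reference sampling grid (12 points over 0-8 h) and
# per-variable measurement sds scaled to a fraction of each variable's
# dynamic range (2% by default), used both to generate noise and as the
# objective weights so the chi-squared statistic is correctly calibrated

ref_times <- function(n = 12, t_max = 8) seq(0, t_max, length.out = n)

noise_sds_for <- function(model, truth = builtin_truth(model),
                          times = ref_times(), frac = 0.02) {
  traj <- simulate_model(model, truth, times)
  vars <- setdiff(names(traj), "time")
  vapply(vars, function(v) frac * max(abs(traj[[v]])), 0)
}

quiet_fit <- function(...) suppressWarnings(fit_growth(...))

max_rel_err <- function(est, truth) {
  truth <- truth[names(truth)]
  max(abs(est[names(truth)] - truth) / abs(truth))
}

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv"),
                            eol = "\n") {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = eol)
  path
}
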