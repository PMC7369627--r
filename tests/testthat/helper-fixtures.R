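# shared fixtures: a typical Baltic-incubation core context and speciation
# parameters (8 degC, salinity 10)
make_ctx <- function(core_id = "C1", treatment = "control", phi = 0.9,
                     abundance = 500) {
  core_context(core_id, treatment, phi, 8, 10, abundance,
               overlying_o2 = 310)
}

make_params <- function() speciation_params(8, 10)

# closed-form ordinary-least-squares oracle (normal equations), independent
# of stats::lm
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# write a small two-column profile file for read_profile tests
write_profile_file <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}
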