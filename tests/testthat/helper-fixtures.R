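# Shared fixture builders. Everything is generated in code; the only
# on-disk inputs are the packaged reference tables.

blackberry_tac_truth <- c(1644.47, -13.53, -12.56, 18.42)
blackberry_color <- list(means = c(10.68, 13.80, 4.95),
                         sds = c(2.23, 3.90, 1.70))

make_spec <- function(..., seed = 1) {
  defaults <- list(fruit_label = "blackberry",
                   true_coefficients = blackberry_tac_truth,
                   color_means = blackberry_color$means,
                   color_sds = blackberry_color$sds,
                   seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(synthetic_spec, args)
}

# One synthetic spec per published fruit x analyte model, with the noise
# SD chosen so the expected R^2 matches the published one:
# noise_sd^2 = var(signal) * (1/R^2 - 1).
reference_specs <- function(seed = 7) {
  models <- reference_models()
  colors <- reference_colors()
  specs <- list()
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    cc <- colors[colors$fruit == m$fruit, ]
    sds <- c(cc$L_sd, cc$a_sd, cc$b_sd)
    signal_var <- sum((c(m$b1, m$b2, m$b3) * sds)^2)
    noise_sd <- sqrt(signal_var * (1 / m$r2 - 1))
    specs[[paste(m$fruit, m$analyte, sep = ".")]] <- synthetic_spec(
      fruit_label = m$fruit,
      true_coefficients = c(m$b0, m$b1, m$b2, m$b3),
      color_means = c(cc$L_mean, cc$a_mean, cc$b_mean),
      color_sds = sds, noise_sd = noise_sd, analyte = m$analyte,
      seed = seed + i
    )
  }
  specs
}
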