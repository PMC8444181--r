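# shared fixtures built in code

# correlated standard-normal pair with exact population correlation rho
rgauss_pair <- function(n, rho, seed) {
  withr_seed <- function(expr) {
    set.seed(seed)
    expr
  }
  withr_seed({
    z1 <- rnorm(n)
    z2 <- rnorm(n)
    list(x = z1, y = rho * z1 + sqrt(1 - rho^2) * z2)
  })
}

# minimal valid event table
toy_events <- function(n = 10, genotype = "wt", dose = 10, time = 15,
                       replicate = "1", stat3 = NULL, pstat3 = NULL) {
  event_table(data.frame(
    cell_index = seq_len(n),
    stat3 = stat3 %||% (100 + seq_len(n)),
    pstat3 = pstat3 %||% (10 + seq_len(n)),
    genotype = genotype,
    dose_ng_ml = dose,
    time_min = time,
    replicate = replicate,
    stringsAsFactors = FALSE
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gaussian channel from per-level means/sds
gaussian_channel <- function(means, sds = rep(1, length(means)), n = 2000,
                             seed = 1) {
  set.seed(seed)
  channel_samples(
    seq_along(means),
    Map(function(m, s) rnorm(n, m, s), means, sds)
  )
}
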