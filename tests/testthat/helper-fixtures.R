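# shared fixtures built in code

moro_spec <- function() {
  read_site_spec(system.file("extdata", "moro.yaml", package = "soilrisk"))
}

ifelodun_spec <- function() {
  read_site_spec(system.file("extdata", "ifelodun.yaml", package = "soilrisk"))
}

# small deterministic table for unit tests
toy_table <- function() {
  concentration_table(
    cbind(As = c(18, 22, 26, 30), Pb = c(400, 450, 500, 550), Mg = c(120, 140, 160, 180)),
    site_id = "toy")
}

# random positive table for property tests
random_table <- function(n, k, seed) {
  withr::with_seed(seed, {
    m <- matrix(stats::rlnorm(n * k, meanlog = 2, sdlog = 0.8), n, k)
  })
  colnames(m) <- paste0("M", seq_len(k))
  concentration_table(m, site_id = paste0("rand", seed))
}

# independent two-pass Pearson oracle (product-moment formula by hand)
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
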