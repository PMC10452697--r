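# Independent brute-force oracle for the Poisson concentration estimate:
# maximize the binomial likelihood of observing d positive chambers out of
# n, with per-chamber positive probability 1 - exp(-lambda), by numerical
# optimization over lambda. Never calls the closed form under test.
oracle_concentration <- function(d, n, volume_ul) {
  if (d == 0) return(0)
  nll <- function(lam) -(d * log(1 - exp(-lam)) - (n - d) * lam)
  stats::optimize(nll, c(1e-9, 25), tol = 1e-13)$minimum / volume_ul
}

# A small chip for fast unit tests (240 chambers, paper-like geometry).
small_layout <- function(n_rows = 12, chambers_per_row = 20) {
  chip_layout(2, n_rows, chambers_per_row, 87, 120, 60, 55)
}

# Two-channel test panel: reference on Cy5, one mutation on HEX.
g12d_panel <- function() {
  panel_config(c("Cy5", "HEX"), "Cy5", c(G12D = "HEX"))
}

# Hand-built chamber call table with full control over the calls.
make_calls <- function(ref, mut, filled = rep(TRUE, length(ref))) {
  n <- length(ref)
  df <- data.frame(chamber_id = seq_len(n), row = 1L, col = seq_len(n),
                   x_px = 0, y_px = 0, filled = filled,
                   Cy5_intensity = NA_real_, Cy5_call = ref,
                   HEX_intensity = NA_real_, HEX_call = mut)
  structure(df, channels = c("Cy5", "HEX"),
            thresholds = c(Cy5 = NA_real_, HEX = NA_real_),
            class = c("chamber_calls", "data.frame"))
}
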