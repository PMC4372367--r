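# Shared fixtures: compact phantom geometries and quadrature oracles.

# full "standard" geometry (48x48x12, 60 timepoints at TR 1.5 s)
standard_acq <- function() acquisition_params()

# compact geometry for fast unit tests and Monte-Carlo loops
small_acq <- function(nt = 40L, shape = c(24L, 24L, 8L))
  acquisition_params(n_timepoints = nt, matrix_shape = shape)

# pipeline config matched to the compact phantom's artery size
small_config <- function(...) pipeline_config(n_aif = 6L, ...)

# independent fine-grid trapezoid quadrature (pracma)
trapz_oracle <- function(t, y) pracma::trapz(t, y)

# closed-form gamma-variate evaluated on an arbitrary grid, peak-normalized
gamma_closed_form <- function(t, t0, alpha, beta, amplitude) {
  y <- ifelse(t > t0, (t - t0)^alpha * exp(-(t - t0) / beta), 0)
  amplitude * y / ((alpha * beta)^alpha * exp(-alpha))
}

# truth lookup: name -> row of the truth table
truth_row <- function(truths, name) truths[truths$name == name, ]

# map VOI rows to their per-structure truth values
join_truth <- function(voi, truths) {
  key <- paste0(voi$structure, ifelse(voi$side == "right", "_r", "_l"))
  voi$cbf_true <- truths$cbf_true[match(key, truths$name)]
  voi$cbv_true <- truths$cbv_true[match(key, truths$name)]
  voi
}
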