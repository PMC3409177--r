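# Shared fixtures and independent oracles used across test files.

# Brute-force oracle: mean SI over ALL nonzero cyclic rotations of g_last.
brute_force_rotation_floor <- function(g0, g_last) {
  n <- length(g_last)
  mean(sapply(seq_len(n - 1L), function(k) {
    rot <- c(g_last[(k + 1L):n], g_last[seq_len(k)])
    sum(g0 * rot) / sqrt(sum(g0^2) * sum(rot^2))
  }))
}

# Small deterministic neuron: n_puncta x n_timepoints trace table built
# from an explicit fluorescence matrix (rows = puncta).
traces_from_matrix <- function(f, dt = 10, status = NULL,
                               neuron = "n01") {
  n <- nrow(f); nt <- ncol(f)
  if (is.null(status)) status <- matrix("tracked", n, nt)
  data.frame(experiment = rep("fix", n * nt), neuron = rep(neuron, n * nt),
             punctum = rep(sprintf("p%04d", seq_len(n)), times = nt),
             t_min = rep((seq_len(nt) - 1) * dt, each = n),
             fluorescence = as.vector(f), status = as.vector(status),
             stringsAsFactors = FALSE)
}

# Puncta x time fluorescence matrix for one neuron of a trace table.
trace_matrix_of <- function(traces, nrn) {
  d <- traces[traces$neuron == nrn, ]
  t(sapply(split(d, d$punctum),
           function(x) x$fluorescence[order(x$t_min)]))
}

# Noise-free generator configuration (setpoint dynamics only);
# explicit arguments override the silenced defaults.
quiet_params <- function(...) {
  defaults <- list(fluctuation_sd = 0, reconfiguration_sd = 0,
                   bleach_rate = 0, loss_prob = 0, measurement_noise_sd = 0)
  args <- list(...)
  do.call(sim_params, c(args, defaults[setdiff(names(defaults),
                                               names(args))]))
}
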