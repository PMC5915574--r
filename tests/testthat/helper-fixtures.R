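# Shared fixtures: everything is generated in code at test time.

# Random centered data matrix of the kind scale_center produces.
random_scaled <- function(I, T, sd = 1) {
  Y <- matrix(rnorm(I * T, sd = sd), I, T)
  Y - rowMeans(Y)
}

# A minimal hand-built dse_series with prescribed whole-scope values, for
# testing formula-level operations without a backing matrix.
fake_dse <- function(D, A_avg, T = length(D) + 1L, I = 100L) {
  structure(list(
    whole = list(A = rep(A_avg, T), D = D, S = rep(A_avg, T - 1L) - D,
                 E = numeric(T)),
    global = NULL, nonglobal = NULL,
    averages = list(whole = list(A = A_avg, D = mean(D), S = NA, E = NA)),
    abscissa = list(A = seq_len(T), D = seq_len(T - 1L) + 0.5,
                    S = seq_len(T - 1L) + 0.5, E = seq_len(T)),
    I = I, T = T), class = "dse_series")
}

# Brute-force oracle for the DSE series: direct per-element loops, kept
# deliberately independent of the vectorized implementation.
oracle_dse <- function(Y) {
  I <- nrow(Y); T <- ncol(Y)
  A <- sapply(seq_len(T), function(t) sum(Y[, t]^2) / I)
  D <- sapply(seq_len(T - 1), function(t) sum(((Y[, t + 1] - Y[, t]) / 2)^2) / I)
  S <- sapply(seq_len(T - 1), function(t) sum(((Y[, t + 1] + Y[, t]) / 2)^2) / I)
  E <- numeric(T); E[c(1, T)] <- A[c(1, T)] / 2
  list(A = A, D = D, S = S, E = E,
       avg = c(A = sum(A), D = sum(D), S = sum(S), E = sum(E)) / T)
}

python_bin <- function() Sys.which("python")
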