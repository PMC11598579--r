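# Independent brute-force oracles and scoring helpers used across tests.
# These deliberately use naive double loops so they share no code with the
# package implementations they check.

chebyshev_match <- function(x, i, j, m, r) {
  max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r
}

apen_bruteforce <- function(x, m, r) {
  N <- length(x)
  phi <- function(mm) {
    n_templates <- N - mm + 1
    logs <- numeric(n_templates)
    for (i in seq_len(n_templates)) {
      count <- 0
      for (j in seq_len(n_templates))
        if (chebyshev_match(x, i, j, mm, r)) count <- count + 1
      logs[i] <- log(count / n_templates)
    }
    mean(logs)
  }
  phi(m) - phi(m + 1)
}

saen_bruteforce <- function(x, m, r) {
  N <- length(x)
  n_templates <- N - m   # templates admitting an (m+1)-extension
  A <- 0; B <- 0
  for (i in seq_len(n_templates)) {
    for (j in seq_len(n_templates)) {
      if (i == j) next
      if (chebyshev_match(x, i, j, m, r)) B <- B + 1
      if (chebyshev_match(x, i, j, m + 1, r)) A <- A + 1
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# Greedy one-to-one matching of detected to true event times.
score_events <- function(detected, truth, tol = 0.03) {
  used <- rep(FALSE, length(detected))
  hits <- 0
  for (tr in truth) {
    d <- abs(detected - tr)
    d[used] <- Inf
    if (length(d) && min(d) <= tol) {
      used[which.min(d)] <- TRUE
      hits <- hits + 1
    }
  }
  list(recall = hits / length(truth),
       precision = if (length(detected)) hits / length(detected) else 0,
       hits = hits)
}

# Matched-pair ISI error (seconds) between detected and true contacts.
isi_abs_error <- function(detected, truth) {
  paired <- vapply(truth, function(tr) detected[which.min(abs(detected - tr))],
                   numeric(1))
  mean(abs(diff(paired) - diff(truth)))
}

# Lag-1 autocorrelation about a known mean (avoids the centering bias of
# the standard sample ACF for long-range-dependent series).
lag1_autocorr <- function(x, mu) {
  xc <- x - mu
  sum(xc[-1] * xc[-length(xc)]) / sum(xc^2)
}

# Heel-contact series constructed directly from times (for segmentation
# tests that do not need a signal).
contacts_from_times <- function(times, fs = 100) {
  gaitcx:::new_heel_contacts(round(times * fs) + 1L, fs = fs, t0 = 0,
                             stream = "raw")
}

# Hand-built wavelet trace wrapper.
trace_from_values <- function(values, fs = 100) {
  structure(list(c = values, scale = 12, fs = fs, t0 = 0),
            class = "cwt_trace")
}

signal_from_values <- function(values, fs = 100, stream = "filtered") {
  gaitcx:::new_uniform_signal(values, fs = fs, t0 = 0, stream = stream)
}
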