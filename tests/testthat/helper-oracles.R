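# Independent oracles and small signal builders used across the suite.

# Maximum bipartite matching by augmenting paths (Kuhn's algorithm) under
# the |det - ann| <= tol constraint. Exact; used as the matcher oracle on
# small instances.
oracle_max_matching <- function(ann, det, tol) {
  n_a <- length(ann)
  n_d <- length(det)
  match_d <- integer(n_d) # detection -> annotation (0 = free)
  augment <- function(i, seen) {
    for (j in seq_len(n_d)) {
      if (!seen[[j]] && abs(det[[j]] - ann[[i]]) <= tol) {
        seen[[j]] <- TRUE
        if (match_d[[j]] == 0L) {
          match_d[[j]] <<- i
          return(list(ok = TRUE, seen = seen))
        }
        sub <- augment(match_d[[j]], seen)
        seen <- sub$seen
        if (sub$ok) {
          match_d[[j]] <<- i
          return(list(ok = TRUE, seen = seen))
        }
      }
    }
    list(ok = FALSE, seen = seen)
  }
  size <- 0L
  for (i in seq_len(n_a)) {
    if (augment(i, rep(FALSE, n_d))$ok) size <- size + 1L
  }
  size
}

# Random matcher instance: sorted annotation/detection positions.
random_match_instance <- function(max_points = 12L, span = 400L) {
  list(
    ann = sort(sample.int(span, sample.int(max_points, 1L))),
    det = sort(sample.int(span, sample.int(max_points, 1L)))
  )
}

# Train of identical Gaussian pulses with exact apex ground truth.
# Returns an ecg_record plus 0-based apex samples.
pulse_train <- function(n_pulses = 10L, period_s = 1, fs = 360,
                        width_s = 0.02, amp = 1, first_s = 1,
                        duration_s = first_s + n_pulses * period_s) {
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  centers <- first_s + (seq_len(n_pulses) - 1L) * period_s
  centers <- round(centers * fs) / fs
  x <- numeric(n)
  for (ctr in centers) {
    x <- x + amp * exp(-((t - ctr)^2) / (2 * width_s^2))
  }
  list(
    record = ecg_record(x, fs = fs, record_id = "pulse-train"),
    truth_sample = as.integer(round(centers * fs))
  )
}

# One shared benchmark fixture + full sweep per test run (built lazily;
# reused by the harness and acceptance tests).
.qrsbench_cache <- new.env(parent = emptyenv())

get_fixture <- function() {
  if (is.null(.qrsbench_cache$fixture)) {
    dir <- file.path(tempdir(), "qrsbench-fixture")
    .qrsbench_cache$fixture <- make_benchmark_fixture(dir, seed = 20L)
    .qrsbench_cache$fixture_dir <- dir
  }
  .qrsbench_cache$fixture
}

get_sweep <- function() {
  if (is.null(.qrsbench_cache$sweep)) {
    fx <- get_fixture()
    .qrsbench_cache$sweep <- run_sweep(
      fx$records, fx$truths,
      noise = fx$noise,
      algorithms = 1:4, snr_targets = c(15, 7, 3),
      mode = "power-consistent"
    )
  }
  .qrsbench_cache$sweep
}
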