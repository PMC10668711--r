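# Independent oracles used by the tests. These deliberately re-derive
# results by brute force, separate from the package implementations.

# Maximum-cardinality tolerance matching by exhaustive recursion: how many
# spot/reference pairs can be formed one-to-one with |spot - ref interval|
# within tol? Feasible for <= ~8 events per stream.
oracle_max_matching <- function(spot_t, ref_start, ref_end = ref_start,
                                tol = 1) {
  nr <- length(ref_start)
  ok <- lapply(seq_len(nr), function(j) {
    which(spot_t >= ref_start[j] - tol & spot_t <= ref_end[j] + tol)
  })
  best <- function(j, used) {
    if (j > nr) return(0L)
    res <- best(j + 1L, used)               # leave ref j unmatched
    for (s in setdiff(ok[[j]], used))
      res <- max(res, 1L + best(j + 1L, c(used, s)))
    res
  }
  best(1L, integer())
}

# Brute-force time-domain delay-and-sum at arbitrary points (nearest-sample
# shifts), written independently of the compiled path.
oracle_das_values <- function(x, fs, mic_pos, px, py, start, win,
                              c_sound = 343) {
  M <- nrow(mic_pos)
  vapply(seq_along(px), function(i) {
    acc <- numeric(win)
    for (m in seq_len(M)) {
      d <- sqrt((px[i] - mic_pos[m, 1])^2 + (py[i] - mic_pos[m, 2])^2 +
                  mic_pos[m, 3]^2)
      k <- round(d / c_sound * fs)
      acc <- acc + x[start + k + seq_len(win), m]
    }
    max(abs(acc)) / M
  }, numeric(1))
}

# Single synthetic burst event row in the shape generate_sound_events()
# produces.
burst_event <- function(t = 0.1, duration_s = 0.2, x = 1.0, y = 0.5,
                        cf = 40500, bw = 2000, amp = 0.05,
                        label = "sow_vocal", id = 1L) {
  data.frame(t = t, duration_s = duration_s, x_m = x, y_m = y,
             center_freq = cf, bandwidth = bw, amplitude = amp,
             audible = TRUE, label = label, id = id,
             stringsAsFactors = FALSE)
}
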