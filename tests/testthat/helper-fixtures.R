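# Shared fixtures: all built in code, nothing stored on disk.

# a small constant-background volume with optional inserts
tiny_volume <- function(dims = c(8, 8, 8), hu = -90, spacing = c(1, 1, 1)) {
  ct_volume(array(hu, dim = dims), spacing = spacing, subject_id = "tiny")
}

# thin-z phantom: full in-plane geometry, 40 axial slices (fast)
thin_phantom_spec <- function(...) {
  phantom_spec(shape = c(40L, 128L, 128L), ...)
}

# eight synthetic line profiles with a known per-line limit structure:
# pure lines constant at `pure_hu`, mixed lines a 50/50 two-spike mixture
constant_profiles <- function(pure_hu = -80, at_hu = -90, lt_hu = 55) {
  lapply(LINE_LABELS <- c("a", "b", "c", "d", "e", "f", "g", "h"),
         function(lb) {
    if (lb %in% c("a", "b", "e", "g")) {
      line_profile(rep(pure_hu, 50), "pure_at", lb)
    } else {
      line_profile(c(rep(at_hu, 25), rep(lt_hu, 25)), "mixed", lb)
    }
  })
}

# brute-force 3x3x3 median with reflected borders (independent oracle)
median3_oracle <- function(a) {
  d <- dim(a)
  refl <- function(i, n) ifelse(i < 1, 2 - i, ifelse(i > n, 2 * n - i, i))
  out <- array(NA_real_, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    nb <- as.vector(a[refl(i + (-1:1), d[1]),
                      refl(j + (-1:1), d[2]),
                      refl(k + (-1:1), d[3])])
    out[i, j, k] <- median(nb)
  }
  out
}

# exact two-sided signed-rank p-value by enumeration of all sign patterns
wilcoxon_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  ws <- apply(signs, 1, function(s) sum(r[unlist(s)]))
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}
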