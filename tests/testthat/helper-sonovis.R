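# shared test helpers: component matching and small brute-force oracles

# best one-to-one matching of estimated to true components by |Pearson r|,
# exhaustive over permutations (n <= 8)
match_components <- function(H_est, H_true) {
  n <- nrow(H_true)
  stopifnot(nrow(H_est) == n, n <= 8L)
  R <- abs(stats::cor(t(H_est), t(H_true)))
  perms <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  perms <- perms[apply(perms, 1L, function(p) length(unique(p)) == n), ,
                 drop = FALSE]
  scores <- apply(perms, 1L, function(p) sum(R[cbind(seq_len(n), p)]))
  p <- perms[which.max(scores), ]
  list(perm = p, r = R[cbind(seq_len(n), p)])
}

# exhaustive run-scan event oracle, independent of the rle-based detector
oracle_events <- function(h, threshold, fps, min_len) {
  out <- NULL
  i <- 1L
  n <- length(h)
  while (i <= n) {
    if (h[i] > threshold) {
      j <- i
      while (j < n && h[j + 1L] > threshold) j <- j + 1L
      if (j - i + 1L >= min_len)
        out <- rbind(out, data.frame(onset_s = (i - 1L) / fps,
                                     offset_s = j / fps,
                                     strength_raw = max(h[i:j])))
      i <- j + 1L
    } else i <- i + 1L
  }
  if (is.null(out))
    data.frame(onset_s = numeric(0), offset_s = numeric(0),
               strength_raw = numeric(0))
  else out
}

# naive triple-loop color remix: image(s,c) = sum_n W[s,n]*max(h[n],0)*C[n,c]
oracle_colorize <- function(W, h, C) {
  out <- matrix(0, nrow(W), 3L)
  for (s in seq_len(nrow(W)))
    for (ch in 1:3)
      for (n in seq_len(ncol(W)))
        out[s, ch] <- out[s, ch] + W[s, n] * max(h[n], 0) * C[n, ch]
  out
}
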