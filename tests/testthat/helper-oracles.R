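# brute-force Shapley oracle: average marginal contribution over all d! orders
permutation_shapley <- function(g, x, baseline) {
  d <- length(x)
  perms <- all_permutations(d)
  phi <- numeric(d)
  for (p in seq_len(nrow(perms))) {
    cur <- baseline
    v_prev <- g(cur)
    for (i in perms[p, ]) {
      cur[i] <- x[i]
      v_new <- g(cur)
      phi[i] <- phi[i] + (v_new - v_prev)
      v_prev <- v_new
    }
  }
  phi / nrow(perms)
}

# all permutations of 1..n, recursively
all_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}
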