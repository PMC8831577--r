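# Shared small fixtures. A compact phantom geometry keeps per-test
# generation around a tenth of a second.

small_spec <- function(r_max_mm = 8, ...) {
  phantom_spec(shape = c(40L, 40L), n_heart = 8L, pad = 2L,
               r_max_mm = r_max_mm, ...)
}

# brute-force median filter with replicate padding: the independent
# oracle for the Rcpp implementation
brute_median3d <- function(vol, k) {
  d <- dim(vol)
  h <- (k - 1L) %/% 2L
  out <- vol
  for (z in seq_len(d[3])) for (c in seq_len(d[2])) for (r in seq_len(d[1])) {
    rs <- pmin(pmax(r + (-h[1]):h[1], 1L), d[1])
    cs <- pmin(pmax(c + (-h[2]):h[2], 1L), d[2])
    zs <- pmin(pmax(z + (-h[3]):h[3], 1L), d[3])
    out[r, c, z] <- stats::median(vol[rs, cs, zs])
  }
  out
}

random_mask_pair <- function(nr = 8, nc = 8, p = 0.3) {
  list(a = matrix(stats::rbinom(nr * nc, 1, p), nr, nc),
       b = matrix(stats::rbinom(nr * nc, 1, p), nr, nc))
}
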