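# Independent brute-force oracles for overlap and surface-distance metrics:
# plain set arithmetic on voxel index sets and all-pairs nearest distances
# over explicitly enumerated 6-connectivity boundary voxels.

brute_dsc <- function(a, b) {
  ia <- which(a == 1); ib <- which(b == 1)
  if (length(ia) + length(ib) == 0) return(1)
  2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
}

brute_surface <- function(m) {
  d <- dim(m)
  out <- matrix(0, 0, 3)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (m[i, j, k] == 1) {
      nb <- c(if (i > 1) m[i - 1, j, k] else 0,
              if (i < d[1]) m[i + 1, j, k] else 0,
              if (j > 1) m[i, j - 1, k] else 0,
              if (j < d[2]) m[i, j + 1, k] else 0,
              if (k > 1) m[i, j, k - 1] else 0,
              if (k < d[3]) m[i, j, k + 1] else 0)
      if (any(nb == 0)) out <- rbind(out, c(i, j, k))
    }
  }
  out
}

brute_asd <- function(a, b, sp) {
  sa <- sweep(brute_surface(a), 2, sp, `*`)
  sb <- sweep(brute_surface(b), 2, sp, `*`)
  d2 <- outer(rowSums(sa^2), rowSums(sb^2), `+`) - 2 * sa %*% t(sb)
  d2[d2 < 0] <- 0
  (mean(sqrt(apply(d2, 1, min))) + mean(sqrt(apply(d2, 2, min)))) / 2
}
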