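# Independent brute-force oracles used to cross-check the package's
# statistics. Each is a deliberately naive reimplementation kept separate
# from the package code paths.

oracle_d10 <- function(y, n = 10) {
  y <- y[is.finite(y)]
  if (length(y) == 0) return(0)
  s <- sort(y)                      # ascending, take the tail
  k <- min(n, length(s))
  sum(rev(s)[1:k]) / k
}

oracle_robust_z <- function(d, med, mad) (d - med) / mad

oracle_classify <- function(z) {
  if (z > -3) "none"
  else if (z > -9) "mild"
  else if (z > -15) "moderate"
  else "high"
}

oracle_z_prime <- function(a, b) {
  1 - 3 * (sd(a) + sd(b)) / abs(mean(a) - mean(b))
}

oracle_cv <- function(x) 100 * sd(x) / mean(x)

# rank-then-Pearson with average ranks for ties
oracle_spearman <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

oracle_concordance <- function(s1, s2) {
  d <- abs(s1 - s2)
  100 * c(same = mean(d == 0), adjacent = mean(d == 1), discordant = mean(d >= 2))
}

# dictionary count of canonical pathway sets
oracle_combination_count <- function(pathway_strings) {
  keys <- vapply(pathway_strings, function(p) {
    paste(sort(unique(trimws(strsplit(p, ";")[[1]]))), collapse = "|")
  }, character(1))
  counts <- new.env()
  for (k in keys) assign(k, (get0(k, counts) %||% 0L) + 1L, counts)
  out <- sort(vapply(ls(counts), get, integer(1), envir = counts),
              decreasing = TRUE)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# naive grayscale opening (erosion then dilation) with a disc, O(n * r^2)
oracle_opening <- function(img, radius) {
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  nr <- nrow(img); nc <- ncol(img)
  sweep_one <- function(src, fun) {
    out <- matrix(0, nr, nc)
    for (r in 1:nr) for (c in 1:nc) {
      rr <- r + offs$dr; cc <- c + offs$dc
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      out[r, c] <- fun(src[cbind(rr[ok], cc[ok])])
    }
    out
  }
  er <- sweep_one(img, min)
  sweep_one(er, max)
}

# verdict oracle: direct transcription of the duplicate-agreement rules
oracle_verdict <- function(qc1, int1, eff1, qc2, int2, eff2,
                           min_qc = 3, min_int = 3) {
  qp1 <- qc1 >= min_qc; qp2 <- qc2 >= min_qc
  ip1 <- int1 >= min_int; ip2 <- int2 >= min_int
  if (!qp1 && !qp2) return("qc_excluded")
  if ((qp1 && !ip1) || (qp2 && !ip2)) return("toxic_excluded")
  if (qp1 && qp2 && ip1 && ip2 && eff1 && eff2) return("hit")
  "non_hit"
}
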