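# Independent oracle for the studentized range distribution: direct
# numerical integration of P(Q <= q | k means, nu df), never calling
# ptukey. S = sqrt(chi^2_nu / nu); P(range of k std normals <= w) =
# k * Int phi(u) [Phi(u + w) - Phi(u)]^(k-1) du.

range_cdf <- function(w, k) {
  if (w <= 0) return(0)
  f <- function(u) k * stats::dnorm(u) *
    (stats::pnorm(u + w) - stats::pnorm(u))^(k - 1)
  stats::integrate(f, -Inf, Inf, rel.tol = 1e-9)$value
}

tukey_cdf_oracle <- function(q, k, nu) {
  if (q <= 0) return(0)
  fs <- function(s) {
    # density of sqrt(chi^2_nu / nu)
    exp((nu / 2) * log(nu / 2) - lgamma(nu / 2) + (nu - 1) * log(s) -
          nu * s^2 / 2) * 2
  }
  g <- function(s) vapply(s, function(si) fs(si) * range_cdf(q * si, k), 0)
  stats::integrate(g, 0, Inf, rel.tol = 1e-7)$value
}

.q_crit_cache <- new.env(parent = emptyenv())

q_crit_oracle <- function(alpha, k, nu) {
  key <- paste(alpha, k, nu, sep = "|")
  hit <- .q_crit_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- stats::uniroot(function(q) tukey_cdf_oracle(q, k, nu) - (1 - alpha),
                        c(0.1, 60), tol = 1e-7)$root
  .q_crit_cache[[key]] <- val
  val
}

# brute-force SNK accept/reject pattern built on the oracle critical values
snk_oracle_pattern <- function(groups, alpha = 0.05) {
  m <- vapply(groups, mean, 0)
  n <- vapply(groups, length, 0L)
  o <- order(m); m <- m[o]; n <- n[o]
  k <- length(m)
  df <- sum(n) - k
  msw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0)) / df
  crit <- vapply(2:k, function(r) q_crit_oracle(alpha, r, df), 0)
  sig <- matrix(FALSE, k, k)
  # widest ranges first; enclosed pairs blocked by non-significant ranges
  for (r in seq(k, 2L)) {
    for (i in seq_len(k - r + 1L)) {
      j <- i + r - 1L
      blocked <- FALSE
      if (r < k) {
        encl <- c(if (i > 1L) !sig[i - 1L, j], if (j < k) !sig[i, j + 1L])
        blocked <- any(encl)
      }
      if (blocked) { sig[i, j] <- FALSE; next }
      nh <- 2 / (1 / n[i] + 1 / n[j])
      q <- (m[j] - m[i]) / sqrt(msw / nh)
      sig[i, j] <- q > crit[r - 1L]
    }
  }
  sig[upper.tri(sig)]
}

# package SNK result reshaped into the same upper-triangle logical vector
snk_pattern_from_result <- function(res, k) {
  sig <- matrix(FALSE, k, k)
  idx <- 1L
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    sig[i, j] <- res$pairwise$significant[idx]; idx <- idx + 1L
  }
  sig[upper.tri(sig)]
}
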