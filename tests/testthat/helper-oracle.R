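# Brute-force schedule oracle: enumerates the sampled tilt angles of a
# sinusoid observed at t_n = n / PRFe until the sequence repeats, partitions
# the steady-state samples into monotonic half-sweeps, and decides the volume
# rate from coverage alone (independent of the closed-form classification).
oracle_rate <- function(r, phi, fm = 250) {
  p <- NULL
  for (k in seq_len(20000)) {
    if (abs(k / r - round(k / r)) < 1e-9 * max(1, k / r)) {
      p <- k
      break
    }
  }
  stopifnot(!is.null(p))
  m0 <- round(p / r)
  n <- seq_len(3L * p)
  psi <- 2 * pi * n / r + phi
  pos <- round(sin(psi), 9)
  u <- (psi - pi / 2) / pi
  at_peak <- abs(u - round(u)) < 1e-8
  k_id <- ifelse(at_peak, round(u), floor(u))
  ids <- c(k_id, k_id[at_peak] - 1L)
  vals <- c(pos, pos[at_peak])
  interior <- ids > min(ids) & ids < max(ids)
  sweep_sets <- lapply(split(vals[interior], ids[interior]),
                       function(s) sort(unique(s)))
  all_pos <- sort(unique(pos[n > p & n <= 2 * p]))
  covered <- length(sweep_sets) > 0 &&
    all(vapply(sweep_sets, identical, logical(1), y = all_pos))
  if (m0 == 1 && covered) {
    list(fv = 2 * fm, np = length(all_pos))
  } else {
    list(fv = fm / m0, np = p)
  }
}

# Random rational PRFe/Fm ratios with bounded denominator.
random_ratios <- function(n, seed, den_max = 8, r_min = 2.2, r_max = 100) {
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    den <- sample.int(den_max, 1)
    num <- sample(seq(ceiling(r_min * den), floor(r_max * den)), 1)
    g <- gcd2(num, den)
    out[[i]] <- c(num = num / g, den = den / g)
  }
  out
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
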