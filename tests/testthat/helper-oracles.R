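# Independent brute-force oracle for the Minkowski exponent: plain-formula
# bisection on C - (B^m + W^m)^(1/m) over a sign-change bracket located by a
# coarse grid. Deliberately shares no code with the package solver.
oracle_minkowski_exponent <- function(best, worst, combined,
                                      lo = 1e-3, hi = 500) {
  b <- max(best, worst)
  w <- min(best, worst)
  if (combined <= b) return(NA_real_)
  f <- function(m) combined - (b^m + w^m)^(1 / m)
  grid <- exp(seq(log(lo), log(hi), length.out = 400))
  fv <- vapply(grid, f, numeric(1))
  i <- which(fv[-1] * fv[-length(fv)] <= 0)[1]
  if (is.na(i)) return(NA_real_)
  a <- grid[i]; z <- grid[i + 1]
  for (k in 1:200) {
    mid <- (a + z) / 2
    if (f(a) * f(mid) <= 0) z <- mid else a <- mid
  }
  (a + z) / 2
}

# Tiny deterministic neuron table with known classes, for rule tests.
rule_table_neurons <- function() {
  tibble::tibble(
    id = sprintf("r%02d", 1:6),
    rate_dom = c(40, 40, 40, 40, 40, 40),
    rate_nondom = c(1, 25, 25, 25, 25, 0.5),
    rate_binoc = c(60, 55, 33, 40, 20, 41),
    var_dom = rep(40, 6),
    var_nondom = c(1, 25, 25, 25, 25, 0.5),
    responsive_nondom = c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE)
  )
}

# Small CSF table: one subject, configurable per-frequency enhancement.
one_subject_csf <- function(enhancing, subject = "s1", study = "st") {
  n <- length(enhancing)
  sf <- c(1, 1.5, 3, 6, 12, 18.5)[seq_len(n)]
  best <- seq(100, 40, length.out = n)
  worst <- best * 0.8
  binoc <- ifelse(enhancing, best * 1.2, best * 0.95)
  tibble::tibble(study = study, subject = subject, sf = sf,
                 sens_left = best, sens_right = worst, sens_binoc = binoc)
}
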