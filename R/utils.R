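# Shared helpers: circular arithmetic in clock hours, seeded substreams.

hours_to_rad <- function(h, cycle_h = 24) 2 * pi * h / cycle_h

rad_to_hours <- function(theta, cycle_h = 24) {
  (theta * cycle_h / (2 * pi)) %% cycle_h
}

# Resultant vector of a set of phases (hours); workhorse for circstats and
# for phase checks in the simulator tests.
circ_resultant <- function(phases_h, weights = NULL, cycle_h = 24) {
  theta <- hours_to_rad(phases_h, cycle_h)
  if (is.null(weights)) weights <- rep(1, length(theta))
  w <- weights / sum(weights)
  C <- sum(w * cos(theta))
  S <- sum(w * sin(theta))
  list(C = C, S = S, R = sqrt(C^2 + S^2))
}

# Deterministic per-gene substream seed: adding genes to a simulation must
# not perturb the draws of earlier genes, so every gene gets its own seed
# derived from the master seed, its index and a stage tag.
substream_seed <- function(master_seed, index, stage = 0L) {
  m <- 2147483647
  s <- (as.double(master_seed) %% m) * 48271 %% m
  s <- (s + as.double(index) * 69621 + as.double(stage) * 16807) %% m
  as.integer(s)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# von Mises sampler (Best & Fisher 1979 rejection scheme), in clock hours.
# kappa = 0 falls back to the circular uniform.
rvonmises_h <- function(n, mu_h, kappa, cycle_h = 24) {
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) return(runif(n, 0, cycle_h))
  mu <- hours_to_rad(mu_h, cycle_h)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      theta <- mu + sign(u[3] - 0.5) * acos(f)
      out[i] <- rad_to_hours(theta, cycle_h)
      i <- i + 1L
    }
  }
  out
}

stop_if_not_prob <- function(p, what = "p") {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop(sprintf("%s values must lie in (0, 1]", what), call. = FALSE)
  }
  invisible(p)
}
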