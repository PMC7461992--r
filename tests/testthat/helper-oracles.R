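# Shared test oracles, kept independent of the package's accumulation path.

# Brute-force fine-step integrator for profile accumulation:
# dK/dt = 2*sqrt(K)*po2^(c/2) on oxygen, dK/dt = -0.079*K on air.
# The very first oxygen step from K = 0 is seeded with its exact value
# (dt*po2^(c/2))^2, after which plain Euler proceeds.
bf_integrate <- function(segments, c, dt = 0.001, rate = 0.079) {
  K <- 0
  for (j in seq_len(nrow(segments))) {
    s <- segments[j, ]
    n <- round(s$duration / dt)
    if (s$kind == "oxygen") {
      a <- exp((c / 2) * log(s$po2))
      i <- 1L
      if (K == 0 && n > 0L) {
        K <- (a * dt)^2
        i <- 2L
      }
      while (i <= n) {
        K <- K + 2 * sqrt(K) * a * dt
        i <- i + 1L
      }
    } else {
      K <- K * (1 - rate * dt)^n
    }
  }
  K
}

# Random at-rest profile within the data envelope: oxygen at 2.2-3.7 bar for
# 3-25 min, optional interleaved 2-10 min air breaks.
random_profile <- function(params = "DRY_REST") {
  n_ox <- sample(2:4, 1)
  segs <- list()
  for (i in seq_len(n_ox)) {
    segs <- c(segs, list(segment(runif(1, 2.2, 3.7), runif(1, 3, 25),
                                 "oxygen")))
    if (i < n_ox && runif(1) < 0.8) {
      segs <- c(segs, list(segment(runif(1, 0.2, 0.7), runif(1, 2, 10),
                                   "air")))
    }
  }
  exposure_profile(segs, params)
}

# Tiny hand-checkable censored dataset.
hand_dataset <- function() {
  exposure_dataset(po2 = c(2.8, 2.8, 3.2, 3.2, 2.5),
                   time = c(30, 45, 20, 60, 90),
                   event = c(TRUE, FALSE, TRUE, FALSE, TRUE))
}
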