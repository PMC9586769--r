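# Independent oracles used across the suite.  These deliberately take the
# brute-force route (explicit loops, normal equations, cascade filters) so
# they share no code with the package implementation.

truth <- reference_params()

# --- excitation kernel, written term by term from its printed definition ---
oracle_kernel <- function(lag, dose, th, normalized = FALSE) {
  th <- unclass(as_hawkes_params(th))
  sig <- 1 / (th["a1"] + th["b1"] * exp(-th["kappa1"] * (th["m1"] + dose) * th["a2"]))
  norm <- if (normalized) th["b2"]^th["kappa2"] / gamma(th["kappa2"])
          else 1 / (th["b2"]^th["kappa2"] * gamma(th["kappa2"]))
  unname(ifelse(lag > 0,
                sig * lag^(th["kappa2"] - 1) * exp(-th["b2"] * lag) * norm,
                0))
}

oracle_intensity <- function(t, sched, th, normalized = FALSE) {
  th2 <- unclass(as_hawkes_params(th))
  sapply(t, function(ti) {
    mu <- th2["a0"] + th2["b0"] * sin(th2["alpha0"] * ti + th2["beta0"])
    tot <- 0
    for (i in seq_len(nrow(sched)))
      if (sched$time[i] < ti)
        tot <- tot + oracle_kernel(ti - sched$time[i], sched$dose[i], th,
                                   normalized)
    unname(mu + tot)
  })
}

# --- MODWT by explicit cascade-filter circular convolution ----------------
# Level-j equivalent filters are built by convolving upsampled Haar MODWT
# filters; each coefficient series is then one circular convolution with x.
oracle_modwt <- function(x, J) {
  n <- length(x)
  g <- c(0.5, 0.5)
  h <- c(0.5, -0.5)
  upsample <- function(f, j) {
    if (j == 1) return(f)
    out <- numeric((length(f) - 1) * 2^(j - 1) + 1)
    out[seq(1, length(out), by = 2^(j - 1))] <- f
    out
  }
  conv <- function(a, b) {       # full linear convolution
    out <- numeric(length(a) + length(b) - 1)
    for (i in seq_along(a)) for (k in seq_along(b))
      out[i + k - 1] <- out[i + k - 1] + a[i] * b[k]
    out
  }
  circ_filter <- function(f) {   # y[t] = sum_l f[l+1] x[(t - l) mod n]
    sapply(seq_len(n), function(t) {
      s <- 0
      for (l in seq_along(f) - 1)
        s <- s + f[l + 1] * x[((t - 1 - l) %% n) + 1]
      s
    })
  }
  detail <- scale <- vector("list", J)
  gj <- 1
  for (j in seq_len(J)) {
    hj_eq <- conv(gj, upsample(h, j))     # cascade: j-1 scalings then wavelet
    gj <- conv(gj, upsample(g, j))
    detail[[j]] <- circ_filter(hj_eq)
    scale[[j]] <- circ_filter(gj)
  }
  list(detail = detail, scale = scale)
}

# --- Granger F by two explicit normal-equation OLS fits -------------------
oracle_granger_f <- function(x, d, m, intercept = TRUE) {
  n <- length(x)
  rows <- (m + 1):n
  lag <- function(v, i) v[rows - i]
  Xur <- cbind(if (intercept) 1, sapply(1:m, function(i) lag(d, i)),
               sapply(1:m, function(i) lag(x, i)))
  Xr <- cbind(if (intercept) 1, sapply(1:m, function(i) lag(x, i)))
  y <- x[rows]
  ssr <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% beta)^2)
  }
  ssr_r <- ssr(Xr); ssr_ur <- ssr(Xur)
  k <- ncol(Xur)
  f <- ((ssr_r - ssr_ur) / m) / (ssr_ur / (length(y) - k))
  list(f = f, p = pf(f, m, length(y) - k, lower.tail = FALSE),
       ssr_r = ssr_r, ssr_ur = ssr_ur)
}

# random parameter draw inside the canonical box
draw_params <- function() {
  b <- reference_bounds()
  v <- b[, 1] + runif(11) * (b[, 2] - b[, 1])
  as_hawkes_params(v)
}

make_sim <- function(seed, n_steps = 800, noise_variance = 0,
                     normalized = TRUE, n_events = 60, mean_gap = 13,
                     dose = 25, mode = "level") {
  sched <- generate_event_schedule(n_events, mean_gap, dose, seed = seed,
                                   horizon = n_steps - 1)
  sim <- simulate_series(truth, sched, n_steps = n_steps,
                         noise_variance = noise_variance, seed = seed,
                         mode = mode, normalized = normalized)
  list(sim = sim, sched = sched)
}
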