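# Independent oracle implementations used to cross-check the package.
# These deliberately take the dumbest correct route (brute force,
# enumeration, closed form) and share no code with the implementation.

# continuous LoG formula evaluated at pixel centres, before any zero-sum shift
oracle_log_formula <- function(ssf, spacing) {
  sigma <- ssf / sqrt(2)
  r_px <- ceiling(4 * sigma / spacing)
  off <- seq(-r_px, r_px) * spacing
  r2 <- outer(off^2, off^2, "+")
  -1 / (pi * sigma^4) * (1 - r2 / (2 * sigma^2)) * exp(-r2 / (2 * sigma^2))
}

# brute-force spatial convolution with edge-including reflection padding:
# accumulate kernel-weighted shifted copies of the padded image
oracle_spatial_filter <- function(img, kernel) {
  r <- (nrow(kernel) - 1L) / 2L
  idx <- function(n) c(r:1, 1:n, n:(n - r + 1))
  pad <- img[idx(nrow(img)), idx(ncol(img)), drop = FALSE]
  out <- matrix(0, nrow(img), ncol(img))
  for (di in -r:r) {
    for (dj in -r:r) {
      rows <- (1:nrow(img)) + r + di
      cols <- (1:ncol(img)) + r + dj
      # convolution: kernel entry at offset (di, dj) multiplies img(x - d);
      # the kernel is symmetric so correlation gives the same result
      out <- out + kernel[di + r + 1L, dj + r + 1L] * pad[rows, cols]
    }
  }
  out
}

# pairwise AUC: P(death value "beats" survivor value), ties half credit
oracle_pairwise_auc <- function(values, labels, direction = "lower") {
  d <- values[labels == 1]
  s <- values[labels == 0]
  cmp <- outer(d, s, function(a, b) {
    win <- if (direction == "lower") a < b else a > b
    win + 0.5 * (a == b)
  })
  mean(cmp)
}

# exhaustive Youden scan over observed cutoffs, rule value < c => death
oracle_cutoff_scan <- function(values, labels) {
  cands <- sort(unique(values))
  j <- vapply(cands, function(c0) {
    sens <- mean(values[labels == 1] < c0)
    spec <- mean(values[labels == 0] >= c0)
    sens + spec - 1
  }, numeric(1))
  best <- max(which(j >= max(j) - 1e-12))
  list(cutoff = cands[best], j = j[best])
}

# product-limit estimator computed step by step
oracle_km <- function(time, event) {
  times <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(times))
  for (i in seq_along(times)) {
    at_risk <- sum(time >= times[i])
    d <- sum(time == times[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out[i] <- s
  }
  tibble::tibble(time = times, surv = out)
}

# log-rank chi-square tabulated by hand over distinct event times
oracle_logrank <- function(time, event, group) {
  g <- as.integer(factor(group)) # 1/2
  times <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (tt in times) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & g == 1)
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Cox partial log-likelihood for a single binary covariate, tie-free data,
# vectorized over a beta grid
oracle_cox_grid <- function(time, event, x, betas = seq(-5, 5, by = 1e-4)) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  ev <- which(event == 1)
  s1 <- sum(x[ev])
  a <- vapply(ev, function(i) sum(time >= time[i] & x == 0), numeric(1))
  b <- vapply(ev, function(i) sum(time >= time[i] & x == 1), numeric(1))
  ll <- vapply(betas, function(beta) {
    beta * s1 - sum(log(a + b * exp(beta)))
  }, numeric(1))
  betas[which.max(ll)]
}

# ICC via explicit two-way ANOVA sums of squares
oracle_icc_anova <- function(m, form = "agreement") {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ssr <- k * sum((rowMeans(m) - grand)^2)
  ssc <- n * sum((colMeans(m) - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  if (form == "agreement") {
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
}

# small tie-free survival data set builder
make_survdata <- function(n, seed, p_group = 0.5, beta = 0, censor = 0.3) {
  withr::with_seed(seed, {
    x <- stats::rbinom(n, 1, p_group)
    t <- stats::rexp(n, rate = 0.05 * exp(beta * x))
    c <- stats::rexp(n, rate = 0.05 * censor / (1 - censor + 1e-9))
    data.frame(
      time = pmin(t, c) + stats::runif(n, 0, 1e-6), # break accidental ties
      event = as.integer(t <= c),
      x = x
    )
  })
}
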