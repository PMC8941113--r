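## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wrap angles to [0, 2*pi)
#' @param theta numeric vector of angles (radians).
#' @return angles reduced modulo 2*pi into [0, 2*pi).
#' @keywords internal
wrap_angle <- function(theta) {
  out <- theta %% (2 * pi)
  out[out < 0] <- out[out < 0] + 2 * pi
  # exact 2*pi folds back to 0
  out[out >= 2 * pi] <- 0
  out
}

## Smallest angular separation, in [0, pi].
angle_sep <- function(t1, t2) {
  d <- abs(t1 - t2) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

## Circular mean of angles with optional weights; NA when resultant ~ 0.
circular_mean <- function(theta, w = NULL) {
  if (is.null(w)) w <- rep(1, length(theta))
  z <- sum(w * exp(1i * theta))
  if (Mod(z) < 1e-12) return(NA_real_)
  wrap_angle(Arg(z))
}

## von Mises sampler (Best & Fisher 1979 rejection method, batched); uses R's
## RNG so draws are reproducible under set.seed(). mu may be a vector recycled
## over the n draws.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(wrap_angle(stats::runif(n, 0, 2 * pi)))
  mu <- rep_len(mu, n)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    m <- length(need)
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(pmax(c0, 1e-300) / u2) + 1 - c0 >= 0)
    acc <- need[ok]
    out[acc] <- mu[acc] + sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
    need <- need[!ok]
  }
  wrap_angle(out)
}

stop_hc <- function(...) stop(..., call. = FALSE)

## Assert that x is a single finite number.
check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_hc(sprintf("'%s' must be a single finite number", name))
  invisible(x)
}
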