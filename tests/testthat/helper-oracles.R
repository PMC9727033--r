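# Independent oracles and fixture builders used across the suite.
# Each oracle reimplements the quantity under test by a different route
# (brute force, direct evaluation, numeric integration) and never calls the
# code path it checks.

# --- brute-force DBSCAN -----------------------------------------------------
# O(n^2) neighbourhood-expansion DBSCAN with the package's pinned
# conventions: n_min counts the point itself; seeds scanned in input order;
# breadth-first expansion; border points claimed by the first cluster that
# reaches them; 0 = noise.
bf_dbscan <- function(x, y, eps, min_pts) {
  n <- length(x)
  labels <- integer(n)
  if (n == 0) return(labels)
  d2 <- outer(x, x, `-`)^2 + outer(y, y, `-`)^2
  nbrs <- lapply(seq_len(n), function(i) which(d2[i, ] <= eps^2))
  is_core <- vapply(nbrs, length, integer(1)) >= min_pts
  seen <- logical(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (seen[i] || labels[i] != 0L) next
    seen[i] <- TRUE
    if (!is_core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- i
    qi <- 1L
    while (qi <= length(queue)) {
      j <- queue[qi]; qi <- qi + 1L
      if (!is_core[j]) next  # border point: claimed but not expanded
      for (q in nbrs[[j]]) {
        if (labels[q] != 0L) next
        labels[q] <- cl
        if (!seen[q]) {
          seen[q] <- TRUE
          queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

# membership partitions agree up to label permutation
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(a == 0L, b == 0L)) return(FALSE)
  in_cl <- a != 0L
  key_a <- match(a[in_cl], unique(a[in_cl]))
  key_b <- match(b[in_cl], unique(b[in_cl]))
  identical(key_a, key_b)
}

# --- direct GLR evaluation --------------------------------------------------
# Evaluates the spot-vs-background likelihood-ratio F statistic at one pixel
# by explicit window regression (no convolution tricks).
glr_at_pixel <- function(img, i, j, psf_sigma, window_radius) {
  w <- window_radius
  if (i - w < 1 || i + w > nrow(img) || j - w < 1 || j + w > ncol(img)) {
    return(0)
  }
  win <- img[(i - w):(i + w), (j - w):(j + w)]
  off <- seq(-w, w)
  g <- exp(-outer(off^2, off^2, `+`) / (2 * psf_sigma^2))
  yv <- as.vector(win); gv <- as.vector(g)
  m <- length(yv)
  X <- cbind(1, gv)
  beta <- qr.solve(X, yv)
  if (beta[2] <= 0) return(0)
  rss1 <- sum((yv - X %*% beta)^2)
  rss0 <- sum((yv - mean(yv))^2)
  if (rss1 <= .Machine$double.eps) rss1 <- .Machine$double.eps
  (m - 2) * (rss0 - rss1) / rss1
}

# --- integrated-Gaussian expected image (independent arithmetic) ------------
expected_spot <- function(nr, nc, x0, y0, N, b, sigma) {
  xs <- 0:(nc - 1); ys <- 0:(nr - 1)
  dx <- pnorm((xs + 1 - x0) / sigma) - pnorm((xs - x0) / sigma)
  dy <- pnorm((ys + 1 - y0) / sigma) - pnorm((ys - y0) / sigma)
  N * (dy %o% dx) + b
}

# Poisson log-likelihood of a window under the spot + background model
spot_loglik <- function(win, x0, y0, N, b, sigma) {
  mu <- expected_spot(nrow(win), ncol(win), x0, y0, N, b, sigma)
  mu <- pmax(mu, 1e-12)
  sum(win * log(mu) - mu)
}

# Dense grid search over (x0, y0), profiling (N, b) by identity-link Poisson
# GLM at each node. Coarse pass then 1e-3 px refinement around the best node.
grid_fit_oracle <- function(win, sigma, span = 1.2) {
  prof <- function(x0, y0) {
    g <- as.vector(expected_spot(nrow(win), ncol(win), x0, y0, 1, 0, sigma))
    X <- cbind(g, 1)
    fit <- suppressWarnings(
      stats::glm.fit(X, as.vector(win),
                     family = stats::poisson(link = "identity"),
                     start = c(max(sum(win) - length(win) * min(win), 1),
                               max(min(win), 1e-3))))
    cf <- pmax(fit$coefficients, c(1e-3, 1e-9))
    spot_loglik(win, x0, y0, cf[1], cf[2], sigma)
  }
  cx <- ncol(win) / 2; cy <- nrow(win) / 2
  best <- c(cx, cy); best_ll <- -Inf
  for (step in c(0.05, 0.01, 0.001)) {
    grid <- expand.grid(x = best[1] + seq(-span, span, by = step),
                        y = best[2] + seq(-span, span, by = step))
    ll <- mapply(prof, grid$x, grid$y)
    k <- which.max(ll)
    best <- c(grid$x[k], grid$y[k]); best_ll <- ll[k]
    span <- step * 2
  }
  list(x = best[1], y = best[2], loglik = best_ll)
}

# --- numeric CRLB -----------------------------------------------------------
# Fisher information of the Poisson spot model by central finite differences
# of the expected image; returns the CRLB standard deviation per axis (px).
crlb_numeric <- function(nr, nc, x0, y0, N, b, sigma, h = 1e-4) {
  mu_of <- function(th) {
    as.vector(expected_spot(nr, nc, th[1], th[2], th[3], th[4], sigma))
  }
  th <- c(x0, y0, N, b)
  mu <- pmax(mu_of(th), 1e-12)
  J <- sapply(seq_along(th), function(k) {
    hp <- th; hm <- th
    hk <- h * max(1, abs(th[k]))
    hp[k] <- hp[k] + hk; hm[k] <- hm[k] - hk
    (mu_of(hp) - mu_of(hm)) / (2 * hk)
  })
  FI <- crossprod(J, J / mu)
  V <- solve(FI)
  sqrt(c(x = V[1, 1], y = V[2, 2]))
}

# --- censored lifetime mean oracle ------------------------------------------
# E[S | S < cutoff] where S = min(L, T - B), L from the two-component
# exponential mixture and B uniform over [0, T]. Numeric integration on a
# fine grid, independent of any package code.
censored_short_mean <- function(T_s, cutoff, p_long, mean_short, mean_long,
                                n_grid = 4000) {
  b <- (seq_len(n_grid) - 0.5) / n_grid * T_s
  res <- T_s - b  # residual observation window for each birth time
  dens <- function(l) {
    (1 - p_long) * stats::dexp(l, 1 / mean_short) +
      p_long * stats::dexp(l, 1 / mean_long)
  }
  surv <- function(l) {
    (1 - p_long) * stats::pexp(l, 1 / mean_short, lower.tail = FALSE) +
      p_long * stats::pexp(l, 1 / mean_long, lower.tail = FALSE)
  }
  l <- (seq_len(n_grid) - 0.5) / n_grid * cutoff
  dl <- cutoff / n_grid
  num <- 0; den <- 0
  for (bi in seq_along(b)) {
    r <- res[bi]
    if (r >= cutoff) {
      # censoring beyond the cutoff: only L < cutoff matters
      w <- dens(l) * dl
      num <- num + sum(l * w)
      den <- den + sum(w)
    } else {
      keep <- l < r
      w <- dens(l[keep]) * dl
      num <- num + sum(l[keep] * w) + r * surv(r)
      den <- den + sum(w) + surv(r)
    }
  }
  num / den
}

# observed probability that min(L, T - B) >= cutoff under the same model
censored_long_fraction <- function(T_s, cutoff, p_long, mean_short,
                                   mean_long, n_grid = 4000) {
  b <- (seq_len(n_grid) - 0.5) / n_grid * T_s
  surv <- function(l) {
    (1 - p_long) * stats::pexp(l, 1 / mean_short, lower.tail = FALSE) +
      p_long * stats::pexp(l, 1 / mean_long, lower.tail = FALSE)
  }
  mean(ifelse(T_s - b >= cutoff, surv(cutoff), 0))
}

# --- misc fixtures ----------------------------------------------------------
# well-separated grid of spot centres inside a square image
spaced_centers <- function(n, size, margin = 12, jitter = 2, seed = 1) {
  set.seed(seed)
  side <- ceiling(sqrt(n))
  gx <- seq(margin, size - margin, length.out = side)
  gr <- expand.grid(x = gx, y = gx)[seq_len(n), ]
  as.matrix(gr) + matrix(runif(2 * n, -jitter, jitter), n, 2)
}
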