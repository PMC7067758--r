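#' Continuous one-breakpoint segmented regression
#'
#' Fits a continuous two-segment linear model
#' `y = a + b*x + c*(x - psi)_+` by least squares, estimating the break
#' location `psi` by an exhaustive profile search over all admissible
#' breakpoints at the observed x values (computed in O(n) with cumulative
#' sums) followed by continuous refinement of the profile residual sum of
#' squares in the best bracket and an iterative-linearisation polish. The
#' procedure is deterministic given the input.
#'
#' When the data carry no detectable slope change (the segmented fit does
#' not improve on a single straight line), `converged` is `FALSE` and the
#' best profile solution is still returned; its RSS then equals the simple
#' regression RSS up to numerical precision.
#'
#' @param x,y Numeric vectors (at least 6 points; at least 2 distinct x
#'   values must lie on each side of any candidate break).
#' @return An object of class `breakpoint_fit`: list with `psi`,
#'   `slope_left`, `slope_right`, `intercept` (left-segment intercept),
#'   `rss`, `converged`, `iterations`, `n`.
#' @export
#' @examples
#' x <- seq(0, 20, length.out = 50)
#' y <- ifelse(x < 10, 1 - 0.02 * x, 0.8)
#' fit_breakpoint(x, y)$psi  # ~10
fit_breakpoint <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 6) stop_tp("breakpoint fit requires at least 6 points")
  o <- order(x)
  x <- x[o]; y <- y[o]
  xs <- unique(x)
  m <- length(xs)
  if (m < 4) stop_tp("need at least 2 distinct x values on each side ",
                     "of a candidate break")

  # cumulative statistics over the sorted sample
  cx <- cumsum(x); cx2 <- cumsum(x^2)
  cy <- cumsum(y); cxy <- cumsum(x * y)
  Sx <- cx[n]; Sx2 <- cx2[n]; Sy <- cy[n]; Sxy <- cxy[n]
  Syy <- sum(y^2)
  det2 <- n * Sx2 - Sx^2
  cf_line <- c((Sx2 * Sy - Sx * Sxy), (n * Sxy - Sx * Sy)) / det2
  rss_line <- max(Syy - cf_line[1] * Sy - cf_line[2] * Sxy, 0)

  # profile RSS of [1, x, (x - psi)+]: the hinge term is orthogonalised
  # against [1, x] in closed form, so the whole candidate grid costs O(n)
  hinge_stats <- function(psi) {
    idx <- findInterval(psi, x)          # last index with x <= psi
    k <- n - idx
    sxp <- Sx - cx[idx]; sx2p <- Sx2 - cx2[idx]
    syp <- Sy - cy[idx]; sxyp <- Sxy - cxy[idx]
    Su <- sxp - k * psi
    Suu <- sx2p - 2 * psi * sxp + k * psi^2
    Sxu <- sx2p - psi * sxp
    Syu <- sxyp - psi * syp
    alpha <- (Sx2 * Su - Sx * Sxu) / det2
    beta <- (n * Sxu - Sx * Su) / det2
    num <- Syu - alpha * Sy - beta * Sxy
    den <- Suu - alpha * Su - beta * Sxu
    list(num = num, den = den, Su = Su, Sxu = Sxu, Syu = Syu, k = k)
  }
  rss_at <- function(psi) {
    h <- hinge_stats(psi)
    out <- rss_line - h$num^2 / h$den
    out[!(h$den > 0) | h$k == 0] <- Inf
    pmax(out, 0)
  }
  fit_at <- function(psi, want_coef = FALSE) {
    if (!want_coef) return(list(rss = rss_at(psi)))
    h <- hinge_stats(psi)
    if (!(h$den > 0) || h$k == 0) return(list(rss = Inf, coef = rep(NA_real_, 3)))
    cc <- h$num / h$den
    # refit intercept and slope with the hinge contribution removed
    b1 <- ((Sx2 * (Sy - cc * h$Su) - Sx * (Sxy - cc * h$Sxu))) / det2
    b2 <- ((n * (Sxy - cc * h$Sxu) - Sx * (Sy - cc * h$Su))) / det2
    rss <- max(rss_line - h$num^2 / h$den, 0)
    list(rss = rss, coef = c(b1, b2, cc))
  }

  # profile over admissible observed breakpoints
  cand <- xs[2:(m - 2)]
  prof <- rss_at(cand)
  j <- which.min(prof)
  lo <- cand[max(j - 1, 1)]
  hi <- cand[min(j + 1, length(cand))]
  psi <- cand[j]
  if (hi > lo) {
    opt <- optimize(rss_at, c(lo, hi), tol = 1e-10 * max(diff(range(x)), 1))
    if (opt$objective <= prof[j]) psi <- opt$minimum
  }

  # iterative-linearisation polish (gap term V = -(x > psi), update
  # psi <- psi + gamma/c); kept inside the admissible range
  iterations <- 0L
  for (it in seq_len(10)) {
    u <- pmax(x - psi, 0)
    v <- -(x > psi)
    X <- cbind(1, x, u, v)
    fit <- stats::lm.fit(X, y)
    b <- fit$coefficients
    if (any(is.na(b)) || abs(b[3]) < 1e-12) break
    step <- b[4] / b[3]
    psi_new <- min(max(psi + step, cand[1]), cand[length(cand)])
    iterations <- it
    if (rss_at(psi_new) <= rss_at(psi)) psi <- psi_new
    if (abs(step) < 1e-9 * max(diff(range(x)), 1)) break
  }

  final <- fit_at(psi, want_coef = TRUE)
  b <- final$coef

  # does the break improve on a single straight line?
  improves <- (rss_line - final$rss) > 1e-9 * max(rss_line, 1e-12)
  span <- max(diff(range(x)), 1)
  interior <- psi > cand[1] + 1e-12 * span &&
    psi < cand[length(cand)] - 1e-12 * span

  structure(list(psi = unname(psi),
                 slope_left = unname(b[2]),
                 slope_right = unname(b[2] + b[3]),
                 intercept = unname(b[1]),
                 rss = final$rss,
                 converged = improves && interior,
                 iterations = iterations,
                 n = n),
            class = "breakpoint_fit")
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat(sprintf(paste0("Segmented fit: break at %.4g; slopes %.4g -> %.4g; ",
                     "RSS %.4g%s\n"),
              x$psi, x$slope_left, x$slope_right, x$rss,
              if (x$converged) "" else " (no reliable break)"))
  invisible(x)
}

#' Fitted values of a breakpoint fit
#'
#' @param object A `breakpoint_fit`.
#' @param newdata Numeric vector of x values (required).
#' @param ... Unused.
#' @return Numeric vector of fitted values.
#' @export
predict.breakpoint_fit <- function(object, newdata, ...) {
  object$intercept + object$slope_left * newdata +
    (object$slope_right - object$slope_left) * pmax(newdata - object$psi, 0)
}

#' Bootstrap confidence interval for the break location
#'
#' Case-resampling percentile bootstrap for `psi`.
#'
#' @param x,y Data vectors.
#' @param B Number of bootstrap resamples (default 199).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed for the resampling.
#' @return List with `lower`, `upper`, `psi_hat`, and the vector of
#'   bootstrap estimates `psi_boot` (non-converged resamples are `NA` and
#'   excluded from the percentiles).
#' @export
bootstrap_breakpoint <- function(x, y, B = 199, level = 0.95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fit <- fit_breakpoint(x, y)
  n <- length(x)
  psi_boot <- vapply(seq_len(B), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    f <- tryCatch(fit_breakpoint(x[i], y[i]), error = function(e) NULL)
    if (is.null(f)) NA_real_ else f$psi
  }, numeric(1))
  a <- (1 - level) / 2
  qs <- quantile(psi_boot, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  list(lower = qs[1], upper = qs[2], psi_hat = fit$psi, psi_boot = psi_boot)
}
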