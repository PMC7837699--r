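#' Convert tracked pixel heights to a physical rise series
#'
#' Dough-rise videos are digitized as pixel heights of the dough top; the
#' series is normalized against the pixel height of the culture tube and
#' scaled to millimetres: `height_mm = (X - X0) / Th * tube_mm`. The first
#' point of the series is 0 mm by construction when `X0` is the starting
#' height.
#'
#' @param times hours, strictly increasing.
#' @param pixels raw tracked heights (pixels), same length as `times`.
#' @param X0 starting height in pixels (default: first value of `pixels`).
#' @param Th tube height in pixels; must be positive.
#' @param tube_mm physical tube height in mm (default 103).
#' @param tube,inoculum,replicate optional identifiers carried along.
#' @return object of class `rise_series` with `time_h` and `height_mm`.
#' @export
normalize_heights <- function(times, pixels, X0 = pixels[1], Th,
                              tube_mm = 103, tube = NA, inoculum = NA,
                              replicate = NA) {
  if (length(times) != length(pixels)) stop("times and pixels must align")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!is.numeric(Th) || Th <= 0) stop("tube pixel height Th must be positive")
  height_mm <- (pixels - X0) / Th * tube_mm
  structure(list(time_h = as.numeric(times), height_mm = as.numeric(height_mm),
                 X0 = X0, Th = Th, tube_mm = tube_mm,
                 tube = tube, inoculum = inoculum, replicate = replicate),
            class = "rise_series")
}

#' Build a rise series directly from physical heights
#'
#' @param times hours, strictly increasing.
#' @param height_mm heights in mm.
#' @param ... identifiers passed through (`tube`, `inoculum`, `replicate`).
#' @return a `rise_series`.
#' @export
rise_series <- function(times, height_mm, ...) {
  ids <- list(...)
  if (length(times) != length(height_mm)) stop("times and heights must align")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(time_h = as.numeric(times), height_mm = as.numeric(height_mm),
                 X0 = NA, Th = NA, tube_mm = NA,
                 tube = ids$tube %||% NA, inoculum = ids$inoculum %||% NA,
                 replicate = ids$replicate %||% NA),
            class = "rise_series")
}

#' @export
print.rise_series <- function(x, ...) {
  cat(sprintf("rise_series: %d points over %.1f h, max %.2f mm\n",
              length(x$time_h), diff(range(x$time_h)), max(x$height_mm)))
  invisible(x)
}

#' Truncate a rise series after the dough collapses
#'
#' Removes all points from the first time the height drops strictly more
#' than `frac` (default 5%) below the running maximum — everything from the
#' offending sample onward is cut, so late secondary rises are not
#' resurrected.
#'
#' @param series a `rise_series`.
#' @param frac collapse threshold as a fraction of the running maximum
#'   (default 0.05, strict "more than").
#' @return a `rise_series` that is a prefix of the input.
#' @export
truncate_after_fall <- function(series, frac = 0.05) {
  stopifnot(inherits(series, "rise_series"))
  h <- series$height_mm
  if (!length(h)) stop("empty series")
  runmax <- cummax(h)
  fallen <- h < (1 - frac) * runmax
  cut_at <- which(fallen)[1]
  keep <- if (is.na(cut_at)) seq_along(h) else seq_len(cut_at - 1)
  out <- series
  out$time_h <- series$time_h[keep]
  out$height_mm <- h[keep]
  out
}

#' Fit a logistic growth curve to a rise series
#'
#' Least-squares fit of `N(t) = K / (1 + ((K - N0) / N0) * exp(-r t))`
#' (carrying capacity `K` in mm, intrinsic rate `r` per hour, initial value
#' `N0` in mm). Initial guesses: `K` = maximum height, `N0` = first
#' positive height, `r = 4 * max_slope / K`. Goodness of fit is an F-test
#' of the logistic model against the constant-mean model; the fit is
#' accepted when `gof_p <= 0.01` and `r > 0`.
#'
#' @param series a `rise_series` (typically after [truncate_after_fall()]);
#'   at least 5 points required.
#' @param accept_p acceptance cutoff on the goodness-of-fit p (default 0.01).
#' @return object of class `logistic_fit`: `r`, `K`, `N0`, `rss`, `gof_p`,
#'   `accepted`, `converged`, `fitted`.
#' @export
fit_logistic <- function(series, accept_p = 0.01) {
  stopifnot(inherits(series, "rise_series"))
  t <- series$time_h
  y <- series$height_mm
  if (length(t) < 5) stop("need at least 5 points to fit (after truncation)")
  reject <- function(reason) {
    structure(list(r = NA_real_, K = NA_real_, N0 = NA_real_,
                   rss = NA_real_, gof_p = NA_real_, accepted = FALSE,
                   converged = FALSE, reason = reason, fitted = NULL),
              class = "logistic_fit")
  }
  pos <- y[y > 0]
  if (!length(pos) || stats::sd(y) == 0) return(reject("no rise signal"))
  K0 <- max(y)
  N00 <- pos[1]
  slopes <- diff(y) / diff(t)
  r0 <- max(4 * max(slopes, na.rm = TRUE) / K0, 1e-3)
  logis <- function(t, K, N0, r) K / (1 + ((K - N0) / N0) * exp(-r * t))
  fit <- tryCatch(
    stats::nls(y ~ K / (1 + ((K - N0) / N0) * exp(-r * t)),
               start = list(K = K0, N0 = max(N00, 1e-3), r = r0),
               algorithm = "port",
               lower = c(K = 1e-6, N0 = 1e-9, r = 1e-6),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # fall back to direct minimization on log-parameters
    obj <- function(par) {
      p <- exp(par)
      sum((y - logis(t, p[1], p[2], p[3]))^2)
    }
    opt <- tryCatch(stats::optim(log(c(K0, max(N00, 1e-3), r0)), obj,
                                 method = "Nelder-Mead",
                                 control = list(maxit = 2000)),
                    error = function(e) NULL)
    if (is.null(opt)) return(reject("optimization failed"))
    pars <- exp(opt$par)
    names(pars) <- c("K", "N0", "r")
    fitted_vals <- logis(t, pars["K"], pars["N0"], pars["r"])
    converged <- opt$convergence == 0
  } else {
    pars <- stats::coef(fit)
    fitted_vals <- stats::fitted(fit)
    converged <- TRUE
  }
  rss <- sum((y - fitted_vals)^2)
  tss <- sum((y - mean(y))^2)
  n <- length(y)
  # nested F-test: logistic (3 parameters) vs constant mean (1 parameter)
  if (rss <= .Machine$double.eps * tss || tss == 0) {
    gof_p <- if (tss == 0) 1 else 0
  } else {
    Fstat <- ((tss - rss) / 2) / (rss / (n - 3))
    gof_p <- stats::pf(Fstat, 2, n - 3, lower.tail = FALSE)
  }
  accepted <- converged && is.finite(gof_p) && gof_p <= accept_p && pars[["r"]] > 0
  structure(list(r = pars[["r"]], K = pars[["K"]], N0 = pars[["N0"]],
                 rss = rss, gof_p = gof_p, accepted = accepted,
                 converged = converged, fitted = fitted_vals),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  if (is.na(x$r)) {
    cat("logistic_fit: rejected (", x$reason %||% "no fit", ")\n", sep = "")
  } else {
    cat(sprintf("logistic_fit: r = %.4g /h, K = %.4g mm, N0 = %.4g mm, gof p = %.3g (%s)\n",
                x$r, x$K, x$N0, x$gof_p,
                if (x$accepted) "accepted" else "rejected"))
  }
  invisible(x)
}

#' One-way ANOVA of rise rates across inocula
#'
#' Fixed-effects one-way ANOVA of per-replicate rise rates on the inoculum
#' label; reports the F-test p-value and the adjusted R-squared
#' `1 - (1 - R2) (n - 1) / (n - k)`.
#'
#' @param rates per-replicate rise rates.
#' @param inoculum inoculum label per rate.
#' @return list with `adj_r_squared`, `r_squared`, `F`, `df`, `p.value`.
#'   Degenerate inputs (no between- or within-group variation) give `NA`s.
#' @export
rise_rate_anova <- function(rates, inoculum) {
  if (length(rates) != length(inoculum)) stop("rates and inoculum must align")
  g <- factor(inoculum)
  if (nlevels(g) < 2) stop("need at least 2 inocula")
  n <- length(rates)
  k <- nlevels(g)
  gm <- tapply(rates, g, mean)
  ssb <- sum(tabulate(g) * (gm - mean(rates))^2)
  ssw <- sum((rates - gm[g])^2)
  if (ssw == 0 && ssb == 0) {
    return(list(adj_r_squared = NA_real_, r_squared = NA_real_, F = NA_real_,
                df = c(k - 1, n - k), p.value = NA_real_))
  }
  r2 <- ssb / (ssb + ssw)
  adj <- 1 - (1 - r2) * (n - 1) / (n - k)
  Fstat <- if (ssw == 0) Inf else (ssb / (k - 1)) / (ssw / (n - k))
  p <- if (is.infinite(Fstat)) 0 else stats::pf(Fstat, k - 1, n - k,
                                                lower.tail = FALSE)
  list(adj_r_squared = adj, r_squared = r2, F = Fstat,
       df = c(k - 1, n - k), p.value = p)
}

#' Run the full rise-curve pipeline on a long-format table
#'
#' Normalizes each tube's pixel series, truncates after collapse, and fits
#' the logistic model, returning one row per tube.
#'
#' @param series_df data.frame with columns `tube`, `inoculum`, `replicate`,
#'   `time_h`, `pixels`.
#' @param calibration data.frame with columns `tube`, `X0`, `Th` and
#'   optionally `tube_mm`.
#' @param fall_frac collapse threshold for [truncate_after_fall()].
#' @return data.frame with per-tube `r`, `K`, `N0`, `gof_p`, `accepted`.
#' @export
rise_pipeline <- function(series_df, calibration, fall_frac = 0.05) {
  series_df <- as.data.frame(series_df)
  calibration <- as.data.frame(calibration)
  if (!"tube_mm" %in% names(calibration)) calibration$tube_mm <- 103
  tubes <- unique(series_df$tube)
  res <- lapply(tubes, function(tb) {
    sub <- series_df[series_df$tube == tb, ]
    sub <- sub[order(sub$time_h), ]
    cal <- calibration[calibration$tube == tb, ]
    if (!nrow(cal)) stop("no calibration for tube ", tb)
    s <- normalize_heights(sub$time_h, sub$pixels, X0 = cal$X0[1],
                           Th = cal$Th[1], tube_mm = cal$tube_mm[1],
                           tube = tb, inoculum = sub$inoculum[1],
                           replicate = sub$replicate[1])
    s <- truncate_after_fall(s, frac = fall_frac)
    fit <- if (length(s$time_h) >= 5) fit_logistic(s) else
      structure(list(r = NA_real_, K = NA_real_, N0 = NA_real_,
                     gof_p = NA_real_, accepted = FALSE), class = "logistic_fit")
    data.frame(tube = tb, inoculum = sub$inoculum[1],
               replicate = sub$replicate[1], n_points = length(s$time_h),
               r = fit$r, K = fit$K, N0 = fit$N0, gof_p = fit$gof_p,
               accepted = fit$accepted, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
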