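#' Four-parameter logistic viability curve
#'
#' `f(d) = bottom + (top - bottom) / (1 + 10^(hill * (log10(d) - log10_ic50)))`.
#' With `hill > 0` and `top > bottom`, viability decreases with dose.
#'
#' @param dose_nM dose in nM (positive).
#' @param bottom,top lower/upper asymptotes (fraction-of-control).
#' @param log10_ic50 curve midpoint in log10(nM).
#' @param hill slope (dimensionless).
#' @return viability fractions.
#' @export
logistic_viability <- function(dose_nM, bottom, top, log10_ic50, hill) {
  bottom + (top - bottom) / (1 + 10^(hill * (log10(dose_nM) - log10_ic50)))
}

logistic_variants <- c("FULL_4PL", "TOP_FIXED", "BOTTOM_FIXED")

#' Fit one member of the logistic model family
#'
#' Nonlinear least squares of viability on log10 dose for one of the three
#' admissible variants: the full four-parameter logistic, the variant with the
#' top asymptote fixed at 1 (100 percent of control), or with the bottom fixed
#' at 0. Optimization is bounded (`bottom`/`top` in \[-0.1, 1.5\], `hill` in
#' \[-10, 10\]) L-BFGS-B from three Hill-slope starts, with a tight-tolerance
#' polish from the best start. Replicate viabilities may be supplied; each
#' (dose, viability) point enters the loss with equal weight.
#'
#' All-identical viabilities form a degenerate problem for the full variant:
#' the returned fit is the flat curve at the mean (`bottom = top = mean`,
#' slope 0 convention) flagged `degenerate`.
#'
#' @param data tibble with columns `dose_nM` and `viability` (one row per
#'   measured point; replicates appear as repeated doses).
#' @param variant `"FULL_4PL"`, `"TOP_FIXED"` or `"BOTTOM_FIXED"`.
#' @param sample_id,drug optional identifiers carried into the fit object.
#' @return A `logistic_fit`: parameters, `rss`, `aic`
#'   (`n*log(rss/n) + 2*(n_params+1)`), and `converged`/`degenerate` flags.
#' @export
fit_logistic <- function(data, variant = "FULL_4PL", sample_id = NA_character_,
                         drug = NA_character_) {
  variant <- match.arg(variant, logistic_variants)
  stopifnot(all(c("dose_nM", "viability") %in% names(data)))
  if (any(data$dose_nM <= 0)) abort("doses must be positive")
  if (any(data$viability < 0)) abort("viability must be nonnegative")
  x <- log10(data$dose_nM)
  y <- data$viability
  n_params <- if (variant == "FULL_4PL") 4L else 3L
  if (length(unique(x)) < n_params) {
    abort(paste0("need at least ", n_params, " distinct doses for ", variant))
  }
  n <- length(y)

  if (variant == "FULL_4PL" && sd(y) < 1e-12) {
    return(new_logistic_fit(variant, bottom = mean(y), top = mean(y),
                            log10_ic50 = stats::median(x), hill = 0,
                            rss = sum((y - mean(y))^2), n_params = n_params,
                            n_obs = n, converged = TRUE, degenerate = TRUE,
                            data = data, sample_id = sample_id, drug = drug))
  }

  pred <- function(theta) {
    th <- fill_theta(theta, variant)
    logistic_viability(10^x, th[1], th[2], th[3], th[4])
  }
  obj <- function(theta) sum((y - pred(theta))^2)

  b0 <- min(max(min(y), -0.1), 1.5)
  t0 <- min(max(max(y), -0.1), 1.5)
  half <- (b0 + t0) / 2
  e0 <- x[which.min(abs(y - half))]
  lower <- c(-0.1, -0.1, min(x) - 5, -10)
  upper <- c(1.5, 1.5, max(x) + 5, 10)
  keep <- free_params(variant)

  best <- NULL
  for (h0 in c(0.5, 1, 4)) {
    start <- c(b0, t0, e0, h0)[keep]
    fit <- tryCatch(
      optim(start, obj, method = "L-BFGS-B", lower = lower[keep],
            upper = upper[keep], control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  # slope starts can miss when the transition sits between sparse doses; a
  # cheap (location, slope) grid scan supplies one extra informed start
  grid <- expand.grid(e_try = unique(x), h_try = c(-2, 0.3, 1, 3, 8))
  grid$val <- vapply(seq_len(nrow(grid)), function(i) {
    obj(c(b0, t0, grid$e_try[i], grid$h_try[i])[keep])
  }, numeric(1))
  gbest <- grid[which.min(grid$val), ]
  fit <- tryCatch(
    optim(c(b0, t0, gbest$e_try, gbest$h_try)[keep], obj, method = "L-BFGS-B",
          lower = lower[keep], upper = upper[keep], control = list(maxit = 500)),
    error = function(e) NULL
  )
  if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  converged <- !is.null(best) && is.finite(best$value)
  if (converged) {
    nd <- rep(1e-7, length(best$par))  # fine FD steps; default 1e-3 limits precision
    for (ctrl in list(list(maxit = 1000, factr = 1, ndeps = nd),
                      list(maxit = 1000, factr = 1, ndeps = nd))) {
      polish <- tryCatch(
        optim(best$par, obj, method = "L-BFGS-B", lower = lower[keep],
              upper = upper[keep], control = ctrl),
        error = function(e) NULL
      )
      if (!is.null(polish) && polish$value <= best$value) best <- polish
    }
    # Levenberg-Marquardt polish: quasi-Newton steps stall in the sloppy
    # parameter valleys typical of logistic fits; LM on the residuals does not
    lm_fit <- tryCatch(
      minpack.lm::nls.lm(
        par = best$par, lower = lower[keep], upper = upper[keep],
        fn = function(theta) y - pred(theta),
        control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                             maxiter = 500)),
      error = function(e) NULL
    )
    if (!is.null(lm_fit)) {
      val <- sum(lm_fit$fvec^2)
      if (is.finite(val) && val <= best$value) {
        best <- list(par = lm_fit$par, value = val)
      }
    }
  }

  if (!converged) {
    return(new_logistic_fit(variant, bottom = NA_real_, top = NA_real_,
                            log10_ic50 = NA_real_, hill = NA_real_,
                            rss = Inf, n_params = n_params, n_obs = n,
                            converged = FALSE, degenerate = FALSE,
                            data = data, sample_id = sample_id, drug = drug))
  }
  th <- fill_theta(best$par, variant)
  # report with top >= bottom (flip via negative-slope symmetry; only the free
  # variant may flip, fixed-asymptote fits keep their constraint in place)
  if (variant == "FULL_4PL" && th[2] < th[1]) th <- c(th[2], th[1], th[3], -th[4])
  new_logistic_fit(variant, bottom = th[1], top = th[2], log10_ic50 = th[3],
                   hill = th[4], rss = best$value, n_params = n_params,
                   n_obs = n, converged = TRUE, degenerate = FALSE,
                   data = data, sample_id = sample_id, drug = drug)
}

free_params <- function(variant) {
  switch(variant,
         FULL_4PL = 1:4,
         TOP_FIXED = c(1, 3, 4),
         BOTTOM_FIXED = 2:4)
}

fill_theta <- function(theta, variant) {
  th <- c(0, 1, 0, 1)
  th[free_params(variant)] <- theta
  if (variant == "TOP_FIXED") th[2] <- 1
  if (variant == "BOTTOM_FIXED") th[1] <- 0
  th
}

new_logistic_fit <- function(variant, bottom, top, log10_ic50, hill, rss,
                             n_params, n_obs, converged, degenerate, data,
                             sample_id, drug) {
  aic <- if (is.finite(rss)) {
    n_obs * log(max(rss, 0) / n_obs) + 2 * (n_params + 1)
  } else {
    Inf
  }
  structure(list(variant = variant, bottom = bottom, top = top,
                 log10_ic50 = log10_ic50, hill = hill, rss = rss,
                 n_params = n_params, n_obs = n_obs, aic = aic,
                 converged = converged, degenerate = degenerate,
                 data = as_tibble(data[c("dose_nM", "viability")]),
                 sample_id = sample_id, drug = drug),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit ", x$variant, "> bottom=", signif(x$bottom, 4),
      " top=", signif(x$top, 4), " log10_ic50=", signif(x$log10_ic50, 4),
      " hill=", signif(x$hill, 4), " rss=", signif(x$rss, 4),
      if (x$degenerate) " [degenerate]" else "", "\n", sep = "")
  invisible(x)
}

#' @export
predict.logistic_fit <- function(object, dose_nM, ...) {
  if (object$degenerate) return(rep(object$bottom, length(dose_nM)))
  logistic_viability(dose_nM, object$bottom, object$top, object$log10_ic50,
                     object$hill)
}

#' Broom-style tidiers for logistic fits
#'
#' `tidy()` returns one row per curve parameter; `glance()` returns one row of
#' fit-level summaries.
#'
#' @param x a `logistic_fit`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy logistic_fit
#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble(term = c("bottom", "top", "log10_ic50", "hill"),
         estimate = c(x$bottom, x$top, x$log10_ic50, x$hill),
         fixed = switch(x$variant,
                        FULL_4PL = c(FALSE, FALSE, FALSE, FALSE),
                        TOP_FIXED = c(FALSE, TRUE, FALSE, FALSE),
                        BOTTOM_FIXED = c(TRUE, FALSE, FALSE, FALSE)))
}

#' @rdname tidy.logistic_fit
#' @method glance logistic_fit
#' @export
glance.logistic_fit <- function(x, ...) {
  tibble(variant = x$variant, rss = x$rss, aic = x$aic,
         n_params = x$n_params, n_obs = x$n_obs,
         converged = x$converged, degenerate = x$degenerate)
}

#' Select the best-fitting logistic variant
#'
#' Fits all three family members and returns the converged fit with the
#' smallest information criterion; ties break toward fewer parameters, then
#' toward the earlier position in the family ordering (full, top-fixed,
#' bottom-fixed). Because dose grids are short (typically 8 points), the
#' comparison uses the small-sample corrected criterion
#' `AICc = AIC + 2k(k+1)/(n-k-1)` (k = n_params + 1); plain AIC's constant
#' +2 penalty lets the free fourth parameter win on noise alone at this n.
#' A variant with too few points for a finite correction is never preferred
#' over one with a defined score unless it interpolates exactly.
#'
#' @inheritParams fit_logistic
#' @return the winning `logistic_fit`.
#' @export
select_best_fit <- function(data, sample_id = NA_character_, drug = NA_character_) {
  fits <- lapply(logistic_variants, fit_logistic, data = data,
                 sample_id = sample_id, drug = drug)
  ok <- vapply(fits, function(f) f$converged, logical(1))
  if (!any(ok)) {
    abort(paste0("no logistic variant converged for sample ", sample_id,
                 ", drug ", drug))
  }
  fits <- fits[ok]
  score <- vapply(fits, function(f) {
    if (!is.finite(f$aic)) return(f$aic)
    k <- f$n_params + 1
    corr <- if (f$n_obs - k - 1 > 0) 2 * k * (k + 1) / (f$n_obs - k - 1) else Inf
    f$aic + corr
  }, numeric(1))
  npar <- vapply(fits, function(f) f$n_params, integer(1))
  pos <- match(vapply(fits, function(f) f$variant, character(1)), logistic_variants)
  fits[[order(score, npar, pos)[1]]]
}

#' Integrate a fitted curve into the AUC phenotype
#'
#' Trapezoidal integration of the fitted viability curve on a uniform grid of
#' at least 1001 points in log10 dose over `[lo_nM, hi_nM]`. The result is in
#' fraction x log10(nM) units: a fully resistant flat curve at viability 1
#' integrates to 10 over the default 10-log-unit range; lower AUC means a more
#' sensitive line. Degenerate fits integrate their flat mean curve.
#'
#' @param fit a `logistic_fit`.
#' @param lo_nM,hi_nM integration range in nM (defaults 1e-7 and 1e3).
#' @param n_grid number of grid points (minimum 1001; the denser default keeps
#'   the result stable to well under 1e-6 even for curves whose transition
#'   abuts the integration boundary).
#' @return one-row tibble `sample_id`, `drug`, `auc`, `variant`, `converged`,
#'   `degenerate`.
#' @export
compute_auc <- function(fit, lo_nM = 1e-7, hi_nM = 1e3, n_grid = 4001) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (lo_nM <= 0 || hi_nM <= lo_nM) abort("need 0 < lo_nM < hi_nM")
  n_grid <- max(as.integer(n_grid), 1001L)
  xs <- seq(log10(lo_nM), log10(hi_nM), length.out = n_grid)
  ys <- predict(fit, 10^xs)
  dx <- xs[2] - xs[1]
  auc <- sum((ys[-1] + ys[-n_grid]) / 2) * dx
  tibble(sample_id = fit$sample_id, drug = fit$drug, auc = auc,
         variant = fit$variant, converged = fit$converged,
         degenerate = fit$degenerate)
}

#' Derive AUC phenotypes for a whole dose-response dataset
#'
#' Replicate viabilities are averaged per dose, the best-fitting logistic
#' variant is selected per sample and drug, and the fitted curve is integrated
#' over `[lo_nM, hi_nM]`. Per-sample failures (too few distinct doses, or no
#' variant converging) are collected in the `"failures"` attribute rather than
#' aborting the run.
#'
#' @param data long-format tibble with columns `sample_id`, `drug`, `dose_nM`,
#'   `replicate`, `viability`.
#' @param lo_nM,hi_nM integration range in nM.
#' @return tibble `sample_id`, `drug`, `auc`, `variant`, `converged`, with a
#'   `"failures"` attribute (tibble `sample_id`, `drug`, `reason`).
#' @export
derive_auc_phenotypes <- function(data, lo_nM = 1e-7, hi_nM = 1e3) {
  stopifnot(all(c("sample_id", "drug", "dose_nM", "viability") %in% names(data)))
  if (nrow(data) == 0) abort("empty dose-response dataset")
  avg <- data |>
    group_by(sample_id, drug, dose_nM) |>
    summarise(viability = mean(viability), .groups = "drop")
  groups <- avg |> tidyr::nest(curve = c(dose_nM, viability))
  res <- vector("list", nrow(groups))
  fails <- list()
  for (i in seq_len(nrow(groups))) {
    sid <- groups$sample_id[i]
    drg <- groups$drug[i]
    out <- tryCatch({
      fit <- select_best_fit(groups$curve[[i]], sample_id = sid, drug = drg)
      compute_auc(fit, lo_nM, hi_nM)
    }, error = function(e) conditionMessage(e))
    if (is.character(out)) {
      fails[[length(fails) + 1]] <- tibble(sample_id = sid, drug = drg, reason = out)
    } else {
      res[[i]] <- out
    }
  }
  pheno <- bind_rows(res) |> select(sample_id, drug, auc, variant, converged)
  attr(pheno, "failures") <- if (length(fails)) bind_rows(fails) else
    tibble(sample_id = character(), drug = character(), reason = character())
  pheno
}
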