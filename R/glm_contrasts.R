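# Gaussian identity-link GLM of the delta statistic, fitted by iteratively
# reweighted least squares, and the one-vs-rest contrast rotation that
# produces one marginal coefficient per environmental context.

#' Fit a Gaussian identity-link GLM by IRLS
#'
#' Iteratively reweighted least squares for the Gaussian family with
#' identity link.  For this family the working weights are constant, so the
#' iteration converges to the ordinary-least-squares solution (in exact
#' arithmetic, in one step); the iteration is still run and its convergence
#' checked, since the same scaffold extends to non-constant-weight
#' families.  Standard errors use the moment estimate of the dispersion and
#' p-values the normal (z) approximation, as in standard IRLS GLM software.
#'
#' @param y Numeric response vector.
#' @param X Design matrix (include the intercept column yourself), with
#'   `nrow(X) > ncol(X)` and full column rank.
#' @param max_iter,tol IRLS iteration cap and deviance-change convergence
#'   tolerance.
#' @return list of class `irls_fit`: `coefficients`, `std_err`, `z`,
#'   `p_value`, `fitted`, `dispersion`, `n`, and `metrics` (log-likelihood,
#'   deviance, Pearson chi-square, Cragg-Uhler pseudo R-squared).
#' @export
fit_glm_irls <- function(y, X, max_iter = 25L, tol = 1e-12) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (n <= p)
    stop("need more observations than coefficients", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < p) {
    cols <- colnames(X)
    dropped <- if (!is.null(cols)) cols[-seq_len(qrX$rank)] else
      paste0("column ", (qrX$rank + 1L):p)
    stop("design is rank deficient; collinear: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }

  beta <- rep(0, p)
  dev_old <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- eta                      # identity link
    w <- rep(1, n)                 # Gaussian variance function is constant
    z <- eta + (y - mu)            # working response
    wfit <- stats::lm.wfit(X, z, w)
    beta <- wfit$coefficients
    dev <- sum((y - drop(X %*% beta))^2)
    if (is.finite(dev_old) && abs(dev - dev_old) <= tol * (abs(dev) + 0.1)) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  if (!converged)
    stop("IRLS did not converge in ", max_iter, " iterations",
         call. = FALSE)

  mu <- drop(X %*% beta)
  rss <- sum((y - mu)^2)
  dispersion <- rss / (n - p)
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(xtx_inv) * dispersion)
  zval <- beta / se
  pval <- 2 * stats::pnorm(-abs(zval))

  # Gaussian log-likelihood at the MLE of the variance (rss / n)
  ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
  y0 <- mean(y)
  rss0 <- sum((y - y0)^2)
  ll0 <- -n / 2 * (log(2 * pi * rss0 / n) + 1)
  # Cragg-Uhler (Nagelkerke) pseudo R2: the likelihood-ratio R2
  #   1 - (L0/L1)^(2/n)  (for the Gaussian family this equals 1 - RSS1/RSS0,
  # the classical R2) rescaled by its ceiling 1 - L0^(2/n).  With a
  # continuous response the null density can exceed 1, making the ceiling
  # undefined; the uncorrected likelihood-ratio R2 is reported then.
  r2_cs <- 1 - exp(2 * (ll0 - ll) / n)
  r2_max <- 1 - exp(2 * ll0 / n)
  metrics <- list(log_likelihood = ll,
                  deviance = rss,
                  pearson_chi2 = rss,
                  pseudo_r2_cragg_uhler = if (r2_max > 0)
                    min(r2_cs / r2_max, 1) else max(r2_cs, 0))

  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 std_err = stats::setNames(se, colnames(X)),
                 z = zval, p_value = pval, fitted = mu,
                 dispersion = dispersion, n = n, iterations = it,
                 metrics = metrics),
            class = "irls_fit")
}

#' @export
print.irls_fit <- function(x, ...) {
  cat("Gaussian identity-link GLM (IRLS), n =", x$n, "\n")
  print(data.frame(coef = x$coefficients, std_err = x$std_err,
                   z = x$z, `P>|z|` = x$p_value, check.names = FALSE))
  cat(sprintf("log-likelihood %.3f, deviance %.4f, pseudo R2 (Cragg-Uhler) %.4f\n",
              x$metrics$log_likelihood, x$metrics$deviance,
              x$metrics$pseudo_r2_cragg_uhler))
  invisible(x)
}

#' One-vs-rest contrast rotation over environmental contexts
#'
#' Refits the same Gaussian identity-link GLM repeatedly, each time with a
#' single focal-category indicator (focal context vs all the rest), and
#' extracts the focal coefficient, its standard error and p-value.  Station
#' contrasts ignore layer and vice versa, so the reported effects are
#' marginal shifts: e.g. the OMZ coefficient is the OMZ-vs-rest shift in
#' the response irrespective of depth.  Contrasts are computed separately
#' per guild class.
#'
#' @param scores Guild scores (see [score_strata()]).
#' @param axes Columns of `scores` to rotate over; default
#'   `c("station_class", "layer")`.
#' @param response Response column; `"log_delta"` by default (the scale on
#'   which the delta distributions are roughly symmetric), or `"delta"`.
#' @param guilds Marker registry used to split genes into guild classes;
#'   `NULL` pools everything into one class `"all"`.
#' @return data.frame of class `contrast_table`: `axis`, `focal`,
#'   `guild_class`, `coef`, `std_err`, `p_value`, `n`, plus the fit metrics
#'   of each refit.  Categories with fewer than 2 observations are skipped
#'   with a warning; remaining contrasts are still produced.
#' @export
one_vs_rest_rotation <- function(scores,
                                 axes = c("station_class", "layer"),
                                 response = c("log_delta", "delta"),
                                 guilds = n_cycle_markers()) {
  response <- match.arg(response)
  y_all <- scores[[response]]
  cls <- if (is.null(guilds)) rep("all", nrow(scores)) else
    guild_class_of(scores$gene, guilds)
  rows <- list()
  for (gc in sort(unique(cls))) {
    sel <- cls == gc & is.finite(y_all)
    y <- y_all[sel]
    for (axis in axes) {
      cats <- scores[[axis]][sel]
      if (length(unique(cats)) < 2L)
        stop("axis '", axis, "' has fewer than 2 categories", call. = FALSE)
      for (focal in sort(unique(cats))) {
        ind <- as.numeric(cats == focal)
        if (sum(ind) < 2L || sum(1 - ind) < 2L) {
          warning("skipping ", axis, "=", focal, " (", gc,
                  "): fewer than 2 observations on one side",
                  call. = FALSE)
          next
        }
        X <- cbind(`(Intercept)` = 1, focal = ind)
        fit <- fit_glm_irls(y, X)
        rows[[length(rows) + 1L]] <- data.frame(
          axis = axis, focal = focal, guild_class = gc,
          coef = unname(fit$coefficients["focal"]),
          std_err = unname(fit$std_err["focal"]),
          p_value = fit$p_value[2L], n = fit$n,
          log_likelihood = fit$metrics$log_likelihood,
          deviance = fit$metrics$deviance,
          pearson_chi2 = fit$metrics$pearson_chi2,
          pseudo_r2_cragg_uhler = fit$metrics$pseudo_r2_cragg_uhler,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    stop("no contrast could be fitted", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("contrast_table", "data.frame")
  out
}

#' Format a contrast table with significance marks
#'
#' Orders rows station contrasts first, then layer contrasts, and attaches
#' significance stars: `*` for p < 0.05, `**` for p < 0.01, `***` for
#' p < 0.001 (no mark at or above `alpha`).
#'
#' @param contrasts Output of [one_vs_rest_rotation()].
#' @param alpha Significance level below which any star is shown; default
#'   0.05.
#' @return The contrast data.frame with a `signif` column, ordered for
#'   presentation.
#' @export
summarize_table <- function(contrasts, alpha = 0.05) {
  if (nrow(contrasts) == 0L)
    stop("empty contrast table", call. = FALSE)
  stars <- function(p) {
    if (p >= alpha) "" else if (p < 0.001) "***" else if (p < 0.01) "**"
    else "*"
  }
  contrasts$signif <- vapply(contrasts$p_value, stars, character(1L))
  axis_rank <- ifelse(contrasts$axis == "station_class", 1L, 2L)
  out <- contrasts[order(contrasts$guild_class, axis_rank,
                         contrasts$focal), , drop = FALSE]
  rownames(out) <- NULL
  out
}
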