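# Two-step GAMM: additive stage, then an ARIMA model on its residuals;
# approximate-AIC comparison and leave-one-covariate-out importance.

#' Approximate Akaike Information Criterion
#'
#' `aAIC = n log(sigma^2) + 2 k`, where `n` is the series length, `sigma^2`
#' the variance of the model residuals (innovations for the combined model)
#' and `k` the total degrees of freedom. Smaller is better; it is the
#' criterion used to compare the additive model with and without the ARIMA
#' error stage.
#'
#' @param n Series length (>= 1).
#' @param sigma2 Residual/innovation variance (> 0).
#' @param k Total degrees of freedom (>= 0).
#' @return The criterion value.
#' @export
aaic <- function(n, sigma2, k) {
  if (any(n < 1)) stop("n must be at least 1")
  if (any(sigma2 <= 0)) stop("sigma2 must be positive")
  if (any(k < 0)) stop("k must be non-negative")
  n * log(sigma2) + 2 * k
}

#' Fit the two-step GAMM
#'
#' Step one selects the additive model by bidirectional stepwise AIC over
#' the candidate smooths ([stepwise_select_gam()]); step two selects an
#' ARIMA model for the step-one residuals by AIC grid search
#' ([select_arma_order()]), with the residual series laid out on the full
#' 15-minute grid so gaps are handled by the state-space filter.
#'
#' Total deviance explained is `100 (1 - SS_innov / TSS)`, where `SS_innov`
#' is the sum of squared standardized one-step innovations of the final
#' ARIMA fit — the variation neither the covariates nor the autoregressive
#' structure can predict.
#'
#' @param data An [aligned_dataset()].
#' @param candidates Candidate covariate names for the additive stage.
#' @param p_max,d_max,q_max ARIMA grid bounds (defaults 5, 1, 4).
#' @param max_df Per-smooth effective-df cap (default 6).
#' @return An object of class `gamm_fit` with elements `gam` (`gam_fit`),
#'   `arma` (`arma_fit`), `k_total`, `aaic`, `total_deviance_explained`,
#'   `n`, plus both stage traces.
#' @export
fit_gamm_two_step <- function(data, candidates, p_max = 5L, d_max = 1L,
                              q_max = 4L, max_df = 6L) {
  stopifnot(inherits(data, "aligned_dataset"), length(candidates) >= 1)
  gam <- stepwise_select_gam(data, candidates, max_df = max_df)
  arma <- select_arma_order(gam$residuals_grid,
                            p_max = p_max, d_max = d_max, q_max = q_max)
  build_gamm_fit(gam, arma, candidates)
}

build_gamm_fit <- function(gam, arma, candidates) {
  n <- gam$n
  k_total <- gam$edf_total + arma$spec$p + arma$spec$q
  # sum of squared standardized one-step innovations = n_eff * sigma2_hat
  ss_innov <- arma$n_eff * arma$sigma2
  total_dev <- 100 * (1 - ss_innov / gam$tss)
  structure(list(
    gam = gam, arma = arma, candidates = candidates, n = n,
    k_total = k_total, ss_innov = ss_innov,
    aaic = aaic(n, arma$sigma2, k_total),
    total_deviance_explained = total_dev
  ), class = "gamm_fit")
}

#' @export
print.gamm_fit <- function(x, ...) {
  cat("Two-step GAMM (", x$gam$site, ")\n", sep = "")
  cat("  additive stage: ", paste(names(x$gam$terms), collapse = " + "),
      sprintf("  (deviance explained %.1f%%)\n", x$gam$deviance_explained))
  cat("  error stage   : ", format(x$arma$spec),
      sprintf("  (innovation variance %.4g)\n", x$arma$sigma2))
  cat(sprintf("  total deviance explained %.1f%%, aAIC %.1f (k = %.2f)\n",
              x$total_deviance_explained, x$aaic, x$k_total))
  invisible(x)
}

#' Compare the additive model with and without the ARIMA error stage
#'
#' The additive model's aAIC uses the variance of its residuals and
#' `k = edf_total`; the combined model's uses the ARIMA innovation variance
#' and `k = edf_total + p + q`. Smaller aAIC is better.
#'
#' @param gamm A `gamm_fit`.
#' @return Data frame with rows GAM and GAMM.
#' @export
compare_gam_gamm <- function(gamm) {
  stopifnot(inherits(gamm, "gamm_fit"))
  g <- gamm$gam
  data.frame(
    model = c("GAM", "GAMM"),
    aaic = c(aaic(gamm$n, g$rss / g$n, g$edf_total), gamm$aaic),
    deviance_explained = c(g$deviance_explained,
                           gamm$total_deviance_explained),
    stringsAsFactors = FALSE)
}

#' Leave-one-covariate-out variable importance
#'
#' For each covariate in the fitted model, the additive stage is refitted
#' without it (same remaining terms, smoothing parameters re-optimized — the
#' stepwise search is not re-run) and the ARIMA coefficients are re-estimated
#' at the full model's selected orders. A covariate's importance is the drop
#' in total deviance explained; the autoregressive share is the gap between
#' the total and the additive-stage deviance explained.
#'
#' @param data The [aligned_dataset()] the model was fitted to.
#' @param full A `gamm_fit`.
#' @param covariates Covariates to score; defaults to all terms of the full
#'   model. Requesting a covariate absent from the model is an error.
#' @return An object of class `importance_table` (data frame with columns
#'   `component`, `importance`; rows ordered by decreasing importance, the
#'   autoregressive share last).
#' @export
variable_importance <- function(data, full, covariates = NULL) {
  stopifnot(inherits(data, "aligned_dataset"), inherits(full, "gamm_fit"))
  model_terms <- names(full$gam$terms)
  if (length(model_terms) == 0)
    stop("the full model has no covariates to score")
  if (is.null(covariates)) covariates <- model_terms
  absent <- setdiff(covariates, model_terms)
  if (length(absent))
    stop("importance is undefined for covariates absent from the model: ",
         paste(absent, collapse = ", "))

  ws <- full$gam$workspace
  rows <- full$gam$rows
  imp <- vapply(covariates, function(tm) {
    red_terms <- setdiff(model_terms, tm)
    red <- fit_terms(ws, red_terms)
    res_grid <- rep(NA_real_, length(data$grid))
    res_grid[rows] <- red$residuals
    red_arma <- fit_arma(res_grid, full$arma$spec)
    red_total <- 100 * (1 - red_arma$n_eff * red_arma$sigma2 / full$gam$tss)
    full$total_deviance_explained - red_total
  }, numeric(1))

  ar_share <- full$total_deviance_explained - full$gam$deviance_explained
  out <- data.frame(
    component = c(covariates[order(-imp)], "autoregressive"),
    importance = c(unname(imp[order(-imp)]), ar_share),
    stringsAsFactors = FALSE)
  class(out) <- c("importance_table", class(out))
  out
}

#' Write a structured text report for a fitted two-step GAMM
#'
#' @param gamm A `gamm_fit`.
#' @param file Connection or path ("" prints to the console).
#' @return Invisibly, the lines written.
#' @export
report_gamm <- function(gamm, file = "") {
  g <- gamm$gam
  cmp <- compare_gam_gamm(gamm)
  lines <- c(
    "two-step GAMM report",
    "====================",
    sprintf("site: %s", g$site),
    sprintf("n (complete cases): %d", g$n),
    "definition: total deviance explained = 100*(1 - SS(one-step innovations)/TSS)",
    "",
    "[additive stage]",
    sprintf("terms: %s", paste(names(g$terms), collapse = " + ")),
    vapply(g$terms, function(tm) sprintf("  s(%s): edf=%.3f lambda=%.4g",
                                         tm$label, tm$edf, tm$lambda),
           character(1)),
    sprintf("edf_total=%.3f AIC=%.3f deviance_explained=%.2f%%",
            g$edf_total, g$aic, g$deviance_explained),
    "",
    "[error stage]",
    sprintf("order: %s", format(gamm$arma$spec)),
    sprintf("ar: %s", paste(signif(gamm$arma$ar, 5), collapse = " ")),
    sprintf("ma: %s", paste(signif(gamm$arma$ma, 5), collapse = " ")),
    sprintf("sigma2=%.5g loglik=%.4f aic=%.4f", gamm$arma$sigma2,
            gamm$arma$loglik, gamm$arma$aic),
    "",
    "[comparison]",
    sprintf("%-5s aAIC=%.2f deviance=%.2f%%", cmp$model, cmp$aaic,
            cmp$deviance_explained))
  writeLines(lines, con = file)
  invisible(lines)
}
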