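# Additive-model stage: penalized thin-plate regression spline smooths with
# per-term smoothing parameters chosen by Gaussian AIC, fitted jointly by
# penalized least squares.

#' Build a penalized thin-plate spline basis for one covariate
#'
#' Constructs a low-rank thin-plate regression spline basis (eigen-reduced,
#' curvature penalty) with the sum-to-zero constraint absorbed, so the term
#' is identifiable next to an intercept.  The rank is `max_df + 1` before the
#' constraint, leaving `max_df` columns and a maximum attainable effective
#' degrees of freedom of exactly `max_df` (default 6, the cap used to keep
#' smooths from chasing short-term fluctuations).
#'
#' @param x Numeric covariate values (no missing values).
#' @param max_df Maximum effective degrees of freedom of the smooth.
#' @param label Covariate name used in reports.
#' @return An object of class `smooth_basis` with the design matrix `X`
#'   (centered columns), penalty `S` (symmetric positive semi-definite, its
#'   null space containing the linear trend), and the underlying smooth
#'   construction object used for prediction.
#' @export
build_smooth_basis <- function(x, max_df = 6L, label = "x") {
  if (anyNA(x)) stop("basis construction requires complete x")
  n_distinct <- length(unique(x))
  if (n_distinct < max_df + 2L)
    stop("degenerate covariate '", label, "': needs at least ", max_df + 2L,
         " distinct values, has ", n_distinct)
  df <- data.frame(x = as.numeric(x))
  sm <- mgcv::smoothCon(mgcv::s(x, k = max_df + 1L, bs = "tp"),
                        data = df, knots = NULL, absorb.cons = TRUE)[[1]]
  X <- sm$X
  S <- sm$S[[1]]
  # reference smoothing scale: lambda of this order balances the penalty
  # against the data term, centring the log-lambda search window
  lambda0 <- sum(colSums(X^2)) / max(sum(diag(S)), .Machine$double.eps)
  structure(list(label = label, sm = sm, X = X, S = S,
                 max_df = as.integer(max_df), lambda0 = lambda0,
                 x_range = range(x)),
            class = "smooth_basis")
}

# Evaluate the (centered) basis at new covariate values.
predict_basis <- function(basis, x_new) {
  mgcv::PredictMat(basis$sm, data.frame(x = as.numeric(x_new)))
}

# ---- penalized least-squares workspace -------------------------------------
# Precomputes the joint design and its cross-products once per dataset, so
# that stepwise selection can fit many term subsets without touching the
# n-row design again (all lambda-search linear algebra is p x p).

gam_workspace <- function(y, covariates, candidates, max_df = 6L) {
  n <- length(y)
  bases <- lapply(candidates, function(nm)
    build_smooth_basis(covariates[[nm]], max_df = max_df, label = nm))
  names(bases) <- candidates
  p_each <- vapply(bases, function(b) ncol(b$X), integer(1))
  X <- cbind(`(Intercept)` = rep(1, n),
             do.call(cbind, lapply(bases, function(b) b$X)))
  # column index blocks per term (first column is the intercept)
  idx <- vector("list", length(candidates))
  names(idx) <- candidates
  at <- 2L
  for (i in seq_along(candidates)) {
    idx[[i]] <- at:(at + p_each[i] - 1L)
    at <- at + p_each[i]
  }
  ybar <- mean(y)
  list(y = y, n = n, X = X, XtX = crossprod(X), Xty = drop(crossprod(X, y)),
       yty = sum(y^2), tss = sum((y - ybar)^2), ybar = ybar,
       bases = bases, idx = idx, max_df = max_df)
}

# Penalized normal-equation solve for a given term subset and lambdas.
# Returns coefficients, rss, edf per term, total edf (incl. intercept).
pls_solve <- function(ws, terms, lambda) {
  cols <- c(1L, unlist(ws$idx[terms], use.names = FALSE))
  A <- ws$XtX[cols, cols, drop = FALSE]
  M <- A
  pos <- 2L
  for (tm in terms) {
    b <- ws$bases[[tm]]
    k <- ncol(b$X)
    blk <- pos:(pos + k - 1L)
    M[blk, blk] <- M[blk, blk] + lambda[[tm]] * b$S
    pos <- pos + k
  }
  R <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(R))
    stop("singular penalized design; covariates may be collinear ",
         "(see vif_screen)")
  b_rhs <- ws$Xty[cols]
  beta <- backsolve(R, backsolve(R, b_rhs, transpose = TRUE))
  # influence-matrix trace by blocks: tr(M^-1 A) restricted to each term
  H <- backsolve(R, backsolve(R, A, transpose = TRUE))
  dH <- diag(H)
  edf <- numeric(length(terms)); names(edf) <- terms
  pos <- 2L
  for (i in seq_along(terms)) {
    k <- ncol(ws$bases[[terms[i]]]$X)
    edf[i] <- sum(dH[pos:(pos + k - 1L)])
    pos <- pos + k
  }
  rss <- ws$yty - 2 * sum(beta * b_rhs) + drop(crossprod(beta, A %*% beta))
  rss <- max(rss, 0)
  list(beta = beta, cols = cols, rss = rss, edf = edf,
       edf_total = dH[1] + sum(edf), M = M, R = R, A = A)
}

gaussian_aic <- function(n, rss, edf_total) {
  n * log(max(rss, 1e-300) / n) + 2 * (edf_total + 1)
}

# Coordinate-wise smoothing-parameter selection: each log10(lambda) is
# optimized in turn against the joint Gaussian AIC, cycling until the AIC
# stabilizes (relative change < 1e-6, at most 50 cycles).
optimize_lambdas <- function(ws, terms, lambda = NULL) {
  if (length(terms) == 0)
    return(list(lambda = setNames(numeric(0), character(0))))
  if (is.null(lambda)) {
    lambda <- setNames(vapply(terms, function(tm) ws$bases[[tm]]$lambda0,
                              numeric(1)), terms)
    fixed <- FALSE
  } else {
    lambda <- lambda[terms]
    fixed <- TRUE
  }
  if (fixed) return(list(lambda = lambda))

  aic_of <- function(lam) {
    f <- pls_solve(ws, terms, as.list(lam))
    gaussian_aic(ws$n, f$rss, f$edf_total)
  }
  cur <- aic_of(lambda)
  for (cycle in seq_len(50)) {
    prev <- cur
    for (tm in terms) {
      l0 <- ws$bases[[tm]]$lambda0
      obj <- function(loglam) {
        lam <- lambda
        lam[tm] <- l0 * 10^loglam
        aic_of(lam)
      }
      op <- optimize(obj, interval = c(-8, 8), tol = 1e-4)
      lambda[tm] <- l0 * 10^op$minimum
      cur <- op$objective
    }
    if (abs(prev - cur) < 1e-6 * (abs(prev) + 1)) break
  }
  list(lambda = lambda)
}

fit_terms <- function(ws, terms, lambda = NULL) {
  sel <- optimize_lambdas(ws, terms, lambda)
  lam <- sel$lambda
  if (length(terms) == 0) {
    fitted <- rep(ws$ybar, ws$n)
    res <- ws$y - fitted
    rss <- sum(res^2)
    out <- list(beta = ws$ybar, cols = 1L, rss = rss,
                edf = setNames(numeric(0), character(0)), edf_total = 1,
                M = ws$XtX[1, 1, drop = FALSE], A = ws$XtX[1, 1, drop = FALSE])
  } else {
    out <- pls_solve(ws, terms, as.list(lam))
    fitted <- drop(ws$X[, out$cols, drop = FALSE] %*% out$beta)
    res <- ws$y - fitted
  }
  aic <- gaussian_aic(ws$n, out$rss, out$edf_total)
  sigma2 <- out$rss / max(ws$n - out$edf_total, 1)
  Vp <- sigma2 * chol2inv(chol(out$M))
  list(terms = terms, lambda = lam, beta = out$beta, cols = out$cols,
       fitted = fitted, residuals = res, rss = out$rss, tss = ws$tss,
       edf = out$edf, edf_total = out$edf_total, aic = aic,
       sigma2 = sigma2, Vp = Vp,
       deviance_explained = 100 * (1 - out$rss / ws$tss))
}

# ---- public fitting interface ----------------------------------------------

#' Fit a penalized additive model (GAM stage)
#'
#' Fits `nitrate ~ intercept + sum of smooths` by penalized least squares on
#' the complete-case rows, with each smooth a thin-plate regression spline
#' capped at `max_df` effective degrees of freedom and each smoothing
#' parameter chosen to minimize the Gaussian AIC
#' `n log(rss/n) + 2 (edf_total + 1)` by coordinate-wise search on
#' log(lambda).  Serial correlation is deliberately ignored at this stage;
#' it is handled by the ARIMA model on the residuals.
#'
#' @param data An [aligned_dataset()].
#' @param terms Character vector of covariate names to include as smooths
#'   (may be empty for the intercept-only model).
#' @param max_df Per-smooth effective-df cap (default 6).
#' @param lambda Optional named vector of fixed smoothing parameters,
#'   bypassing AIC selection (used for diagnostics such as the large-lambda
#'   linear limit).
#' @param candidates Covariate set defining the complete-case rows; defaults
#'   to `terms`. Supplying the full candidate set keeps AIC comparable
#'   across nested models during selection.
#' @return An object of class `gam_fit`.
#' @export
fit_penalized_gam <- function(data, terms, max_df = 6L, lambda = NULL,
                              candidates = NULL) {
  stopifnot(inherits(data, "aligned_dataset"))
  if (is.null(candidates)) candidates <- terms
  if (!all(terms %in% candidates)) stop("terms must be a subset of candidates")
  rows <- complete_rows(data, candidates)
  need <- 1 + max_df * length(terms)
  if (length(rows) <= need)
    stop("too few complete-case rows (", length(rows),
         ") for the effective-df budget (", need, ")")
  y <- data$response[rows]
  covs <- data$covariates[rows, , drop = FALSE]
  ws <- gam_workspace(y, covs, candidates, max_df = max_df)
  f <- fit_terms(ws, terms, lambda = lambda)
  as_gam_fit(f, ws, data, rows)
}

as_gam_fit <- function(f, ws, data, rows) {
  res_grid <- rep(NA_real_, length(data$grid))
  res_grid[rows] <- f$residuals
  term_info <- lapply(f$terms, function(tm) {
    b <- ws$bases[[tm]]
    k <- ncol(b$X)
    pos <- which(f$terms == tm)
    offset <- 1L + if (pos > 1)
      sum(vapply(f$terms[seq_len(pos - 1)],
                 function(t2) ncol(ws$bases[[t2]]$X), integer(1))) else 0L
    list(label = tm, basis = b, coef = f$beta[(offset + 1):(offset + k)],
         coef_idx = (offset + 1):(offset + k),
         lambda = unname(f$lambda[tm]), edf = unname(f$edf[tm]))
  })
  names(term_info) <- f$terms
  structure(list(
    intercept = f$beta[1], terms = term_info,
    fitted = f$fitted, residuals = f$residuals, residuals_grid = res_grid,
    rows = rows, n = ws$n, rss = f$rss, tss = f$tss,
    edf_total = f$edf_total, aic = f$aic, sigma2 = f$sigma2, Vp = f$Vp,
    deviance_explained = f$deviance_explained,
    site = data$site, workspace = ws
  ), class = "gam_fit")
}

#' @export
print.gam_fit <- function(x, ...) {
  cat("Penalized additive model (", x$site, "), n = ", x$n, "\n", sep = "")
  if (length(x$terms) == 0) {
    cat("  intercept-only model\n")
  } else {
    for (tm in x$terms)
      cat(sprintf("  s(%s): edf = %.2f, lambda = %.3g\n",
                  tm$label, tm$edf, tm$lambda))
  }
  cat(sprintf("  edf_total = %.2f, AIC = %.2f, deviance explained = %.1f%%\n",
              x$edf_total, x$aic, x$deviance_explained))
  invisible(x)
}

#' Stepwise AIC selection over smooth terms
#'
#' Bidirectional stepwise search over whole smooth terms, starting from the
#' full candidate set (mirroring a screen-then-prune workflow).  At each
#' step every single-term deletion and addition is scored by the Gaussian
#' AIC (with smoothing parameters re-optimized per model); the best move is
#' accepted only if it strictly lowers the AIC, ties broken by candidate
#' order.  Complete cases are defined by the full candidate set so AICs are
#' comparable across models.
#'
#' @param data An [aligned_dataset()].
#' @param candidates Character vector of candidate covariate names.
#' @param max_df Per-smooth effective-df cap (default 6).
#' @return The AIC-best `gam_fit`, with attribute `trace` (data frame of
#'   visited models and AICs).
#' @export
stepwise_select_gam <- function(data, candidates, max_df = 6L) {
  stopifnot(inherits(data, "aligned_dataset"), length(candidates) >= 1)
  rows <- complete_rows(data, candidates)
  if (length(rows) <= 1 + max_df * length(candidates))
    stop("too few complete-case rows for the full candidate model")
  y <- data$response[rows]
  covs <- data$covariates[rows, , drop = FALSE]
  ws <- gam_workspace(y, covs, candidates, max_df = max_df)

  fits <- new.env(parent = emptyenv())
  fit_cached <- function(terms) {
    key <- if (length(terms)) paste(terms, collapse = "+") else "(intercept)"
    if (is.null(fits[[key]])) fits[[key]] <- fit_terms(ws, terms)
    fits[[key]]
  }

  current <- candidates
  cur_fit <- fit_cached(current)
  trace <- data.frame(step = 0L, model = paste(current, collapse = "+"),
                      aic = cur_fit$aic, move = "start",
                      stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    step <- step + 1L
    best_move <- NULL
    best_aic <- cur_fit$aic
    # deletions then additions, each in candidate order (deterministic
    # tie-break: strict improvement required, first best kept)
    for (tm in current) {
      f <- fit_cached(setdiff(current, tm))
      if (f$aic < best_aic - 1e-10) { best_aic <- f$aic
        best_move <- list(type = "drop", term = tm, fit = f) }
    }
    for (tm in setdiff(candidates, current)) {
      f <- fit_cached(c(current, tm))
      if (f$aic < best_aic - 1e-10) { best_aic <- f$aic
        best_move <- list(type = "add", term = tm, fit = f) }
    }
    if (is.null(best_move)) break
    current <- if (best_move$type == "drop") setdiff(current, best_move$term)
               else c(current, best_move$term)
    # keep candidate ordering stable in the model label
    current <- candidates[candidates %in% current]
    cur_fit <- best_move$fit
    trace <- rbind(trace, data.frame(
      step = step, model = paste(current, collapse = "+"),
      aic = cur_fit$aic, move = paste(best_move$type, best_move$term),
      stringsAsFactors = FALSE))
  }
  out <- as_gam_fit(cur_fit, ws, data, rows)
  attr(out, "trace") <- trace
  out
}

#' Partial-effect curves with standard errors
#'
#' Tabulates each fitted smooth \eqn{s_k} over an equally spaced grid within
#' the observed covariate range, with pointwise standard errors from the
#' penalized-fit covariance \eqn{\hat\sigma^2 (X'X + \sum \lambda_k S_k)^{-1}}.
#' Curves are centered over the data by construction (sum-to-zero
#' constraint), so values are expected changes in nitrate relative to the
#' covariate's average contribution.
#'
#' @param fit A `gam_fit`.
#' @param grid_points Number of evaluation points per covariate (>= 2).
#' @return A data frame with columns `covariate`, `value`, `effect`, `se`.
#' @export
evaluate_partial_effects <- function(fit, grid_points = 100L) {
  stopifnot(inherits(fit, "gam_fit"))
  if (grid_points < 2) stop("grid_points must be at least 2")
  out <- lapply(fit$terms, function(tm) {
    xs <- seq(tm$basis$x_range[1], tm$basis$x_range[2],
              length.out = grid_points)
    Xp <- predict_basis(tm$basis, xs)
    eff <- drop(Xp %*% tm$coef)
    Vk <- fit$Vp[tm$coef_idx, tm$coef_idx, drop = FALSE]
    se <- sqrt(pmax(rowSums((Xp %*% Vk) * Xp), 0))
    data.frame(covariate = tm$label, value = xs, effect = eff, se = se,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
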