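# Reading sensor tables, quality filtering, alignment of multi-rate series
# to the 15-minute nitrate grid, and multicollinearity screening.

#' Read a column-mapping dialect file
#'
#' A dialect is a small `key = value` text file mapping the columns of a
#' delimited sensor table onto the fields of a sensor record. Required keys:
#' `timestamp`, `value`, `variable` (the variable name the file carries).
#' Optional: `flag` (quality-flag column, non-zero/true means anomalous) and
#' `sep` (field separator, default comma).
#'
#' @param path Path to the dialect file.
#' @return A named list.
#' @export
read_dialect <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  bad <- !grepl("=", lines, fixed = TRUE)
  if (any(bad)) stop("malformed dialect line: ", lines[bad][1])
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  setNames(as.list(vals), keys)
}

SENSOR_VARIABLES <- c("nitrate", "specific_conductance", "dissolved_oxygen",
                      "temperature", "turbidity", "elevation")

#' Read one sensor variable's table into sensor records
#'
#' Parses a delimited text file of timestamped measurements using a dialect
#' (see [read_dialect()]; a named list works too). Rows whose timestamp or
#' value fail to parse are dropped, with the count reported via a message
#' and in the `rejected` attribute. Timestamps are read as ISO-8601 UTC.
#'
#' @param path Path to the delimited file.
#' @param dialect Named list or dialect-file path with entries `timestamp`,
#'   `value`, `variable`, optional `flag` and `sep`.
#' @return A data frame of class `sensor_records` with columns `timestamp`
#'   (POSIXct UTC), `variable`, `value`, `qc_flag`, sorted by timestamp.
#' @export
read_sensor_table <- function(path, dialect) {
  if (is.character(dialect) && length(dialect) == 1) dialect <- read_dialect(dialect)
  for (k in c("timestamp", "value", "variable"))
    if (is.null(dialect[[k]])) stop("dialect is missing required key '", k, "'")
  sep <- if (!is.null(dialect$sep)) dialect$sep else ","
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (nrow(raw) == 0) stop("empty input file: ", path)
  for (col in c(dialect$timestamp, dialect$value))
    if (!col %in% names(raw)) stop("missing required column '", col, "' in ", path)
  ts <- as.POSIXct(raw[[dialect$timestamp]],
                   tz = "UTC", tryFormats = c("%Y-%m-%dT%H:%M:%SZ",
                                              "%Y-%m-%dT%H:%M:%S",
                                              "%Y-%m-%d %H:%M:%S",
                                              "%Y-%m-%d %H:%M"))
  val <- suppressWarnings(as.numeric(raw[[dialect$value]]))
  flag <- if (!is.null(dialect$flag) && dialect$flag %in% names(raw)) {
    fl <- raw[[dialect$flag]]
    if (is.character(fl)) tolower(fl) %in% c("1", "true", "t", "yes") else as.logical(fl) %in% TRUE
  } else rep(FALSE, nrow(raw))
  keep <- !is.na(ts) & !is.na(val)
  n_rej <- sum(!keep)
  if (n_rej > 0)
    message("read_sensor_table: rejected ", n_rej, " unparseable row(s) in ",
            basename(path))
  out <- data.frame(timestamp = ts[keep], variable = dialect$variable,
                    value = val[keep], qc_flag = flag[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- n_rej
  class(out) <- c("sensor_records", class(out))
  out
}

#' Combine sensor record tables
#' @param ... `sensor_records` data frames.
#' @return A single `sensor_records` data frame.
#' @export
bind_sensor_records <- function(...) {
  out <- do.call(rbind, lapply(list(...), function(x) {
    class(x) <- "data.frame"; x
  }))
  rownames(out) <- NULL
  class(out) <- c("sensor_records", class(out))
  out
}

#' Align covariate series to the 15-minute nitrate grid
#'
#' Builds a regular 15-minute grid spanning the nitrate record, places
#' nitrate values on it (exact timestamp match), and matches each covariate
#' measurement to its nearest grid point within `tolerance` seconds. Records
#' flagged anomalous are removed before matching; covariate measurements not
#' matching any grid point are discarded (only measurements coincident with
#' a nitrate sampling time are analysed).
#'
#' @param records A `sensor_records` data frame containing a `nitrate` series
#'   and any covariate series.
#' @param tolerance Matching tolerance in seconds (< 900); default 60.
#' @param site Site label carried into the result.
#' @return An [aligned_dataset()].
#' @export
align_to_response_grid <- function(records, tolerance = 60, site = "unknown") {
  stopifnot(tolerance > 0, tolerance < 900)
  n_anom <- sum(records$qc_flag)
  records <- records[!records$qc_flag, , drop = FALSE]
  nit <- records[records$variable == "nitrate", , drop = FALSE]
  if (nrow(nit) == 0) stop("no (non-anomalous) nitrate records: nothing to align to")
  t0 <- min(nit$timestamp); t1 <- max(nit$timestamp)
  grid <- seq(t0, t1, by = 900)
  # response: exact placement on the grid (nitrate is published on it)
  pos <- round(as.numeric(nit$timestamp - t0, units = "secs") / 900) + 1
  on_grid <- abs(as.numeric(nit$timestamp - t0, units = "secs") - (pos - 1) * 900) < 1
  response <- rep(NA_real_, length(grid))
  response[pos[on_grid]] <- nit$value[on_grid]

  covs <- list()
  for (v in setdiff(unique(records$variable), "nitrate")) {
    rv <- records[records$variable == v, , drop = FALSE]
    covs[[v]] <- match_nearest(grid, rv$timestamp, rv$value, tolerance)
  }
  qc <- list(anomalous_removed = n_anom,
             nitrate_records = nrow(nit))
  aligned_dataset(grid, response,
                  if (length(covs)) as.data.frame(covs) else
                    data.frame(row.names = seq_along(grid)),
                  site = site, qc = qc)
}

# nearest-neighbour match of (t_obs, v_obs) onto grid times, within tol secs
match_nearest <- function(grid, t_obs, v_obs, tol) {
  out <- rep(NA_real_, length(grid))
  if (length(t_obs) == 0) return(out)
  o <- order(t_obs)
  t_obs <- as.numeric(t_obs)[o]; v_obs <- v_obs[o]
  g <- as.numeric(grid)
  i <- findInterval(g, t_obs)
  lo <- pmax(i, 1L); hi <- pmin(i + 1L, length(t_obs))
  d_lo <- abs(g - t_obs[lo]); d_hi <- abs(g - t_obs[hi])
  use_hi <- d_hi < d_lo
  best <- ifelse(use_hi, hi, lo)
  d_best <- pmin(d_lo, d_hi)
  ok <- i >= 0 & d_best <= tol
  out[ok] <- v_obs[best[ok]]
  out
}

#' Apply the standard covariate transforms
#'
#' Turbidity distributions are strongly right-skewed, so turbidity is
#' replaced by `log(turbidity + 1)` (natural log). The transform is recorded
#' in the dataset metadata and a second application is refused.
#'
#' @param data An [aligned_dataset()] with a `turbidity` column in FNU.
#' @return The transformed dataset.
#' @export
transform_covariates <- function(data) {
  stopifnot(inherits(data, "aligned_dataset"))
  if ("log1p_turbidity" %in% data$transforms)
    stop("transform_covariates has already been applied to this dataset")
  if (!"turbidity" %in% names(data$covariates))
    stop("no turbidity column to transform")
  tb <- data$covariates$turbidity
  if (any(tb < 0, na.rm = TRUE))
    stop("negative turbidity values are invalid (FNU scale)")
  data$covariates$turbidity <- log1p(tb)
  data$transforms <- c(data$transforms, "log1p_turbidity")
  data
}

#' Variance-inflation-factor screen for multicollinearity
#'
#' Computes, for each candidate covariate, `VIF = 1 / (1 - R^2)` from the
#' least-squares regression of that covariate on all other current
#' candidates (with intercept), on complete-case rows. Candidates are
#' removed greedily — largest VIF first, VIFs recomputed after each removal —
#' until all remaining VIFs fall below `threshold` (default 6, the screen
#' used to discard strongly multi-collinear water-quality variables).
#'
#' @param data An [aligned_dataset()].
#' @param candidates Character vector of covariate names (>= 2).
#' @param threshold VIF threshold (default 6).
#' @return An object of class `vif_report`: list with `vif` (named vector on
#'   the retained set), `retained`, `dropped`, and `steps` (per-elimination
#'   VIF tables).
#' @export
vif_screen <- function(data, candidates, threshold = 6) {
  stopifnot(inherits(data, "aligned_dataset"), length(candidates) >= 2)
  rows <- complete_rows(data, candidates)
  if (length(rows) < length(candidates) + 2)
    stop("too few complete rows (", length(rows),
         ") to identify the auxiliary regressions")
  X <- as.matrix(data$covariates[rows, candidates, drop = FALSE])
  current <- candidates
  dropped <- character(0)
  steps <- list()
  repeat {
    v <- compute_vifs(X[, current, drop = FALSE])
    steps[[length(steps) + 1]] <- v
    if (length(current) < 2 || all(v < threshold, na.rm = TRUE)) break
    # deterministic: largest VIF goes; among ties (e.g. an exactly collinear
    # group, all infinite) the latest-listed candidate is dropped, keeping
    # earlier-listed covariates that the user prioritized
    vmax <- max(v)
    worst <- current[max(which(v == vmax | (!is.finite(v) & !is.finite(vmax))))]
    dropped <- c(dropped, worst)
    current <- setdiff(current, worst)
  }
  structure(list(vif = v, retained = current, dropped = dropped,
                 threshold = threshold, steps = steps),
            class = "vif_report")
}

compute_vifs <- function(X) {
  m <- ncol(X)
  out <- setNames(numeric(m), colnames(X))
  for (j in seq_len(m)) {
    yj <- X[, j]
    Zj <- cbind(1, X[, -j, drop = FALSE])
    fit <- qr(Zj)
    res <- qr.resid(fit, yj)
    tssj <- sum((yj - mean(yj))^2)
    r2 <- if (tssj <= 0) 1 else 1 - sum(res^2) / tssj
    out[j] <- if (r2 >= 1 - 1e-12) Inf else max(1 / (1 - r2), 1)
  }
  out
}

#' @export
print.vif_report <- function(x, ...) {
  cat("VIF screen (threshold ", x$threshold, ")\n", sep = "")
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  if (length(x$dropped))
    cat("  dropped :", paste(x$dropped, collapse = ", "), "\n")
  print(round(x$vif, 3))
  invisible(x)
}

#' Write an aligned dataset as CSV with a metadata sidecar
#'
#' @param data An [aligned_dataset()].
#' @param path Output CSV path; the sidecar is written at `<path>.meta`.
#' @return `path`, invisibly.
#' @export
write_aligned_dataset <- function(data, path) {
  df <- data.frame(timestamp = format(data$grid, "%Y-%m-%dT%H:%M:%SZ",
                                      tz = "UTC"),
                   nitrate = data$response,
                   data$covariates, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- c(paste0("site=", data$site),
            paste0("transforms=", paste(data$transforms, collapse = ";")),
            vapply(names(data$qc), function(k)
              paste0("qc_", k, "=", data$qc[[k]]), character(1)))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' Read an aligned dataset written by [write_aligned_dataset()]
#' @param path CSV path (sidecar `<path>.meta` read if present).
#' @return An [aligned_dataset()].
#' @export
read_aligned_dataset <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  grid <- as.POSIXct(df$timestamp, tz = "UTC",
                     format = "%Y-%m-%dT%H:%M:%SZ")
  covs <- df[, setdiff(names(df), c("timestamp", "nitrate")), drop = FALSE]
  site <- "unknown"; transforms <- character(0)
  meta_path <- paste0(path, ".meta")
  if (file.exists(meta_path)) {
    kv <- read_dialect(meta_path)
    if (!is.null(kv$site)) site <- kv$site
    if (!is.null(kv$transforms) && nzchar(kv$transforms))
      transforms <- strsplit(kv$transforms, ";", fixed = TRUE)[[1]]
  }
  aligned_dataset(grid, df$nitrate, covs, site = site,
                  transforms = transforms)
}
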