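# The common container for model fitting: nitrate on a regular 15-minute
# grid with covariates matched to the same grid.

#' Construct an aligned dataset
#'
#' Bundles the response (nitrate) and covariates on a common 15-minute grid.
#' A continuous `time` covariate in days since the first grid point is always
#' present, mirroring the use of a smooth time trend alongside the
#' water-quality covariates.
#'
#' @param grid `POSIXct` vector of grid timestamps, strictly increasing with
#'   constant 15-minute spacing.
#' @param response Numeric nitrate values on the grid (μmol/L), `NA` where
#'   missing.
#' @param covariates Data frame of covariate columns on the grid (`NA` where
#'   missing). A `time` column is added if absent.
#' @param site Site label.
#' @param transforms Character vector of transform tags already applied.
#' @param qc Named list of quality-control counts (free-form).
#' @return An object of class `aligned_dataset`.
#' @export
aligned_dataset <- function(grid, response, covariates, site = "unknown",
                            transforms = character(0), qc = list()) {
  grid <- as.POSIXct(grid, tz = "UTC")
  n <- length(grid)
  if (n < 2) stop("grid must have at least two points")
  sp <- as.numeric(diff(grid), units = "mins")
  if (any(abs(sp - 15) > 1e-6))
    stop("grid spacing must be exactly 15 minutes")
  if (length(response) != n) stop("response length must match grid")
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != n) stop("covariate rows must match grid")
  if (!"time" %in% names(covariates))
    covariates$time <- as.numeric(grid - grid[1], units = "days")
  if (is.unsorted(covariates$time)) stop("time column must be non-decreasing")
  structure(list(grid = grid, response = as.numeric(response),
                 covariates = covariates, site = site,
                 transforms = transforms, qc = qc),
            class = "aligned_dataset")
}

#' @export
print.aligned_dataset <- function(x, ...) {
  cat("Aligned 15-minute sensor dataset —", x$site, "\n")
  cat(sprintf("  %d grid points from %s to %s\n", length(x$grid),
              format(x$grid[1], tz = "UTC"), format(x$grid[length(x$grid)], tz = "UTC")))
  cat(sprintf("  response: %d observed / %d missing\n",
              sum(!is.na(x$response)), sum(is.na(x$response))))
  cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  if (length(x$transforms))
    cat("  transforms:", paste(x$transforms, collapse = ", "), "\n")
  invisible(x)
}

# Rows usable for fitting: response and every named covariate non-missing.
complete_rows <- function(data, terms) {
  stopifnot(inherits(data, "aligned_dataset"))
  miss <- is.na(data$response)
  for (tm in terms) {
    if (!tm %in% names(data$covariates))
      stop("unknown covariate: ", tm)
    miss <- miss | is.na(data$covariates[[tm]])
  }
  which(!miss)
}

#' Per-variable summary table
#'
#' Reports n, mean, median, quartiles and range for the response and each
#' covariate. Quantiles use the linear-interpolation (type 7) convention.
#' If the dataset records a log(turbidity + 1) transform, turbidity is
#' summarised back on the raw FNU scale for display.
#'
#' @param data An [aligned_dataset()].
#' @return A data frame with one row per variable.
#' @export
summarise_variables <- function(data) {
  stopifnot(inherits(data, "aligned_dataset"))
  cols <- c(list(response = data$response), as.list(data$covariates))
  out <- lapply(names(cols), function(nm) {
    v <- cols[[nm]]
    if (nm == "turbidity" && "log1p_turbidity" %in% data$transforms)
      v <- expm1(v)  # display scale is raw FNU
    v <- v[!is.na(v)]
    if (length(v) == 0)
      return(data.frame(variable = nm, n = 0L, mean = NA_real_,
                        median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                        min = NA_real_, max = NA_real_))
    qs <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(variable = nm, n = length(v), mean = mean(v),
               median = qs[2], q1 = qs[1], q3 = qs[3],
               min = min(v), max = max(v))
  })
  do.call(rbind, out)
}
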