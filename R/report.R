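#' Mean dose over a region of interest
#'
#' Volume-weighted mean over the voxels intersecting the ROI, with
#' fractional overlap computed by subsampling. The statistical uncertainty
#' is propagated from per-voxel batch uncertainties assuming independence.
#'
#' @param dose a `dose_grid`.
#' @param center ROI center, world mm.
#' @param edge_mm cubic ROI edge, mm.
#' @param subsamples overlap subsampling per axis.
#' @return list with `dose`, `rel_uncertainty`, `n_voxels`.
#' @export
roi_mean_dose <- function(dose, center, edge_mm = 5, subsamples = 3L) {
  stopifnot(inherits(dose, "dose_grid"))
  w <- box_voi_weights(dose$grid, center, edge_mm, subsamples = subsamples)
  sw <- sum(w)
  if (sw <= 0) stop("ROI does not overlap the dose grid")
  m <- sum(dose$dose * w) / sw
  abs_se <- dose$dose * dose$rel_uncertainty
  se <- sqrt(sum((w * abs_se)^2)) / sw
  list(dose = m, rel_uncertainty = if (m > 0) se / m else 0,
       n_voxels = sum(w > 0))
}

#' Percent difference with the measurement as reference
#'
#' `100 * (measured - comparator) / measured`: a comparator above the
#' measurement yields a negative difference.
#'
#' @param measured reference value (> 0).
#' @param comparator value compared against it.
#' @return percent difference.
#' @export
percent_difference <- function(measured, comparator) {
  if (any(measured <= 0)) stop("measured reference must be positive")
  100 * (measured - comparator) / measured
}

#' Assemble the per-probe agreement table
#'
#' One row per probe: measured dose with its chip standard deviation,
#' image-mode and idealized-mode doses with their Monte Carlo relative
#' uncertainties, percent differences against the measurement, and a
#' verdict testing |percent difference (measured vs image mode)| against
#' the adopted expanded uncertainty of the budget. Probes missing from any
#' mode are listed as incomplete rather than failing the report.
#'
#' @param measured list of probe reductions from [reduce_probe()].
#' @param image_mode list of [roi_mean_dose()] results (Gy), same order.
#' @param ideal_mode list of [roi_mean_dose()] results (Gy), same order.
#' @param budget an `uncertainty_budget` from [combine_uncertainty()].
#' @return An `agreement_table` (a data frame with attributes `budget` and
#'   `ranges`).
#' @export
agreement_report <- function(measured, image_mode, ideal_mode, budget) {
  n <- length(measured)
  rows <- lapply(seq_len(n), function(k) {
    m <- measured[[k]]
    img <- if (k <= length(image_mode)) image_mode[[k]] else NULL
    idl <- if (k <= length(ideal_mode)) ideal_mode[[k]] else NULL
    complete <- !is.null(img) && !is.null(idl)
    data.frame(
      probe = m$probe_id,
      measured_gy = m$dose_gy,
      measured_sd_pct = m$sd_pct,
      image_gy = if (!is.null(img)) img$dose else NA_real_,
      image_mc_pct = if (!is.null(img)) 100 * img$rel_uncertainty else NA_real_,
      ideal_gy = if (!is.null(idl)) idl$dose else NA_real_,
      ideal_mc_pct = if (!is.null(idl)) 100 * idl$rel_uncertainty else NA_real_,
      pct_diff_image = if (!is.null(img))
        percent_difference(m$dose_gy, img$dose) else NA_real_,
      pct_diff_ideal = if (!is.null(idl))
        percent_difference(m$dose_gy, idl$dose) else NA_real_,
      complete = complete)
  })
  tab <- do.call(rbind, rows)
  tab$within_uncertainty <- !is.na(tab$pct_diff_image) &
    abs(tab$pct_diff_image) <= budget$adopted_percent
  ok <- !is.na(tab$pct_diff_image)
  ranges <- list(
    image = if (any(ok)) range(tab$pct_diff_image[ok]) else c(NA, NA),
    ideal = if (any(!is.na(tab$pct_diff_ideal)))
      range(tab$pct_diff_ideal, na.rm = TRUE) else c(NA, NA))
  structure(tab, budget = budget, ranges = ranges,
            class = c("agreement_table", "data.frame"))
}

#' @export
print.agreement_table <- function(x, digits = 3, ...) {
  budget <- attr(x, "budget")
  ranges <- attr(x, "ranges")
  cat("Per-probe measured vs computed absorbed dose\n")
  df <- as.data.frame(x)
  df$complete <- NULL
  print(format(df, digits = digits), row.names = FALSE)
  cat(sprintf("\nPercent difference (measured - image mode): %.2f%% to %.2f%%\n",
              ranges$image[1], ranges$image[2]))
  cat(sprintf("Percent difference (measured - idealized):  %.2f%% to %.2f%%\n",
              ranges$ideal[1], ranges$ideal[2]))
  cat(sprintf("Expanded uncertainty envelope (k = %g): %.1f%%; %d/%d probes within\n",
              budget$k, budget$adopted_percent,
              sum(x$within_uncertainty), nrow(x)))
  invisible(x)
}

#' Write an agreement report to disk
#'
#' Emits the table as CSV, a Markdown summary, and a JSON manifest of every
#' number in the report.
#'
#' @param table an `agreement_table`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_agreement_report <- function(table, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  budget <- attr(table, "budget")
  ranges <- attr(table, "ranges")
  csv <- file.path(dir, "agreement.csv")
  utils::write.csv(as.data.frame(table), csv, row.names = FALSE)
  md <- file.path(dir, "agreement.md")
  con <- file(md, "w")
  writeLines(c("# Measured vs image-based absorbed dose", "",
               paste0("Expanded uncertainty (k = ", budget$k, "): ",
                      sprintf("%.1f%%", budget$adopted_percent)),
               "",
               sprintf("Measured - image mode range: %.2f%% to %.2f%%",
                       ranges$image[1], ranges$image[2]),
               sprintf("Measured - idealized range: %.2f%% to %.2f%%",
                       ranges$ideal[1], ranges$ideal[2])), con)
  close(con)
  js <- file.path(dir, "agreement.json")
  jsonlite::write_json(list(table = as.data.frame(table),
                            budget = unclass(budget), ranges = ranges),
                       js, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(csv = csv, md = md, json = js))
}
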