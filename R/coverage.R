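#' Otsu threshold and tissue mask
#'
#' Classic Otsu's method on a 256-bin histogram spanning the image range:
#' the threshold is the bin boundary maximising between-class variance,
#' and tissue is everything above it (bright under fluorescence). A
#' constant image has no separable classes and yields an all-background
#' mask with a warning.
#'
#' @param image Grayscale numeric matrix.
#' @param levels Number of histogram bins (default 256).
#' @return `otsu_threshold()` returns the threshold value (upper edge of
#'   the optimal background bin); `otsu_tissue_mask()` returns a logical
#'   matrix.
#' @export
otsu_threshold <- function(image, levels = 256L) {
  v <- as.numeric(image)
  if (any(!is.finite(v))) stop("image contains non-finite values")
  rng <- range(v)
  if (rng[1] == rng[2]) {
    warning("constant image: no threshold exists, returning +Inf")
    return(Inf)
  }
  breaks <- seq(rng[1], rng[2], length.out = levels + 1L)
  counts <- tabulate(
    pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L), levels),
    nbins = levels)
  p <- counts / sum(counts)
  mids <- (breaks[-1L] + breaks[-(levels + 1L)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[levels]
  # between-class variance for threshold after bin k (k = 1..levels-1)
  k <- seq_len(levels - 1L)
  valid <- w0[k] > 0 & w0[k] < 1
  sb2 <- rep(-Inf, levels - 1L)
  sb2[valid] <- (mu_t * w0[k][valid] - mu0[k][valid])^2 /
    (w0[k][valid] * (1 - w0[k][valid]))
  breaks[which.max(sb2) + 1L]
}

#' @rdname otsu_threshold
#' @export
otsu_tissue_mask <- function(image, levels = 256L) {
  thr <- otsu_threshold(image, levels)
  image > thr
}

#' Physical area of a binary mask
#'
#' `count * pixel_size_um^2 * 1e-8` cm^2.
#'
#' @param mask Logical matrix.
#' @param pixel_size_um Pixel pitch in micrometres.
#' @return Area in cm^2.
#' @export
area_from_mask <- function(mask, pixel_size_um = 0.645) {
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  sum(mask) * pixel_size_um^2 * 1e-8
}

#' Percent surface coverage
#'
#' Imaged tissue area divided by the reference (3D-scan) surface area,
#' as a percentage.
#'
#' @param sim_area_cm2 Imaged (thresholded) tissue area, cm^2.
#' @param surface_area_cm2 Reference surface area, cm^2 (> 0).
#' @return Percentage.
#' @examples
#' coverage_percent(30.64, 67.56)  # 45.35
#' @export
coverage_percent <- function(sim_area_cm2, surface_area_cm2) {
  if (any(surface_area_cm2 <= 0)) stop("surface_area_cm2 must be > 0")
  100 * sim_area_cm2 / surface_area_cm2
}

#' Read a per-case summary table
#'
#' CSV with columns `method` (`manual` or `apps`), `case`,
#' `sim_area_cm2`, `surface_area_cm2` (may be empty), `coverage_pct`
#' (may be empty), `elapsed_min`. A packaged copy of the published
#' case series is at
#' `system.file("extdata", "table1.csv", package = "circumscan")`.
#'
#' @param path CSV path.
#' @return Data frame of case records.
#' @export
read_case_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("method", "case", "sim_area_cm2", "elapsed_min")
  if (!all(need %in% names(df)))
    stop("case table must contain columns: ", paste(need, collapse = ", "))
  if (any(df$sim_area_cm2 < 0, na.rm = TRUE)) stop("areas must be >= 0")
  df
}

#' Summarize a case series
#'
#' Per-method mean and population standard deviation (divisor N — the
#' convention that reproduces the published per-column spreads exactly;
#' the sample SD, divisor N-1, does not) for imaged area, surface area,
#' coverage and elapsed time, printed-table rounding (2 decimals, times
#' to whole minutes, half away from zero). Coverage for cases without
#' their own surface scan is computed against the mean surface area of
#' the scanned cases. Throughput per method is mean imaged area over
#' mean elapsed time (1 decimal); the throughput ratio compares methods
#' before rounding.
#'
#' @param records Data frame from [read_case_table()].
#' @return An object of class `coverage_report`: `summary` (per-method
#'   data frame), `throughput` (named, cm^2/min), `throughput_ratio`.
#' @export
summarize_cases <- function(records) {
  if (nrow(records) == 0L) stop("no case records")
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  if (!"surface_area_cm2" %in% names(records))
    records$surface_area_cm2 <- NA_real_
  cov <- if ("coverage_pct" %in% names(records)) records$coverage_pct
  else rep(NA_real_, nrow(records))
  fill <- is.na(cov)
  if (any(fill)) {
    ref_surface <- mean(records$surface_area_cm2, na.rm = TRUE)
    cov[fill] <- coverage_percent(records$sim_area_cm2[fill], ref_surface)
  }

  methods <- unique(records$method)
  rows <- lapply(methods, function(m) {
    i <- records$method == m
    sa <- records$surface_area_cm2[i]
    data.frame(
      method = m, n = sum(i),
      mean_sim_area_cm2 = round_half_up(mean(records$sim_area_cm2[i]), 2),
      sd_sim_area_cm2 = round_half_up(pop_sd(records$sim_area_cm2[i]), 2),
      mean_surface_area_cm2 =
        if (all(is.na(sa))) NA_real_ else
          round_half_up(mean(sa, na.rm = TRUE), 2),
      sd_surface_area_cm2 =
        if (all(is.na(sa))) NA_real_ else
          round_half_up(pop_sd(sa[!is.na(sa)]), 2),
      mean_coverage_pct = round_half_up(mean(cov[i]), 2),
      sd_coverage_pct = round_half_up(pop_sd(cov[i]), 2),
      mean_elapsed_min = round_half_up(mean(records$elapsed_min[i])),
      sd_elapsed_min = round_half_up(pop_sd(records$elapsed_min[i])))
  })
  summary <- do.call(rbind, rows)
  thr_raw <- vapply(methods, function(m) {
    i <- records$method == m
    mean(records$sim_area_cm2[i]) / mean(records$elapsed_min[i])
  }, 1)
  throughput <- round_half_up(thr_raw, 1)
  ratio <- if (length(thr_raw) >= 2L)
    round_half_up(max(thr_raw) / min(thr_raw), 1) else NA_real_
  structure(list(summary = summary, throughput = throughput,
                 throughput_ratio = ratio),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  cat("throughput (cm^2/min):",
      paste(names(x$throughput), x$throughput, sep = " = ",
            collapse = ", "),
      sprintf("| ratio %.1fx\n", x$throughput_ratio))
  invisible(x)
}

#' Pathology surface sampling fraction
#'
#' Fraction of the specimen surface examined by conventional slide-based
#' pathology: one thin section per gross tissue block.
#'
#' @param section_um Section thickness examined (default 4 um).
#' @param block_um Gross block thickness (default 3000 um).
#' @return Sampling fraction as a percentage.
#' @examples
#' pathology_sampling_fraction()  # 0.1333 %
#' @export
pathology_sampling_fraction <- function(section_um = 4, block_um = 3000) {
  100 * section_um / block_um
}

#' Coverage improvement over pathology sampling
#'
#' Ratio of an imaging method's surface coverage to the pathology
#' sampling fraction (both in percent).
#'
#' @param coverage_pct Imaging surface coverage, percent.
#' @param sampling_fraction_pct Pathology sampling fraction, percent.
#' @return Dimensionless fold improvement.
#' @export
coverage_improvement_factor <- function(coverage_pct,
                                        sampling_fraction_pct =
                                          pathology_sampling_fraction()) {
  coverage_pct / sampling_fraction_pct
}
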