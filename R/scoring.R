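#' Stability weight of an APR
#'
#' The summed per-residue stability contribution of an APR is clipped to
#' \[-5, +5\] kcal/mol and rescaled linearly to \[0, 1\]:
#' `weight = clip((dg_contrib + 5) / 10, 0, 1)`. A weight of 0 marks a
#' thermodynamically stable (protected) APR, 1 an unstable one.
#'
#' @param dg_contrib Summed per-residue delta-G over the APR (kcal/mol).
#' @return Weight(s) in \[0, 1\].
#' @export
stability_weight <- function(dg_contrib) {
  if (any(!is.finite(dg_contrib)))
    stop("dg_contrib must be finite")
  pmin(1, pmax(0, (dg_contrib + 5) / 10))
}

#' Build stretch points from APRs and their stability contributions
#'
#' A stretch point pairs an APR's intrinsic aggregation score (`tango_sum`)
#' with its local stability (`dg_contrib`), the derived weight and the
#' corrected score `tango_sum * weight`. An APR is flagged critical when its
#' corrected score reaches `critical_threshold`.
#'
#' @param aprs An `apr_set` from [detect_aprs()].
#' @param dg_contrib Numeric vector, one summed delta-G per APR (kcal/mol).
#' @param region Optional character vector of region labels (see
#'   [apr_region_label()]); defaults to `NA`.
#' @param chain Chain identifier recorded in the output.
#' @param critical_threshold Corrected-score threshold for criticality,
#'   default 50.
#' @return A data frame of class `stretch_points` with columns `chain`,
#'   `region`, `start`, `end`, `sequence`, `tango_sum`, `dg_contrib`,
#'   `weight`, `corrected_score`, `critical`.
#' @export
make_stretch_points <- function(aprs, dg_contrib, region = NULL,
                                chain = NA_character_,
                                critical_threshold = 50) {
  n <- nrow(aprs)
  if (length(dg_contrib) != n)
    stop("need one dg_contrib per APR (", n, " APRs, ",
         length(dg_contrib), " values)")
  if (any(!is.finite(dg_contrib))) stop("dg_contrib must be finite")
  if (is.null(region)) region <- rep(NA_character_, n)
  w <- if (n) stability_weight(dg_contrib) else numeric(0)
  out <- data.frame(chain = rep(chain, length.out = n),
                    region = region,
                    start = aprs$start, end = aprs$end,
                    sequence = aprs$sequence,
                    tango_sum = aprs$tango_sum,
                    dg_contrib = dg_contrib,
                    weight = w,
                    corrected_score = aprs$tango_sum * w,
                    stringsAsFactors = FALSE)
  out$critical <- out$corrected_score >= critical_threshold
  attr(out, "critical_threshold") <- critical_threshold
  class(out) <- c("stretch_points", class(out))
  out
}

#' Total Solubis score of a set of stretch points
#'
#' Sums the stability-corrected per-APR scores, so the total is dominated by
#' critical APRs; thermodynamically protected APRs (`dg_contrib <= -5`)
#' contribute nothing.
#'
#' @param points A `stretch_points` data frame (possibly covering both
#'   chains of one antibody).
#' @param id Antibody identifier recorded in the report.
#' @return A list of class `solubis_report`: `id`, `solubis_score`,
#'   `total_tango`, `n_aprs`, `n_critical`, `critical_threshold`, `points`.
#' @export
solubis_score <- function(points, id = NA_character_) {
  thr <- attr(points, "critical_threshold")
  if (is.null(thr)) thr <- 50
  structure(list(id = id,
                 solubis_score = sum(points$corrected_score),
                 total_tango = sum(points$tango_sum),
                 n_aprs = nrow(points),
                 n_critical = sum(points$critical),
                 critical_threshold = thr,
                 points = points),
            class = "solubis_report")
}

#' @export
print.solubis_report <- function(x, ...) {
  cat("<solubis report>", if (!is.na(x$id)) x$id else "", "\n")
  cat(sprintf("  Solubis score: %.1f (raw aggregation total %.1f)\n",
              x$solubis_score, x$total_tango))
  cat(sprintf("  APRs: %d, of which critical: %d (threshold %.0f)\n",
              x$n_aprs, x$n_critical, x$critical_threshold))
  invisible(x)
}

#' Two-dimensional stretch-point density
#'
#' Bins stretch points from one or many antibodies on a
#' (`dg_contrib`, `tango_sum`) grid -- the numeric content of a density
#' stretch-plot.
#'
#' @param points A `stretch_points` data frame (rows from many antibodies
#'   may be concatenated with `rbind`).
#' @param dg_breaks,tango_breaks Bin edges (numeric vectors) for the
#'   stability and aggregation axes.
#' @param normalize Report fractions of points instead of counts.
#' @return A data frame with columns `dg_low`, `dg_high`, `tango_low`,
#'   `tango_high`, `count`.
#' @export
stretch_density <- function(points,
                            dg_breaks = seq(-15, 15, by = 2.5),
                            tango_breaks = seq(0, 600, by = 50),
                            normalize = FALSE) {
  if (nrow(points) == 0L) stop("no stretch points to bin")
  xb <- cut(pmin(pmax(points$dg_contrib, min(dg_breaks)), max(dg_breaks)),
            dg_breaks, include.lowest = TRUE)
  yb <- cut(pmin(pmax(points$tango_sum, min(tango_breaks)),
                 max(tango_breaks)),
            tango_breaks, include.lowest = TRUE)
  tab <- table(xb, yb)
  grid <- expand.grid(xi = seq_len(length(dg_breaks) - 1L),
                      yi = seq_len(length(tango_breaks) - 1L))
  count <- as.numeric(tab)[(grid$yi - 1L) * (length(dg_breaks) - 1L) +
                             grid$xi]
  if (normalize) count <- count / nrow(points)
  data.frame(dg_low = dg_breaks[grid$xi], dg_high = dg_breaks[grid$xi + 1L],
             tango_low = tango_breaks[grid$yi],
             tango_high = tango_breaks[grid$yi + 1L],
             count = count)
}
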