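#' Surrogate parameters for the intrinsic aggregation-propensity profile
#'
#' The per-residue score emulates the interface of a beta-aggregation
#' predictor: each residue gets a score in \[0, 100\], with scores >= 5 over
#' runs of >= 5 residues defining aggregation-prone regions (APRs). For a
#' window `w` of five residues the energy is
#' `E_w = sum(h + b) - lambda * |q_w| - gamma * nP(w)`, where `h` is min-max
#' normalized Kyte-Doolittle hydropathy, `b` min-max normalized Chou-Fasman
#' beta-sheet propensity, `q_w` the window net charge (K/R +1, D/E -1) and
#' `nP` the proline count. Residue `i` scores
#' `100 * plogis((max_w E_w - e0) / s)` over the windows containing `i`.
#'
#' The defaults are a fixed, versioned calibration: hydrophobic I/V-rich
#' hexapeptides in a polar context are called as APRs with exact boundaries,
#' while poly-charged and proline-containing controls stay below the
#' APR-calling floor of 5.
#'
#' @param window Window length (and minimum APR length), default 5.
#' @param e0 Logistic midpoint energy.
#' @param s Logistic scale; smaller values sharpen APR boundaries.
#' @param lambda Net-charge penalty per unit window charge.
#' @param gamma Proline penalty per proline in the window.
#' @return A list of class `propensity_params`.
#' @export
propensity_params <- function(window = 5L, e0 = 10, s = 0.3,
                              lambda = 2, gamma = 2) {
  stopifnot(window >= 1L, s > 0)
  structure(list(window = as.integer(window), e0 = e0, s = s,
                 lambda = lambda, gamma = gamma),
            class = "propensity_params")
}

#' Per-residue intrinsic aggregation-propensity profile
#'
#' @param sequence One-letter amino-acid sequence (canonical letters; `X`
#'   allowed and scores 0).
#' @param params A [propensity_params()] set.
#' @return An object of class `propensity_profile`: list with `sequence`,
#'   `scores` (numeric, one value in \[0, 100\] per residue) and `params`.
#' @export
propensity_profile <- function(sequence, params = propensity_params()) {
  sequence <- toupper(sequence)
  aa <- strsplit(sequence, "")[[1]]
  if (!all(aa %in% c(AA1, "X")))
    stop("sequence contains letters outside the canonical alphabet: ",
         paste(unique(aa[!aa %in% c(AA1, "X")]), collapse = ", "))
  n <- length(aa)
  w <- params$window
  if (n < w) {
    warning("sequence shorter than the ", w, "-residue window; all-zero ",
            "profile")
    scores <- numeric(n)
  } else {
    hb <- HYDRO_NORM[aa] + BETA_NORM[aa]
    hb[is.na(hb)] <- 0                       # X
    q <- aa_charge(aa)
    isP <- aa == "P"
    isX <- aa == "X"
    nw <- n - w + 1L
    # summed per window directly (not via running sums) so that a point
    # mutation leaves windows outside its reach bitwise unchanged
    wsum <- function(v) vapply(seq_len(nw), function(i)
      sum(v[i:(i + w - 1L)]), numeric(1))
    ew <- wsum(hb) - params$lambda * abs(wsum(q)) - params$gamma * wsum(isP)
    ew[wsum(isX) > 0] <- -Inf               # X invalidates the window
    scores <- vapply(seq_len(n), function(i) {
      ws <- max(1L, i - w + 1L):min(nw, i)
      best <- max(ew[ws])
      if (!is.finite(best)) return(0)
      100 * stats::plogis((best - params$e0) / params$s)
    }, numeric(1))
    scores[isX] <- 0
  }
  structure(list(sequence = sequence, scores = scores, params = params),
            class = "propensity_profile")
}

#' Detect aggregation-prone regions in a propensity profile
#'
#' APRs are the maximal runs of at least `min_len` consecutive residues whose
#' score is at least `threshold`; they are non-overlapping and sorted by
#' start position.
#'
#' @param profile A [propensity_profile()], or a bare numeric score vector.
#' @param min_len Minimum APR length (default 5).
#' @param threshold Per-residue score floor (default 5).
#' @return A data frame of class `apr_set` with columns `start`, `end`
#'   (1-based, closed), `sequence` and `tango_sum` (summed per-residue score
#'   over the interval).
#' @export
detect_aprs <- function(profile, min_len = 5L, threshold = 5) {
  if (min_len < 1L) stop("min_len must be >= 1")
  if (inherits(profile, "propensity_profile")) {
    scores <- profile$scores
    seq1 <- profile$sequence
  } else {
    scores <- as.numeric(profile)
    seq1 <- NULL
  }
  ok <- scores >= threshold
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  out <- data.frame(start = starts[keep], end = ends[keep])
  out$sequence <- if (!is.null(seq1) && nrow(out))
    substring(seq1, out$start, out$end) else character(nrow(out))
  out$tango_sum <- vapply(seq_len(nrow(out)), function(k)
    sum(scores[out$start[k]:out$end[k]]), numeric(1))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("apr_set", class(out))
  out
}

#' Effect of a point mutation on the aggregation profile
#'
#' Recomputes the profile on the mutated sequence and reports, for every
#' wild-type APR interval, the change in its summed score (new sum over the
#' same interval minus old sum). Negative values are aggregation-suppressing.
#'
#' @param sequence Wild-type sequence.
#' @param pos 1-based sequence index of the mutation site.
#' @param mut One-letter mutant residue.
#' @param params A [propensity_params()] set.
#' @param aprs Optional wild-type `apr_set` (recomputed when missing).
#' @param min_len,threshold APR-calling parameters used when `aprs` is
#'   recomputed.
#' @return List with `profile` (mutant [propensity_profile()]) and `delta`
#'   (data frame `start`, `end`, `d_tango`, one row per wild-type APR).
#' @export
mutant_profile_delta <- function(sequence, pos, mut,
                                 params = propensity_params(),
                                 aprs = NULL, min_len = 5L, threshold = 5) {
  sequence <- toupper(sequence)
  mut <- toupper(mut)
  n <- nchar(sequence)
  if (pos < 1L || pos > n) stop("mutation index ", pos, " outside sequence")
  wt <- substr(sequence, pos, pos)
  if (wt == mut) stop("identity mutation ", wt, pos, mut)
  wt_prof <- propensity_profile(sequence, params)
  if (is.null(aprs))
    aprs <- detect_aprs(wt_prof, min_len = min_len, threshold = threshold)
  mutated <- sequence
  substr(mutated, pos, pos) <- mut
  mut_prof <- propensity_profile(mutated, params)
  d <- vapply(seq_len(nrow(aprs)), function(k) {
    idx <- aprs$start[k]:aprs$end[k]
    sum(mut_prof$scores[idx]) - sum(wt_prof$scores[idx])
  }, numeric(1))
  list(profile = mut_prof,
       delta = data.frame(start = aprs$start, end = aprs$end, d_tango = d))
}

#' @export
print.propensity_profile <- function(x, ...) {
  cat("<propensity profile> ", length(x$scores), " residues, ",
      sum(x$scores >= 5), " at/above the APR floor\n", sep = "")
  invisible(x)
}
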