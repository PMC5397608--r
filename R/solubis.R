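#' Score an antibody for native-state aggregation risk
#'
#' The main entry point. Runs the full pipeline on an antibody Fv (or full
#' chain) pair: CDR/FR annotation, per-residue intrinsic aggregation
#' propensity, APR detection, per-APR local stability, stretch points and
#' the total Solubis score. Each APR's raw aggregation score is multiplied
#' by a stability weight in \[0, 1\] derived from its summed contribution to
#' the free energy of folding, so APRs that are thermodynamically protected
#' by the fold drop out and the total is dominated by critical APRs.
#'
#' Stability comes from one of three sources, in order of preference: a
#' per-residue free-energy table (e.g. real force-field output routed
#' through [read_residue_energy_table()]), a structure (the built-in
#' surrogate of [stability_profile()]), or neither -- in which case every
#' residue gets `delta_g = 0`, every APR weight is 0.5, and the report is
#' flagged `mode = "sequence-only"`.
#'
#' @param heavy,light Chain sequences (one-letter strings) or
#'   [annotate_chain()] objects; at least one must be given.
#' @param structure Optional `pdb_structure` from [read_pdb_chains()]. Chain
#'   sequences in the structure must match the supplied sequences.
#' @param energy_table Optional `residue_energy_table`; takes precedence
#'   over `structure` as the stability source.
#' @param chain_ids Mapping from antibody chain type to structure/table
#'   chain identifier, default `c(H = "H", L = "L")`.
#' @param id Antibody identifier.
#' @param params [propensity_params()] for the aggregation surrogate.
#' @param stab_params [stability_params()] for the stability surrogate.
#' @param min_len,threshold APR-calling parameters (defaults 5 and 5).
#' @param critical_threshold Corrected-score threshold flagging an APR as
#'   critical, default 50.
#' @return An object of class `solubis`: the [solubis_score()] report plus
#'   `chains`, `profiles`, `stability`, `mode`, and all thresholds.
#' @examples
#' fx <- make_toy_fv(seed = 1)
#' fit <- solubis(heavy = fx$heavy, light = fx$light, id = "toy")
#' fit
#' @export
solubis <- function(heavy = NULL, light = NULL, structure = NULL,
                    energy_table = NULL, chain_ids = c(H = "H", L = "L"),
                    id = "antibody",
                    params = propensity_params(),
                    stab_params = stability_params(),
                    min_len = 5L, threshold = 5,
                    critical_threshold = 50) {
  if (is.null(heavy) && is.null(light))
    stop("need at least one chain sequence")
  chains <- list()
  if (!is.null(heavy)) chains$H <- annotate_chain(heavy, "H")
  if (!is.null(light)) chains$L <- annotate_chain(light, "L")

  mode <- if (!is.null(energy_table)) "energy-table"
  else if (!is.null(structure)) "structure" else "sequence-only"

  profiles <- list(); stab <- list(); pts <- list()
  for (ct in names(chains)) {
    ch <- chains[[ct]]
    profiles[[ct]] <- propensity_profile(ch$sequence, params)
    aprs <- detect_aprs(profiles[[ct]], min_len = min_len,
                        threshold = threshold)
    sid <- unname(chain_ids[ct])
    if (mode == "energy-table") {
      stab[[ct]] <- stability_profile(structure = structure, chain_id = sid,
                                      params = stab_params,
                                      energy_table = energy_table,
                                      numbering = data.frame(
                                        position = ch$numbering$position,
                                        ins = ch$numbering$ins))
    } else if (mode == "structure") {
      sc <- structure$chains[[sid]]
      if (is.null(sc))
        stop("structure has no chain '", sid, "' for the ", ct, " chain")
      if (sc$sequence != ch$sequence)
        stop("structure chain '", sid, "' sequence does not match the ",
             ct, " chain sequence")
      stab[[ct]] <- stability_profile(structure, sid, stab_params)
    } else {
      stab[[ct]] <- structure(list(chain_id = sid,
                                   delta_g = numeric(nchar(ch$sequence)),
                                   rsa = rep(NA_real_, nchar(ch$sequence)),
                                   hb_backbone = NA, hb_sidechain = NA,
                                   clash = NA, provenance = "none"),
                              class = "stability_profile")
    }
    dg <- vapply(seq_len(nrow(aprs)), function(k)
      apr_dg_contrib(stab[[ct]], c(aprs$start[k], aprs$end[k])), numeric(1))
    region <- vapply(seq_len(nrow(aprs)), function(k)
      apr_region_label(ch, c(aprs$start[k], aprs$end[k])), character(1))
    pts[[ct]] <- make_stretch_points(aprs, dg, region = region, chain = ct,
                                     critical_threshold = critical_threshold)
  }
  points <- do.call(rbind, pts)
  rownames(points) <- NULL
  attr(points, "critical_threshold") <- critical_threshold
  class(points) <- c("stretch_points", "data.frame")
  rep <- solubis_score(points, id = id)
  rep$chains <- chains
  rep$profiles <- profiles
  rep$stability <- stab
  rep$mode <- mode
  rep$params <- params
  rep$stab_params <- stab_params
  rep$min_len <- min_len
  rep$threshold <- threshold
  rep$structure <- structure
  rep$chain_ids <- chain_ids
  class(rep) <- c("solubis", "solubis_report")
  rep
}

#' @export
print.solubis <- function(x, ...) {
  cat("<solubis> ", x$id, "  [", x$mode, "]\n", sep = "")
  cat(sprintf("  Solubis score: %.1f (raw aggregation total %.1f)\n",
              x$solubis_score, x$total_tango))
  cat(sprintf("  APRs: %d, critical: %d (corrected score >= %.0f)\n",
              x$n_aprs, x$n_critical, x$critical_threshold))
  invisible(x)
}

#' @export
summary.solubis <- function(object, ...) {
  print(object)
  if (object$n_aprs) {
    cat("\n  Stretch points:\n")
    df <- object$points
    df$tango_sum <- round(df$tango_sum, 1)
    df$dg_contrib <- round(df$dg_contrib, 2)
    df$weight <- round(df$weight, 2)
    df$corrected_score <- round(df$corrected_score, 1)
    print(df, row.names = FALSE)
  }
  invisible(object)
}

#' Stretch-plot of a scored antibody
#'
#' Scatter of the antibody's APRs with the summed stability contribution on
#' the abscissa and the raw summed aggregation score on the ordinate.
#' Critical APRs (corrected score at or above the threshold) are circled;
#' the clipping band at +/- 5 kcal/mol is shaded.
#'
#' @param x A `solubis` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.solubis <- function(x, ...) {
  p <- x$points
  if (nrow(p) == 0L) {
    plot(0, 0, type = "n", xlab = expression(Delta * G^contrib ~ "(kcal/mol)"),
         ylab = "summed aggregation score")
    return(invisible(x))
  }
  xlim <- range(c(p$dg_contrib, -6, 6))
  ylim <- c(0, max(p$tango_sum) * 1.1)
  cols <- ifelse(p$region == "FR", "steelblue",
                 ifelse(p$chain == "H", "firebrick", "forestgreen"))
  plot(p$dg_contrib, p$tango_sum, xlim = xlim, ylim = ylim,
       pch = 19, col = cols,
       xlab = expression(Delta * G^contrib ~ "(kcal/mol)"),
       ylab = "summed aggregation score",
       main = paste0(x$id, " (Solubis score ",
                     round(x$solubis_score, 1), ")"), ...)
  graphics::rect(-5, ylim[1], 5, ylim[2], border = NA,
                 col = grDevices::adjustcolor("grey", 0.15))
  graphics::abline(v = c(-5, 5), lty = 3, col = "grey40")
  crit <- p$critical
  if (any(crit))
    graphics::points(p$dg_contrib[crit], p$tango_sum[crit], pch = 1,
                     cex = 2.2, col = "red")
  graphics::legend("topleft", bty = "n",
                   legend = c("FR APR", "CDR APR (H)", "CDR APR (L)",
                              "critical"),
                   pch = c(19, 19, 19, 1),
                   col = c("steelblue", "firebrick", "forestgreen", "red"))
  invisible(x)
}
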