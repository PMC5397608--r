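# Variant design: gatekeeper scans over APRs (MASS plots) and
# net-charge-increasing scans outside the heavy-chain CDRs.

resolve_position <- function(chain, position, ins = "") {
  idx <- which(chain$numbering$position == position &
                 chain$numbering$ins == ins)
  if (length(idx) != 1L)
    stop("position ", position, ins, " not found in chain ",
         chain$chain_type)
  idx
}

# delta-delta-G for one substitution under the fit's stability source;
# 0 (flagged upstream) when only a sequence is available
fit_ddg <- function(fit, chain_type, idx, mut) {
  if (fit$mode == "structure") {
    sid <- unname(fit$chain_ids[chain_type])
    ddg_of_mutation(fit$structure, sid, idx, mut,
                    params = fit$stab_params,
                    stability = fit$stability[[chain_type]])
  } else 0
}

#' Gatekeeper scan over one APR (MASS plot data)
#'
#' Enumerates every mutation of an APR residue to an aggregation gatekeeper
#' (D, E, K, R or P -- five mutations per position, skipping positions whose
#' wild type already is that gatekeeper) and attaches the change in the
#' APR's summed aggregation score (`d_tango`, negative = suppressing) and
#' the predicted stability change (`ddg`). The (`d_tango`, `ddg`) pairs are
#' the mutant aggregation and stability spectrum of the APR.
#'
#' @param fit A [solubis()] object.
#' @param chain `"H"` or `"L"`.
#' @param apr Row index into the chain's APRs (in `fit$points`), or an
#'   interval `c(start, end)` matching one of them.
#' @return A data frame of class `mass_scan` with columns `chain`,
#'   `position`, `ins`, `wt`, `mut`, `d_tango`, `ddg`, `d_charge`, sorted by
#'   (`d_tango`, `ddg`) ascending.
#' @export
mass_scan <- function(fit, chain = c("H", "L"), apr = 1L) {
  stopifnot(inherits(fit, "solubis"))
  chain <- match.arg(chain)
  ch <- fit$chains[[chain]]
  if (is.null(ch)) stop("fit has no ", chain, " chain")
  cp <- fit$points[fit$points$chain == chain, , drop = FALSE]
  if (length(apr) == 2L) {
    k <- which(cp$start == apr[1] & cp$end == apr[2])
    if (length(k) != 1L)
      stop("no APR [", apr[1], ",", apr[2], "] on chain ", chain)
  } else k <- apr
  if (k < 1L || k > nrow(cp)) stop("APR index out of range")
  iv <- c(cp$start[k], cp$end[k])
  if (iv[2] < iv[1]) stop("empty APR")
  aa <- strsplit(ch$sequence, "")[[1]]
  aprs <- data.frame(start = iv[1], end = iv[2])

  rows <- list()
  for (i in iv[1]:iv[2]) {
    for (gk in GATEKEEPERS) {
      if (aa[i] == gk) next
      d <- mutant_profile_delta(ch$sequence, i, gk, params = fit$params,
                                aprs = aprs)$delta$d_tango[1]
      rows[[length(rows) + 1L]] <- data.frame(
        chain = chain,
        position = ch$numbering$position[i],
        ins = ch$numbering$ins[i],
        wt = aa[i], mut = gk,
        d_tango = d,
        ddg = fit_ddg(fit, chain, i, gk),
        d_charge = as.integer(aa_charge(gk) - aa_charge(aa[i])),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chain = character(), position = integer(), ins = character(),
               wt = character(), mut = character(), d_tango = numeric(),
               ddg = numeric(), d_charge = integer(),
               stringsAsFactors = FALSE)
  out <- out[order(out$d_tango, out$ddg, out$position, out$mut), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "apr") <- iv
  class(out) <- c("mass_scan", class(out))
  out
}

#' Shortlist gatekeeper candidates from a MASS scan
#'
#' Keeps candidates whose predicted destabilization does not exceed
#' `max_ddg`, then ranks by aggregation suppression (most negative
#' `d_tango` first), breaking ties by `ddg`, then position, then mutant
#' residue alphabetically.
#'
#' @param candidates A [mass_scan()] data frame.
#' @param max_ddg Maximum tolerated delta-delta-G (kcal/mol), default +0.5.
#' @param top_n Keep at most this many candidates (default all).
#' @return The ranked shortlist (same columns).
#' @export
select_mass_candidates <- function(candidates, max_ddg = 0.5, top_n = Inf) {
  if (nrow(candidates) == 0L) stop("no candidates to select from")
  keep <- candidates[candidates$ddg <= max_ddg, , drop = FALSE]
  if (nrow(keep) == 0L) {
    warning("all candidates exceed max_ddg = ", max_ddg)
    return(keep)
  }
  keep <- keep[order(keep$d_tango, keep$ddg, keep$position, keep$mut), ,
               drop = FALSE]
  if (is.finite(top_n)) keep <- utils::head(keep, top_n)
  rownames(keep) <- NULL
  keep
}

#' Net-charge-increasing scan outside the heavy-chain CDRs
#'
#' At every position outside the CDRs (framework and constant residues),
#' enumerates the substitutions that raise the chain's net charge by at
#' least one unit: X to K and X to R for any X not already K/R (+1, or +2
#' from D/E), plus the acid-to-amide substitutions D to N, D to Q, E to N
#' and E to Q (+1). Each candidate carries its predicted delta-delta-G.
#'
#' @param fit A [solubis()] object with a heavy chain.
#' @param chain Chain to scan, default `"H"`.
#' @return A data frame of class `supercharge_scan` with columns `chain`,
#'   `position`, `ins`, `wt`, `mut`, `d_charge`, `ddg`, sorted by `ddg`
#'   ascending.
#' @export
supercharge_scan <- function(fit, chain = "H") {
  stopifnot(inherits(fit, "solubis"))
  ch <- fit$chains[[chain]]
  if (is.null(ch)) stop("fit has no ", chain, " chain")
  if (is.null(ch$regions)) stop("chain has no region labels")
  aa <- strsplit(ch$sequence, "")[[1]]
  outside <- !grepl("^CDR", ch$regions)
  rows <- list()
  for (i in which(outside)) {
    wt <- aa[i]
    muts <- character(0)
    if (!wt %in% c("K", "R")) muts <- c("K", "R")
    if (wt %in% c("D", "E")) muts <- c(muts, "N", "Q")
    for (m in muts) {
      rows[[length(rows) + 1L]] <- data.frame(
        chain = chain,
        position = ch$numbering$position[i],
        ins = ch$numbering$ins[i],
        wt = wt, mut = m,
        d_charge = as.integer(aa_charge(m) - aa_charge(wt)),
        ddg = fit_ddg(fit, chain, i, m),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chain = character(), position = integer(), ins = character(),
               wt = character(), mut = character(), d_charge = integer(),
               ddg = numeric(), stringsAsFactors = FALSE)
  out <- out[order(out$ddg, out$position, out$mut), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("supercharge_scan", class(out))
  out
}

#' Apply mutations and rescore the variant
#'
#' Applies a set of point mutations (each at a distinct position, wild-type
#' letters verified against the sequence) and re-runs the full pipeline:
#' aggregation profile, APR detection, stability aggregation and scoring.
#' Region labels and numbering are inherited from the wild type, as is the
#' per-residue stability profile (the structure is not re-modelled -- the
#' variant score is a ranking prediction).
#'
#' @param fit A [solubis()] object (the wild type).
#' @param mutations A list of mutation strings (e.g. `"SL50K"`) or
#'   [parse_mutation_string()] objects. An empty list returns a rescored
#'   wild type.
#' @return A list of class `variant_design`: `mutations`, `d_charge` (total
#'   change in net charge) and `fit`, the variant's `solubis` object.
#' @export
compose_variant <- function(fit, mutations = list()) {
  stopifnot(inherits(fit, "solubis"))
  specs <- lapply(mutations, function(m)
    if (inherits(m, "mutation_spec")) m else parse_mutation_string(m))
  keys <- vapply(specs, function(s)
    paste(s$chain, s$position, s$ins, sep = "\r"), character(1))
  if (anyDuplicated(keys)) {
    dup <- specs[[which(duplicated(keys))[1]]]
    stop("duplicated mutation position ", dup$chain, dup$position, dup$ins)
  }

  newseq <- lapply(fit$chains, function(ch) ch$sequence)
  d_charge <- 0L
  for (s in specs) {
    ch <- fit$chains[[s$chain]]
    if (is.null(ch)) stop("fit has no ", s$chain, " chain")
    idx <- resolve_position(ch, s$position, s$ins)
    have <- substr(newseq[[s$chain]], idx, idx)
    if (have != s$wild_type)
      stop("wild-type mismatch at ", s$chain, s$position, s$ins,
           ": sequence has ", have, ", mutation expects ", s$wild_type)
    substr(newseq[[s$chain]], idx, idx) <- s$mutant
    d_charge <- d_charge +
      as.integer(aa_charge(s$mutant) - aa_charge(s$wild_type))
  }

  pts <- list()
  profiles <- list()
  for (ct in names(fit$chains)) {
    ch <- fit$chains[[ct]]
    var_ch <- ch
    var_ch$sequence <- newseq[[ct]]
    var_ch$numbering$aa <- strsplit(newseq[[ct]], "")[[1]]
    profiles[[ct]] <- propensity_profile(var_ch$sequence, fit$params)
    aprs <- detect_aprs(profiles[[ct]], min_len = fit$min_len,
                        threshold = fit$threshold)
    dg <- vapply(seq_len(nrow(aprs)), function(k)
      apr_dg_contrib(fit$stability[[ct]], c(aprs$start[k], aprs$end[k])),
      numeric(1))
    region <- vapply(seq_len(nrow(aprs)), function(k)
      apr_region_label(var_ch, c(aprs$start[k], aprs$end[k])), character(1))
    pts[[ct]] <- make_stretch_points(aprs, dg, region = region, chain = ct,
                                     critical_threshold =
                                       fit$critical_threshold)
  }
  points <- do.call(rbind, pts)
  rownames(points) <- NULL
  attr(points, "critical_threshold") <- fit$critical_threshold
  class(points) <- c("stretch_points", "data.frame")
  mut_tags <- vapply(specs, format, character(1))
  vid <- if (length(mut_tags)) paste(c(fit$id, mut_tags), collapse = "_")
  else fit$id
  rep <- solubis_score(points, id = vid)
  rep$mode <- fit$mode
  rep$profiles <- profiles
  structure(list(mutations = specs, d_charge = d_charge,
                 report = rep),
            class = "variant_design")
}

#' @export
print.variant_design <- function(x, ...) {
  tags <- vapply(x$mutations, format, character(1))
  cat("<variant>", if (length(tags)) paste(tags, collapse = " ")
      else "(wild type)", "\n")
  cat(sprintf("  net-charge change: %+d\n", x$d_charge))
  cat(sprintf("  Solubis score: %.1f (%d APRs, %d critical)\n",
              x$report$solubis_score, x$report$n_aprs, x$report$n_critical))
  invisible(x)
}
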