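# Pipeline orchestration: config handling and the score / design /
# evaluate commands behind the command-line interface
# (inst/cli/solubis.R). Every command is deterministic given (inputs,
# config, seed) and echoes its thresholds into the output metadata.

#' Pipeline run configuration
#'
#' Bundles every tunable threshold of the pipeline; all values are echoed
#' verbatim into the run manifest written next to each command's outputs.
#'
#' @param threshold Per-residue APR-calling floor (default 5).
#' @param min_len Minimum APR length (default 5).
#' @param critical_threshold Corrected-score threshold for criticality
#'   (default 50).
#' @param gap_cutoff Melting / aggregation-onset gap cutoff in degrees C
#'   (default 5).
#' @param max_ddg Stability filter for gatekeeper shortlists, kcal/mol
#'   (default 0.5).
#' @param seed Integer seed recorded in the manifest.
#' @param params,stab_params Surrogate parameter sets.
#' @return A list of class `run_config`.
#' @export
run_config <- function(threshold = 5, min_len = 5L, critical_threshold = 50,
                       gap_cutoff = 5.0, max_ddg = 0.5, seed = 1L,
                       params = propensity_params(),
                       stab_params = stability_params()) {
  structure(list(threshold = threshold, min_len = as.integer(min_len),
                 critical_threshold = critical_threshold,
                 gap_cutoff = gap_cutoff, max_ddg = max_ddg,
                 seed = as.integer(seed), params = params,
                 stab_params = stab_params),
            class = "run_config")
}

config_manifest <- function(config, extra = list()) {
  c(list(tool = "solubis",
         version = as.character(utils::packageVersion("solubis")),
         threshold = config$threshold, min_len = config$min_len,
         critical_threshold = config$critical_threshold,
         gap_cutoff = config$gap_cutoff, max_ddg = config$max_ddg,
         seed = config$seed,
         propensity_params = unclass(config$params),
         stability_params = unclass(config$stab_params)),
    extra)
}

# fit one antibody from file inputs; FASTA identifiers must end in _H / _L
fit_from_inputs <- function(fasta, pdb = NULL, energies = NULL, config,
                            id = NULL) {
  seqs <- read_fasta(fasta)
  hid <- grep("_H$", names(seqs), value = TRUE)
  lid <- grep("_L$", names(seqs), value = TRUE)
  if (length(hid) > 1L || length(lid) > 1L)
    stop("more than one _H or _L record in ", fasta)
  if (length(hid) + length(lid) == 0L)
    stop("FASTA identifiers must end in _H or _L to mark the chains")
  structure_obj <- if (!is.null(pdb)) read_pdb_chains(pdb) else NULL
  table_obj <- if (!is.null(energies))
    read_residue_energy_table(energies) else NULL
  if (is.null(id))
    id <- sub("_[HL]$", "", c(hid, lid)[1])
  solubis(heavy = if (length(hid)) unname(seqs[hid]) else NULL,
          light = if (length(lid)) unname(seqs[lid]) else NULL,
          structure = structure_obj, energy_table = table_obj, id = id,
          params = config$params, stab_params = config$stab_params,
          min_len = config$min_len, threshold = config$threshold,
          critical_threshold = config$critical_threshold)
}

stretch_point_table <- function(fit) {
  p <- fit$points
  data.frame(antibody = rep(fit$id, nrow(p)),
             chain = p$chain, region = p$region, start = p$start,
             end = p$end, sequence = p$sequence, tango_sum = p$tango_sum,
             dg_contrib = p$dg_contrib, weight = p$weight,
             corrected_score = p$corrected_score,
             critical = tolower(as.character(p$critical)),
             stringsAsFactors = FALSE)
}

#' Score an antibody from files
#'
#' Reads sequences (FASTA; identifiers ending `_H` / `_L`), an optional
#' structure (PDB) or per-residue energy table (TSV), scores the antibody
#' and writes `stretch_points.csv`, `report.json` and `manifest.json` into
#' `outdir`. Without a stability source the report is flagged
#' `"sequence-only"` and every APR weight is 0.5.
#'
#' @param fasta,pdb,energies Input paths (`pdb`/`energies` optional).
#' @param outdir Output directory (created if needed).
#' @param config A [run_config()].
#' @return The `solubis` fit, invisibly.
#' @export
run_score <- function(fasta, pdb = NULL, energies = NULL,
                      outdir = ".", config = run_config()) {
  fit <- fit_from_inputs(fasta, pdb, energies, config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_report(stretch_point_table(fit),
               file.path(outdir, "stretch_points.csv"), "csv")
  write_report(list(antibody = fit$id, mode = fit$mode,
                    solubis_score = fit$solubis_score,
                    total_tango = fit$total_tango, n_aprs = fit$n_aprs,
                    n_critical = fit$n_critical,
                    critical_threshold = fit$critical_threshold),
               file.path(outdir, "report.json"), "json")
  write_report(config_manifest(config, list(command = "score")),
               file.path(outdir, "manifest.json"), "json")
  invisible(fit)
}

#' Design aggregation-suppressing variants from files
#'
#' Scores the antibody, runs a gatekeeper scan over every critical APR
#' (writing `mass_scan.csv`), a net-charge-increasing scan outside the
#' heavy-chain CDRs (`supercharge.csv`), and composes the top shortlisted
#' gatekeeper mutation into a variant report (`variants.json`). With no
#' critical APR the MASS file is header-only and a warning is raised.
#'
#' @inheritParams run_score
#' @return List with `fit`, `mass`, `supercharge`, `variant`, invisibly.
#' @export
run_design <- function(fasta, pdb = NULL, energies = NULL,
                       outdir = ".", config = run_config()) {
  fit <- fit_from_inputs(fasta, pdb, energies, config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  crit <- which(fit$points$critical)
  mass <- NULL
  for (k in crit) {
    p <- fit$points[k, ]
    sc <- mass_scan(fit, chain = p$chain, apr = c(p$start, p$end))
    mass <- rbind(mass, sc)
  }
  if (is.null(mass)) {
    warning("no critical APRs; MASS scan is empty")
    mass <- data.frame(chain = character(), position = integer(),
                       ins = character(), wt = character(),
                       mut = character(), d_tango = numeric(),
                       ddg = numeric(), d_charge = integer(),
                       stringsAsFactors = FALSE)
  }
  sel_keys <- character(0)
  if (nrow(mass)) {
    sel <- suppressWarnings(
      select_mass_candidates(mass, max_ddg = config$max_ddg))
    sel_keys <- paste(sel$chain, sel$position, sel$ins, sel$mut)
  }
  mass_out <- data.frame(chain = mass$chain, position = mass$position,
                         wt = mass$wt, mut = mass$mut,
                         d_tango = mass$d_tango, ddg = mass$ddg,
                         selected = tolower(as.character(
                           paste(mass$chain, mass$position, mass$ins,
                                 mass$mut) %in% sel_keys)),
                         stringsAsFactors = FALSE)
  write_report(mass_out, file.path(outdir, "mass_scan.csv"), "csv")

  sc <- if (!is.null(fit$chains$H)) supercharge_scan(fit, "H") else
    data.frame(chain = character(), position = integer(), ins = character(),
               wt = character(), mut = character(), d_charge = integer(),
               ddg = numeric(), stringsAsFactors = FALSE)
  write_report(data.frame(chain = sc$chain, position = sc$position,
                          wt = sc$wt, mut = sc$mut, d_charge = sc$d_charge,
                          ddg = sc$ddg, stringsAsFactors = FALSE),
               file.path(outdir, "supercharge.csv"), "csv")

  variant <- NULL
  if (length(sel_keys)) {
    first <- strsplit(sel_keys[1], " ")[[1]]
    wt_at <- mass$wt[paste(mass$chain, mass$position, mass$ins,
                           mass$mut) == sel_keys[1]][1]
    mstr <- paste0(wt_at, first[1], first[2], first[3], first[4])
    variant <- compose_variant(fit, list(mstr))
    write_report(list(mutations = mstr, d_charge = variant$d_charge,
                      solubis_score = variant$report$solubis_score,
                      total_tango = variant$report$total_tango,
                      n_aprs = variant$report$n_aprs,
                      n_critical = variant$report$n_critical,
                      wild_type_score = fit$solubis_score),
                 file.path(outdir, "variants.json"), "json")
  }
  write_report(config_manifest(config, list(command = "design")),
               file.path(outdir, "manifest.json"), "json")
  invisible(list(fit = fit, mass = mass, supercharge = sc,
                 variant = variant))
}

#' Evaluate scores against thermal data from a records CSV
#'
#' Reads a CSV with columns `antibody`, `solubis_score` and either `gap` or
#' `t_m`/`t_agg` (plus optional `forced_label`), labels the records at the
#' configured gap cutoff, and writes `roc.csv` and `evaluation.json` (AUC,
#' MCC at the best threshold, Pearson correlation of score versus gap).
#'
#' @param records_csv Input CSV path.
#' @param outdir Output directory.
#' @param config A [run_config()].
#' @return List with `records`, `roc`, `auc`, `mcc`, `pearson`, invisibly.
#' @export
run_evaluate <- function(records_csv, outdir = ".", config = run_config()) {
  df <- utils::read.csv(records_csv, stringsAsFactors = FALSE)
  forced <- NULL
  if ("forced_label" %in% names(df)) {
    has <- !is.na(df$forced_label)
    if (any(has)) forced <- stats::setNames(as.integer(df$forced_label[has]),
                                            df$antibody[has])
  }
  df <- label_records(df, gap_cutoff = config$gap_cutoff, forced = forced)
  roc <- roc_curve(df$solubis_score, df$label)
  # decision threshold: maximize Youden's J over the ROC thresholds
  j <- roc$points$tpr - roc$points$fpr
  best_thr <- roc$points$threshold[which.max(j)]
  m <- mcc(df$solubis_score, df$label, best_thr)
  r <- if (sum(!is.na(df$gap)) >= 3)
    pearson(df$solubis_score[!is.na(df$gap)], df$gap[!is.na(df$gap)])
  else NA_real_
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_report(roc$points, file.path(outdir, "roc.csv"), "csv")
  write_report(list(auc = roc$auc, mcc = m, threshold = best_thr,
                    pearson = r, n = nrow(df),
                    n_positive = sum(df$label == 1L)),
               file.path(outdir, "evaluation.json"), "json")
  write_report(config_manifest(config, list(command = "evaluate")),
               file.path(outdir, "manifest.json"), "json")
  invisible(list(records = df, roc = roc, auc = roc$auc, mcc = m,
                 pearson = r, threshold = best_thr))
}
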