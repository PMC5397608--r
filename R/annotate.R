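#' Annotate an antibody chain with CDR/FR region labels
#'
#' Locates the three CDRs of a variable domain with Chothia-style anchor
#' rules and labels every residue `FR1`, `CDR1`, `FR2`, `CDR2`, `FR3`,
#' `CDR3`, `FR4` or `CONST` (past the end of the variable domain).
#'
#' Anchor rules, heavy chain: CDR-H1 starts four residues after the first
#' conserved Cys and spans seven residues; CDR-H2 starts 15 residues after
#' the H1 end and spans six; CDR-H3 starts three residues after the second
#' conserved Cys and ends immediately before the conserved `WG.G` motif.
#' Light chain: CDR-L1 starts after the first conserved Cys and ends before
#' the next conserved Trp; CDR-L2 starts 16 residues after the L1 end and
#' spans seven; CDR-L3 starts after the second conserved Cys and ends before
#' the conserved `FG.G` motif. FR4 spans the ten residues from that motif.
#'
#' These anchors are robust for standard Fv domains; for anything unusual an
#' `external_numbering` sidecar (a data frame with columns `position`, `ins`,
#' `aa`, `region`, e.g. from an external numbering tool) is used verbatim.
#'
#' @param sequence One-letter amino-acid sequence (variable domain first).
#' @param chain_type `"H"` or `"L"`.
#' @param external_numbering Optional sidecar data frame; when supplied,
#'   numbering and regions are taken from it and no anchor search is done.
#' @return An object of class `antibody_chain`: list with `chain_type`,
#'   `sequence`, `numbering` (data frame `position`, `ins`, `aa`) and
#'   `regions` (character vector, one label per residue).
#' @export
annotate_chain <- function(sequence, chain_type = c("H", "L"),
                           external_numbering = NULL) {
  chain_type <- match.arg(chain_type)
  if (inherits(sequence, "antibody_chain")) return(sequence)
  sequence <- toupper(sequence)
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)

  if (!is.null(external_numbering)) {
    en <- external_numbering
    req <- c("position", "ins", "aa", "region")
    if (!all(req %in% names(en)))
      stop("external numbering must have columns: ",
           paste(req, collapse = ", "))
    if (nrow(en) != n)
      stop("external numbering covers ", nrow(en), " residues; sequence has ",
           n)
    numbering <- data.frame(position = as.integer(en$position),
                            ins = as.character(en$ins), aa = aa,
                            stringsAsFactors = FALSE)
    regions <- as.character(en$region)
  } else {
    if (n < 70)
      stop("sequence too short for a variable domain (", n,
           " residues) and no external numbering supplied")
    cys <- which(aa == "C")
    if (length(cys) < 1L)
      stop("anchor not found: first conserved Cys")
    c1 <- cys[1]
    if (chain_type == "H") {
      cdr1 <- c(c1 + 4L, c1 + 10L)
      cdr2 <- c(cdr1[2] + 15L, cdr1[2] + 20L)
      c2 <- cys[cys > cdr2[2]]
      if (length(c2) < 1L)
        stop("anchor not found: second conserved Cys (heavy chain)")
      c2 <- c2[1]
      cdr3_start <- c2 + 3L
      wm <- gregexpr("WG.G", sequence)[[1]]
      wm <- wm[wm > cdr3_start]
      if (length(wm) < 1L || wm[1] < 0)
        stop("anchor not found: WG.G motif ending CDR-H3")
      cdr3 <- c(cdr3_start, wm[1] - 1L)
      fr4_end <- min(n, wm[1] + 9L)
    } else {
      trp <- which(aa == "W")
      w1 <- trp[trp > c1 + 1L]
      if (length(w1) < 1L)
        stop("anchor not found: conserved Trp ending CDR-L1")
      cdr1 <- c(c1 + 1L, w1[1] - 1L)
      cdr2 <- c(cdr1[2] + 16L, cdr1[2] + 22L)
      c2 <- cys[cys > cdr2[2]]
      if (length(c2) < 1L)
        stop("anchor not found: second conserved Cys (light chain)")
      c2 <- c2[1]
      fm <- gregexpr("FG.G", sequence)[[1]]
      fm <- fm[fm > c2 + 1L]
      if (length(fm) < 1L || fm[1] < 0)
        stop("anchor not found: FG.G motif ending CDR-L3")
      cdr3 <- c(c2 + 1L, fm[1] - 1L)
      fr4_end <- min(n, fm[1] + 9L)
    }
    if (cdr3[2] < cdr3[1] || cdr2[2] >= cdr3[1] || cdr1[2] >= cdr2[1])
      stop("anchor layout inconsistent; supply external numbering")
    regions <- rep("CONST", n)
    regions[1:(cdr1[1] - 1L)] <- "FR1"
    regions[cdr1[1]:cdr1[2]] <- "CDR1"
    regions[(cdr1[2] + 1L):(cdr2[1] - 1L)] <- "FR2"
    regions[cdr2[1]:cdr2[2]] <- "CDR2"
    regions[(cdr2[2] + 1L):(cdr3[1] - 1L)] <- "FR3"
    regions[cdr3[1]:cdr3[2]] <- "CDR3"
    regions[(cdr3[2] + 1L):fr4_end] <- "FR4"
    numbering <- data.frame(position = seq_len(n), ins = "",
                            aa = aa, stringsAsFactors = FALSE)
  }
  structure(list(chain_type = chain_type, sequence = sequence,
                 numbering = numbering, regions = regions),
            class = "antibody_chain")
}

#' @export
print.antibody_chain <- function(x, ...) {
  cat("<antibody chain ", x$chain_type, "> ", nchar(x$sequence),
      " residues\n", sep = "")
  for (r in c("CDR1", "CDR2", "CDR3")) {
    idx <- which(x$regions == r)
    if (length(idx))
      cat(sprintf("  %s-%s: %d-%d  %s\n", r, x$chain_type, min(idx), max(idx),
                  substr(x$sequence, min(idx), max(idx))))
  }
  invisible(x)
}

#' CDR intervals of an annotated chain
#'
#' @param chain An `antibody_chain`.
#' @return Named list of `c(start, end)` sequence intervals, one per CDR
#'   present.
#' @export
cdr_intervals <- function(chain) {
  stopifnot(inherits(chain, "antibody_chain"))
  out <- list()
  for (r in c("CDR1", "CDR2", "CDR3")) {
    idx <- which(chain$regions == r)
    if (length(idx)) out[[r]] <- c(min(idx), max(idx))
  }
  out
}

#' Net charge of an annotated chain
#'
#' Counts K and R as +1 and D and E as -1 (histidine neutral unless
#' `his_positive`); termini are ignored. The scope restricts the count to a
#' region class.
#'
#' @param chain An `antibody_chain`.
#' @param scope `"chain"` (all residues), `"framework"` (everything outside
#'   the CDRs, i.e. FR1-FR4 plus any constant-region residues), or `"cdr"`.
#' @param his_positive Count histidine as +1 (default `FALSE`).
#' @return Integer net charge with attribute `scope`.
#' @export
net_charge <- function(chain, scope = c("chain", "framework", "cdr"),
                       his_positive = FALSE) {
  stopifnot(inherits(chain, "antibody_chain"))
  scope <- match.arg(scope)
  aa <- strsplit(chain$sequence, "")[[1]]
  keep <- switch(scope,
                 chain = rep(TRUE, length(aa)),
                 framework = !grepl("^CDR", chain$regions),
                 cdr = grepl("^CDR", chain$regions))
  val <- as.integer(sum(aa_charge(aa[keep], his_positive = his_positive)))
  structure(val, scope = scope)
}

#' Region label of an APR interval
#'
#' An interval overlapping a CDR by at least one residue is labeled by that
#' CDR; overlap with two or more CDRs gives `"mixed"`; no CDR overlap gives
#' `"FR"`.
#'
#' @param chain An `antibody_chain`.
#' @param interval `c(start, end)`, 1-based closed, in sequence coordinates.
#' @return `"FR"`, `"CDR1"`, `"CDR2"`, `"CDR3"` or `"mixed"`.
#' @export
apr_region_label <- function(chain, interval) {
  stopifnot(inherits(chain, "antibody_chain"))
  if (length(interval) != 2L || interval[2] < interval[1])
    stop("empty or invalid interval")
  n <- nchar(chain$sequence)
  if (interval[1] < 1L || interval[2] > n)
    stop("interval [", interval[1], ",", interval[2],
         "] outside chain of length ", n)
  hit <- unique(chain$regions[interval[1]:interval[2]])
  cdrs <- hit[grepl("^CDR", hit)]
  if (length(cdrs) == 0L) return("FR")
  if (length(cdrs) > 1L) return("mixed")
  cdrs
}
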