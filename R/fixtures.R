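# Synthetic fixtures: toy Fv sequences with planted APRs, toy structures
# with controlled burial, and the published antibody benchmark table.
# Everything regenerates byte-identically from (seed, flags).

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# polar framework background: no C/W/F (anchor letters), no hydrophobics
BACKGROUND_AA <- c("S", "T", "G", "N", "Q")

#' Build a toy Fv pair with one planted APR
#'
#' Generates ~110-residue heavy and light chains carrying the anchor motifs
#' the annotation rules expect (conserved Cys/Trp and the `WG.G` / `FG.G`
#' motifs), a polar framework background (S/T/G/N/Q with a few scattered
#' K/E), and one contiguous hydrophobic APR -- an alternating I/V segment --
#' planted either in CDR-H3 or in heavy-chain FR3. The alternating I/V
#' pattern keeps every 5-window inside the APR above, and every window
#' crossing its boundary below, the calling threshold, so the detected
#' interval equals the planted interval exactly. Charged background
#' residues are kept at least five positions away from the APR so that
#' window locality leaves the planted segment and its gatekeeper response
#' untouched.
#'
#' @param seed Integer seed; regeneration with the same seed and flags is
#'   byte-identical.
#' @param apr_in_cdr Plant the APR in CDR-H3 (`TRUE`, default) or in
#'   heavy-chain FR3 (`FALSE`).
#' @param apr_length APR length, 5 to 14 residues (default 6).
#' @return An object of class `planted_fixture`: list with `heavy`, `light`
#'   (sequences), `apr_chain` (`"H"`), `apr` (planted `c(start, end)`),
#'   `apr_in_cdr`, `cdr_h`, `cdr_l` (planted CDR intervals), `seed`,
#'   `apr_length`.
#' @export
make_toy_fv <- function(seed = 1L, apr_in_cdr = TRUE, apr_length = 6L) {
  apr_length <- as.integer(apr_length)
  if (apr_length < 5L) stop("apr_length must be >= 5")
  if (apr_length > 14L)
    stop("apr_length ", apr_length, " exceeds the host region")
  with_local_seed(seed, {
    bg <- function(n) paste(sample(BACKGROUND_AA, n, replace = TRUE),
                            collapse = "")
    apr_seq <- paste(rep(c("I", "V"), length.out = apr_length),
                     collapse = "")

    # ---- heavy chain ----
    # FR1 1-25 with the first Cys at 22; CDR-H1 26-32; FR2 33-46;
    # CDR-H2 47-52; FR3 53-94 with the second Cys at 92; CDR-H3 from 95;
    # FR4 = WGQGTLVTVS; two trailing constant residues.
    h3_len <- if (apr_in_cdr) apr_length + 2L else 8L
    fr1 <- paste0(bg(21), "C", bg(3))                    # 1-25, C at 22
    h1 <- bg(7)                                          # 26-32
    fr2 <- bg(14)                                        # 33-46
    h2 <- bg(6)                                          # 47-52
    if (apr_in_cdr) {
      fr3 <- paste0(bg(39), "C", bg(2))                  # 53-94, C at 92
      h3 <- paste0(bg(1), apr_seq, bg(1))                # APR at 96..95+len
      apr_start <- 96L
    } else {
      # APR inside FR3 at 65..64+len, margins >= 5 from region edges
      pre <- bg(11)                                      # 53-63
      post_len <- 91L - (64L + apr_length)               # ..-91
      fr3 <- paste0(pre, bg(1), apr_seq, bg(post_len), "C", bg(2))
      h3 <- bg(h3_len)
      apr_start <- 65L
    }
    fr4 <- "WGQGTLVTVS"
    heavy <- paste0(fr1, h1, fr2, h2, fr3, h3, fr4, "TS")
    h3_start <- 95L
    cdr_h <- list(CDR1 = c(26L, 32L), CDR2 = c(47L, 52L),
                  CDR3 = c(h3_start, h3_start + h3_len - 1L))

    # ---- light chain ----
    # FR1 1-23 with Cys at 23; CDR-L1 24-34; conserved Trp at 35;
    # FR2 35-49; CDR-L2 50-56; FR3 57-88 with Cys at 88; CDR-L3 89-96;
    # FR4 = FGGGTKLEIK from 97.
    lfr1 <- paste0(bg(22), "C")
    l1 <- bg(11)
    lfr2 <- paste0("W", bg(14))
    l2 <- bg(7)
    lfr3 <- paste0(bg(31), "C")
    l3 <- bg(8)
    light <- paste0(lfr1, l1, lfr2, l2, lfr3, l3, "FGGGTKLEIK")
    cdr_l <- list(CDR1 = c(24L, 34L), CDR2 = c(50L, 56L),
                  CDR3 = c(89L, 96L))

    apr <- c(apr_start, apr_start + apr_length - 1L)

    # scatter a few K/E into heavy-chain framework, >= 5 residues from
    # the planted APR and clear of the anchor landmarks
    candidates <- setdiff(c(3:18, 36:44, 55:60, 80:88),
                          seq(apr[1] - 5L, apr[2] + 5L))
    npick <- 4L
    picks <- sort(sample(candidates, npick))
    hv <- strsplit(heavy, "")[[1]]
    hv[picks] <- sample(c("K", "E"), npick, replace = TRUE)
    heavy <- paste(hv, collapse = "")

    structure(list(heavy = heavy, light = light, apr_chain = "H",
                   apr = apr, apr_in_cdr = apr_in_cdr,
                   cdr_h = cdr_h, cdr_l = cdr_l,
                   seed = seed, apr_length = apr_length),
              class = "planted_fixture")
  })
}

#' @export
print.planted_fixture <- function(x, ...) {
  cat("<planted fixture> seed", x$seed, "\n")
  cat("  H:", nchar(x$heavy), "residues; L:", nchar(x$light), "residues\n")
  cat("  planted APR: H", x$apr[1], "-", x$apr[2], " (",
      if (x$apr_in_cdr) "CDR-H3" else "FR3", "): ",
      substr(x$heavy, x$apr[1], x$apr[2]), "\n", sep = "")
  invisible(x)
}

# lattice spacing (A) between consecutive residues of a toy chain; wide
# enough that an exposed residue keeps most of its surface
TOY_SPACING <- 7.0

# backbone + pseudo side chain on a deterministic lattice
toy_chain_atoms <- function(sequence, chain_id, y0 = 0) {
  aa <- strsplit(sequence, "")[[1]]
  rows <- list()
  for (i in seq_along(aa)) {
    x <- TOY_SPACING * i
    at <- rbind(c("N", x - 1.2, y0 - 0.4, 0),
                c("CA", x, y0, 0),
                c("C", x + 1.2, y0 + 0.4, 0),
                c("O", x + 1.2, y0 + 1.6, 0))
    if (aa[i] != "G") at <- rbind(at, c("CB", x, y0, 1.5))
    rows[[i]] <- data.frame(chain = chain_id, resno = i, ins = "",
                            resid = names(AA3)[match(aa[i], AA3)],
                            elety = at[, 1],
                            element = substr(at[, 1], 1, 1),
                            x = as.numeric(at[, 2]),
                            y = as.numeric(at[, 3]) ,
                            z = as.numeric(at[, 4]),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# occluding shell + hydrogen-bond partners around residues [s, e] of a
# toy heavy chain lying on the x-axis
toy_shell_atoms <- function(s, e, radius = 4.2, n_ring = 12L) {
  theta <- seq(0, 2 * pi, length.out = n_ring + 1L)[-(n_ring + 1L)]
  # offset so no ring atom sits exactly on the CB axis (z direction)
  theta <- theta + pi / n_ring
  xs <- seq(TOY_SPACING * (s - 1) - TOY_SPACING / 2,
            TOY_SPACING * (e + 1) + TOY_SPACING / 2, by = TOY_SPACING / 2)
  rows <- list()
  k <- 0L
  for (x in xs) {
    for (t in theta) {
      k <- k + 1L
      rows[[k]] <- c(x, radius * cos(t), radius * sin(t))
    }
  }
  # end caps
  for (x in c(TOY_SPACING * (s - 1) - TOY_SPACING,
              TOY_SPACING * (e + 1) + TOY_SPACING)) {
    for (r in c(0, 2.1)) {
      for (t in if (r == 0) 0 else theta[seq(1, n_ring, by = 2)]) {
        k <- k + 1L
        rows[[k]] <- c(x, r * cos(t), r * sin(t))
      }
    }
  }
  # one hydrogen-bond partner per APR residue, 3.2 A below the backbone N
  for (i in s:e) {
    k <- k + 1L
    rows[[k]] <- c(TOY_SPACING * i - 1.2, -3.6, 0)
  }
  m <- do.call(rbind, rows)
  data.frame(chain = "X", resno = seq_len(nrow(m)), ins = "",
             resid = "GLY", elety = "O", element = "O",
             x = m[, 1], y = m[, 2], z = m[, 3], stringsAsFactors = FALSE)
}

format_pdb_atoms <- function(atoms) {
  sprintf("ATOM  %5d  %-3s%4s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          seq_len(nrow(atoms)), atoms$elety, atoms$resid, atoms$chain,
          atoms$resno, atoms$x, atoms$y, atoms$z, 1.00, 0.00, atoms$element)
}

#' Build a toy structure with controlled APR burial
#'
#' Places the fixture's chains as backbone traces plus single pseudo
#' side-chain atoms on a deterministic lattice. With `burial = "exposed"`
#' every residue sits on the convex surface (planted-APR RSA > 0.75, no
#' hydrogen bonds). With `burial = "buried"` the planted APR is wrapped in a
#' packed shell of occluding atoms (RSA < 0.25) with one hydrogen-bond
#' partner per APR residue, driving the APR's summed stability contribution
#' below the -5 kcal/mol clip so its weight -- and its contribution to the
#' Solubis score -- becomes exactly 0. The two variants differ only in
#' coordinates, never in sequence.
#'
#' @param fixture A [make_toy_fv()] fixture.
#' @param burial `"exposed"` or `"buried"` (placement of the planted APR).
#' @return List with `pdb` (PDB-format lines), `structure` (the lines
#'   parsed back through [read_pdb_chains()]) and `energy_table` (a matched
#'   `residue_energy_table` holding the surrogate [stability_profile()]
#'   values for both chains).
#' @export
make_toy_structure <- function(fixture, burial = c("exposed", "buried")) {
  stopifnot(inherits(fixture, "planted_fixture"))
  burial <- match.arg(burial)
  atoms <- rbind(toy_chain_atoms(fixture$heavy, "H", y0 = 0),
                 toy_chain_atoms(fixture$light, "L", y0 = 60))
  if (burial == "buried")
    atoms <- rbind(atoms,
                   toy_shell_atoms(fixture$apr[1], fixture$apr[2]))
  lines <- c("REMARK   1 SYNTHETIC TOY STRUCTURE (LATTICE FIXTURE)",
             format_pdb_atoms(atoms), "END")
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  on.exit(unlink(path))
  struct <- read_pdb_chains(path)

  tabs <- lapply(c("H", "L"), function(ch) {
    prof <- stability_profile(struct, ch)
    nb <- struct$chains[[ch]]$numbering
    data.frame(chain = ch, position = nb$resno, ins = nb$ins, aa = nb$aa,
               delta_g = prof$delta_g, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  rownames(tab) <- NULL
  class(tab) <- c("residue_energy_table", class(tab))
  list(pdb = lines, structure = struct, energy_table = tab, burial = burial)
}

#' Published antibody benchmark panel
#'
#' The validation panel of eleven publicly available antibodies (mAb1 to
#' mAb11) plus the engineered mAb2 variants, with published raw aggregation
#' totals (TANGO), Solubis scores, APR counts, aggregation classes, and the
#' measured melting / aggregation-onset gaps where available. Gaps reported
#' only as "less than one degree" are encoded as 0.5 degrees C. mAb7
#' aggregated before thermal analysis was possible and carries a forced
#' class-1 label instead of a gap; mAb1 and mAb6 could not be produced or
#' fragmented and are excluded from the scored panel.
#'
#' @param include_mutants Include the engineered mAb2 variants (default
#'   `TRUE`).
#' @return Data frame with columns `antibody`, `total_tango`,
#'   `solubis_score`, `n_aprs`, `label`, `gap` (degrees C, `NA` when not
#'   measurable), `mutant` (logical).
#' @export
mab_benchmark <- function(include_mutants = TRUE) {
  wt <- data.frame(
    antibody = c("mAb2", "mAb3", "mAb4", "mAb5", "mAb7", "mAb8", "mAb9",
                 "mAb10", "mAb11"),
    total_tango = c(1908, 1131, 1621, 2269, 2042, 1639, 680, 695, 771),
    solubis_score = c(377, 71, 51, 321, 681, 50, 93, 71, 4),
    n_aprs = c(8L, 7L, 6L, 10L, 7L, 7L, 5L, 5L, 3L),
    label = c(1L, 0L, 0L, 1L, 1L, 0L, 1L, 0L, 0L),
    gap = c(18.9, 4.6, 0.5, 8.5, NA, 2.8, 7.6, 0.5, 0.5),
    mutant = FALSE,
    stringsAsFactors = FALSE)
  if (!include_mutants) return(wt)
  mt <- data.frame(
    antibody = c("mAb2_VH100R", "mAb2_FH101P", "mAb2_SL50D", "mAb2_SL50K",
                 "mAb2_SL50K_SH21R_SH85R", "mAb2_SL52R",
                 "mAb2_FH101P_SL50K", "mAb2_FH101P_SL50K_SH21R_SH85R",
                 "mAb2_FH101P_SL52R", "mAb2_FH101P_SL52R_SH21R_SH85R"),
    total_tango = c(1652, 1653, 1256, 1228, 1228, 1246, 972, 972, 991, 990),
    solubis_score = c(268, 279, 125, 119, 119, 127, 30, 30, 30, 30),
    n_aprs = c(8L, 8L, 7L, 7L, 7L, 7L, 7L, 7L, 7L, 7L),
    label = c(1L, 0L, 1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L),
    gap = NA_real_,
    mutant = TRUE,
    stringsAsFactors = FALSE)
  rbind(wt, mt)
}
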