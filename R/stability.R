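#' Parameters of the local-stability surrogate
#'
#' The per-residue contribution to the free energy of folding is estimated
#' from structure as
#' `delta_g_i = -(alpha * (1 - RSA_i) * H_i + beta * HB_i) + kappa * C_i`
#' (kcal/mol, negative = stabilizing, the usual force-field sign
#' convention), where `RSA` is relative solvent accessibility, `H` the
#' hydrophobic transfer scale in \[0, 1\] (hydrophilic residues at 0), `HB`
#' the hydrogen-bond count by a geometric criterion and `C` the steric clash
#' count.
#'
#' @param alpha Burial reward per fully buried, fully hydrophobic residue
#'   (kcal/mol), default 0.8.
#' @param beta Reward per hydrogen bond (kcal/mol), default 0.5.
#' @param kappa Penalty per steric clash (kcal/mol), default 1.0.
#' @param hb_cutoff Donor-acceptor distance cutoff for a hydrogen bond (A).
#' @param clash_cutoff Non-bonded heavy-atom distance below which a pair
#'   counts as a clash (A).
#' @param probe Solvent probe radius (A).
#' @param n_sphere_points Sphere points per atom in the rolling-probe
#'   surface-area calculation.
#' @return A list of class `stability_params`.
#' @export
stability_params <- function(alpha = 0.8, beta = 0.5, kappa = 1.0,
                             hb_cutoff = 3.5, clash_cutoff = 2.5,
                             probe = 1.4, n_sphere_points = 100L) {
  structure(list(alpha = alpha, beta = beta, kappa = kappa,
                 hb_cutoff = hb_cutoff, clash_cutoff = clash_cutoff,
                 probe = probe, n_sphere_points = as.integer(n_sphere_points)),
            class = "stability_params")
}

# deterministic golden-spiral points on the unit sphere
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

atom_radii <- function(element) {
  r <- VDW_RADII[element]
  r[is.na(r)] <- 1.80
  unname(r)
}

#' Relative solvent accessibility of a chain
#'
#' Shrake-Rupley rolling-probe accessible surface area, computed per atom on
#' a deterministic golden-spiral point set and summed per residue, divided by
#' the residue type's reference maximum (Gly-X-Gly values) and clipped to
#' \[0, 1\]. All heavy atoms of the structure -- including other chains --
#' act as occluders.
#'
#' @param structure A `pdb_structure` from [read_pdb_chains()].
#' @param chain_id Chain whose residues are reported.
#' @param params A [stability_params()] set.
#' @return Numeric vector of per-residue RSA in \[0, 1\], one value per
#'   residue of the chain, in chain order.
#' @export
relative_accessibility <- function(structure, chain_id,
                                   params = stability_params()) {
  stopifnot(inherits(structure, "pdb_structure"))
  ch <- structure$chains[[chain_id]]
  if (is.null(ch)) stop("no chain '", chain_id, "' in structure")
  all_xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  all_r <- atom_radii(structure$atoms$element) + params$probe
  pts <- sphere_points(params$n_sphere_points)

  ca <- ch$atoms
  rkey <- paste(ca$resno, ca$ins, sep = "\r")
  ukeys <- unique(rkey)
  gkey <- paste(structure$atoms$chain, structure$atoms$resno,
                structure$atoms$ins, sep = "\r")

  vapply(seq_along(ukeys), function(k) {
    sel <- which(structure$atoms$chain == chain_id &
                   gkey == paste(chain_id, ukeys[k], sep = "\r"))
    aa <- three_to_one(structure$atoms$resid[sel[1]])
    if (length(sel) < 3L) {
      warning("residue ", chain_id, sub("\r", "", ukeys[k]),
              " has fewer than 3 atoms; RSA set to 1")
      return(1)
    }
    asa <- 0
    for (ai in sel) {
      ri <- all_r[ai]
      centre <- all_xyz[ai, ]
      d2 <- (all_xyz[, 1] - centre[1])^2 + (all_xyz[, 2] - centre[2])^2 +
        (all_xyz[, 3] - centre[3])^2
      nb <- which(d2 < (ri + all_r)^2 & d2 > 1e-8)
      surf <- sweep(pts * ri, 2, centre, "+")
      if (length(nb)) {
        occluded <- rep(FALSE, nrow(surf))
        for (j in nb) {
          dj2 <- (surf[, 1] - all_xyz[j, 1])^2 +
            (surf[, 2] - all_xyz[j, 2])^2 + (surf[, 3] - all_xyz[j, 3])^2
          occluded <- occluded | dj2 < all_r[j]^2
          if (all(occluded)) break
        }
        frac <- mean(!occluded)
      } else frac <- 1
      asa <- asa + frac * 4 * pi * ri^2
    }
    maxasa <- MAX_ASA[aa]
    if (is.na(maxasa)) maxasa <- mean(MAX_ASA)
    min(1, max(0, asa / maxasa))
  }, numeric(1))
}

# hydrogen bonds and clashes per residue of one chain, given the whole
# structure as context
hb_clash_counts <- function(structure, chain_id, params) {
  at <- structure$atoms
  ch_sel <- at$chain == chain_id
  rkey <- paste(at$resno, at$ins, sep = "\r")
  ukeys <- unique(rkey[ch_sel])
  nres <- length(ukeys)
  hb_bb <- hb_sc <- clash <- integer(nres)

  xyz <- as.matrix(at[, c("x", "y", "z")])
  is_N <- at$element == "N"
  is_O <- at$element == "O"
  backbone <- at$elety %in% c("N", "CA", "C", "O", "OXT")

  # candidate donor (N) / acceptor (O) pairs
  don <- which(is_N)
  acc <- which(is_O)
  hb_pairs <- NULL
  if (length(don) && length(acc)) {
    for (d in don) {
      d2 <- (xyz[acc, 1] - xyz[d, 1])^2 + (xyz[acc, 2] - xyz[d, 2])^2 +
        (xyz[acc, 3] - xyz[d, 3])^2
      hit <- acc[d2 < params$hb_cutoff^2 & d2 > 1e-8]
      for (a in hit) {
        same_res <- at$chain[d] == at$chain[a] && rkey[d] == rkey[a]
        adjacent <- at$chain[d] == at$chain[a] &&
          abs(at$resno[d] - at$resno[a]) < 2L
        if (same_res || adjacent) next
        # angle proxy: antecedent C of the acceptor O (same residue, < 1.8 A)
        ante <- which(at$chain == at$chain[a] & rkey == rkey[a] &
                        at$element == "C")
        ok <- TRUE
        if (length(ante)) {
          da <- sqrt((xyz[ante, 1] - xyz[a, 1])^2 +
                       (xyz[ante, 2] - xyz[a, 2])^2 +
                       (xyz[ante, 3] - xyz[a, 3])^2)
          ante <- ante[da < 1.8]
          if (length(ante)) {
            cvec <- xyz[ante[1], ] - xyz[a, ]
            nvec <- xyz[d, ] - xyz[a, ]
            cosang <- sum(cvec * nvec) /
              (sqrt(sum(cvec^2)) * sqrt(sum(nvec^2)))
            ok <- cosang < 0    # C-O...N angle > 90 degrees
          }
        }
        if (ok) hb_pairs <- rbind(hb_pairs, c(d, a))
      }
    }
  }

  for (k in seq_len(nres)) {
    sel <- which(ch_sel & rkey == ukeys[k])
    if (!is.null(hb_pairs)) {
      inv <- hb_pairs[, 1] %in% sel | hb_pairs[, 2] %in% sel
      involved <- hb_pairs[inv, , drop = FALSE]
      if (nrow(involved)) {
        bb <- backbone[involved[, 1]] & backbone[involved[, 2]]
        own_sc <- (involved[, 1] %in% sel & !backbone[involved[, 1]]) |
          (involved[, 2] %in% sel & !backbone[involved[, 2]])
        hb_sc[k] <- sum(own_sc)
        hb_bb[k] <- sum(!own_sc)
      }
    }
    # clashes: heavy-atom pairs < clash_cutoff, excluding intra-residue
    # pairs and the peptide C(i)-N(i+1) bond
    for (ai in sel) {
      d2 <- (xyz[, 1] - xyz[ai, 1])^2 + (xyz[, 2] - xyz[ai, 2])^2 +
        (xyz[, 3] - xyz[ai, 3])^2
      near <- which(d2 < params$clash_cutoff^2 & d2 > 1e-8)
      for (aj in near) {
        if (at$chain[aj] == at$chain[ai] && rkey[aj] == rkey[ai]) next
        if (at$chain[aj] == at$chain[ai] &&
            abs(at$resno[aj] - at$resno[ai]) == 1L &&
            ((at$elety[ai] == "C" && at$elety[aj] == "N") ||
             (at$elety[ai] == "N" && at$elety[aj] == "C"))) next
        clash[k] <- clash[k] + 1L
      }
    }
  }
  list(hb_backbone = hb_bb, hb_sidechain = hb_sc, clash = clash,
       res_keys = ukeys)
}

#' Per-residue contribution to the free energy of folding
#'
#' Structure-derived surrogate for a per-residue stability decomposition:
#' see [stability_params()] for the functional form. When a
#' `residue_energy_table` is supplied instead of coordinates, its values are
#' used verbatim (provenance `"external_table"`), which is the preferred
#' route when output of a full empirical force field is available.
#'
#' @param structure A `pdb_structure`, or `NULL` when `energy_table` is
#'   given.
#' @param chain_id Chain identifier.
#' @param params A [stability_params()] set.
#' @param energy_table Optional `residue_energy_table`; rows for `chain_id`
#'   are matched to residues by position and insertion code.
#' @param numbering Optional numbering data frame (`position`, `ins`) used to
#'   match `energy_table` rows when no structure is given.
#' @return An object of class `stability_profile`: list with `chain_id`,
#'   `delta_g` (kcal/mol per residue), `rsa`, `hb_backbone`, `hb_sidechain`,
#'   `clash` (all `NA` for external tables) and `provenance`.
#' @export
stability_profile <- function(structure = NULL, chain_id,
                              params = stability_params(),
                              energy_table = NULL, numbering = NULL) {
  if (!is.null(energy_table)) {
    rows <- energy_table[energy_table$chain == chain_id, , drop = FALSE]
    if (nrow(rows) == 0L)
      stop("energy table has no rows for chain '", chain_id, "'")
    if (is.null(numbering)) {
      if (is.null(structure))
        stop("need a structure or a numbering to align the energy table")
      numbering <- structure$chains[[chain_id]]$numbering
      names(numbering)[names(numbering) == "resno"] <- "position"
    }
    key <- paste(numbering$position, numbering$ins, sep = "\r")
    tkey <- paste(rows$position, rows$ins, sep = "\r")
    idx <- match(key, tkey)
    dg <- rows$delta_g[idx]
    if (anyNA(dg)) {
      warning(sum(is.na(dg)), " residue(s) missing from the energy table; ",
              "delta_g set to 0")
      dg[is.na(dg)] <- 0
    }
    return(structure(list(chain_id = chain_id, delta_g = dg,
                          rsa = rep(NA_real_, length(dg)),
                          hb_backbone = NA, hb_sidechain = NA, clash = NA,
                          provenance = "external_table"),
                     class = "stability_profile"))
  }
  stopifnot(inherits(structure, "pdb_structure"))
  ch <- structure$chains[[chain_id]]
  if (is.null(ch)) stop("no chain '", chain_id, "' in structure")
  rsa <- relative_accessibility(structure, chain_id, params)
  hc <- hb_clash_counts(structure, chain_id, params)
  aa <- strsplit(ch$sequence, "")[[1]]
  htil <- HYDRO_TRANSFER[aa]
  htil[is.na(htil)] <- 0
  hb <- hc$hb_backbone + hc$hb_sidechain
  dg <- unname(-(params$alpha * (1 - rsa) * htil + params$beta * hb) +
                 params$kappa * hc$clash)
  structure(list(chain_id = chain_id, delta_g = dg, rsa = rsa,
                 hb_backbone = hc$hb_backbone,
                 hb_sidechain = hc$hb_sidechain, clash = hc$clash,
                 provenance = "surrogate"),
            class = "stability_profile")
}

#' Summed stability contribution of an APR
#'
#' @param stability A [stability_profile()].
#' @param apr Either an interval `c(start, end)` in chain residue order or a
#'   one-row slice of an `apr_set`.
#' @return The exact sum of the per-residue `delta_g` over the interval
#'   (kcal/mol).
#' @export
apr_dg_contrib <- function(stability, apr) {
  stopifnot(inherits(stability, "stability_profile"))
  iv <- if (is.data.frame(apr)) c(apr$start[1], apr$end[1]) else apr
  n <- length(stability$delta_g)
  if (iv[1] < 1L || iv[2] > n || iv[2] < iv[1])
    stop("APR interval [", iv[1], ",", iv[2],
         "] outside stability profile of length ", n)
  sum(stability$delta_g[iv[1]:iv[2]])
}

#' Predicted stability change of a point mutation
#'
#' Recomputes the site's burial term with the mutant residue's hydrophobic
#' transfer value while retaining the wild-type's relative accessibility and
#' backbone hydrogen bonds; side-chain hydrogen bonds are dropped when a
#' polar residue is mutated to an apolar one. Positive values are
#' destabilizing. No side-chain repacking or backbone relaxation is
#' attempted: the value ranks mutations, it does not predict calorimetry.
#'
#' @param structure A `pdb_structure`.
#' @param chain_id Chain identifier.
#' @param pos 1-based residue index in the chain.
#' @param mut One-letter mutant residue.
#' @param params A [stability_params()] set.
#' @param stability Optional precomputed [stability_profile()] for the chain
#'   (saves recomputing the surface).
#' @return Predicted delta-delta-G in kcal/mol.
#' @export
ddg_of_mutation <- function(structure, chain_id, pos, mut,
                            params = stability_params(), stability = NULL) {
  stopifnot(inherits(structure, "pdb_structure"))
  ch <- structure$chains[[chain_id]]
  if (is.null(ch)) stop("no chain '", chain_id, "' in structure")
  aa <- strsplit(ch$sequence, "")[[1]]
  if (pos < 1L || pos > length(aa)) stop("position ", pos, " outside chain")
  wt <- aa[pos]
  mut <- toupper(mut)
  if (wt == mut) stop("identity mutation ", wt, pos, mut)
  if (is.null(stability))
    stability <- stability_profile(structure, chain_id, params)
  rsa <- stability$rsa[pos]
  if (is.na(rsa)) stop("no coordinates for residue ", pos)
  h_wt <- HYDRO_TRANSFER[wt]; h_mut <- HYDRO_TRANSFER[mut]
  if (is.na(h_wt) || is.na(h_mut)) stop("unknown residue in mutation")
  ddg <- params$alpha * (1 - rsa) * (h_wt - h_mut)
  drop_sc <- wt %in% POLAR_SIDECHAIN && !(mut %in% POLAR_SIDECHAIN)
  if (drop_sc) ddg <- ddg + params$beta * stability$hb_sidechain[pos]
  unname(ddg)
}

#' @export
print.stability_profile <- function(x, ...) {
  cat("<stability profile> chain ", x$chain_id, ", ",
      length(x$delta_g), " residues (", x$provenance, ")\n", sep = "")
  invisible(x)
}
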