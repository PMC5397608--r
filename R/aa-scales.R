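# Amino-acid property tables used by the aggregation and stability surrogates.

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
         GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
         LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
         SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
         MSE = "M")

# Kyte-Doolittle hydropathy
KYTE_DOOLITTLE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# Chou-Fasman beta-sheet propensity P(beta)
CHOU_FASMAN_BETA <- c(A = 0.83, R = 0.93, N = 0.89, D = 0.54, C = 1.19,
                      Q = 1.10, E = 0.37, G = 0.75, H = 0.87, I = 1.60,
                      L = 1.30, K = 0.74, M = 1.05, F = 1.38, P = 0.55,
                      S = 0.75, T = 1.19, W = 1.37, Y = 1.47, V = 1.70)

# Unit side-chain charges at neutral pH; histidine neutral by default.
AA_CHARGE <- c(K = 1, R = 1, D = -1, E = -1)

# Theoretical maximum accessible surface areas (Gly-X-Gly context), A^2,
# Tien et al. 2013 values; used to turn absolute SASA into relative SASA.
MAX_ASA <- c(A = 129, R = 274, N = 195, D = 193, C = 167,
             Q = 225, E = 223, G = 104, H = 224, I = 197,
             L = 201, K = 236, M = 224, F = 240, P = 159,
             S = 155, T = 172, W = 285, Y = 263, V = 174)

# Heavy-atom van der Waals radii by element (A)
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

# Residues whose side chains can donate/accept hydrogen bonds
POLAR_SIDECHAIN <- c("S", "T", "N", "Q", "Y", "H", "K", "R", "D", "E", "W")

# Min-max normalized scales over the 20 canonical residues
.norm01 <- function(x) (x - min(x)) / (max(x) - min(x))

HYDRO_NORM <- .norm01(KYTE_DOOLITTLE)       # h in the window energy
BETA_NORM  <- .norm01(CHOU_FASMAN_BETA)     # b in the window energy

# Hydrophobic transfer scale for the burial term: positive hydropathy
# scaled to [0,1], hydrophilic residues at exactly 0.
HYDRO_TRANSFER <- pmax(KYTE_DOOLITTLE, 0) / max(KYTE_DOOLITTLE)

GATEKEEPERS <- c("D", "E", "K", "R", "P")

aa_charge <- function(aa, his_positive = FALSE) {
  chg <- AA_CHARGE[aa]
  chg[is.na(chg)] <- 0
  if (his_positive) chg[aa == "H"] <- 1
  unname(chg)
}

is_canonical_aa <- function(aa) aa %in% AA1

three_to_one <- function(resid) {
  out <- AA3[toupper(resid)]
  if (anyNA(out)) {
    bad <- unique(toupper(resid)[is.na(out)])
    warning("non-standard residue(s) mapped to 'X': ",
            paste(bad, collapse = ", "), call. = FALSE)
    out[is.na(out)] <- "X"
  }
  unname(out)
}
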