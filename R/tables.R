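# Reference tables: residue scattering parameters, atomic parameters and
# van der Waals radii.  Standard biochemical values; electrons counted for the
# in-chain residue (peptide unit), volumes are Chothia-type packing volumes.

#' Residue-level scattering and mass parameters
#'
#' One row per standard amino-acid residue (in-chain unit, i.e. minus one
#' water): total electron count including hydrogens, packing volume
#' (A^3) and average residue mass (Da).  These drive residue-level coarse
#' graining (`b_eff = electrons - rho_solvent * volume`) and sequence masses.
#'
#' @return A tibble with columns `resname`, `aa1`, `electrons`, `volume`,
#'   `mass`.
#' @export
residue_params <- function() {
  tibble::tribble(
    ~resname, ~aa1, ~electrons, ~volume, ~mass,
    "GLY", "G", 30,  60.1,  57.052,
    "ALA", "A", 38,  88.6,  71.079,
    "SER", "S", 46,  89.0,  87.078,
    "PRO", "P", 52, 112.7,  97.117,
    "VAL", "V", 54, 140.0,  99.133,
    "THR", "T", 54, 116.1, 101.105,
    "CYS", "C", 54, 108.5, 103.144,
    "LEU", "L", 62, 166.7, 113.160,
    "ILE", "I", 62, 166.7, 113.160,
    "ASN", "N", 60, 114.1, 114.104,
    "ASP", "D", 60, 111.1, 115.089,
    "GLN", "Q", 68, 143.8, 128.131,
    "LYS", "K", 70, 168.6, 128.174,
    "GLU", "E", 68, 138.4, 129.116,
    "MET", "M", 70, 162.9, 131.198,
    "HIS", "H", 72, 153.2, 137.141,
    "PHE", "F", 78, 189.9, 147.177,
    "ARG", "R", 84, 173.4, 156.188,
    "TYR", "Y", 86, 193.6, 163.176,
    "TRP", "W", 98, 227.8, 186.213
  )
}

# mass of one water molecule (Da), added once per chain terminus pair
.water_mass <- 18.015

# average residue parameters used as fallback for unknown residue names
.average_residue <- function() {
  rp <- residue_params()
  list(electrons = mean(rp$electrons), volume = mean(rp$volume),
       mass = mean(rp$mass))
}

# Atomic electron counts and displaced solvent volumes (A^3) for heavy atoms
# (hydrogens folded into bound heavy atoms are ignored at atom level).
.atom_params <- function() {
  tibble::tribble(
    ~element, ~electrons, ~volume,
    "H",  1,  5.15,
    "C",  6, 16.44,
    "N",  7,  2.49,
    "O",  8,  9.13,
    "S", 16, 19.86,
    "P", 15,  5.73,
    "FE", 26, 7.99,
    "ZN", 30, 9.85
  )
}

# van der Waals radii (A) for SASA
.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                FE = 1.40, ZN = 1.39)
.vdw_default <- 1.70

# electron density of bulk water, e / A^3
.rho_solvent_default <- 0.334

# Gaussian width from volume: sigma = k * V^(1/3), with k such that the
# per-axis second moment matches a uniform sphere of the same volume:
# sphere radius a = (3V/4pi)^(1/3), per-axis variance a^2/5.
.gauss_width <- function(volume) {
  (3 * volume / (4 * pi))^(1 / 3) / sqrt(5)
}

# background amino-acid composition (typical globular protein frequencies)
# used when generating synthetic residue-typed models
.aa_frequencies <- function() {
  f <- c(ALA = 8.3, ARG = 5.5, ASN = 4.1, ASP = 5.5, CYS = 1.4, GLN = 3.9,
         GLU = 6.8, GLY = 7.1, HIS = 2.3, ILE = 5.9, LEU = 9.7, LYS = 5.8,
         MET = 2.4, PHE = 3.9, PRO = 4.7, SER = 6.6, THR = 5.3, TRP = 1.1,
         TYR = 2.9, VAL = 6.9)
  f / sum(f)
}
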