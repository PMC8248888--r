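#' Survey of deposited benchmark structures
#'
#' Unit-cell contents of the PDB entries routinely used to benchmark
#' dual-space phasing at atomic resolution, as printed in the published
#' survey tables: non-H atom count N per centering, refined water count,
#' and scatterer class.  Used as the input for the empirical solvent
#' expansion factor (see [solvent_expansion_factor()]).
#'
#' @return Tibble with columns `pdb`, `class` (weak / medium / strong),
#'   `n_atoms` (non-H atoms incl. solvent, per centering) and `n_water`
#'   (refined water molecules, per centering; water contributes one O
#'   atom each).
#' @export
pdb_survey <- function() {
  tibble::tribble(
    ~pdb,    ~class,   ~n_atoms, ~n_water,
    "1a7y",  "weak",       314,       44,
    "3sbn",  "weak",       444,       32,
    "1ob4",  "weak",       548,       60,
    "1a7z",  "weak",      1228,        4,
    "1alz",  "weak",      1348,        4,
    "1byz",  "medium",     479,       30,
    "2erl",  "medium",     656,       44,
    "1p9g",  "medium",     702,      122,
    "3nir",  "medium",     902,      196,
    "1a0m",  "medium",    1144,      168,
    "4lzt",  "medium",    1183,      139,
    "1f94",  "medium",    1232,      236,
    "1hhu",  "medium",    1310,      250,
    "3odv",  "medium",    1392,      180,
    "3psm",  "medium",    1882,      366,
    "3bcj",  "medium",    7308,     1374,
    "2bf9",  "strong",     768,      164,
    "8rxn",  "strong",    1010,      204,
    "1w3m",  "strong",    1276,      191,
    "2ov0",  "strong",    2060,      432,
    "1c75",  "strong",    2660,      500,
    "3d1p",  "strong",    2702,      498,
    "1pwl",  "strong",    3030,      429,
    "1a6m",  "strong",    3154,      372,
    "41au",  "strong",    3278,      740,
    "1eb6",  "strong",    3300,      518,
    "1b0y",  "strong",    3348,      824,
    "1x8q",  "strong",    3662,      720,
    "2fdn",  "strong",    3964,      768,
    "3fsa",  "strong",    4488,      856,
    "1c7k",  "strong",    4532,      464,
    "3ks3",  "strong",    5626,      962,
    "1heu",  "strong",    7618,     1297)
}

#' Empirical solvent expansion factor
#'
#' The peak count N fed to the ipp procedure is protein plus solvent
#' atoms.  When the water count is unknown it can be estimated from the
#' survey: averaging (N_protein + N_water) / N_protein over all survey
#' entries with more than `min_atoms` atoms gives approximately 1.22,
#' i.e. about 0.22 water molecules worth of atoms per protein atom.
#'
#' @param survey A data frame with `n_atoms` and `n_water` columns;
#'   defaults to [pdb_survey()].
#' @param min_atoms Only entries with `n_atoms` above this bound enter
#'   the average (small oligopeptides with little ordered solvent would
#'   bias it).
#' @return List with `factor` (the mean), `sd` and `n_entries`.
#' @export
solvent_expansion_factor <- function(survey = pdb_survey(), min_atoms = 700) {
  s <- survey[survey$n_atoms > min_atoms, ]
  r <- s$n_atoms / (s$n_atoms - s$n_water)
  list(factor = mean(r), sd = stats::sd(r), n_entries = nrow(s))
}

#' Ordered interatomic difference vectors among n scatterers
#'
#' The Patterson-type modulus synthesis of a structure whose scattering
#' is dominated by n strong sites shows n^2 - n non-origin difference
#' vector peaks (ordered pairs i != j).  For a 16-Fe cluster arrangement
#' this is the classic 240-peak special case, used as a peak-count
#' override for the first shifted-modulus iteration.
#'
#' @param n Number of dominant scatterers.
#' @return n^2 - n.
#' @export
interatomic_vector_count <- function(n) {
  stopifnot(n >= 1)
  n^2 - n
}
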