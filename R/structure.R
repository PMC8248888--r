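#' Point-atom crystal structure in P1
#'
#' A `crystal_structure` bundles a [unit_cell()] with a tibble of point-atom
#' sites.  Sites carry fractional coordinates, a scattering weight `w`
#' (electrons; the atomic number Z for a neutral point atom) and an element
#' label.  Coordinates are reduced mod 1 on construction.
#'
#' The scatterer class of the structure is derived from the strongest
#' scatterer present: `"strong"` when max Z >= 19, `"medium"` when
#' 16 <= max Z < 19 (S or Cl present), `"weak"` otherwise.
#'
#' @param cell A [unit_cell()].
#' @param sites A data frame with columns `x`, `y`, `z` (fractional),
#'   `w` (> 0) and optionally `label`.
#' @return A `crystal_structure` object: list with `cell`, `sites`
#'   (tibble) and `class_tag`.
#' @examples
#' st <- crystal_structure(unit_cell(10, 10, 10),
#'                         data.frame(x = 0, y = 0, z = 0, w = 6))
#' st$class_tag
#' @export
crystal_structure <- function(cell, sites) {
  stopifnot(is_unit_cell(cell))
  sites <- tibble::as_tibble(sites)
  req <- c("x", "y", "z", "w")
  if (!all(req %in% names(sites)))
    stop("sites must have columns x, y, z, w", call. = FALSE)
  if (nrow(sites) == 0) stop("no atoms", call. = FALSE)
  if (any(sites$w <= 0)) stop("scattering weights must be positive", call. = FALSE)
  sites$x <- sites$x %% 1
  sites$y <- sites$y %% 1
  sites$z <- sites$z %% 1
  if (!"label" %in% names(sites)) sites$label <- guess_element(sites$w)
  structure(list(cell = cell, sites = sites,
                 class_tag = scatterer_class(max(sites$w))),
            class = "crystal_structure")
}

#' @export
print.crystal_structure <- function(x, ...) {
  cat(sprintf("<crystal_structure> %d point atoms (%s scatterers), cell V=%.4g A^3\n",
              nrow(x$sites), x$class_tag, x$cell$volume))
  invisible(x)
}

is_crystal_structure <- function(x) inherits(x, "crystal_structure")

scatterer_class <- function(zmax) {
  if (zmax >= 19) "strong" else if (zmax >= 16) "medium" else "weak"
}

guess_element <- function(w) {
  tab <- c(C = 6, N = 7, O = 8, S = 16, Cl = 17, K = 19, Ca = 20,
           Fe = 26, Cu = 29, Zn = 30, Se = 34, Br = 35)
  names(tab)[pmax(1L, findInterval(w + 0.5, tab))]
}

#' Write a structure as minimal PDB-format ATOM records
#'
#' Emits a CRYST1 card (P1) followed by one ATOM record per site with
#' orthogonalized coordinates, so the structure can be inspected in any
#' standard molecular viewer.
#'
#' @param structure A [crystal_structure()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  stopifnot(is_crystal_structure(structure))
  cl <- structure$cell
  lines <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                   cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma)
  orth <- fractional_to_cartesian(cl, as.matrix(structure$sites[, c("x", "y", "z")]))
  s <- structure$sites
  lines <- c(lines, sprintf(
    "ATOM  %5d %-4s UNK A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(s)), substr(s$label, 1, 4), 1L,
    orth[, 1], orth[, 2], orth[, 3], 1, 0, s$label))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a minimal PDB file back into a structure
#'
#' Inverse of [write_structure_pdb()] for files this package wrote: parses
#' the CRYST1 card and ATOM records, converting orthogonal back to
#' fractional coordinates.  Scattering weights are taken from the element
#' column.
#'
#' @param path PDB file path.
#' @return A [crystal_structure()].
#' @export
read_structure_pdb <- function(path) {
  lines <- readLines(path)
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr) != 1) stop("expected exactly one CRYST1 card", call. = FALSE)
  nums <- as.numeric(c(substr(cr, 7, 15), substr(cr, 16, 24), substr(cr, 25, 33),
                       substr(cr, 34, 40), substr(cr, 41, 47), substr(cr, 48, 54)))
  cell <- unit_cell(nums[1], nums[2], nums[3], nums[4], nums[5], nums[6])
  at <- grep("^ATOM  ", lines, value = TRUE)
  if (length(at) == 0) stop("no atoms", call. = FALSE)
  xyz <- cbind(as.numeric(substr(at, 31, 38)),
               as.numeric(substr(at, 39, 46)),
               as.numeric(substr(at, 47, 54)))
  el <- trimws(substr(at, 77, 78))
  ztab <- c(C = 6, N = 7, O = 8, S = 16, Cl = 17, K = 19, Ca = 20,
            Fe = 26, Cu = 29, Zn = 30, Se = 34, Br = 35)
  w <- unname(ztab[el])
  if (any(is.na(w))) stop("unknown element in PDB file", call. = FALSE)
  frac <- cartesian_to_fractional(cell, xyz)
  crystal_structure(cell, tibble::tibble(
    x = frac[, 1], y = frac[, 2], z = frac[, 3], w = w, label = el))
}

# standard PDB orthogonalization (a along x, b in xy plane)
orthogonalization_matrix <- function(cell) {
  ca <- cos(cell$alpha * pi / 180); cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180); sg <- sin(cell$gamma * pi / 180)
  v <- cell$volume / (cell$a * cell$b * cell$c)
  matrix(c(cell$a, cell$b * cg, cell$c * cb,
           0,      cell$b * sg, cell$c * (ca - cb * cg) / sg,
           0,      0,           cell$c * v / sg), 3, 3, byrow = TRUE)
}

fractional_to_cartesian <- function(cell, frac) {
  t(orthogonalization_matrix(cell) %*% t(frac))
}

cartesian_to_fractional <- function(cell, xyz) {
  t(solve(orthogonalization_matrix(cell)) %*% t(xyz))
}
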