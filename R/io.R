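#' Write a reflection set as whitespace text
#'
#' The package's native exchange format: a small header (cell, d_min,
#' reflection count) followed by one `h k l |E| [phase_deg]` record per
#' Friedel-unique reflection.  Writing and re-reading a canonical file
#' is the identity.
#'
#' @param reflections Reflection tibble with attributes `cell`, `d_min`.
#' @param path Output path.
#' @param phases Optional phases in radians; written as a degrees column
#'   (used for ground-truth sidecar files, never for engine input).
#' @return `path`, invisibly.
#' @export
write_reflections <- function(reflections, path, phases = NULL) {
  cell <- attr(reflections, "cell")
  d_min <- attr(reflections, "d_min")
  stopifnot(is_unit_cell(cell), !is.null(d_min))
  header <- c("# smipp reflection file",
              sprintf("CELL %.6g %.6g %.6g %.6g %.6g %.6g",
                      cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma),
              sprintf("DMIN %.6g", d_min),
              sprintf("NREF %d", nrow(reflections)))
  if (is.null(phases)) {
    rec <- sprintf("%d %d %d %.8g", reflections$h, reflections$k,
                   reflections$l, reflections$E)
  } else {
    stopifnot(length(phases) == nrow(reflections))
    rec <- sprintf("%d %d %d %.8g %.8g", reflections$h, reflections$k,
                   reflections$l, reflections$E, (phases * 180 / pi) %% 360)
  }
  writeLines(c(header, rec), path)
  invisible(path)
}

#' Read a reflection text file
#'
#' Parses the format of [write_reflections()], validates it (malformed
#' lines are reported with their line number; duplicate indices or
#' Friedel-mate duplicates are rejected by name) and precomputes the
#' working-set mean modulus.
#'
#' @param path Input path.
#' @return Reflection tibble (`h`, `k`, `l`, `E`, optionally `phase` in
#'   degrees) with attributes `cell`, `d_min`, `mean_E`.
#' @export
read_reflections <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  grab <- function(key) {
    m <- grep(paste0("^", key, "\\b"), lines)
    if (length(m) != 1) stop("expected exactly one ", key, " header line",
                             call. = FALSE)
    as.numeric(strsplit(trimws(lines[m]), "\\s+")[[1]][-1])
  }
  cellv <- grab("CELL")
  if (length(cellv) != 6) stop("CELL header needs 6 numbers", call. = FALSE)
  cell <- unit_cell(cellv[1], cellv[2], cellv[3], cellv[4], cellv[5], cellv[6])
  d_min <- grab("DMIN")[1]
  nref <- as.integer(grab("NREF")[1])
  body <- grepl("^\\s*-?[0-9]", lines)
  rec_lines <- lines[body]
  rec_nos <- lineno[body]
  toks <- strsplit(trimws(rec_lines), "\\s+")
  nf <- lengths(toks)
  bad <- which(!(nf %in% c(4L, 5L)))
  if (length(bad) > 0)
    stop("malformed reflection record at line ", rec_nos[bad[1]], call. = FALSE)
  vals <- suppressWarnings(lapply(toks, as.numeric))
  bad <- which(vapply(vals, function(v) any(is.na(v)), logical(1)))
  if (length(bad) > 0)
    stop("malformed reflection record at line ", rec_nos[bad[1]], call. = FALSE)
  m <- do.call(rbind, lapply(vals, function(v) c(v, NA)[1:5]))
  if (nrow(m) != nref)
    stop(sprintf("NREF header says %d but %d records found", nref, nrow(m)),
         call. = FALSE)
  hkl <- m[, 1:3, drop = FALSE]
  if (any(hkl != round(hkl))) stop("non-integer Miller index", call. = FALSE)
  storage.mode(hkl) <- "integer"
  if (any(m[, 4] < 0)) stop("negative |E| modulus", call. = FALSE)
  key_p <- paste(hkl[, 1], hkl[, 2], hkl[, 3])
  key_m <- paste(-hkl[, 1], -hkl[, 2], -hkl[, 3])
  dup <- which(duplicated(key_p) | key_m %in% key_p)
  if (length(dup) > 0)
    stop("duplicate or Friedel-mate duplicate index (",
         key_p[dup[1]], ")", call. = FALSE)
  out <- tibble::tibble(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3], E = m[, 4])
  if (!all(is.na(m[, 5]))) out$phase <- m[, 5]
  attr(out, "cell") <- cell
  attr(out, "d_min") <- d_min
  attr(out, "mean_E") <- mean(out$E)
  out
}

#' Ground truth from a sidecar reflection file
#'
#' Converts a reflection tibble carrying a `phase` column (degrees),
#' as written by [write_reflections()] with `phases`, into the truth
#' list consumed by [align_and_score()] via [run_trial()].
#'
#' @param reflections Reflection tibble with a `phase` column.
#' @return List with `phases` in radians.
#' @export
as_ground_truth <- function(reflections) {
  if (!"phase" %in% names(reflections))
    stop("no phase column: not a ground-truth sidecar", call. = FALSE)
  list(phases = reflections$phase * pi / 180)
}

#' Import structure factors from an mmCIF file
#'
#' Best-effort adapter for deposited structure-factor mmCIF files: reads
#' the `_refln` loop, takes an E-type column directly when present, or
#' normalizes an F-type amplitude column by resolution-shell averaging
#' (|E|^2 = F^2 / <F^2>_shell, 20 equal-count shells).  Indices are
#' folded onto the canonical Friedel hemisphere; duplicates after
#' folding are dropped with a warning.  A path to a native text file
#' (see [write_reflections()]) is passed through unchanged.
#'
#' @param path mmCIF (or native text) file path.
#' @return Reflection tibble with attributes `cell`, `d_min`, `mean_E`.
#' @export
import_external <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("smipp reflection file", first)) return(read_reflections(path))
  lines <- readLines(path)
  num <- function(tag) {
    m <- grep(paste0("^\\s*", tag, "\\s"), lines, value = TRUE)
    if (length(m) == 0) return(NA_real_)
    as.numeric(strsplit(trimws(m[1]), "\\s+")[[1]][2])
  }
  cell <- unit_cell(num("_cell.length_a"), num("_cell.length_b"),
                    num("_cell.length_c"),
                    ifelse(is.na(num("_cell.angle_alpha")), 90, num("_cell.angle_alpha")),
                    ifelse(is.na(num("_cell.angle_beta")),  90, num("_cell.angle_beta")),
                    ifelse(is.na(num("_cell.angle_gamma")), 90, num("_cell.angle_gamma")))
  # locate the _refln loop
  loop_starts <- grep("^\\s*loop_", lines)
  refln <- NULL
  for (ls in loop_starts) {
    j <- ls + 1
    tags <- character(0)
    while (j <= length(lines) && grepl("^\\s*_", lines[j])) {
      tags <- c(tags, trimws(lines[j])); j <- j + 1
    }
    if (any(grepl("^_refln\\.", tags))) {
      rows <- character(0)
      while (j <= length(lines) && !grepl("^\\s*(loop_|_|#|$)", lines[j])) {
        rows <- c(rows, lines[j]); j <- j + 1
      }
      refln <- list(tags = tags, rows = rows)
      break
    }
  }
  if (is.null(refln)) stop("no _refln loop found", call. = FALSE)
  toks <- strsplit(trimws(refln$rows), "\\s+")
  tab <- do.call(rbind, toks)
  colnames(tab) <- refln$tags
  need <- c("_refln.index_h", "_refln.index_k", "_refln.index_l")
  if (!all(need %in% refln$tags))
    stop("missing Miller index columns in _refln loop", call. = FALSE)
  e_col <- intersect(c("_refln.E_meas", "_refln.pdbx_E_value"), refln$tags)
  f_col <- intersect(c("_refln.F_meas_au", "_refln.F_meas"), refln$tags)
  if (length(e_col) == 0 && length(f_col) == 0)
    stop("no amplitude column; available columns: ",
         paste(refln$tags, collapse = ", "), call. = FALSE)
  hkl <- cbind(as.integer(tab[, need[1]]), as.integer(tab[, need[2]]),
               as.integer(tab[, need[3]]))
  if (length(e_col) > 0) {
    E <- as.numeric(tab[, e_col[1]])
  } else {
    f <- as.numeric(tab[, f_col[1]])
    q <- 1 / d_spacing(cell, hkl)^2
    shell <- cut(rank(q, ties.method = "first"), 20, labels = FALSE)
    msq <- tapply(f^2, shell, mean)
    E <- f / sqrt(msq[shell])
  }
  ok <- is.finite(E)
  hkl <- hkl[ok, , drop = FALSE]; E <- E[ok]
  flip <- hkl[, 1] < 0 | (hkl[, 1] == 0 & hkl[, 2] < 0) |
    (hkl[, 1] == 0 & hkl[, 2] == 0 & hkl[, 3] < 0)
  hkl[flip, ] <- -hkl[flip, , drop = FALSE]
  key <- paste(hkl[, 1], hkl[, 2], hkl[, 3])
  if (anyDuplicated(key)) {
    warning("duplicate indices after Friedel folding; keeping first occurrence")
    keep <- !duplicated(key)
    hkl <- hkl[keep, , drop = FALSE]; E <- E[keep]
  }
  nz <- rowSums(hkl != 0) > 0
  hkl <- hkl[nz, , drop = FALSE]; E <- E[nz]
  out <- tibble::tibble(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3], E = E)
  attr(out, "cell") <- cell
  attr(out, "d_min") <- min(d_spacing(cell, hkl))
  attr(out, "mean_E") <- mean(E)
  out[order(out$h, out$k, out$l), ]
}

#' Read a flat key-value configuration file
#'
#' YAML with flat keys mirroring the [phasing_config()] field names;
#' used by the command-line interface, where flags override file values.
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
load_config <- function(path) {
  yaml::read_yaml(path)
}
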