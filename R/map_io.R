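# CCP4/MRC map and minimal PDB input/output.
#
# The map writer emits MRC2000-style mode-2 (float32) maps with cubic
# voxels, space group P1, orthogonal axes, column/row/section = x/y/z, and
# the origin in the ORIGIN header words (50-52). The reader accepts exactly
# this subset. Header word ledger (1-based, 256 four-byte words):
#   1-3   NX NY NZ        4 MODE        5-7  N*START      8-10 MX MY MZ
#   11-16 CELL a b c alpha beta gamma   17-19 MAPC MAPR MAPS
#   20-22 DMIN DMAX DMEAN 23 ISPG       24 NSYMBT        25-49 EXTRA
#   50-52 ORIGIN x y z    53 "MAP "     54 MACHST        55 RMS
#   56 NLABL              57-256 labels (800 bytes)

#' Write a density map in CCP4/MRC format
#'
#' @param map A [density_map()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ccp4 <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  d <- map$dims
  vals <- as.vector(map$values)
  wi(d)                                  # 1-3
  wi(2L)                                 # 4 MODE: float32
  wi(c(0L, 0L, 0L))                      # 5-7
  wi(d)                                  # 8-10 sampling = extent
  wf(d * map$voxel)                      # 11-13 cell edges (A)
  wf(c(90, 90, 90))                      # 14-16 angles
  wi(c(1L, 2L, 3L))                      # 17-19 axis order x,y,z
  wf(c(min(vals), max(vals), mean(vals)))# 20-22
  wi(1L)                                 # 23 ISPG = P1
  wi(0L)                                 # 24 NSYMBT
  wi(rep(0L, 25))                        # 25-49 EXTRA
  wf(map$origin)                         # 50-52 ORIGIN (A)
  writeChar("MAP ", con, 4, eos = NULL)  # 53
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # 54 MACHST little-endian
  wf(sd(vals))                           # 55 RMS
  wi(0L)                                 # 56 NLABL
  writeBin(raw(800), con)                # 57-256 labels
  writeBin(as.numeric(vals), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a CCP4/MRC map written by [write_ccp4()]
#'
#' Supports the subset this package writes: mode 2, axis order x/y/z,
#' orthogonal cell, cubic voxels.
#'
#' @param path Map file path.
#' @return A [density_map()].
#' @export
read_ccp4 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (mode != 2) .stopf("unsupported MRC mode %d (only float32 mode 2)", mode)
  ri(3); mxyz <- ri(3)
  cell <- rf(3); angles <- rf(3)
  axes <- ri(3)
  if (!identical(axes, c(1L, 2L, 3L))) .stopf("unsupported axis order")
  if (any(abs(angles - 90) > 1e-3)) .stopf("only orthogonal cells supported")
  rf(3); ri(2); ri(25)
  origin <- rf(3)
  readBin(con, "raw", 4)   # MAP_
  readBin(con, "raw", 4)   # MACHST
  rf(1); ri(1); readBin(con, "raw", 800)
  voxels <- cell / mxyz
  if (diff(range(voxels)) > 1e-6 * voxels[1]) .stopf("only cubic voxels supported")
  vals <- readBin(con, "numeric", prod(d), size = 4, endian = "little")
  density_map(array(vals, d), origin = origin, voxel = voxels[1])
}

#' Write atom sites as a minimal PDB file
#'
#' Emits HETATM records with orthogonal Angstrom coordinates, occupancy and
#' B columns. Effective electron counts (which plain PDB cannot carry) go in
#' the element column only through the element symbol; use [atom_sites()]
#' with explicit `n_electrons` after reading to restore ionized values.
#'
#' @param sites An [atom_sites()] data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(sites, path) {
  stopifnot(inherits(sites, "atom_sites"))
  lines <- vapply(seq_len(nrow(sites)), function(i) {
    el <- sites$element[i]
    sprintf("HETATM%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, substr(el, 1, 4), "LIG", i,
            sites$x[i], sites$y[i], sites$z[i],
            sites$occupancy[i], sites$b_factor[i], substr(toupper(el), 1, 2))
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read atom sites from a minimal PDB file
#'
#' Parses ATOM/HETATM records (fixed columns); electron counts are assigned
#' from the element symbol (H, C, N, O, S, Gd known) unless overridden.
#'
#' @param path PDB file path.
#' @param n_electrons Optional vector overriding per-site electron counts.
#' @return An [atom_sites()] data.frame.
#' @export
read_pdb <- function(path, n_electrons = NULL) {
  lines <- readLines(path)
  rec <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (!length(rec)) .stopf("no ATOM/HETATM records in %s", path)
  num <- function(a, b) as.numeric(trimws(substr(rec, a, b)))
  el <- trimws(substr(rec, 77, 78))
  el <- ifelse(el == "", trimws(substr(rec, 13, 14)), el)
  el <- paste0(substr(el, 1, 1), tolower(substr(el, 2, 2)))
  atom_sites(x = num(31, 38), y = num(39, 46), z = num(47, 54),
             element = el, n_electrons = n_electrons,
             occupancy = num(55, 60), b_factor = num(61, 66))
}
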