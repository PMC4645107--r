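# Synthetic-map electron counting. Atoms are rendered as isotropic 3-D
# Gaussians (integral = occupancy * n_electrons, variance from the
# crystallographic B-factor convention B = 8 pi^2 <u^2>); omit-region
# integrals of positive density are calibrated against a reference region of
# known electron count (e.g. part of a tryptophan, 48 electrons), with
# occupancy correction. Ratio-based counting is invariant under global map
# scaling, so single-Gaussian atoms (no form-factor sums) suffice.

#' Atom sites
#'
#' @param x,y,z Orthogonal coordinates in Angstrom.
#' @param element Element symbols.
#' @param n_electrons Effective electrons per site (ionized values allowed).
#' @param occupancy Fractional occupancies in (0, 1].
#' @param b_factor Isotropic B-factors in A^2 (> 0).
#' @return data.frame of class `atom_sites`.
#' @export
atom_sites <- function(x, y, z, element = "C", n_electrons = NULL,
                       occupancy = 1, b_factor = 15) {
  n <- length(x)
  if (is.null(n_electrons)) {
    n_electrons <- .ELECTRONS_BY_ELEMENT[element]
    if (anyNA(n_electrons)) {
      .stopf("unknown element(s) %s: supply n_electrons explicitly",
             paste(unique(element[is.na(n_electrons)]), collapse = ", "))
    }
  }
  df <- data.frame(x = x, y = y, z = z,
                   element = rep_len(element, n),
                   n_electrons = as.numeric(rep_len(n_electrons, n)),
                   occupancy = rep_len(occupancy, n),
                   b_factor = rep_len(b_factor, n),
                   stringsAsFactors = FALSE)
  if (any(df$occupancy <= 0 | df$occupancy > 1)) .stopf("occupancy must be in (0, 1]")
  if (any(df$n_electrons < 0)) .stopf("n_electrons must be >= 0")
  if (any(df$b_factor <= 0)) .stopf("b_factor must be > 0")
  class(df) <- c("atom_sites", "data.frame")
  df
}

.ELECTRONS_BY_ELEMENT <- c(H = 1, C = 6, N = 7, O = 8, S = 16, Gd = 64)

#' Density map container
#'
#' A real-space electron-density grid (e-/A^3) on a cubic-voxel, axis-aligned
#' box. `values[i, j, k]` sits at `origin + (c(i, j, k) - 1) * voxel`.
#'
#' @param values 3-D numeric array.
#' @param origin Length-3 position of the first voxel centre (Angstrom).
#' @param voxel Cubic voxel edge (Angstrom, > 0).
#' @return Object of class `density_map`.
#' @export
density_map <- function(values, origin = c(0, 0, 0), voxel = 0.3) {
  if (!is.array(values) || length(dim(values)) != 3L) .stopf("values must be a 3-D array")
  if (!all(is.finite(values))) .stopf("map values must be finite")
  if (!.is_number(voxel) || voxel <= 0) .stopf("voxel must be > 0")
  if (length(origin) != 3L) .stopf("origin must have length 3")
  structure(list(origin = as.numeric(origin), voxel = voxel,
                 dims = dim(values), values = values),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %d x %d x %d voxels of %.3g A; origin (%s) A\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel,
              paste(sprintf("%.2f", x$origin), collapse = ", ")))
  cat(sprintf("  total electrons: %.2f; range [%.3g, %.3g] e-/A^3\n",
              sum(x$values) * x$voxel^3, min(x$values), max(x$values)))
  invisible(x)
}

#' Spherical omit region
#'
#' @param center Length-3 centre (Angstrom).
#' @param radius Sphere radius (Angstrom, > 0).
#' @return Object of class `omit_region`.
#' @export
omit_region <- function(center, radius = 2.0) {
  if (length(center) != 3L) .stopf("center must have length 3")
  if (!.is_number(radius) || radius <= 0) .stopf("radius must be > 0")
  structure(list(center = as.numeric(center), radius = radius), class = "omit_region")
}

# Axis coordinate vectors of a map.
.axis_coords <- function(map) {
  lapply(1:3, function(a) map$origin[a] + (seq_len(map$dims[a]) - 1) * map$voxel)
}

#' Render atom sites to a density map
#'
#' Each site contributes an isotropic 3-D Gaussian of integral
#' `occupancy * n_electrons` and standard deviation
#' `sigma = sqrt(B / (8 pi^2))`. Sites must sit at least three FWHM
#' (`FWHM = sqrt(8 ln 2) * sigma`) inside every grid face so that the
#' rendered total is conserved to well under 0.5%.
#'
#' @param sites An [atom_sites()] data.frame.
#' @param origin,voxel,dims Grid specification; by default a bounding box
#'   with a 3.5-FWHM margin around the sites is used.
#' @return A [density_map()].
#' @export
render_map <- function(sites, origin = NULL, voxel = 0.3, dims = NULL) {
  stopifnot(inherits(sites, "atom_sites"))
  sig <- .b_to_sigma(sites$b_factor)
  fwhm <- sig * .FWHM_PER_SIGMA
  if (is.null(origin) || is.null(dims)) {
    margin <- 3.5 * max(fwhm)
    lo <- c(min(sites$x), min(sites$y), min(sites$z)) - margin
    hi <- c(max(sites$x), max(sites$y), max(sites$z)) + margin
    origin <- lo
    dims <- ceiling((hi - lo) / voxel) + 1L
  }
  map <- density_map(array(0, dims), origin = origin, voxel = voxel)
  ax <- .axis_coords(map)
  lo <- map$origin
  hi <- map$origin + (map$dims - 1L) * map$voxel
  for (i in seq_len(nrow(sites))) {
    pos <- c(sites$x[i], sites$y[i], sites$z[i])
    if (any(pos - 3 * fwhm[i] < lo) || any(pos + 3 * fwhm[i] > hi)) {
      .stopf("site %d at (%.2f, %.2f, %.2f) is within 3 FWHM of the grid boundary",
             i, pos[1], pos[2], pos[3])
    }
    amp <- sites$occupancy[i] * sites$n_electrons[i]
    gx <- dnorm(ax[[1]], pos[1], sig[i])
    gy <- dnorm(ax[[2]], pos[2], sig[i])
    gz <- dnorm(ax[[3]], pos[3], sig[i])
    # restrict to a 5-sigma window for speed; negligible mass outside
    ix <- which(gx > dnorm(5) * max(gx)); iy <- which(gy > dnorm(5) * max(gy))
    iz <- which(gz > dnorm(5) * max(gz))
    map$values[ix, iy, iz] <- map$values[ix, iy, iz] +
      amp * (gx[ix] %o% gy[iy] %o% gz[iz])
  }
  map
}

#' Voxelwise difference of two maps
#'
#' @param map_a,map_b [density_map()]s on identical grids.
#' @return `map_a - map_b` as a [density_map()].
#' @export
difference_map <- function(map_a, map_b) {
  stopifnot(inherits(map_a, "density_map"), inherits(map_b, "density_map"))
  if (!isTRUE(all.equal(map_a$origin, map_b$origin)) ||
      !identical(map_a$dims, map_b$dims) ||
      !isTRUE(all.equal(map_a$voxel, map_b$voxel))) {
    .stopf("maps are on different grids")
  }
  density_map(map_a$values - map_b$values, origin = map_a$origin, voxel = map_a$voxel)
}

# Logical mask of voxels whose centres lie within any of the given regions.
.region_mask <- function(map, regions) {
  if (inherits(regions, "omit_region")) regions <- list(regions)
  ax <- .axis_coords(map)
  mask <- array(FALSE, map$dims)
  lo <- map$origin; hi <- map$origin + (map$dims - 1L) * map$voxel
  for (rg in regions) {
    if (any(rg$center - rg$radius < lo - map$voxel / 2) ||
        any(rg$center + rg$radius > hi + map$voxel / 2)) {
      .stopf("region at (%s) A, radius %.2f A, extends outside the grid",
             paste(sprintf("%.2f", rg$center), collapse = ", "), rg$radius)
    }
    dx2 <- (ax[[1]] - rg$center[1])^2
    dy2 <- (ax[[2]] - rg$center[2])^2
    dz2 <- (ax[[3]] - rg$center[3])^2
    d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    mask <- mask | (d2 <= rg$radius^2)
  }
  mask
}

#' Integrate positive density over an omit region
#'
#' Sum of map values exceeding `threshold` over voxels whose centres lie
#' within the region (a sphere, or a union of spheres), times the voxel
#' volume.
#'
#' @param map A [density_map()].
#' @param region An [omit_region()] or a list of them (union of spheres).
#' @param threshold Positivity threshold in e-/A^3 (default 0).
#' @return Integrated electrons.
#' @export
integrate_positive <- function(map, region, threshold = 0) {
  stopifnot(inherits(map, "density_map"))
  mask <- .region_mask(map, region)
  v <- map$values[mask]
  sum(v[v > threshold]) * map$voxel^3
}

#' Electron counting against a known reference region
#'
#' The estimate is
#' `(I_target / I_reference) * reference_electrons * (occ_ref / occ_target)`,
#' where `I` are positive-density omit-region integrals. When additional
#' reference regions are supplied (mimicking the repeat-with-other-residues
#' error estimate), the relative uncertainty is the coefficient of variation
#' of the estimates across references.
#'
#' @param map A [density_map()].
#' @param target An [omit_region()] (or union list) around the site of
#'   interest.
#' @param reference Reference region (or union list) of known content.
#' @param target_occupancy,reference_occupancy Site occupancies.
#' @param reference_electrons Electrons in the fully occupied reference
#'   (default 48: e.g. eight carbon-like atoms of a tryptophan fragment).
#' @param threshold Positivity threshold passed to [integrate_positive()].
#' @param extra_references Optional list of additional reference regions
#'   (each an `omit_region` or union list) for the uncertainty estimate.
#' @return Object of class `electron_count`: `electrons`,
#'   `relative_uncertainty` (`NA` without extra references), and the raw
#'   integrals.
#' @export
electrons_by_reference <- function(map, target, reference,
                                   target_occupancy = 1, reference_occupancy = 1,
                                   reference_electrons = 48, threshold = 0,
                                   extra_references = NULL) {
  i_t <- integrate_positive(map, target, threshold)
  i_r <- integrate_positive(map, reference, threshold)
  if (i_r <= 0) .stopf("reference integral is not positive; cannot calibrate")
  est <- function(ir) (i_t / ir) * reference_electrons *
    (reference_occupancy / target_occupancy)
  electrons <- est(i_r)
  rel_unc <- NA_real_
  if (!is.null(extra_references) && length(extra_references) > 0) {
    all_est <- c(electrons, vapply(extra_references, function(rg) {
      ir <- integrate_positive(map, rg, threshold)
      if (ir <= 0) return(NA_real_)
      est(ir)
    }, numeric(1)))
    all_est <- all_est[is.finite(all_est)]
    if (length(all_est) >= 2) rel_unc <- sd(all_est) / mean(all_est)
  }
  structure(list(electrons = electrons, relative_uncertainty = rel_unc,
                 target_integral = i_t, reference_integral = i_r,
                 reference_electrons = reference_electrons),
            class = "electron_count")
}

#' @export
print.electron_count <- function(x, ...) {
  cat(sprintf("<electron_count> %.2f e-%s\n", x$electrons,
              if (is.finite(x$relative_uncertainty))
                sprintf(" (+- %.0f%%)", 100 * x$relative_uncertainty) else ""))
  invisible(x)
}

#' Peak heights in map-sigma units
#'
#' Map value at each position (trilinear interpolation) divided by the
#' standard deviation of all voxels — the usual "n sigma" peak height.
#'
#' @param map A [density_map()].
#' @param positions Matrix (n x 3) or length-3 vector of positions in
#'   Angstrom.
#' @return Numeric vector of sigma levels.
#' @export
peak_sigma_levels <- function(map, positions) {
  stopifnot(inherits(map, "density_map"))
  if (is.null(dim(positions))) positions <- matrix(positions, nrow = 1)
  s <- sd(as.vector(map$values))
  if (s == 0) .stopf("degenerate map: zero variance")
  vapply(seq_len(nrow(positions)), function(i) {
    .interp_map(map, positions[i, ]) / s
  }, numeric(1))
}

# Trilinear interpolation of a map at one position.
.interp_map <- function(map, pos) {
  u <- (pos - map$origin) / map$voxel
  i0 <- floor(u); fr <- u - i0
  if (any(i0 < 0) || any(i0 + 2 > map$dims)) {
    .stopf("position (%s) outside the map grid",
           paste(sprintf("%.2f", pos), collapse = ", "))
  }
  v <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- prod(ifelse(c(dx, dy, dz) == 1, fr, 1 - fr))
    v <- v + w * map$values[i0[1] + 1 + dx, i0[2] + 1 + dy, i0[3] + 1 + dz]
  }
  v
}
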