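# Shrake-Rupley solvent-accessible surface area with a deterministic
# golden-angle (Fibonacci) sphere lattice. Radii: C 1.70, N 1.55, O 1.52,
# S 1.80, default 1.80 A; probe 1.4 A.

.vdw_radius <- function(element) {
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
  out <- r[element]
  out[is.na(out)] <- 1.80
  unname(out)
}

# deterministic unit sphere points (golden-angle lattice)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# per-atom accessible area for one atom set (matrix xyz, radii)
.atom_sasa <- function(xyz, radii, probe, points) {
  n <- nrow(xyz)
  ext <- radii + probe
  out <- numeric(n)
  if (n == 1) return(4 * pi * ext^2)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    neigh <- which(d2[i, ] < (ext[i] + ext)^2 & seq_len(n) != i)
    pts <- sweep(points * ext[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, nrow(pts))
    for (j in neigh) {
      if (!any(free)) break
      dx <- pts[free, 1] - xyz[j, 1]
      dy <- pts[free, 2] - xyz[j, 2]
      dz <- pts[free, 3] - xyz[j, 3]
      free[free] <- dx * dx + dy * dy + dz * dz >= ext[j]^2
    }
    out[i] <- mean(free) * 4 * pi * ext[i]^2
  }
  out
}

#' Solvent-accessible surface area per residue
#'
#' Shrake-Rupley SASA with a fixed deterministic sphere-point lattice
#' (default 960 points per atom) and a 1.4 A probe. The relative SASA of a
#' residue is its in-context SASA divided by the SASA of the same atoms
#' computed in isolation, so an isolated residue has relative SASA exactly
#' 1; values are clipped to [0, 1.2].
#'
#' @param model A `structure_model`.
#' @param probe Probe radius in Angstrom (default 1.4).
#' @param n_points Sphere points per atom (default 960).
#' @return A tibble with one row per residue: `chain`, `resno`, `ins`,
#'   `resid`, `res_key`, `sasa` (A^2), `sasa_ref` (isolated-residue
#'   reference, A^2), `rel_sasa`.
#' @export
compute_sasa <- function(model, probe = 1.4, n_points = 960) {
  if (nrow(model) == 0) stop("empty structure model", call. = FALSE)
  points <- .sphere_points(n_points)
  xyz <- as.matrix(model[, c("x", "y", "z")])
  radii <- .vdw_radius(model$element)
  atom_area <- .atom_sasa(xyz, radii, probe, points)
  key <- .res_key(model$chain, model$resno, model$ins)
  res <- structure_residues(model)
  res$sasa <- unname(as.numeric(rowsum(atom_area, key)[res$res_key, ]))
  res$sasa_ref <- vapply(res$res_key, function(k) {
    idx <- which(key == k)
    sum(.atom_sasa(xyz[idx, , drop = FALSE], radii[idx], probe, points))
  }, numeric(1), USE.NAMES = FALSE)
  res$rel_sasa <- pmin(pmax(res$sasa / res$sasa_ref, 0), 1.2)
  dplyr::select(res, "chain", "resno", "ins", "resid", "res_key",
                "sasa", "sasa_ref", "rel_sasa")
}
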