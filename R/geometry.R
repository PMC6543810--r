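# Least-squares rigid superposition (Kabsch, via SVD).  Returns the rotation
# R and translation t mapping `mobile` onto `fixed` (both n x 3), i.e.
# mobile %*% R + t ~= fixed, with det(R) = +1.
kabsch <- function(mobile, fixed) {
  cm <- colMeans(mobile); cf <- colMeans(fixed)
  A <- sweep(mobile, 2, cm); B <- sweep(fixed, 2, cf)
  H <- crossprod(A, B)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  t <- cf - as.numeric(cm %*% R)
  list(R = R, t = t)
}

apply_rigid <- function(xyz, tr) sweep(xyz %*% tr$R, 2, tr$t, `+`)

rmsd_xyz <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Per-frame ligand RMSD after rigid superposition
#'
#' For each frame, superposes the frame onto a reference frame by a
#' least-squares rigid fit on `fit_selection`, then reports the RMSD of
#' `analyze_selection` in Angstrom.  Fitting on the protein and analysing
#' the ligand gives the ligand-in-site RMSD used to judge pose convergence;
#' fitting on the ligand itself gives its internal/conformational RMSD.
#'
#' @param trj a `kir_trajectory`.
#' @param analyze_selection atom ids whose deviation is measured.
#' @param fit_selection atom ids used for the superposition (>= 3).
#' @param reference reference frame index (default 1).
#' @return numeric vector of length `n_frames(trj)`; zero at the reference.
#' @export
ligand_rmsd <- function(trj, analyze_selection, fit_selection = analyze_selection,
                        reference = 1L) {
  if (length(analyze_selection) == 0L || length(fit_selection) == 0L)
    stop("selections must be non-empty")
  if (length(fit_selection) < 3L)
    stop("fit selection needs >= 3 atoms (superposition is underdetermined)")
  ai <- atom_rows(trj, analyze_selection)
  fi <- atom_rows(trj, fit_selection)
  if (reference < 1 || reference > n_frames(trj)) stop("reference frame out of range")
  ref <- frame_coords(trj, reference)
  vapply(seq_len(n_frames(trj)), function(f) {
    cur <- frame_coords(trj, f)
    tr <- kabsch(cur[fi, , drop = FALSE], ref[fi, , drop = FALSE])
    fitted <- apply_rigid(cur[ai, , drop = FALSE], tr)
    rmsd_xyz(fitted, ref[ai, , drop = FALSE])
  }, numeric(1))
}

# deterministic Fibonacci-lattice points on the unit sphere
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Bondi-style van der Waals radii (Angstrom); elements not listed fall back
# to carbon.
vdw_radii_table <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                     P = 1.80, F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98)

vdw_radius <- function(element) {
  r <- vdw_radii_table[as.character(element)]
  r[is.na(r)] <- vdw_radii_table[["C"]]
  unname(r)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Deterministic numerical SASA: each atom's solvent-expanded sphere
#' (vdW + probe radius) carries a Fibonacci lattice of `n_points` test
#' points; a point is accessible if it lies outside every other atom's
#' expanded sphere.
#'
#' @param xyz `n x 3` coordinate matrix, Angstrom.
#' @param elements character vector of element symbols (length n), used to
#'   look up van der Waals radii; alternatively supply `radii` directly.
#' @param probe_radius solvent probe radius, Angstrom (default 1.4, water).
#' @param n_points test points per atom (default 960).
#' @param radii optional explicit vdW radii, Angstrom.
#' @return total SASA in Angstrom^2, with attribute `per_atom`.
#' @export
sasa <- function(xyz, elements = NULL, probe_radius = 1.4, n_points = 960L,
                 radii = NULL) {
  if (probe_radius <= 0) stop("probe radius must be positive")
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (is.null(radii)) {
    if (is.null(elements)) stop("supply elements or radii")
    radii <- vdw_radius(elements)
  }
  R <- radii + probe_radius
  pts <- fibonacci_sphere(n_points)
  per_atom <- numeric(n)
  # neighbour pre-filter: atoms can only occlude if centres are closer than
  # the sum of expanded radii
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (R + R[i])^2 & seq_len(n) != i)
    surf <- sweep(pts * R[i], 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      d2j <- rowSums(sweep(surf, 2, xyz[j, ])^2)
      acc <- acc & d2j >= R[j]^2
      if (!any(acc)) break
    }
    per_atom[i] <- 4 * pi * R[i]^2 * mean(acc)
  }
  structure(sum(per_atom), per_atom = per_atom)
}

#' Buried interface area between ligand and receptor
#'
#' Buried area `= (SASA(ligand) + SASA(receptor) - SASA(complex)) / 2`,
#' reported in nm^2.  Used to compare how intimately a pose packs against
#' the binding site (e.g. a loosely surface-bound pose vs a refined docked
#' pose).
#'
#' @param trj a `kir_trajectory` (or a plain list with `atoms` and coords
#'   accessible through [frame_coords()]).
#' @param frame frame index.
#' @param ligand_selection,receptor_selection disjoint atom-id vectors.
#' @param probe_radius probe radius in Angstrom.
#' @param n_points Shrake-Rupley points per atom.
#' @return buried interface area in nm^2.
#' @export
interface_area <- function(trj, frame = 1L, ligand_selection, receptor_selection,
                           probe_radius = 1.4, n_points = 960L) {
  if (length(ligand_selection) == 0L || length(receptor_selection) == 0L)
    stop("selections must be non-empty")
  if (length(intersect(ligand_selection, receptor_selection)))
    stop("ligand and receptor selections must be disjoint")
  li <- atom_rows(trj, ligand_selection)
  ri <- atom_rows(trj, receptor_selection)
  xyz <- frame_coords(trj, frame)
  el <- trj$atoms$element
  s_l <- sasa(xyz[li, , drop = FALSE], el[li], probe_radius, n_points)
  s_r <- sasa(xyz[ri, , drop = FALSE], el[ri], probe_radius, n_points)
  s_c <- sasa(xyz[c(li, ri), , drop = FALSE], el[c(li, ri)], probe_radius, n_points)
  buried_A2 <- (as.numeric(s_l) + as.numeric(s_r) - as.numeric(s_c)) / 2
  buried_A2 / 100  # Angstrom^2 -> nm^2
}
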