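#' @importFrom stats approx coef predict residuals rnorm runif sd setNames t.test vcov
#' @importFrom graphics plot hist polygon lines abline points
#' @importFrom grDevices adjustcolor
#' @importFrom utils head modifyList read.csv write.csv
NULL

#' Read a ligand/selection configuration
#'
#' Configurations declare, by atom id or residue name, which atoms of the
#' topology belong to the ligand and to PIP2, the ligand bond list and atom
#' typing used for pharmacophore perception, the fragment decomposition, and
#' the frame spacing in ns.  They are plain R lists; this helper loads them
#' from a YAML file and applies defaults.
#'
#' @param source path to a YAML file, or a list already in config shape.
#' @return a list with (at least) elements `dt`, `ligand`, `pip2`,
#'   `fragments`.
#' @export
read_selection_config <- function(source) {
  cfg <- if (is.character(source)) yaml::read_yaml(source) else source
  if (!is.list(cfg)) stop("selection config must be a list or a YAML file path")
  defaults <- list(dt = 1.0, ligand = list(), pip2 = list(), fragments = list())
  cfg <- modifyList(defaults, cfg)
  if (!is.null(cfg$ligand$bonds)) {
    cfg$ligand$bonds <- lapply(cfg$ligand$bonds, as.integer)
    bad <- vapply(cfg$ligand$bonds, length, 1L) != 2L
    if (any(bad)) stop("ligand bonds must be pairs of atom ids")
  }
  cfg
}

# pre-scan MODEL/ENDMDL blocks: returns ATOM/HETATM counts per model so that
# a frame with a deviant atom count can be reported by model index (bio3d
# silently mis-shapes such files).
scan_model_atom_counts <- function(lines) {
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0L) {
    return(sum(grepl("^(ATOM  |HETATM)", lines)))
  }
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) != length(model_starts))
    stop("unbalanced MODEL/ENDMDL records in trajectory file")
  vapply(seq_along(model_starts), function(i) {
    blk <- lines[model_starts[i]:model_ends[i]]
    sum(grepl("^(ATOM  |HETATM)", blk))
  }, integer(1))
}

#' Load a multi-model PDB trajectory
#'
#' Reads a coordinate ensemble stored as a multi-model PDB (MODEL/ENDMDL
#' blocks, coordinates in Angstrom) together with a selection configuration
#' declaring the ligand and PIP2 atoms and the frame spacing.  Frame times
#' are `(0, dt, 2*dt, ...)` ns unless the config supplies explicit `times`.
#'
#' @param file path to a multi-model PDB file.
#' @param config selection configuration (list or YAML path), see
#'   [read_selection_config()].
#' @return an object of class `kir_trajectory`: list with `atoms`
#'   (data.frame topology), `coords` (`n_atoms x 3 x n_frames` array, Angstrom),
#'   `times` (ns), and the `config`.
#' @export
load_trajectory <- function(file, config = list()) {
  config <- read_selection_config(config)
  lines <- readLines(file)
  counts <- scan_model_atom_counts(lines)
  if (length(counts) > 1L && length(unique(counts)) != 1L) {
    bad <- which(counts != counts[1])[1]
    stop(sprintf("model %d has %d atoms but model 1 has %d", bad, counts[bad], counts[1]))
  }
  pdb <- bio3d::read.pdb(file, multi = TRUE, verbose = FALSE)
  atoms <- data.frame(
    atom_id  = as.integer(pdb$atom$eleno),
    name     = trimws(pdb$atom$elety),
    element  = ifelse(is.na(pdb$atom$elesy) | trimws(pdb$atom$elesy) == "",
                      substr(trimws(pdb$atom$elety), 1, 1), trimws(pdb$atom$elesy)),
    resname  = trimws(pdb$atom$resid),
    resno    = as.integer(pdb$atom$resno),
    chain    = ifelse(is.na(pdb$atom$chain), "A", pdb$atom$chain),
    stringsAsFactors = FALSE
  )
  n_atoms <- nrow(atoms)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_frames <- nrow(xyz)
  coords <- array(NA_real_, dim = c(n_atoms, 3L, n_frames))
  for (f in seq_len(n_frames)) coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)

  atoms$is_ligand <- flag_selection(atoms, config$ligand)
  atoms$is_pip2   <- flag_selection(atoms, config$pip2)

  times <- if (!is.null(config$times)) as.numeric(config$times)
           else (seq_len(n_frames) - 1) * config$dt
  new_trajectory(atoms, coords, times, config)
}

flag_selection <- function(atoms, sel) {
  flag <- rep(FALSE, nrow(atoms))
  if (!is.null(sel$resname)) flag <- flag | atoms$resname %in% sel$resname
  if (!is.null(sel$residues)) flag <- flag | atoms$resno %in% as.integer(sel$residues)
  if (!is.null(sel$atom_ids)) {
    ids <- as.integer(sel$atom_ids)
    missing <- setdiff(ids, atoms$atom_id)
    if (length(missing))
      stop("configured atom id(s) not present in topology: ",
           paste(missing, collapse = ", "))
    flag <- flag | atoms$atom_id %in% ids
  }
  flag
}

new_trajectory <- function(atoms, coords, times, config = list()) {
  stopifnot(nrow(atoms) == dim(coords)[1], dim(coords)[2] == 3)
  n_frames <- dim(coords)[3]
  if (length(times) != n_frames) stop("times length must equal frame count")
  if (n_frames > 1 && any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (any(atoms$resno < 1)) stop("residue numbers must be >= 1 (declare numbering explicitly)")
  structure(list(atoms = atoms, coords = coords, times = times, config = config),
            class = "kir_trajectory")
}

#' @export
print.kir_trajectory <- function(x, ...) {
  cat(sprintf("<kir_trajectory> %d atoms, %d frames, %.6g-%.6g ns\n",
              nrow(x$atoms), n_frames(x), x$times[1], x$times[n_frames(x)]))
  cat(sprintf("  ligand atoms: %d, PIP2 atoms: %d\n",
              sum(x$atoms$is_ligand), sum(x$atoms$is_pip2)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trj a `kir_trajectory`.
#' @export
n_frames <- function(trj) dim(trj$coords)[3]

#' Extract one frame's coordinates
#' @param trj a `kir_trajectory`.
#' @param i frame index (1-based).
#' @return `n_atoms x 3` matrix (Angstrom), row order matching `trj$atoms`.
#' @export
frame_coords <- function(trj, i) {
  if (i < 1 || i > n_frames(trj)) stop("frame index out of range")
  m <- trj$coords[, , i, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

#' Write a trajectory as a multi-model PDB
#'
#' Inverse of [load_trajectory()]; coordinates round-trip to the PDB format's
#' 3-decimal precision (1e-3 Angstrom).
#'
#' @param trj a `kir_trajectory`.
#' @param file output path.
#' @export
write_trajectory <- function(trj, file) {
  a <- trj$atoms
  nf <- n_frames(trj)
  xyz <- t(vapply(seq_len(nf),
                  function(f) as.numeric(t(frame_coords(trj, f))),
                  numeric(3L * nrow(a))))
  bio3d::write.pdb(file = file, xyz = xyz, type = rep("ATOM", nrow(a)),
                   eleno = a$atom_id, elety = a$name, resid = a$resname,
                   resno = a$resno, chain = a$chain, elesy = a$element)
  invisible(file)
}

# atom-id based row lookup, with validation
atom_rows <- function(trj, atom_ids) {
  idx <- match(as.integer(atom_ids), trj$atoms$atom_id)
  if (anyNA(idx))
    stop("atom id(s) not in topology: ",
         paste(atom_ids[is.na(idx)], collapse = ", "))
  idx
}

#' Decompose the ligand into named fragments
#'
#' Splits the ligand into chemically meaningful pieces for the per-fragment
#' interaction map (for a rosiglitazone-like ligand: the pyridine `RingA`,
#' benzene `RingB`, thiazolidinedione `RingC`, and the two connecting linkers
#' `LinkerD`, `LinkerE`).  Fragment atom sets must be pairwise disjoint
#' subsets of the ligand.
#'
#' @param trj a `kir_trajectory`.
#' @param fragment_config named list of atom-id vectors; defaults to
#'   `trj$config$fragments`.
#' @return named list of integer atom-id vectors, class `kir_fragment_map`.
#' @export
decompose_ligand <- function(trj, fragment_config = NULL) {
  frags <- fragment_config %||% trj$config$fragments
  if (is.null(frags) || length(frags) == 0L) stop("no fragment configuration given")
  frags <- lapply(frags, as.integer)
  if (any(vapply(frags, length, 1L) == 0L)) stop("every fragment must be non-empty")
  ligand_ids <- trj$atoms$atom_id[trj$atoms$is_ligand]
  all_ids <- unlist(frags, use.names = FALSE)
  outside <- setdiff(all_ids, ligand_ids)
  if (length(outside))
    stop("fragment atoms are not ligand atoms: ", paste(outside, collapse = ", "))
  dup <- unique(all_ids[duplicated(all_ids)])
  if (length(dup))
    stop("fragments overlap on atom id(s): ", paste(sort(dup), collapse = ", "))
  structure(frags, class = "kir_fragment_map")
}

#' @export
print.kir_fragment_map <- function(x, ...) {
  cat("<kir_fragment_map>\n")
  for (nm in names(x))
    cat(sprintf("  %-8s %d atoms (%s)\n", nm, length(x[[nm]]),
                paste(x[[nm]], collapse = ",")))
  invisible(x)
}

# fragment name for a set of ligand atom ids ("unassigned" if none hit)
fragment_of <- function(fragments, atom_ids) {
  for (nm in names(fragments))
    if (any(atom_ids %in% fragments[[nm]])) return(nm)
  "unassigned"
}

`%||%` <- function(a, b) if (is.null(a)) b else a
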