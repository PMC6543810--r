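#' Default geometric perception rules
#'
#' Cutoffs for interaction detection and pharmacophore feature tolerances.
#' These are conventional interaction-geometry defaults (documented
#' conventions of this package, configurable per call):
#' hydrophobic apolar-C/apolar-C contact <= 4.5 A; aromatic ring-ring
#' centroid <= 5.0 A with plane-normal angle <= 30 deg; hydrogen bond
#' heavy-atom distance <= 3.5 A with D-H...A angle >= 130 deg (the angle
#' test is skipped when explicit hydrogens are absent); positive-ionizable
#' N to anionic O <= 5.6 A.  Feature tolerance radius r_tol defaults to
#' 1.5 A for every feature kind.
#'
#' @param ... overrides for individual elements.
#' @return named list of rule parameters.
#' @export
default_perception_rules <- function(...) {
  rules <- list(
    h_dist = 4.5, ar_dist = 5.0, ar_angle = 30,
    hb_dist = 3.5, hb_angle = 130, pi_dist = 5.6,
    r_tol = c(H = 1.5, AR = 1.5, HBD = 1.5, HBA = 1.5, PI = 1.5)
  )
  modifyList(rules, list(...))
}

feature_kinds <- c("H", "AR", "HBD", "HBA", "PI")

# canonical empty feature table
empty_features <- function() {
  data.frame(kind = character(), x = numeric(), y = numeric(), z = numeric(),
             nx = numeric(), ny = numeric(), nz = numeric(),
             atoms = I(list()), r_tol = numeric(), stringsAsFactors = FALSE)
}

make_feature <- function(kind, center, atoms, r_tol, normal = c(NA, NA, NA)) {
  data.frame(kind = kind, x = center[1], y = center[2], z = center[3],
             nx = normal[1], ny = normal[2], nz = normal[3],
             atoms = I(list(sort(as.integer(atoms)))), r_tol = r_tol,
             stringsAsFactors = FALSE)
}

feature_centers <- function(features) as.matrix(features[, c("x", "y", "z")])

# plane normal of a point set by SVD (unit vector)
plane_normal <- function(xyz) {
  s <- svd(scale(xyz, scale = FALSE))
  n <- s$v[, 3]
  n / sqrt(sum(n^2))
}

# connected components of an undirected bond graph restricted to `ids`
bond_components <- function(ids, bonds) {
  ids <- sort(unique(as.integer(ids)))
  comp <- setNames(seq_along(ids), ids)
  for (b in bonds) {
    i <- as.character(b[1]); j <- as.character(b[2])
    if (!is.null(comp[[i]]) && !is.null(comp[[j]]) && comp[[i]] != comp[[j]]) {
      comp[comp == comp[[j]]] <- comp[[i]]
    }
  }
  split(ids, comp[as.character(ids)])
}

#' Perceive pharmacophore features on the ligand
#'
#' Builds the ligand's abstract interaction features for one frame from the
#' atom typing declared in the selection config (determinism: no on-the-fly
#' protonation or aromaticity prediction).  Aromatic (AR) features sit at
#' ring centroids with the ring-plane normal; hydrophobic (H) features at
#' centroids of bond-connected apolar-carbon clusters; donor (HBD),
#' acceptor (HBA) and positive-ionizable (PI) features on the declared
#' heavy atoms.
#'
#' @param trj a `kir_trajectory` whose config carries `ligand$bonds`,
#'   `ligand$aromatic_atoms`, `ligand$apolar_atoms`, `ligand$donors`,
#'   `ligand$acceptors`, `ligand$cation_n` (all atom-id vectors).
#' @param frame frame index.
#' @param rules perception rules, see [default_perception_rules()].
#' @return feature table: one row per feature with kind, center (x,y,z, A),
#'   optional unit normal (nx,ny,nz), member ligand atom ids, and r_tol.
#' @export
perceive_features <- function(trj, frame = 1L, rules = default_perception_rules()) {
  lig <- trj$config$ligand
  xyz <- frame_coords(trj, frame)
  rows_of <- function(ids) atom_rows(trj, ids)
  out <- empty_features()

  arom <- as.integer(lig$aromatic_atoms %||% integer())
  if (length(arom)) {
    if (is.null(lig$bonds)) stop("ring perception requires a ligand bond list")
    for (ring in bond_components(arom, lig$bonds)) {
      rc <- xyz[rows_of(ring), , drop = FALSE]
      out <- rbind(out, make_feature("AR", colMeans(rc), ring,
                                     rules$r_tol[["AR"]], plane_normal(rc)))
    }
  }
  apolar <- as.integer(lig$apolar_atoms %||% integer())
  if (length(apolar)) {
    clusters <- if (is.null(lig$bonds)) list(apolar) else bond_components(apolar, lig$bonds)
    for (cl in clusters) {
      cc <- xyz[rows_of(cl), , drop = FALSE]
      out <- rbind(out, make_feature("H", colMeans(cc), cl, rules$r_tol[["H"]]))
    }
  }
  for (d in as.integer(lig$donors %||% integer()))
    out <- rbind(out, make_feature("HBD", xyz[rows_of(d), ], d, rules$r_tol[["HBD"]]))
  for (a in as.integer(lig$acceptors %||% integer()))
    out <- rbind(out, make_feature("HBA", xyz[rows_of(a), ], a, rules$r_tol[["HBA"]]))
  for (p in as.integer(lig$cation_n %||% integer()))
    out <- rbind(out, make_feature("PI", xyz[rows_of(p), ], p, rules$r_tol[["PI"]]))
  rownames(out) <- NULL
  out
}

# --- receptor atom classification (heavy-atom conventions) ------------------

lipid_resnames <- c("POPC", "POP", "PC")
water_resnames <- c("HOH", "SOL", "WAT", "TIP3")

receptor_mask <- function(atoms, scope = c("protein_pip2", "all")) {
  scope <- match.arg(scope)
  keep <- !atoms$is_ligand & !(atoms$resname %in% water_resnames)
  if (scope == "protein_pip2")
    keep <- keep & !(atoms$resname %in% lipid_resnames)
  keep
}

ring_atoms_by_res <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

partner_label <- function(resname, resno, chain, is_pip2) {
  ifelse(is_pip2, "PIP2", paste0(resname, resno, ".", chain))
}

empty_records <- function() {
  data.frame(frame_index = integer(), kind = character(),
             ligand_atoms = I(list()), fragment = character(),
             partner = character(), partner_resname = character(),
             partner_resno = integer(), partner_chain = character(),
             distance = numeric(), angle = numeric(), stringsAsFactors = FALSE)
}

make_record <- function(frame, kind, atoms, fragment, res, distance, angle = NA_real_) {
  data.frame(frame_index = frame, kind = kind, ligand_atoms = I(list(atoms)),
             fragment = fragment, partner = res$label,
             partner_resname = res$resname, partner_resno = res$resno,
             partner_chain = res$chain, distance = distance, angle = angle,
             stringsAsFactors = FALSE)
}

#' Detect ligand-receptor interactions in one frame
#'
#' Matches each ligand pharmacophore feature against the receptor (protein
#' and PIP2 by default; membrane lipids and waters are excluded from the
#' interaction map) using the geometric rules.  One record is emitted per
#' (feature, partner residue) pair that satisfies a rule, carrying the
#' minimal qualifying distance and the fragment assignment of the feature's
#' ligand atoms.
#'
#' @param trj a `kir_trajectory`.
#' @param frame frame index.
#' @param features ligand feature table from [perceive_features()].
#' @param fragments optional `kir_fragment_map` for fragment labels.
#' @param rules perception rules.
#' @param scope `"protein_pip2"` (default; the receptor scope used for
#'   interaction maps) or `"all"` to include lipid partners.
#' @return interaction record data.frame (possibly 0 rows).
#' @export
detect_interactions <- function(trj, frame = 1L, features = perceive_features(trj, frame),
                                fragments = NULL, rules = default_perception_rules(),
                                scope = c("protein_pip2", "all")) {
  scope <- match.arg(scope)
  atoms <- trj$atoms
  xyz <- frame_coords(trj, frame)
  keep <- receptor_mask(atoms, scope)
  rec <- atoms[keep, , drop = FALSE]
  rxyz <- xyz[keep, , drop = FALSE]
  if (nrow(rec) == 0L || nrow(features) == 0L) return(empty_records())

  rec$label <- partner_label(rec$resname, rec$resno, rec$chain, rec$is_pip2)
  # receptor atom classes
  apolar_rec <- rec$element == "C" & !(rec$name %in% c("C", "CA", "O"))
  acceptor_rec <- rec$element == "O"
  donor_rec <- rec$element == "N"
  anionic_rec <- (rec$resname == "ASP" & rec$name %in% c("OD1", "OD2")) |
    (rec$resname == "GLU" & rec$name %in% c("OE1", "OE2")) |
    (rec$is_pip2 & rec$element == "O" & grepl("P", rec$name))

  res_key <- paste(rec$label, rec$resno, rec$chain)
  res_info <- function(i) list(label = rec$label[i], resname = rec$resname[i],
                               resno = rec$resno[i], chain = rec$chain[i])
  out <- empty_records()

  hits_by_residue <- function(mask, center, cutoff) {
    if (!any(mask)) return(NULL)
    d <- sqrt(rowSums(sweep(rxyz[mask, , drop = FALSE], 2, center)^2))
    ok <- d <= cutoff
    if (!any(ok)) return(NULL)
    idx <- which(mask)[ok]
    # min distance per residue
    sp <- split(seq_along(idx), res_key[idx])
    lapply(sp, function(s) {
      best <- s[which.min(d[ok][s])]
      list(i = idx[best], distance = d[ok][s][which.min(d[ok][s])])
    })
  }

  lig_cfg <- trj$config$ligand
  donor_h <- lig_cfg$donor_h  # optional named list: donor atom id -> H atom id

  for (k in seq_len(nrow(features))) {
    ft <- features[k, ]
    center <- as.numeric(ft[, c("x", "y", "z")])
    f_atoms <- ft$atoms[[1]]
    frag <- if (is.null(fragments)) "unassigned" else fragment_of(fragments, f_atoms)
    if (ft$kind == "H") {
      # contact if any apolar receptor atom within cutoff of any member atom
      members <- xyz[atom_rows(trj, f_atoms), , drop = FALSE]
      if (!any(apolar_rec)) next
      ridx <- which(apolar_rec)
      dmat <- vapply(ridx, function(j)
        min(sqrt(rowSums(sweep(members, 2, rxyz[j, ])^2))), numeric(1))
      ok <- dmat <= rules$h_dist
      for (grp in split(which(ok), res_key[ridx[ok]])) {
        b <- grp[which.min(dmat[grp])]
        out <- rbind(out, make_record(frame, "H", f_atoms, frag,
                                      res_info(ridx[b]), dmat[b]))
      }
    } else if (ft$kind == "AR") {
      normal <- as.numeric(ft[, c("nx", "ny", "nz")])
      for (res in split(which(rec$resname %in% names(ring_atoms_by_res)),
                        res_key[rec$resname %in% names(ring_atoms_by_res)])) {
        rn <- rec$resname[res[1]]
        ring_rows <- res[rec$name[res] %in% ring_atoms_by_res[[rn]]]
        if (length(ring_rows) < 5L) next
        rcent <- colMeans(rxyz[ring_rows, , drop = FALSE])
        d <- sqrt(sum((rcent - center)^2))
        if (d > rules$ar_dist) next
        rnorm <- plane_normal(rxyz[ring_rows, , drop = FALSE])
        ang <- acos(pmin(1, abs(sum(normal * rnorm)))) * 180 / pi
        if (ang <= rules$ar_angle)
          out <- rbind(out, make_record(frame, "AR", f_atoms, frag,
                                        res_info(res[1]), d, ang))
      }
    } else if (ft$kind %in% c("HBD", "HBA")) {
      partner_mask <- if (ft$kind == "HBD") acceptor_rec else donor_rec
      hits <- hits_by_residue(partner_mask, center, rules$hb_dist)
      for (h in hits) {
        ang <- NA_real_
        if (ft$kind == "HBD" && !is.null(donor_h)) {
          hid <- donor_h[[as.character(f_atoms[1])]]
          if (!is.null(hid)) {
            hpos <- xyz[atom_rows(trj, as.integer(hid)), ]
            v1 <- center - hpos; v2 <- rxyz[h$i, ] - hpos
            ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                    sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
            if (ang < rules$hb_angle) next
          }
        }
        out <- rbind(out, make_record(frame, ifelse(ft$kind == "HBD", "HB_donor",
                                                    "HB_acceptor"),
                                      f_atoms, frag, res_info(h$i), h$distance, ang))
      }
    } else if (ft$kind == "PI") {
      hits <- hits_by_residue(anionic_rec, center, rules$pi_dist)
      for (h in hits)
        out <- rbind(out, make_record(frame, "PI", f_atoms, frag,
                                      res_info(h$i), h$distance))
    }
  }
  rownames(out) <- NULL
  out
}
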