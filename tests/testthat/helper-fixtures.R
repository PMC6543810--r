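`%||%` <- function(a, b) if (is.null(a)) b else a

# --- fixture builders -------------------------------------------------------

fix_atoms <- function(n, resname = "LIG", resno = 1L, chain = "A",
                      element = "C", name = NULL, is_ligand = TRUE,
                      is_pip2 = FALSE, id_start = 1L) {
  data.frame(atom_id = seq_len(n) + id_start - 1L,
             name = name %||% paste0(element, seq_len(n)),
             element = element, resname = resname, resno = resno,
             chain = chain, is_ligand = is_ligand, is_pip2 = is_pip2,
             stringsAsFactors = FALSE)
}

fix_traj <- function(atoms, frames, times = NULL, config = list()) {
  coords <- array(unlist(frames), dim = c(nrow(atoms), 3L, length(frames)))
  if (is.null(times)) times <- seq_along(frames) - 1
  kirpharm:::new_trajectory(atoms, coords, times, config)
}

rand_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rand_rigid <- function(xyz) {
  sweep(xyz %*% rand_rotation(), 2, runif(3, -10, 10), `+`)
}

fix_features <- function(kinds, centers, atoms = NULL, r_tol = 1.5) {
  atoms <- atoms %||% as.list(seq_along(kinds))
  do.call(rbind, lapply(seq_along(kinds), function(i)
    kirpharm:::make_feature(kinds[i], centers[i, ], atoms[[i]], r_tol)))
}

fix_record <- function(frame, kind, atoms, fragment = "RingA",
                       partner = "PHE76.A", resname = "PHE", resno = 76L,
                       chain = "A", distance = 4.0) {
  kirpharm:::make_record(frame, kind, as.integer(atoms), fragment,
                         list(label = partner, resname = resname,
                              resno = resno, chain = chain), distance)
}

# --- independent oracles ----------------------------------------------------

# least-squares rigid superposition of `mobile` onto `fixed` by the Horn
# quaternion method (eigen-decomposition route, independent of the package's
# SVD-based fit; handles collinear/degenerate sets)
oracle_superpose <- function(mobile, fixed) {
  n <- nrow(mobile)
  if (n == 1L) return(fixed)
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(fixed, 2, colMeans(fixed))
  M <- crossprod(A, B)
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  N <- matrix(c(
    Sxx+Syy+Szz, Syz-Szy,     Szx-Sxz,     Sxy-Syx,
    Syz-Szy,     Sxx-Syy-Szz, Sxy+Syx,     Szx+Sxz,
    Szx-Sxz,     Sxy+Syx,     -Sxx+Syy-Szz, Syz+Szy,
    Sxy-Syx,     Szx+Sxz,     Syz+Szy,     -Sxx-Syy+Szz), 4, 4, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1-2*(y^2+z^2), 2*(x*y - w*z), 2*(x*z + w*y),
    2*(x*y + w*z), 1-2*(x^2+z^2), 2*(y*z - w*x),
    2*(x*z - w*y), 2*(y*z + w*x), 1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
  sweep(A %*% t(R), 2, colMeans(fixed), `+`)
}

# exhaustive-assignment pharmacophore matching oracle
oracle_match <- function(mcent, mkinds, r_tol, ccent, ckinds) {
  cand <- lapply(mkinds, function(k) which(ckinds == k))
  if (any(lengths(cand) == 0L))
    return(list(matched = FALSE, score = NA_real_))
  grid <- expand.grid(cand, KEEP.OUT.ATTRS = FALSE)
  keep <- !apply(grid, 1, anyDuplicated)
  grid <- grid[keep, , drop = FALSE]
  if (nrow(grid) == 0L) return(list(matched = FALSE, score = NA_real_))
  best <- NULL
  for (r in seq_len(nrow(grid))) {
    idx <- as.integer(grid[r, ])
    target <- ccent[idx, , drop = FALSE]
    fitted <- oracle_superpose(mcent, target)
    d <- sqrt(rowSums((fitted - target)^2))
    matched <- all(d <= r_tol)
    score <- 1 - mean(d) / r_tol
    if (is.null(best) || (matched && !best$matched) ||
        (matched == best$matched && score > best$score + 1e-12))
      best <- list(matched = matched, score = score)
  }
  best
}

# naive triple-loop recount of the interaction map
oracle_recount <- function(records, frag_names, n_frames) {
  combos <- unique(records[, c("partner", "kind")])
  out <- matrix(0, nrow(combos), length(frag_names),
                dimnames = list(paste(combos$partner, combos$kind, sep = "|"),
                                frag_names))
  for (r in seq_len(nrow(combos))) for (f in frag_names) {
    seen <- 0L
    for (fr in unique(records$frame_index)) {
      hit <- any(records$frame_index == fr & records$partner == combos$partner[r] &
                 records$kind == combos$kind[r] & records$fragment == f)
      seen <- seen + as.integer(hit)
    }
    out[r, f] <- 100 * seen / n_frames
  }
  out
}

# brute-force all-pairs interaction scan for point features (H/HBD/HBA/PI)
oracle_pair_scan <- function(trj, frame, features, rules, scope = "protein_pip2") {
  atoms <- trj$atoms
  xyz <- kirpharm:::frame_coords(trj, frame)
  rec <- which(!atoms$is_ligand &
               !(atoms$resname %in% c("HOH", "SOL", "WAT", "TIP3")) &
               (scope == "all" | !(atoms$resname %in% c("POPC", "POP", "PC"))))
  hits <- list()
  for (k in seq_len(nrow(features))) {
    ft <- features[k, ]
    ctr <- as.numeric(ft[, c("x", "y", "z")])
    for (j in rec) {
      a <- atoms[j, ]
      d <- sqrt(sum((xyz[j, ] - ctr)^2))
      ok <- switch(ft$kind,
        H = a$element == "C" && !(a$name %in% c("C", "CA", "O")) &&
            min(sqrt(rowSums(sweep(
              xyz[match(ft$atoms[[1]], atoms$atom_id), , drop = FALSE],
              2, xyz[j, ])^2))) <= rules$h_dist,
        HBD = a$element == "O" && d <= rules$hb_dist,
        HBA = a$element == "N" && d <= rules$hb_dist,
        FALSE)
      if (isTRUE(ok)) {
        lab <- if (a$is_pip2) "PIP2" else paste0(a$resname, a$resno, ".", a$chain)
        key <- paste(k, lab)
        hits[[key]] <- TRUE
      }
    }
  }
  sort(names(hits))
}
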