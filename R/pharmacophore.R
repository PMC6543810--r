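# record kind -> feature kind
record_to_feature_kind <- c(H = "H", AR = "AR", HB_donor = "HBD",
                            HB_acceptor = "HBA", PI = "PI")

atoms_key <- function(atoms) paste(sort(as.integer(atoms)), collapse = ",")

#' Identity key of a pharmacophore model
#'
#' Two per-frame models are "identical" (and merged into one representative)
#' when they share the same multiset of feature kinds with the same involved
#' ligand atoms.  The key is the sorted `kind:atom_ids` listing, so it is
#' invariant under feature reordering.
#'
#' @param features a feature table.
#' @return a single character key.
#' @export
model_identity_key <- function(features) {
  if (nrow(features) == 0L) return("")
  parts <- paste0(features$kind, ":",
                  vapply(features$atoms, atoms_key, character(1)))
  paste(sort(parts), collapse = ";")
}

new_pharmacophore <- function(features, source_frame = NA_integer_) {
  if (nrow(features) > 0L) {
    ord <- order(paste0(features$kind, ":",
                        vapply(features$atoms, atoms_key, character(1))))
    features <- features[ord, , drop = FALSE]
  }
  rownames(features) <- NULL
  structure(list(features = features, identity_key = model_identity_key(features),
                 source_frame = source_frame),
            class = "kir_pharmacophore")
}

#' @export
print.kir_pharmacophore <- function(x, ...) {
  cat(sprintf("<kir_pharmacophore> %d features [%s]\n", nrow(x$features),
              paste(x$features$kind, collapse = ", ")))
  invisible(x)
}

#' Build the pharmacophore model of a single frame
#'
#' The frame's model keeps exactly those ligand features that participate in
#' at least one detected ligand-receptor interaction in that frame.  Frames
#' with no interactions yield an empty-model sentinel (0 features), which
#' [merge_models()] excludes from the frequency denominator.
#'
#' @param frame_records interaction records of one frame.
#' @param frame_features the ligand feature table of the same frame.
#' @return a `kir_pharmacophore` (possibly empty).
#' @export
build_frame_model <- function(frame_records, frame_features) {
  if (nrow(frame_records) > 0L && length(unique(frame_records$frame_index)) > 1L)
    stop("records span multiple frames; build one model per frame")
  frame <- if (nrow(frame_records)) frame_records$frame_index[1] else NA_integer_
  if (nrow(frame_records) == 0L || nrow(frame_features) == 0L)
    return(new_pharmacophore(empty_features(), frame))
  rec_keys <- unique(paste0(record_to_feature_kind[frame_records$kind], ":",
                            vapply(frame_records$ligand_atoms, atoms_key, character(1))))
  feat_keys <- paste0(frame_features$kind, ":",
                      vapply(frame_features$atoms, atoms_key, character(1)))
  keep <- feat_keys %in% rec_keys
  new_pharmacophore(frame_features[keep, , drop = FALSE], frame)
}

#' Merge per-frame models into representative models
#'
#' Groups per-frame pharmacophore models by identity key (same feature kinds
#' on the same ligand atoms) and merges each group into one representative
#' whose feature centers are the mean over member frames.  Empty models are
#' excluded from the frequency denominator, which is reported alongside.
#'
#' @param models list of `kir_pharmacophore` objects.
#' @return class `kir_representatives`: list of entries
#'   `list(model, count, frequency)` ordered by count descending then key,
#'   with attributes `n_models` (denominator) and `n_empty`.
#' @export
merge_models <- function(models) {
  keys <- vapply(models, function(m) m$identity_key, character(1))
  empty <- keys == ""
  models <- models[!empty]; keys <- keys[!empty]
  if (length(models) == 0L) stop("no non-empty models to merge")
  groups <- split(seq_along(models), keys)
  reps <- lapply(groups, function(idx) {
    base <- models[[idx[1]]]
    feats <- base$features
    centers <- Reduce(`+`, lapply(idx, function(i) feature_centers(models[[i]]$features))) /
      length(idx)
    feats$x <- centers[, 1]; feats$y <- centers[, 2]; feats$z <- centers[, 3]
    list(model = new_pharmacophore(feats), count = length(idx),
         frequency = length(idx) / length(models))
  })
  ord <- order(-vapply(reps, `[[`, numeric(1), "count"), names(groups))
  reps <- reps[ord]
  structure(reps, n_models = length(models), n_empty = sum(empty),
            class = "kir_representatives")
}

#' @export
print.kir_representatives <- function(x, ...) {
  cat(sprintf("<kir_representatives> %d representative models from %d frame models (%d empty frames excluded)\n",
              length(x), attr(x, "n_models"), attr(x, "n_empty")))
  for (i in seq_along(x))
    cat(sprintf("  Model %d: %d features [%s], %d frames (%.2f%%)\n", i,
                nrow(x[[i]]$model$features),
                paste(x[[i]]$model$features$kind, collapse = ","),
                x[[i]]$count, 100 * x[[i]]$frequency))
  invisible(x)
}

# enumerate injective kind-consistent assignments; returns best per
# `matched` then score, first-found (lexicographic) on ties
enumerate_match <- function(mcent, mkinds, mtol, ccent, ckinds) {
  m <- length(mkinds)
  cand <- lapply(mkinds, function(k) which(ckinds == k))
  if (any(vapply(cand, length, 1L) == 0L)) return(NULL)
  best <- NULL
  assign <- integer(m)
  used <- rep(FALSE, length(ckinds))
  recurse <- function(i) {
    if (i > m) {
      cc <- ccent[assign, , drop = FALSE]
      tr <- kabsch(mcent, cc)
      fitted <- apply_rigid(mcent, tr)
      d <- sqrt(rowSums((fitted - cc)^2))
      matched <- all(d <= mtol)
      score <- 1 - mean(d / mtol)
      better <- is.null(best) || (matched && !best$matched) ||
        (matched == best$matched && score > best$score + 1e-12)
      if (better)
        best <<- list(matched = matched, score = score, pairing = assign,
                      distances = d)
      return(invisible(NULL))
    }
    for (j in cand[[i]]) {
      if (used[j]) next
      used[j] <<- TRUE; assign[i] <<- j
      recurse(i + 1)
      used[j] <<- FALSE
    }
    invisible(NULL)
  }
  recurse(1L)
  best
}

#' Geometrically match a pharmacophore model against a conformer
#'
#' Searches all injective, kind-consistent assignments of model features to
#' conformer features; each assignment is evaluated after a least-squares
#' rigid superposition of the paired feature centers.  The conformer matches
#' when some assignment places every pair within the tolerance radius; the
#' score of a matched assignment is `s = 1 - mean(d_i / r_tol_i)` (with a
#' uniform tolerance: one minus the mean displacement over r_tol), so
#' `s = 1` for a perfect geometric fit and `s -> 0` at the tolerance limit.
#'
#' @param model a `kir_pharmacophore` (<= 6 features; exhaustive search).
#' @param conformer_features feature table of one conformer.
#' @param r_tol optional uniform tolerance override in Angstrom.
#' @return list of class `kir_match`: `matched`, `score`, `pairing`
#'   (model feature index -> conformer feature row), `distances` (Angstrom).
#' @export
match_model <- function(model, conformer_features, r_tol = NULL) {
  feats <- model$features
  if (nrow(feats) == 0L) stop("cannot match an empty model")
  if (nrow(feats) > 6L) stop("exhaustive matching supports at most 6 model features")
  res <- if (nrow(conformer_features) == 0L) NULL else
    enumerate_match(feature_centers(feats), feats$kind,
                    if (is.null(r_tol)) feats$r_tol else rep(r_tol, nrow(feats)),
                    feature_centers(conformer_features), conformer_features$kind)
  if (is.null(res))
    res <- list(matched = FALSE, score = NA_real_, pairing = integer(),
                distances = numeric())
  structure(res, class = "kir_match")
}

#' @export
print.kir_match <- function(x, ...) {
  cat(sprintf("<kir_match> matched=%s score=%.4f\n", x$matched,
              if (is.na(x$score)) NA else x$score))
  invisible(x)
}

# normalize a library given as a tabular feature-point data.frame
# (molecule_id, conformer_id, kind, x, y, z) into a nested list
as_feature_library <- function(library) {
  if (is.data.frame(library)) {
    needed <- c("molecule_id", "conformer_id", "kind", "x", "y", "z")
    if (!all(needed %in% names(library)))
      stop("tabular library needs columns: ", paste(needed, collapse = ", "))
    split_mol <- split(library, library$molecule_id)
    library <- lapply(split_mol, function(mol) {
      confs <- lapply(split(mol, mol$conformer_id), function(cf) {
        data.frame(kind = cf$kind, x = cf$x, y = cf$y, z = cf$z,
                   nx = NA_real_, ny = NA_real_, nz = NA_real_,
                   atoms = I(replicate(nrow(cf), integer(), simplify = FALSE)),
                   r_tol = NA_real_, stringsAsFactors = FALSE)
      })
      list(id = mol$molecule_id[1], conformers = unname(confs))
    })
    names(library) <- vapply(library, `[[`, character(1), "id")
  }
  library
}

#' Screen a conformer library with the common-hits approach
#'
#' Every representative model screens every molecule: a molecule's per-model
#' score `s_m` is the best match score over its conformers, `n_active` is the
#' number of models it matches, and the CHA score is `S = sum of matched
#' s_m`.  Molecules matching fewer than `min_active` models are filtered
#' out; hits are ranked by `S` descending.  By construction every hit
#' satisfies `S <= n_active`.
#'
#' @param representatives a `kir_representatives` (or list of models).
#' @param library either a nested list (`id`, `conformers` = list of feature
#'   tables) or a tabular data.frame (molecule_id, conformer_id, kind,
#'   x, y, z).
#' @param min_active minimum number of matched models to qualify (default 2,
#'   the "at least two of five models" filter).
#' @param max_conformers per-molecule conformer cap (default 200).
#' @param r_tol optional uniform tolerance override, Angstrom.
#' @return data.frame of class `kir_screen_hits`: molecule_id, cha_score,
#'   n_active, n_models, and per-model score columns `s_1..s_k` (NA when
#'   unmatched).
#' @export
screen_library <- function(representatives, library, min_active = 2L,
                           max_conformers = 200L, r_tol = NULL) {
  models <- lapply(representatives, function(r)
    if (inherits(r, "kir_pharmacophore")) r else r$model)
  k <- length(models)
  if (k == 0L) stop("need at least one representative model")
  if (min_active > k)
    stop(sprintf("min_active (%d) exceeds the number of models (%d)", min_active, k))
  library <- as_feature_library(library)
  if (length(library) == 0L) stop("library is empty")
  rows <- lapply(library, function(mol) {
    confs <- head(mol$conformers, max_conformers)
    s <- vapply(models, function(m) {
      sc <- vapply(confs, function(cf) {
        r <- match_model(m, cf, r_tol)
        if (r$matched) r$score else NA_real_
      }, numeric(1))
      if (all(is.na(sc))) NA_real_ else max(sc, na.rm = TRUE)
    }, numeric(1))
    n_active <- sum(!is.na(s))
    data.frame(molecule_id = mol$id, cha_score = sum(s, na.rm = TRUE),
               n_active = n_active, n_models = k,
               as.list(setNames(s, paste0("s_", seq_len(k)))),
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  hits <- hits[hits$n_active >= min_active, , drop = FALSE]
  hits <- hits[order(-hits$cha_score, hits$molecule_id), , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("kir_screen_hits", "data.frame")
  hits
}

#' Serialize representative models to YAML
#' @param representatives a `kir_representatives`.
#' @param file output path.
#' @export
write_representatives <- function(representatives, file) {
  obj <- lapply(seq_along(representatives), function(i) {
    r <- representatives[[i]]
    f <- r$model$features
    list(model = i, count = r$count, frequency = r$frequency,
         features = lapply(seq_len(nrow(f)), function(j) list(
           kind = f$kind[j], center = as.numeric(f[j, c("x", "y", "z")]),
           r_tol = f$r_tol[j], ligand_atoms = as.integer(f$atoms[[j]]))))
  })
  yaml::write_yaml(list(n_models = attr(representatives, "n_models"),
                        representatives = obj), file)
  invisible(file)
}

#' Read representative models from YAML
#' @param file path written by [write_representatives()].
#' @return a `kir_representatives`.
#' @export
read_representatives <- function(file) {
  obj <- yaml::read_yaml(file)
  reps <- lapply(obj$representatives, function(r) {
    feats <- do.call(rbind, lapply(r$features, function(ft)
      make_feature(ft$kind, as.numeric(ft$center), as.integer(ft$ligand_atoms),
                   ft$r_tol)))
    list(model = new_pharmacophore(feats), count = r$count, frequency = r$frequency)
  })
  structure(reps, n_models = obj$n_models, n_empty = 0L,
            class = "kir_representatives")
}
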