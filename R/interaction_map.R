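#' Aggregate interaction records into a per-fragment contact-frequency map
#'
#' Builds the fragment x (residue, interaction kind) matrix of
#' percentage-of-frames values: a cell counts the frames in which at least
#' one interaction of that (partner residue, kind, fragment) combination was
#' observed, divided by the total frame count.  Multiple same-kind records
#' in one frame count once.
#'
#' @param records interaction record data.frame (rows from
#'   [detect_interactions()] over all frames).
#' @param fragments a `kir_fragment_map` (used to validate fragment names)
#'   or a character vector of fragment names.
#' @param n_frames total number of frames the records were computed over.
#' @return object of class `kir_interaction_map`: list with `cells`
#'   (matrix, rows = "partner|kind", cols = fragments, values = % frames),
#'   `rows` (data.frame partner/resno/kind per row) and `n_frames`.
#' @export
build_interaction_map <- function(records, fragments, n_frames) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  frag_names <- if (is.character(fragments)) fragments else names(fragments)
  if (nrow(records)) {
    # frame indices may be 0- or 1-based; they must fit in n_frames
    if (max(records$frame_index) - min(records$frame_index) >= n_frames)
      stop("record frame indices span more than n_frames frames")
    unknown <- setdiff(unique(records$fragment), c(frag_names, "unassigned"))
    if (length(unknown))
      stop("records reference unknown fragment(s): ", paste(unknown, collapse = ", "))
  }
  rows_key <- if (nrow(records)) unique(records[, c("partner", "partner_resno", "kind")])
              else records[, c("partner", "partner_resno", "kind")]
  if (nrow(rows_key)) {
    rows_key <- rows_key[order(rows_key$partner_resno, rows_key$partner, rows_key$kind), ]
    rownames(rows_key) <- NULL
  }
  cells <- matrix(0, nrow = nrow(rows_key), ncol = length(frag_names),
                  dimnames = list(paste(rows_key$partner, rows_key$kind, sep = "|"),
                                  frag_names))
  if (nrow(records)) {
    u <- unique(records[, c("frame_index", "partner", "partner_resno", "kind", "fragment")])
    u <- u[u$fragment %in% frag_names, , drop = FALSE]
    if (nrow(u)) {
      key <- paste(u$partner, u$kind, sep = "|")
      tab <- table(key, factor(u$fragment, levels = frag_names))
      cells[rownames(tab), colnames(tab)] <- as.matrix(tab) / n_frames * 100
    }
  }
  structure(list(cells = cells, rows = rows_key, fragments = frag_names,
                 n_frames = n_frames),
            class = "kir_interaction_map")
}

#' @export
print.kir_interaction_map <- function(x, digits = 1, ...) {
  cat(sprintf("<kir_interaction_map> %d partner/kind rows x %d fragments over %d frames\n",
              nrow(x$cells), ncol(x$cells), x$n_frames))
  if (nrow(x$cells)) print(round(x$cells, digits))
  invisible(x)
}

#' Export an interaction map as CSV
#' @param x a `kir_interaction_map`.
#' @param file output path.
#' @export
write_interaction_map <- function(x, file) {
  df <- data.frame(partner = x$rows$partner, kind = x$rows$kind,
                   x$cells, check.names = FALSE)
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' List contacts persisting above a frame-percentage threshold
#'
#' @param map a `kir_interaction_map`.
#' @param threshold_pct keep cells with value strictly above this (0-100).
#' @return data.frame (fragment, partner, resno, kind, pct), sorted by pct
#'   descending, then residue number ascending.
#' @export
persistent_contacts <- function(map, threshold_pct = 75) {
  if (threshold_pct < 0 || threshold_pct > 100) stop("threshold must be in [0,100]")
  if (nrow(map$cells) == 0L)
    return(data.frame(fragment = character(), partner = character(),
                      resno = integer(), kind = character(), pct = numeric()))
  long <- do.call(rbind, lapply(seq_len(ncol(map$cells)), function(j) {
    data.frame(fragment = colnames(map$cells)[j], partner = map$rows$partner,
               resno = map$rows$partner_resno, kind = map$rows$kind,
               pct = map$cells[, j], stringsAsFactors = FALSE)
  }))
  if (is.null(long)) long <- data.frame(fragment = character(), partner = character(),
                                        resno = integer(), kind = character(),
                                        pct = numeric())
  long <- long[long$pct > threshold_pct, , drop = FALSE]
  long <- long[order(-long$pct, long$resno), , drop = FALSE]
  rownames(long) <- NULL
  long
}

#' Binding-site occupancy and residence time
#'
#' A frame is "bound" when the minimum heavy-atom distance between the
#' ligand selection and the site residues is at or below the site cutoff.
#' The longest contiguous bound run is reported on the trajectory clock;
#' n contiguous frames at spacing dt span (n-1)*dt ns.
#'
#' @param trj a `kir_trajectory`.
#' @param ligand_selection ligand atom ids (defaults to flagged ligand atoms).
#' @param site list with `residues` (residue numbers), optional `chain`,
#'   and `cutoff` in Angstrom (default 4.0).
#' @param mode `"min"` (minimum heavy-atom distance, default) or `"com"`
#'   (centre-of-mass distance).
#' @return list of class `kir_occupancy`: `bound` (logical per frame),
#'   `fraction`, `longest` (start/end/duration in ns), `cutoff`.
#' @export
site_occupancy <- function(trj, ligand_selection = NULL, site, mode = c("min", "com")) {
  mode <- match.arg(mode)
  if (is.null(ligand_selection))
    ligand_selection <- trj$atoms$atom_id[trj$atoms$is_ligand]
  if (length(ligand_selection) == 0L) stop("ligand selection is empty")
  cutoff <- site$cutoff %||% 4.0
  if (cutoff <= 0) stop("site cutoff must be positive")
  sel <- trj$atoms$resno %in% as.integer(site$residues) & !trj$atoms$is_ligand
  if (!is.null(site$chain)) sel <- sel & trj$atoms$chain %in% site$chain
  if (!any(sel)) stop("site residues not found in topology")
  li <- atom_rows(trj, ligand_selection)
  si <- which(sel)
  nf <- n_frames(trj)
  bound <- logical(nf)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(trj, f)
    if (mode == "min") {
      dmin <- min(vapply(li, function(i)
        min(sqrt(rowSums(sweep(xyz[si, , drop = FALSE], 2, xyz[i, ])^2))), numeric(1)))
    } else {
      dmin <- sqrt(sum((colMeans(xyz[li, , drop = FALSE]) -
                        colMeans(xyz[si, , drop = FALSE]))^2))
    }
    bound[f] <- dmin <= cutoff
  }
  runs <- rle(bound)
  longest <- list(start = NA_real_, end = NA_real_, duration = 0)
  if (any(bound)) {
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    b <- which(runs$values)
    best <- b[which.max(runs$lengths[b])]
    longest <- list(start = trj$times[starts[best]], end = trj$times[ends[best]],
                    duration = trj$times[ends[best]] - trj$times[starts[best]])
  }
  structure(list(bound = bound, fraction = mean(bound), longest = longest,
                 cutoff = cutoff),
            class = "kir_occupancy")
}

#' @export
print.kir_occupancy <- function(x, ...) {
  cat(sprintf("<kir_occupancy> bound fraction %.3f; longest run %s\n",
              x$fraction,
              if (x$longest$duration > 0 || !is.na(x$longest$start))
                sprintf("%.6g-%.6g ns (%.6g ns)", x$longest$start,
                        x$longest$end, x$longest$duration)
              else "none"))
  invisible(x)
}
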