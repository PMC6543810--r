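# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# ---------------------------------------------------------------------------
# ensemble generator: per-frame pharmacophore regimes
# ---------------------------------------------------------------------------

# feature geometry template of a rosiglitazone-like ligand: two hydrophobic
# ring centroids (pyridine, benzene), the thiazolidinedione N-H donor, and
# two carbonyl acceptors; atom ids are the ligand's heavy-atom numbering
ligand_feature_templates <- function(r_tol = 1.5) {
  list(
    H_pyr  = make_feature("H",   c(0.0, 0.0, 0.0),  1:6,  r_tol),
    H_benz = make_feature("H",   c(5.2, 0.8, 0.0), 10:15, r_tol),
    HBD_N  = make_feature("HBD", c(9.6, 1.2, 0.4),  20L,  r_tol),
    HBD_N2 = make_feature("HBD", c(9.0, 2.1, -0.6), 21L,  r_tol),
    HBA_O1 = make_feature("HBA", c(10.4, -0.9, -0.3), 22L, r_tol),
    HBA_O2 = make_feature("HBA", c(11.1, 0.6, 0.9),  23L, r_tol)
  )
}

# partner residues of the stub receptor, one per template feature
stub_partners <- list(
  H_pyr  = list(label = "PHE76.A",  resname = "PHE", resno = 76L,  chain = "A", kind = "H",           distance = 4.0),
  H_benz = list(label = "VAL172.A", resname = "VAL", resno = 172L, chain = "A", kind = "H",           distance = 4.1),
  HBD_N  = list(label = "PIP2",     resname = "PIP", resno = 401L, chain = "A", kind = "HB_donor",    distance = 2.9),
  HBD_N2 = list(label = "LEU64.A",  resname = "LEU", resno = 64L,  chain = "A", kind = "HB_donor",    distance = 3.1),
  HBA_O1 = list(label = "TRP69.A",  resname = "TRP", resno = 69L,  chain = "A", kind = "HB_acceptor", distance = 3.0),
  HBA_O2 = list(label = "ARG177.A", resname = "ARG", resno = 177L, chain = "A", kind = "HB_acceptor", distance = 3.2)
)

#' Default ensemble specification
#'
#' Five model regimes emulating the structure of the observed per-frame
#' pharmacophore ensemble: a dominant three-feature model (two hydrophobics
#' plus the thiazolidinedione N-H donor) present in ~95.5% of frames, and
#' four minority models sharing the hydrophobic pair with differing polar
#' features.  Probabilities (0.9552, 0.0120, 0.0120, 0.0120, 0.0088) give
#' an expected dominant count of 4,776 out of 5,000 frames.
#'
#' @param n_frames number of frames (default 5000).
#' @param jitter_sd Gaussian jitter of feature centers, Angstrom
#'   (default 0.3).
#' @return list of class `kir_ensemble_spec` with `regimes` (feature-name
#'   sets), `probs`, `jitter_sd`, `n_frames`.
#' @export
default_ensemble_spec <- function(n_frames = 5000L, jitter_sd = 0.3) {
  structure(list(
    regimes = list(
      model1 = c("H_pyr", "H_benz", "HBD_N"),
      model2 = c("H_pyr", "H_benz"),
      model3 = c("H_pyr", "H_benz", "HBD_N", "HBA_O1"),
      model4 = c("H_pyr", "H_benz", "HBD_N2", "HBA_O2"),
      model5 = c("H_pyr", "H_benz", "HBA_O1")
    ),
    probs = c(0.9552, 0.0120, 0.0120, 0.0120, 0.0088),
    jitter_sd = jitter_sd, n_frames = as.integer(n_frames)),
    class = "kir_ensemble_spec")
}

#' Generate a synthetic pharmacophore-feature trajectory
#'
#' Draws a model regime per frame from the spec's categorical distribution
#' and emits that regime's ligand features (centers jittered with Gaussian
#' noise) together with matching interaction records against a stub
#' receptor.  The ground-truth regime sequence is returned for recovery
#' tests.
#'
#' @param spec a `kir_ensemble_spec` (default [default_ensemble_spec()]).
#' @param seed integer seed.
#' @return list with `features` (per-frame feature tables), `records`
#'   (per-frame interaction records), `regimes` (integer ground truth),
#'   `trajectory` (a stub `kir_trajectory` with ligand + receptor atoms),
#'   and `spec`.
#' @export
gen_feature_trajectory <- function(spec = default_ensemble_spec(), seed = 1L) {
  if (abs(sum(spec$probs) - 1) > 1e-9)
    stop("regime probabilities must sum to 1")
  if (any(spec$probs <= 0)) stop("regime probabilities must be positive")
  templates <- ligand_feature_templates()
  regime_feats <- lapply(spec$regimes, function(fn) {
    tab <- do.call(rbind, templates[fn])
    rownames(tab) <- NULL
    tab
  })
  regime_recs <- lapply(spec$regimes, function(fn) {
    do.call(rbind, lapply(fn, function(nm) {
      p <- stub_partners[[nm]]
      make_record(1L, p$kind, templates[[nm]]$atoms[[1]], "unassigned", p,
                  p$distance)
    }))
  })
  with_seed(seed, {
    n <- spec$n_frames
    regimes <- sample.int(length(spec$regimes), n, replace = TRUE,
                          prob = spec$probs)
    features <- vector("list", n)
    records <- vector("list", n)
    for (f in seq_len(n)) {
      ft <- regime_feats[[regimes[f]]]
      jit <- matrix(rnorm(3L * nrow(ft), sd = spec$jitter_sd), ncol = 3)
      ft$x <- ft$x + jit[, 1]; ft$y <- ft$y + jit[, 2]; ft$z <- ft$z + jit[, 3]
      features[[f]] <- ft
      rec <- regime_recs[[regimes[f]]]
      rec$frame_index <- f
      records[[f]] <- rec
    }
    trj <- stub_trajectory(n)
    list(features = features, records = records, regimes = regimes,
         trajectory = trj, spec = spec)
  })
}

# minimal trajectory carrying the template ligand atoms plus the stub
# receptor residues; coordinates are static (features carry the jitter)
stub_trajectory <- function(n_frames = 1L, dt = 0.02) {
  templates <- ligand_feature_templates()
  lig_rows <- do.call(rbind, lapply(names(templates), function(nm) {
    ft <- templates[[nm]]
    ids <- ft$atoms[[1]]
    ctr <- as.numeric(ft[, c("x", "y", "z")])
    off <- fibonacci_sphere(max(length(ids), 2L))[seq_along(ids), , drop = FALSE] * 1.2
    data.frame(atom_id = ids, name = paste0("C", ids), element = "C",
               resname = "RSG", resno = 500L, chain = "L",
               x = ctr[1] + off[, 1], y = ctr[2] + off[, 2], z = ctr[3] + off[, 3],
               stringsAsFactors = FALSE)
  }))
  lig_rows$element[lig_rows$atom_id %in% 20:21] <- "N"
  lig_rows$element[lig_rows$atom_id %in% 22:23] <- "O"
  rec_rows <- do.call(rbind, lapply(names(stub_partners), function(nm) {
    p <- stub_partners[[nm]]
    ctr <- as.numeric(ligand_feature_templates()[[nm]][, c("x", "y", "z")])
    data.frame(atom_id = 100L + match(nm, names(stub_partners)),
               name = if (p$kind == "H") "CD1" else if (p$kind == "HB_donor") "O1P" else "NE",
               element = if (p$kind == "HB_donor") "O" else if (p$kind == "HB_acceptor") "N" else "C",
               resname = p$resname, resno = p$resno, chain = p$chain,
               x = ctr[1] + p$distance, y = ctr[2], z = ctr[3],
               stringsAsFactors = FALSE)
  }))
  atoms <- rbind(lig_rows, rec_rows)
  atoms$is_ligand <- atoms$resname == "RSG"
  atoms$is_pip2 <- atoms$resname == "PIP"
  coords <- array(rep(as.matrix(atoms[, c("x", "y", "z")]), n_frames),
                  dim = c(nrow(atoms), 3L, n_frames))
  atoms <- atoms[, setdiff(names(atoms), c("x", "y", "z"))]
  new_trajectory(atoms, coords, (seq_len(n_frames) - 1) * dt,
                 config = list(ligand = list(
                   atom_ids = atoms$atom_id[atoms$is_ligand],
                   bonds = c(lapply(1:5, function(i) c(i, i + 1L)), list(c(6L, 1L)),
                             lapply(10:14, function(i) c(i, i + 1L)), list(c(15L, 10L))),
                   apolar_atoms = c(1:6, 10:15),
                   donors = 20:21, acceptors = 22:23),
                   fragments = list(RingA = 1:6, RingB = 10:15, RingC = 20:23)))
}

# ---------------------------------------------------------------------------
# umbrella-sampling generator
# ---------------------------------------------------------------------------

#' Define an analytic reference potential
#'
#' @param form `"harmonic"` (`U = kappa xi^2 / 2`), `"double_well"`
#'   (`U = a (xi^2 - b^2)^2`), or `"table"` (piecewise-linear through
#'   `xi`, `U`).
#' @param range sampled reaction-coordinate range in nm, `c(lo, hi)`.
#' @param kappa,a,b,xi,U form parameters (kJ/mol and nm units).
#' @return list of class `kir_potential` with an evaluator `U(xi)`.
#' @export
potential_spec <- function(form = c("harmonic", "double_well", "table"),
                           range, kappa = 100, a = 1000, b = 0.3,
                           xi = NULL, U = NULL) {
  form <- match.arg(form)
  fun <- switch(form,
    harmonic = function(x) 0.5 * kappa * x^2,
    double_well = function(x) a * (x^2 - b^2)^2,
    table = {
      if (is.null(xi) || is.null(U)) stop("table potential needs xi and U")
      function(x) approx(xi, U, xout = x, rule = 2)$y
    })
  if (!all(is.finite(fun(seq(range[1], range[2], length.out = 101)))))
    stop("potential must be finite over the sampled range")
  structure(list(form = form, range = range, U = fun,
                 params = list(kappa = kappa, a = a, b = b)),
            class = "kir_potential")
}

#' Generate umbrella windows from an analytic potential
#'
#' Draws each window's samples exactly from the biased Boltzmann density
#' `p_i(xi) ~ exp(-beta (U(xi) + k_i (xi - xi_i)^2 / 2))` by inverse-CDF
#' sampling on a fine grid (10^4 points over the declared range), so the
#' WHAM estimate can be compared against known ground truth.
#'
#' @param potential a `kir_potential`.
#' @param centers window centers in nm.
#' @param k force constant(s), kJ/(mol nm^2); recycled over windows.
#' @param n_per_window samples per window.
#' @param temperature_K temperature (default 310 K).
#' @param seed integer seed.
#' @param grid_n inverse-CDF grid size (default 1e4).
#' @return list of `kir_window`.
#' @export
gen_us_windows <- function(potential, centers, k = 1000, n_per_window = 5000L,
                           temperature_K = 310, seed = 1L, grid_n = 1e4L) {
  if (any(centers < potential$range[1] | centers > potential$range[2]))
    stop("window centers must lie within the potential's range")
  k <- rep_len(k, length(centers))
  beta <- 1 / (kB_kj * temperature_K)
  grid <- seq(potential$range[1], potential$range[2], length.out = grid_n)
  Ug <- potential$U(grid)
  with_seed(seed, {
    lapply(seq_along(centers), function(i) {
      E <- Ug + 0.5 * k[i] * (grid - centers[i])^2
      w <- exp(-beta * (E - min(E)))
      if (!any(w > 0) || !all(is.finite(w)))
        stop("biased density is not normalizable on the declared range")
      cdf <- cumsum(w); cdf <- cdf / cdf[length(cdf)]
      u <- runif(n_per_window)
      keep <- !duplicated(cdf)
      samples <- approx(cdf[keep], grid[keep], xout = u, rule = 2)$y
      umbrella_window(centers[i], k[i], samples)
    })
  })
}

# ---------------------------------------------------------------------------
# dose-response generator
# ---------------------------------------------------------------------------

#' Generate synthetic dose-response (fractional block) data
#'
#' Hill-model block values plus Gaussian measurement noise, truncated to
#' the guard band `-0.05..1.05` that a normalized patch-clamp block can
#' plausibly occupy.
#'
#' @param ic50 planted IC50 in micromolar.
#' @param h planted Hill coefficient.
#' @param doses concentrations in micromolar.
#' @param n replicates per dose.
#' @param sigma Gaussian noise SD on the block scale (default 0.03).
#' @param seed integer seed.
#' @param drug,branch labels carried in the table.
#' @return data.frame of class `kir_dose_table` (drug, branch, conc, block,
#'   replicate) with the planted parameters as attributes.
#' @export
gen_dose_response <- function(ic50, h, doses, n = 8L, sigma = 0.03, seed = 1L,
                              drug = "drug", branch = "outward") {
  if (any(doses <= 0)) stop("doses must be positive")
  if (sigma < 0) stop("noise sigma must be >= 0")
  with_seed(seed, {
    tab <- expand.grid(replicate = seq_len(n), conc = sort(doses))
    mu <- hill_block(tab$conc, ic50, h)
    block <- mu + rnorm(nrow(tab), sd = sigma)
    tab <- data.frame(drug = drug, branch = branch, conc = tab$conc,
                      block = pmin(1.05, pmax(-0.05, block)),
                      replicate = tab$replicate, stringsAsFactors = FALSE)
    structure(tab, planted = list(ic50 = ic50, h = h, sigma = sigma, n = n),
              class = c("kir_dose_table", "data.frame"))
  })
}

# ---------------------------------------------------------------------------
# screening-library generator
# ---------------------------------------------------------------------------

#' Generate a planted active/decoy screening library
#'
#' Actives: each molecule selects `n_models_per_active` representative
#' models and carries one conformer per selected model whose features sit
#' within `r_tol / 2` of that model's features (Gaussian jitter, clipped),
#' under a random rigid transform.  Decoys: the same feature-kind multiset
#' as a representative, with every feature displaced beyond `2 r_tol` and
#' positions permuted, destroying the internal geometry.  Ground-truth
#' labels are attached for retrieval tests.
#'
#' @param representatives a `kir_representatives`.
#' @param n_actives,n_decoys library composition.
#' @param sigma jitter SD for active feature placement, Angstrom
#'   (default 0.3).
#' @param n_models_per_active models each active is planted around
#'   (default 2, matching the screening filter).
#' @param seed integer seed.
#' @return tabular library data.frame (molecule_id, conformer_id, kind,
#'   x, y, z) with attribute `labels` (molecule_id, role, planted models).
#' @export
gen_screen_library <- function(representatives, n_actives = 10L, n_decoys = 50L,
                               sigma = 0.3, n_models_per_active = 2L, seed = 1L) {
  models <- lapply(representatives, function(r)
    if (inherits(r, "kir_pharmacophore")) r else r$model)
  k <- length(models)
  if (k == 0L) stop("need at least one representative model")
  clip_jitter <- function(n, max_norm) {
    j <- matrix(rnorm(3 * n, sd = sigma), ncol = 3)
    nr <- sqrt(rowSums(j^2))
    too_far <- nr > max_norm
    j[too_far, ] <- j[too_far, , drop = FALSE] * (max_norm / nr[too_far])
    j
  }
  with_seed(seed, {
    rows <- list(); labels <- list()
    for (i in seq_len(n_actives)) {
      id <- sprintf("active_%03d", i)
      chosen <- sort(sample.int(k, min(n_models_per_active, k)))
      for (ci in seq_along(chosen)) {
        m <- models[[chosen[ci]]]
        ctr <- feature_centers(m$features)
        tol <- m$features$r_tol
        pos <- ctr + clip_jitter(nrow(ctr), 0.45 * min(tol))
        pos <- sweep(pos %*% random_rotation(), 2, runif(3, -20, 20), `+`)
        rows[[length(rows) + 1L]] <- data.frame(
          molecule_id = id, conformer_id = ci, kind = m$features$kind,
          x = pos[, 1], y = pos[, 2], z = pos[, 3], stringsAsFactors = FALSE)
      }
      labels[[length(labels) + 1L]] <- data.frame(
        molecule_id = id, role = "active",
        models = paste(chosen, collapse = ","), stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_decoys)) {
      id <- sprintf("decoy_%03d", i)
      m <- models[[(i - 1L) %% k + 1L]]
      ctr <- feature_centers(m$features)
      tol <- max(m$features$r_tol)
      nf <- nrow(ctr)
      # scrambled geometry: place every feature uniformly in the model's
      # spatial envelope (sphere around the centroid), each at least
      # 2 r_tol away from its template position, so internal distances are
      # fully randomized rather than perturbed
      centroid <- colMeans(ctr)
      rad <- 1.5 * max(sqrt(rowSums(sweep(ctr, 2, centroid)^2))) + 2 * tol
      pos <- ctr
      for (j in seq_len(nf)) {
        repeat {
          cand <- centroid + rnorm(3) * rad / sqrt(3)
          r2 <- sum((cand - centroid)^2)
          if (r2 <= rad^2 && sum((cand - ctr[j, ])^2) > (2 * tol)^2) break
        }
        pos[j, ] <- cand
      }
      pos <- pos[sample.int(nf), , drop = FALSE]
      pos <- sweep(pos %*% random_rotation(), 2, runif(3, -20, 20), `+`)
      rows[[length(rows) + 1L]] <- data.frame(
        molecule_id = id, conformer_id = 1L, kind = m$features$kind,
        x = pos[, 1], y = pos[, 2], z = pos[, 3], stringsAsFactors = FALSE)
      labels[[length(labels) + 1L]] <- data.frame(
        molecule_id = id, role = "decoy", models = "", stringsAsFactors = FALSE)
    }
    structure(do.call(rbind, rows), labels = do.call(rbind, labels))
  })
}
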