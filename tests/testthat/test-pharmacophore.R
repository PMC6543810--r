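triangle_model <- function(scale = 4, r_tol = 1.5, kinds = c("H", "H", "HBD")) {
  centers <- rbind(c(0, 0, 0), c(scale, 0, 0), c(scale / 2, scale, 0))
  kirpharm:::new_pharmacophore(fix_features(kinds, centers, r_tol = r_tol))
}

test_that("frame models keep exactly the interacting features", {
  ft <- fix_features(c("H", "H", "HBD"),
                     rbind(c(0, 0, 0), c(5, 0, 0), c(9, 1, 0)),
                     atoms = list(1:6, 10:15, 20L))
  recs <- rbind(fix_record(3L, "H", 1:6), fix_record(3L, "H", 10:15),
                fix_record(3L, "HB_donor", 20L))
  m <- build_frame_model(recs, ft)
  expect_equal(nrow(m$features), 3L)
  expect_equal(m$identity_key, "H:1,2,3,4,5,6;H:10,11,12,13,14,15;HBD:20")

  # only the features named by records survive
  m2 <- build_frame_model(recs[1, ], ft)
  expect_equal(m2$features$kind, "H")
  # duplicated records on one feature count once
  m3 <- build_frame_model(rbind(recs, recs[1, ]), ft)
  expect_equal(nrow(m3$features), 3L)
  # no records -> empty sentinel
  empty <- build_frame_model(kirpharm:::empty_records(), ft)
  expect_equal(nrow(empty$features), 0L)
  expect_equal(empty$identity_key, "")
  # mixed frames are rejected
  bad <- rbind(fix_record(1L, "H", 1:6), fix_record(2L, "H", 1:6))
  expect_error(build_frame_model(bad, ft), "multiple frames")
})

test_that("identity keys are invariant under feature reordering", {
  ft <- fix_features(c("HBD", "H"), rbind(c(1, 2, 3), c(4, 5, 6)),
                     atoms = list(20L, 1:3))
  k1 <- model_identity_key(ft)
  k2 <- model_identity_key(ft[2:1, ])
  expect_identical(k1, k2)
})

test_that("merging groups identical models and averages their geometry", {
  mk <- function(kind_set, jitter = 0) {
    centers <- switch(kind_set,
                      A = rbind(c(0, 0, 0), c(4, 0, 0)),
                      B = rbind(c(0, 0, 0), c(6, 0, 0)),
                      C = rbind(c(0, 0, 0), c(8, 0, 0)))
    atoms <- switch(kind_set, A = list(1:3, 4:6), B = list(1:3, 7:9),
                    C = list(1:3, 10:12))
    kirpharm:::new_pharmacophore(
      fix_features(c("H", "H"), centers + jitter, atoms = atoms))
  }
  models <- list(mk("A", 0.1), mk("A", -0.1), mk("A", 0.2), mk("A", -0.2),
                 mk("B"), mk("C"))
  reps <- merge_models(models)
  expect_equal(unname(vapply(reps, `[[`, numeric(1), "count")), c(4, 1, 1))
  expect_equal(attr(reps, "n_models"), 6L)
  # counts match an independent grouping oracle
  keys <- vapply(models, `[[`, character(1), "identity_key")
  want <- sort(as.integer(table(keys)), decreasing = TRUE)
  expect_equal(unname(vapply(reps, `[[`, numeric(1), "count")), as.numeric(want))
  # frequencies sum to one; centers are the group mean (jitters cancel)
  expect_equal(sum(vapply(reps, `[[`, numeric(1), "frequency")), 1)
  expect_equal(reps[[1]]$model$features$x, c(0, 4), tolerance = 1e-9)

  same <- merge_models(list(mk("A"), mk("A"), mk("A")))
  expect_length(same, 1L)
  expect_equal(same[[1]]$frequency, 1.0)

  # empty sentinels are excluded from the denominator
  with_empty <- c(models, list(kirpharm:::new_pharmacophore(kirpharm:::empty_features())))
  reps2 <- merge_models(with_empty)
  expect_equal(attr(reps2, "n_models"), 6L)
  expect_equal(attr(reps2, "n_empty"), 1L)
})

test_that("a conformer equal to the model matches with score one, rigidly invariant", {
  set.seed(41)
  m <- triangle_model()
  r <- match_model(m, m$features)
  expect_true(r$matched)
  expect_equal(r$score, 1.0, tolerance = 1e-9)

  for (rep in 1:5) {
    conf <- m$features
    rot <- rand_rigid(kirpharm:::feature_centers(conf))
    conf$x <- rot[, 1]; conf$y <- rot[, 2]; conf$z <- rot[, 3]
    r2 <- match_model(m, conf)
    expect_true(r2$matched)
    expect_equal(r2$score, 1.0, tolerance = 1e-6)
  }
})

test_that("matching agrees with the exhaustive-permutation oracle near the tolerance boundary", {
  set.seed(42)
  m <- triangle_model()
  for (disp in c(0.5, 1.4, 2.2, 4.0)) {
    conf <- m$features
    conf$z[3] <- conf$z[3] + disp
    got <- match_model(m, conf)
    want <- oracle_match(kirpharm:::feature_centers(m$features), m$features$kind,
                         1.5, kirpharm:::feature_centers(conf), conf$kind)
    expect_equal(got$matched, want$matched)
    expect_equal(got$score, want$score, tolerance = 1e-6)
    if (got$matched) {
      expect_true(all(got$distances <= 1.5))
      expect_equal(got$score, 1 - mean(got$distances) / 1.5, tolerance = 1e-9)
    }
  }
  # zero-feature conformer is unmatched, not an error
  none <- match_model(m, kirpharm:::empty_features())
  expect_false(none$matched)
  expect_error(match_model(kirpharm:::new_pharmacophore(kirpharm:::empty_features()),
                           m$features), "empty")
})

make_two_models <- function() {
  list(triangle_model(scale = 4),
       triangle_model(scale = 6, kinds = c("H", "H", "HBA")))
}

lib_from_conformers <- function(confs) {
  # confs: named list molecule -> list of feature tables
  do.call(rbind, lapply(names(confs), function(id) {
    do.call(rbind, lapply(seq_along(confs[[id]]), function(ci) {
      cf <- confs[[id]][[ci]]
      data.frame(molecule_id = id, conformer_id = ci, kind = cf$kind,
                 x = cf$x, y = cf$y, z = cf$z, stringsAsFactors = FALSE)
    }))
  }))
}

test_that("screening sums per-model best scores over matched models", {
  models <- make_two_models()
  jig <- function(ft, dz) { ft$z <- ft$z + dz * c(1, -1, 1); ft }
  lib <- lib_from_conformers(list(
    hit  = list(jig(models[[1]]$features, 0.3), jig(models[[2]]$features, 0.6)),
    half = list(models[[1]]$features),
    miss = list(jig(models[[1]]$features, 5))))
  hits <- screen_library(models, lib, min_active = 2L)
  expect_equal(hits$molecule_id, "hit")
  # CHA score equals the independently recomputed sum of per-model bests
  mol <- lib[lib$molecule_id == "hit", ]
  s <- vapply(models, function(m) {
    best <- -Inf
    for (ci in unique(mol$conformer_id)) {
      cf <- mol[mol$conformer_id == ci, ]
      feats <- fix_features(cf$kind, as.matrix(cf[, c("x", "y", "z")]))
      r <- match_model(m, feats)
      if (r$matched) best <- max(best, r$score)
    }
    best
  }, numeric(1))
  expect_equal(hits$cha_score, sum(s[is.finite(s)]), tolerance = 1e-9)
  expect_equal(hits$n_active, 2L)
  expect_true(all(hits$cha_score <= hits$n_active))

  # molecules matching < min_active models are dropped, not errors
  one <- screen_library(models, lib, min_active = 1L)
  expect_setequal(one$molecule_id, c("hit", "half"))
  expect_error(screen_library(models, lib, min_active = 3L), "min_active")
})

test_that("raising min_active never adds hits; adding conformers never lowers scores", {
  set.seed(43)
  ens <- gen_feature_trajectory(default_ensemble_spec(200L), seed = 9)
  models <- mapply(build_frame_model, ens$records, ens$features, SIMPLIFY = FALSE)
  reps <- merge_models(models)
  lib <- gen_screen_library(reps, n_actives = 4, n_decoys = 10, seed = 2)
  h1 <- screen_library(reps, lib, min_active = 1L)
  h2 <- screen_library(reps, lib, min_active = 2L)
  expect_true(all(h2$molecule_id %in% h1$molecule_id))
  expect_true(all(h1$cha_score <= h1$n_active))

  # drop one active's second conformer: its per-model scores cannot rise
  vic <- h2$molecule_id[grepl("active", h2$molecule_id)][1]
  sub <- lib[!(lib$molecule_id == vic & lib$conformer_id == 2), ]
  hs <- screen_library(reps, sub, min_active = 1L)
  full_row <- h1[h1$molecule_id == vic, grep("^s_", names(h1))]
  sub_row <- hs[hs$molecule_id == vic, grep("^s_", names(hs))]
  if (nrow(sub_row)) {
    both <- !is.na(full_row) & !is.na(sub_row)
    expect_true(all(sub_row[both] <= full_row[both] + 1e-9))
  }
})

test_that("representative models survive a YAML round trip", {
  ens <- gen_feature_trajectory(default_ensemble_spec(100L), seed = 4)
  models <- mapply(build_frame_model, ens$records, ens$features, SIMPLIFY = FALSE)
  reps <- merge_models(models)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_representatives(reps, f)
  back <- read_representatives(f)
  expect_equal(length(back), length(reps))
  expect_equal(back[[1]]$count, reps[[1]]$count)
  expect_equal(back[[1]]$model$identity_key, reps[[1]]$model$identity_key)
  expect_equal(kirpharm:::feature_centers(back[[1]]$model$features),
               kirpharm:::feature_centers(reps[[1]]$model$features),
               tolerance = 1e-6)
})
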