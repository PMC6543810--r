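hexagon <- function(r = 1.39, z = 0) {
  th <- seq(0, 2 * pi, length.out = 7)[-7]
  cbind(r * cos(th), r * sin(th), z)
}

ring_config <- function(extra = list()) {
  cfg <- list(ligand = list(
    resname = "LIG",
    bonds = c(lapply(1:5, function(i) c(i, i + 1L)), list(c(6L, 1L))),
    aromatic_atoms = 1:6, apolar_atoms = 1:6))
  modifyList(cfg, extra)
}

test_that("a benzene ring yields one AR feature at the centroid with a unit normal", {
  atoms <- fix_atoms(6)
  trj <- fix_traj(atoms, list(hexagon()), config = ring_config())
  ft <- perceive_features(trj)
  ar <- ft[ft$kind == "AR", ]
  expect_equal(nrow(ar), 1L)
  expect_equal(as.numeric(ar[, c("x", "y", "z")]), c(0, 0, 0), tolerance = 1e-9)
  n <- abs(as.numeric(ar[, c("nx", "ny", "nz")]))
  expect_equal(n, c(0, 0, 1), tolerance = 1e-9)
  expect_setequal(ar$atoms[[1]], 1:6)
  # the same six apolar carbons also cluster into one hydrophobic feature
  expect_equal(sum(ft$kind == "H"), 1L)
})

test_that("ring perception without a bond list is an error", {
  atoms <- fix_atoms(6)
  cfg <- ring_config(); cfg$ligand$bonds <- NULL
  trj <- fix_traj(atoms, list(hexagon()), config = cfg)
  expect_error(perceive_features(trj), "bond list")
})

test_that("donor, acceptor and single-carbon features sit on their atoms", {
  atoms <- fix_atoms(3, element = "C")
  atoms$element <- c("N", "O", "C")
  xyz <- matrix(c(0, 0, 0, 3, 0, 0, 6, 0, 0), 3, byrow = TRUE)
  trj <- fix_traj(atoms, list(xyz), config = list(ligand = list(
    resname = "LIG", donors = 1L, acceptors = 2L, apolar_atoms = 3L)))
  ft <- perceive_features(trj)
  expect_setequal(ft$kind, c("HBD", "HBA", "H"))
  expect_equal(as.numeric(ft[ft$kind == "HBD", c("x", "y", "z")]), c(0, 0, 0))
  expect_equal(as.numeric(ft[ft$kind == "H", c("x", "y", "z")]), c(6, 0, 0))
  expect_true(all(ft$r_tol == 1.5))
})

test_that("feature perception is covariant under rigid transforms", {
  set.seed(21)
  atoms <- fix_atoms(6)
  base <- hexagon()
  for (rep in 1:3) {
    R <- rand_rotation(); t <- runif(3, -8, 8)
    moved <- sweep(base %*% R, 2, t, `+`)
    trj <- fix_traj(atoms, list(base, moved), config = ring_config())
    f1 <- perceive_features(trj, 1)
    f2 <- perceive_features(trj, 2)
    expect_equal(nrow(f1), nrow(f2))
    c1 <- sweep(as.matrix(f1[, c("x", "y", "z")]) %*% R, 2, t, `+`)
    expect_equal(c1, as.matrix(f2[, c("x", "y", "z")]), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

hb_fixture <- function(dist_O) {
  atoms <- rbind(fix_atoms(1, element = "N", resname = "LIG"),
                 fix_atoms(1, element = "O", name = "O", resname = "GLY",
                           resno = 100L, is_ligand = FALSE, id_start = 2L))
  xyz <- matrix(c(0, 0, 0, dist_O, 0, 0), 2, byrow = TRUE)
  fix_traj(atoms, list(xyz), config = list(ligand = list(atom_ids = 1L, donors = 1L)))
}

test_that("hydrogen bonds are detected within 3.5 A and rejected beyond", {
  trj <- hb_fixture(3.0)
  rec <- detect_interactions(trj, 1)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$kind, "HB_donor")
  expect_equal(rec$partner, "GLY100.A")
  expect_equal(rec$distance, 3.0, tolerance = 1e-9)

  far <- hb_fixture(4.2)
  expect_equal(nrow(detect_interactions(far, 1)), 0L)
})

test_that("hydrophobic contacts record the pair distance against the residue", {
  atoms <- rbind(fix_atoms(1, element = "C", resname = "LIG"),
                 fix_atoms(1, element = "C", name = "CD1", resname = "ILE",
                           resno = 60L, is_ligand = FALSE, id_start = 2L))
  xyz <- matrix(c(0, 0, 0, 4, 0, 0), 2, byrow = TRUE)
  trj <- fix_traj(atoms, list(xyz),
                  config = list(ligand = list(atom_ids = 1L, apolar_atoms = 1L)))
  rec <- detect_interactions(trj, 1)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$kind, "H")
  expect_equal(rec$partner, "ILE60.A")
  expect_equal(rec$distance, 4.0, tolerance = 1e-9)
})

test_that("membrane lipid partners are excluded under the default receptor scope", {
  atoms <- rbind(fix_atoms(1, element = "C", resname = "LIG"),
                 fix_atoms(1, element = "C", name = "C12", resname = "POPC",
                           resno = 300L, is_ligand = FALSE, id_start = 2L))
  xyz <- matrix(c(0, 0, 0, 4, 0, 0), 2, byrow = TRUE)
  trj <- fix_traj(atoms, list(xyz),
                  config = list(ligand = list(atom_ids = 1L, apolar_atoms = 1L)))
  expect_equal(nrow(detect_interactions(trj, 1)), 0L)
  all_scope <- detect_interactions(trj, 1, scope = "all")
  expect_equal(all_scope$partner, "POPC300.A")
})

test_that("interaction detection agrees with a brute-force pair scan", {
  set.seed(22)
  rules <- default_perception_rules()
  for (rep in 1:5) {
    n_rec <- 40L
    lig_atoms <- fix_atoms(3, resname = "LIG")
    lig_atoms$element <- c("C", "N", "O")
    rec_atoms <- fix_atoms(n_rec, resname = "XXX", resno = 1L,
                           is_ligand = FALSE, id_start = 4L)
    rec_atoms$resname <- sample(c("ALA", "ILE", "SER", "POPC"), n_rec, TRUE)
    rec_atoms$resno <- sample(50:80, n_rec, TRUE)
    rec_atoms$element <- sample(c("C", "N", "O"), n_rec, TRUE)
    rec_atoms$name <- paste0(rec_atoms$element, "B")
    atoms <- rbind(lig_atoms, rec_atoms)
    xyz <- rbind(matrix(rnorm(9, sd = 1.5), 3),
                 matrix(rnorm(3 * n_rec, sd = 4), n_rec))
    trj <- fix_traj(atoms, list(xyz), config = list(ligand = list(
      atom_ids = 1:3, apolar_atoms = 1L, donors = 2L, acceptors = 3L)))
    ft <- perceive_features(trj, 1)
    rec <- detect_interactions(trj, 1, ft)
    got <- sort(unique(paste(match(paste0(rec$kind), c("H", "HB_donor", "HB_acceptor")),
                             rec$partner)))
    # oracle keys by feature row; map rows to kinds in the same order
    want <- oracle_pair_scan(trj, 1, ft, rules)
    want <- sort(unique(vapply(strsplit(want, " "), function(p) {
      paste(match(ft$kind[as.integer(p[1])], c("H", "HBD", "HBA")), p[2])
    }, character(1))))
    expect_identical(got, want)
  }
})
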