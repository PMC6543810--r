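frags3 <- c("RingA", "RingB", "RingC")

test_that("cells are the percentage of frames showing the contact", {
  recs <- rbind(fix_record(0L, "H", 1:3), fix_record(1L, "H", 1:3),
                fix_record(2L, "H", 1:3))
  m <- build_interaction_map(recs, frags3, n_frames = 4L)
  expect_equal(unname(m$cells["PHE76.A|H", "RingA"]), 75.0)
  expect_equal(m$n_frames, 4L)
  # duplicate same-kind records in one frame count once
  recs2 <- rbind(recs, fix_record(0L, "H", 4:5))
  m2 <- build_interaction_map(recs2, frags3, n_frames = 4L)
  expect_equal(unname(m2$cells["PHE76.A|H", "RingA"]), 75.0)
})

test_that("no records gives an empty all-zero matrix with the declared frame count", {
  m <- build_interaction_map(kirpharm:::empty_records(), frags3, n_frames = 10L)
  expect_equal(nrow(m$cells), 0L)
  expect_equal(m$n_frames, 10L)
  expect_equal(nrow(persistent_contacts(m, 0)), 0L)
})

test_that("unknown fragments in records are rejected", {
  recs <- fix_record(0L, "H", 1:3, fragment = "Nope")
  expect_error(build_interaction_map(recs, frags3, 4L), "Nope")
})

test_that("the map equals a naive recount oracle on random record sets", {
  set.seed(31)
  for (rep in 1:5) {
    nf <- 30L
    n <- 120L
    residues <- data.frame(partner = c("PHE76.A", "VAL172.A", "PIP2"),
                           resno = c(76L, 172L, 401L))
    pick <- sample(3L, n, TRUE)
    recs <- do.call(rbind, lapply(seq_len(n), function(i)
      fix_record(sample(nf, 1) - 1L, sample(c("H", "AR", "HB_donor"), 1),
                 1:2, fragment = sample(frags3, 1),
                 partner = residues$partner[pick[i]],
                 resno = residues$resno[pick[i]])))
    m <- build_interaction_map(recs, frags3, nf)
    want <- oracle_recount(recs, frags3, nf)
    expect_equal(m$cells[rownames(want), colnames(want)], want,
                 tolerance = 1e-12)
  }
})

test_that("merging two trajectories' records is frame-count-weighted", {
  set.seed(32)
  recs <- do.call(rbind, lapply(1:80, function(i)
    fix_record(sample(20L, 1) - 1L, "H", 1:2,
               fragment = sample(frags3, 1))))
  a <- recs[recs$frame_index < 8, ]
  b <- recs[recs$frame_index >= 8, ]
  m_all <- build_interaction_map(recs, frags3, 20L)
  m_a <- build_interaction_map(a, frags3, 8L)
  m_b <- build_interaction_map(b, frags3, 12L)
  combined <- (m_a$cells["PHE76.A|H", ] * 8 + m_b$cells["PHE76.A|H", ] * 12) / 20
  expect_equal(m_all$cells["PHE76.A|H", ], combined, tolerance = 1e-12)
})

test_that("a planted 0.80-probability contact is recovered within binomial error", {
  set.seed(33)
  nf <- 5000L
  present <- runif(nf) < 0.80
  recs <- do.call(rbind, lapply(which(present), function(f)
    fix_record(f - 1L, "H", 1:3)))
  m <- build_interaction_map(recs, frags3, nf)
  sigma3 <- 3 * sqrt(0.8 * 0.2 / nf) * 100
  expect_lt(abs(m$cells["PHE76.A|H", "RingA"] - 80), sigma3)
  expect_true(nrow(persistent_contacts(m, 0)) >= 1)
})

test_that("persistent contacts filter and sort by percentage then residue number", {
  recs <- rbind(
    do.call(rbind, lapply(0:7, function(f) fix_record(f, "H", 1:3, resno = 76L))),
    do.call(rbind, lapply(0:6, function(f)
      fix_record(f, "H", 1:3, partner = "VAL172.A", resname = "VAL", resno = 172L))),
    do.call(rbind, lapply(0:3, function(f)
      fix_record(f, "H", 1:3, partner = "ILE60.A", resname = "ILE", resno = 60L))))
  m <- build_interaction_map(recs, frags3, 10L)  # 80, 70, 40 %
  pc <- persistent_contacts(m, 65)
  expect_equal(pc$resno, c(76L, 172L))
  expect_equal(pc$pct, c(80, 70))
  expect_equal(nrow(persistent_contacts(m, 100)), 0L)
})

occupancy_fixture <- function(bound_at, n, dt = 1, d_bound = 3, d_free = 10) {
  atoms <- rbind(fix_atoms(1, resname = "LIG"),
                 fix_atoms(1, resname = "PHE", resno = 76L, is_ligand = FALSE,
                           id_start = 2L))
  d <- ifelse(seq_len(n) %in% bound_at, d_bound, d_free)
  coords <- array(0, dim = c(2, 3, n))
  coords[2, 1, ] <- d
  kirpharm:::new_trajectory(atoms, coords, (seq_len(n) - 1) * dt)
}

test_that("site occupancy reports the longest bound interval on the trajectory clock", {
  # bound exactly over frames with times 300..1500 ns, plus a short early visit
  trj <- occupancy_fixture(c(10:20, 301:1501), 1601L)
  occ <- site_occupancy(trj, 1L, site = list(residues = 76L, cutoff = 4.0))
  expect_equal(occ$longest$start, 300)
  expect_equal(occ$longest$end, 1500)
  expect_equal(occ$longest$duration, 1200)
})

test_that("never-bound and always-bound trajectories hit the boundary conventions", {
  never <- site_occupancy(occupancy_fixture(integer(), 50L), 1L,
                          site = list(residues = 76L, cutoff = 4.0))
  expect_equal(never$fraction, 0)
  expect_equal(never$longest$duration, 0)

  always <- site_occupancy(occupancy_fixture(1:100, 100L), 1L,
                           site = list(residues = 76L, cutoff = 4.0))
  expect_equal(always$fraction, 1)
  expect_equal(always$longest$duration, 99)
})

test_that("occupancy duration is monotone in the cutoff", {
  set.seed(34)
  trj <- occupancy_fixture(integer(), 200L)
  trj$coords[2, 1, ] <- runif(200, 2, 8)
  durations <- vapply(c(2.5, 4, 6, 8.5), function(cut)
    site_occupancy(trj, 1L, site = list(residues = 76L, cutoff = cut))$longest$duration,
    numeric(1))
  expect_true(all(diff(durations) >= 0))
  expect_error(site_occupancy(trj, integer(), site = list(residues = 76L)), "empty")
  expect_error(site_occupancy(trj, 1L, site = list(residues = 999L)), "not found")
})
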