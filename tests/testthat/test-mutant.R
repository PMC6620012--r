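test_that("side-chain replacement changes heavy-atom counts by composition", {
  g <- build_helix("AAGAA")
  ga <- mutate_side_chain(g, "A", 3, "A")
  expect_equal(nrow(ga$atoms) - nrow(g$atoms), 1)  # Gly -> Ala adds CB
  w <- build_helix("AAWAA")
  wg <- mutate_side_chain(w, "A", 3, "G")
  sc_atoms <- wg$atoms[wg$atoms$resi == 3 &
                       !wg$atoms$name %in% c("N", "CA", "C", "O"), ]
  expect_equal(nrow(sc_atoms), 0)
  expect_identical(wg$residues$aa[3], "G")
})

test_that("backbone coordinates are bit-identical after mutation and repacking", {
  h <- fix_helix15()
  m <- mutate_side_chain(h, "A", 8, "W")
  bb <- c("N", "CA", "C", "O")
  wt_bb <- h$atoms[h$atoms$name %in% bb, c("resi", "name", "x", "y", "z")]
  mut_bb <- m$atoms[m$atoms$name %in% bb, c("resi", "name", "x", "y", "z")]
  expect_identical(wt_bb$x, mut_bb$x)
  expect_identical(wt_bb$y, mut_bb$y)
  expect_identical(wt_bb$z, mut_bb$z)
  rp <- repack_neighborhood(m, "A", 8, fast_repack())
  rp_bb <- rp$model$atoms[rp$model$atoms$name %in% bb,
                          c("x", "y", "z")]
  expect_identical(mut_bb$x, rp_bb$x)
  expect_identical(mut_bb$y, rp_bb$y)
  expect_identical(mut_bb$z, rp_bb$z)
})

test_that("mutating to the wild-type residue or an ineligible site errors", {
  h <- fix_helix12()
  expect_error(mutate_side_chain(h, "A", 3, "A"), "equals the wild-type")
  expect_error(mutate_side_chain(h, "A", 99, "W"), "not found")
})

test_that("zero Monte-Carlo steps return the input unchanged", {
  m <- mutate_side_chain(fix_helix12(), "A", 6, "L")
  rp <- repack_neighborhood(m, "A", 6, repack_config(mc_steps = 0))
  expect_identical(rp$model$atoms, m$atoms)
  expect_equal(rp$initial_energy, rp$final_energy)
})

test_that("repacking is deterministic under a fixed seed", {
  m <- mutate_side_chain(fix_helix15(), "A", 8, "F")
  r1 <- repack_neighborhood(m, "A", 8, fast_repack(seed = 42))
  r2 <- repack_neighborhood(m, "A", 8, fast_repack(seed = 42))
  expect_identical(r1$model$atoms, r2$model$atoms)
  expect_identical(r1$trace, r2$trace)
  r3 <- repack_neighborhood(m, "A", 8, fast_repack(seed = 43))
  expect_false(identical(r3$trace, r1$trace))
})

test_that("repacking conserves composition and only moves the 5 A shell", {
  h <- fix_helix15()
  m <- mutate_side_chain(h, "A", 3, "W")
  rp <- repack_neighborhood(m, "A", 3, fast_repack())
  expect_identical(rp$model$atoms$name, m$atoms$name)
  expect_identical(rp$model$residues$aa, m$residues$aa)
  dmin <- tmvarboost:::residue_min_dist(m, 3)
  outside <- m$residues$resi[dmin > 5]
  expect_gt(length(outside), 0)  # the fixture must exercise locality
  for (ri in outside) {
    before <- m$atoms[m$atoms$resi == ri, c("x", "y", "z")]
    after <- rp$model$atoms[rp$model$atoms$resi == ri, c("x", "y", "z")]
    expect_identical(before$x, after$x)
    expect_identical(before$y, after$y)
    expect_identical(before$z, after$z)
  }
})

test_that("repacking a clashed mutant strictly lowers the pair energy", {
  # bulky Trp dropped into a tight leucine core at default chis clashes
  m <- mutate_side_chain(fix_helix15(), "A", 8, "W")
  e0 <- system_energy(m)
  rp <- repack_neighborhood(m, "A", 8, repack_config(mc_steps = 200,
                                                     seed = 7))
  expect_equal(rp$initial_energy, e0, tolerance = 1e-9)
  expect_lt(rp$final_energy, e0)
  # direct evaluation of the returned model agrees with the reported value
  expect_equal(system_energy(rp$model), rp$final_energy, tolerance = 1e-6)
  # best-so-far: the reported final energy is never above any later state
  expect_lte(rp$final_energy, min(rp$trace$energy))
})
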