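test_that("gen_shell is deterministic and its ground truth matches the closed form", {
  spec <- shell_spec(axes_nm = c(22, 16, 12), thickness_nm = 2, spacing = 4, seed = 7)
  sh1 <- gen_shell(spec)
  sh2 <- gen_shell(spec)
  expect_identical(sh1$model$residues, sh2$model$residues)
  # inner axes 18 x 12 x 8 nm: (4/3) pi (a/2-t)(b/2-t)(c/2-t)
  expect_equal(sh1$truth$cavity_volume, 4 / 3 * pi * 9 * 6 * 4, tolerance = 1e-12)
  expect_equal(sh1$truth$cavity_axes, c(18, 12, 8))
  expect_equal(sh1$truth$opening_count, 0)
  # interior and exterior ground-truth sets are disjoint
  ik <- paste(sh1$truth$interior_residues$chain, sh1$truth$interior_residues$resno)
  ek <- paste(sh1$truth$exterior_residues$chain, sh1$truth$exterior_residues$resno)
  expect_length(intersect(ik, ek), 0)
})

test_that("gen_shell builds a D2 tetramer with shared numbering and plants openings", {
  sh <- small_shell()
  expect_equal(chain_ids(sh$model), c("A", "B", "C", "D"))
  ra <- sh$model$residues[sh$model$residues$chain == "A", ]
  rb <- sh$model$residues[sh$model$residues$chain == "B", ]
  expect_equal(ra$resno, rb$resno)
  # chain B is chain A rotated two-fold about z
  expect_equal(rb$x, -ra$x)
  expect_equal(rb$y, -ra$y)
  expect_equal(rb$z, ra$z)

  two <- small_shell(openings = list(opening_spec(c(0, 1, 0), 10),
                                     opening_spec(c(0, -1, 0), 10)))
  expect_equal(two$truth$opening_count, 2)
  expect_lt(nrow(two$model$residues), nrow(sh$model$residues))
})

test_that("gen_shell rejects a wall thicker than the smallest semi-axis", {
  expect_error(shell_spec(axes_nm = c(10, 8, 6), thickness_nm = 3), "thickness")
})

test_that("gen_pae produces exact blocks without noise and respects the clip ceiling", {
  part <- domain_partition(rep(c(1L, 2L), each = 30))
  pae <- gen_pae(part, 60, within_mean = 4, between_mean = 25, noise_sd = 0, seed = 1)
  expect_equal(pae[1, 2], 4)
  expect_equal(pae[1, 40], 25)
  expect_equal(pae[40, 1], 25)
  expect_true(all(unclass(pae)[1:30, 1:30] == 4))

  noisy <- gen_pae(part, 60, noise_sd = 20, seed = 2)
  expect_gte(min(noisy), 0)
  expect_lte(max(noisy), 31.75)

  expect_error(gen_pae(part, 61), "length must equal n")
  expect_error(gen_pae(part, 60, within_mean = 10, between_mean = 5), "between_mean > within_mean")
})

test_that("gen_pae linker residues draw from the between-domain distribution", {
  part <- domain_partition(c(rep(1L, 20), rep(0L, 5), rep(2L, 20)))
  pae <- gen_pae(part, 45, noise_sd = 0, seed = 1)
  expect_true(all(unclass(pae)[21:25, ] == 25))
})

test_that("gen_crosslinks plants verifiable satisfied and violated links", {
  sh <- small_shell()
  gx <- gen_crosslinks(sh$model, n_satisfied = 9, n_violated = 0, seed = 11)
  expect_equal(nrow(gx$table), 9)
  d <- mapply(function(a, b) brute_min_distance(sh$model, a, b),
              gx$truth$res_a, gx$truth$res_b)
  expect_true(all(d <= 35))
  expect_equal(unname(d), gx$truth$distance, tolerance = 1e-9)

  gv <- gen_crosslinks(sh$model, n_satisfied = 0, n_violated = 3, seed = 5)
  dv <- mapply(function(a, b) brute_min_distance(sh$model, a, b),
               gv$truth$res_a, gv$truth$res_b)
  expect_true(all(dv > 35))

  gx2 <- gen_crosslinks(sh$model, n_satisfied = 9, n_violated = 0, seed = 11)
  expect_identical(gx$table, gx2$table)
})

test_that("gen_crosslinks declares infeasible requests", {
  tiny <- atomic_model(data.frame(chain = "A", resno = 1:2, resname = "GLY",
                                  x = c(0, 1), y = 0, z = 0))
  expect_error(gen_crosslinks(tiny, n_satisfied = 0, n_violated = 1, seed = 1),
               "infeasible")
})

test_that("gen_sec reproduces the planted law exactly without noise", {
  gs <- gen_sec(slope = -0.05, intercept = 6, noise_sd = 0, unknown_mw = 1032, seed = 1)
  st <- gs$table[!is.na(gs$table$mw_kda), ]
  fit <- fit_calibration(st)
  expect_equal(fit$slope, -0.05, tolerance = 1e-10)
  expect_equal(fit$intercept, 6, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)
  # Blue Dextran is excluded from the regression as a void marker
  expect_false(any(grepl("Dextran", fit$standards_used)))
  # unknown row is unlabeled
  expect_true(is.na(gs$table$mw_kda[gs$table$name == "unknown"]))

  gs2 <- gen_sec(slope = -0.05, intercept = 6, noise_sd = 0, unknown_mw = 1032, seed = 1)
  expect_identical(gs$table, gs2$table)
  expect_error(gen_sec(unknown_mw = -5), "non-positive")
  expect_error(gen_sec(slope = 0.05, unknown_mw = 10), "negative")
})

test_that("gen_seq_pair hits the identity target within 1/length and is seeded", {
  same <- gen_seq_pair(100, 1.0, seed = 1)
  expect_identical(same$seqs[["A"]], same$seqs[["B"]])

  gp <- gen_seq_pair(1000, 0.25, seed = 3)
  a <- strsplit(gp$seqs[["A"]], "")[[1]]
  b <- strsplit(gp$seqs[["B"]], "")[[1]]
  realized <- mean(a == b)
  expect_gte(realized, 0.249)
  expect_lte(realized, 0.251)
  expect_equal(realized, gp$realized_identity)

  expect_identical(gen_seq_pair(1000, 0.25, seed = 3)$seqs, gp$seqs)
  expect_error(gen_seq_pair(10, 0.5), "length")
  expect_error(gen_seq_pair(100, 0), "target_identity")
})
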