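two_chain_model <- function() {
  # chain A along x at y=0; chain B a parallel copy at y=30
  atomic_model(data.frame(
    chain = rep(c("A", "B"), each = 4),
    resno = rep(1:4, 2), resname = "GLY",
    x = rep(c(0, 10, 20, 30), 2),
    y = rep(c(0, 30), each = 4),
    z = 0))
}

test_that("ca_distance is plain Euclidean geometry with an unmappable signal", {
  m <- atomic_model(data.frame(chain = "A", resno = 1:3, resname = "GLY",
                               x = c(0, 0, NA), y = 0, z = c(0, 35, NA)))
  expect_equal(ca_distance(m, c("A", 1), c("A", 2)), 35.0)
  expect_equal(ca_distance(m, c("A", 1), c("A", 1)), 0.0)
  expect_true(is.na(ca_distance(m, c("A", 1), c("A", 3))))
  expect_true(is.na(ca_distance(m, c("A", 1), c("A", 9))))
})

test_that("single-chain models always resolve intra", {
  m <- atomic_model(data.frame(chain = "A", resno = 1:2, resname = "GLY",
                               x = c(0, 12), y = 0, z = 0))
  a <- assign_link(m, list(protein_a = "model", res_a = 1, protein_b = "model", res_b = 2))
  expect_equal(a$best_class, "intra")
  expect_equal(a$best_distance, 12)
  expect_true(a$satisfied)
})

test_that("the 35 A restraint is inclusive and the margin signed", {
  m <- atomic_model(data.frame(chain = "A", resno = 1:2, resname = "GLY",
                               x = c(0, 35), y = 0, z = 0))
  a <- assign_link(m, list(protein_a = "m", res_a = 1, protein_b = "m", res_b = 2),
                   threshold = 35)
  expect_true(a$satisfied)
  expect_equal(a$margin, 0)

  m2 <- atomic_model(data.frame(chain = "A", resno = 1:2, resname = "GLY",
                                x = c(0, 35.5), y = 0, z = 0))
  a2 <- assign_link(m2, list(protein_a = "m", res_a = 1, protein_b = "m", res_b = 2))
  expect_false(a2$satisfied)
  expect_lt(a2$margin, 0)
})

test_that("intra/inter classification uses minimum distance with a tie margin", {
  m <- two_chain_model()
  # res 1 - res 2 intra: 10 A; inter (A1-B2): sqrt(100+900) = 31.6
  a <- assign_link(m, list(protein_a = "m", res_a = 1, protein_b = "m", res_b = 2))
  expect_equal(a$best_class, "intra")
  expect_equal(a$best_distance, 10)
  # same residue on both endpoints: intra 0, inter 30 -> intra
  b <- assign_link(m, list(protein_a = "m", res_a = 1, protein_b = "m", res_b = 1))
  expect_equal(b$best_class, "intra")
  # tie: intra minimum 10, inter minimum 10.5, within the 1 A margin
  tie <- atomic_model(data.frame(chain = c("A", "A", "B", "B"),
                                 resno = c(1, 2, 1, 2), resname = "GLY",
                                 x = c(0, 10, 20.5, 30.5), y = 0, z = 0))
  t1 <- assign_link(tie, list(protein_a = "m", res_a = 1, protein_b = "m", res_b = 2))
  expect_equal(t1$best_class, "ambiguous")
  expect_equal(t1$best_distance, 10)
})

test_that("assignment equals exhaustive chain-pair enumeration on the tetramer shell", {
  sh <- small_shell()
  set.seed(7)
  universe <- unique(sh$model$residues$resno)
  for (i in 1:100) {
    pr <- sample(universe, 2)
    a <- assign_link(sh$model, list(protein_a = "synthetic_shell", res_a = pr[1],
                                    protein_b = "synthetic_shell", res_b = pr[2]))
    expect_equal(a$best_distance, brute_min_distance(sh$model, pr[1], pr[2]),
                 tolerance = 1e-9)
  }
})

test_that("assignment is invariant under chain relabeling", {
  m <- two_chain_model()
  r <- m$residues
  r$chain <- ifelse(r$chain == "A", "B", "A")
  r <- r[order(match(r$chain, c("A", "B"))), ]
  swapped <- atomic_model(r)
  l <- list(protein_a = "m", res_a = 1, protein_b = "m", res_b = 3)
  expect_equal(assign_link(m, l)$best_distance, assign_link(swapped, l)$best_distance)
  expect_equal(assign_link(m, l)$best_class, assign_link(swapped, l)$best_class)
})

test_that("satisfaction reports aggregate and never drop links", {
  sh <- small_shell()
  empty <- crosslink_table(data.frame(protein_a = character(), res_a = integer(),
                                      protein_b = character(), res_b = integer()))
  r0 <- satisfaction_report(sh$model, empty)
  expect_equal(c(r0$n_links, r0$n_satisfied, r0$n_violated, r0$n_unmappable),
               c(0, 0, 0, 0))

  gv <- gen_crosslinks(sh$model, n_satisfied = 2, n_violated = 3, seed = 21)
  rep <- satisfaction_report(sh$model, gv$table)
  expect_equal(rep$n_links, 5)
  expect_equal(rep$n_violated, 3)
  bad <- rep$assignments[!rep$assignments$satisfied, ]
  expect_true(all(bad$distance > 35))
  expect_equal(rep$n_links, rep$n_satisfied + rep$n_violated + rep$n_unmappable)

  # a link to a residue number absent from the model is unmappable
  ghost <- crosslink_table(data.frame(protein_a = "synthetic_shell", res_a = 1,
                                      protein_b = "synthetic_shell", res_b = 10 * max(sh$model$residues$resno)))
  rg <- satisfaction_report(sh$model, ghost)
  expect_equal(rg$n_unmappable, 1)
})

test_that("distances and reports survive rigid-body transforms", {
  sh <- small_shell()
  moved <- rigid_transform(sh$model, seed = 2)
  gx <- gen_crosslinks(sh$model, n_satisfied = 4, n_violated = 2, seed = 8)
  r1 <- satisfaction_report(sh$model, gx$table)
  r2 <- satisfaction_report(moved, gx$table)
  expect_equal(r1$assignments$distance, r2$assignments$distance, tolerance = 1e-6)
  expect_equal(r1$n_satisfied, r2$n_satisfied)
})

test_that("partner faces are called from surface labels with ambiguity preserved", {
  sh <- small_shell()
  surface <- structure(data.frame(
    chain = "A", resno = 1:6,
    label = c("interior", "interior", "interior", "exterior", "exterior", "buried")),
    class = c("surface_classification", "data.frame"))
  links <- crosslink_table(data.frame(
    protein_a = rep("cage", 6), res_a = c(1, 2, 3, 4, 1, 6),
    protein_b = c("pin", "pin", "pin", "pout", "pmix", "pbur"),
    res_b = c(10, 11, 12, 10, 10, 10)), quiet = TRUE)
  pf <- partner_face(sh$model, links, surface, cage_protein = "cage")
  pf <- pf[order(pf$partner), ]
  expect_equal(pf$face[pf$partner == "pin"], "interior")
  expect_equal(pf$n_interior[pf$partner == "pin"], 3)
  expect_equal(pf$face[pf$partner == "pout"], "exterior")
  expect_equal(pf$face[pf$partner == "pbur"], "ambiguous")
  # one interior + one exterior link: undecidable, counts (1,1)
  mixed <- crosslink_table(data.frame(
    protein_a = c("cage", "cage"), res_a = c(1, 4),
    protein_b = "actin", res_b = c(5, 6)), quiet = TRUE)
  pm <- partner_face(sh$model, mixed, surface, cage_protein = "cage")
  expect_equal(pm$face, "ambiguous")
  expect_equal(c(pm$n_interior, pm$n_exterior), c(1, 1))
})

test_that("a planted interior-binding partner is recovered on the shell", {
  sh <- small_shell()
  g <- voxelize(sh$model)
  masks <- find_cavity(g)
  surface <- classify_surface_residues(sh$model, masks$cavity, masks$exterior, g)
  ti <- sh$truth$interior_residues
  pick <- ti$resno[ti$chain == "A"][1:5]
  links <- crosslink_table(data.frame(
    protein_a = "synthetic_shell", res_a = pick,
    protein_b = "partner1", res_b = 100 + seq_along(pick)), quiet = TRUE)
  pf <- partner_face(sh$model, links, surface, cage_protein = "synthetic_shell")
  expect_equal(pf$face, "interior")
})
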