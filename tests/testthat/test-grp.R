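test_that("the GRP is zero exactly inside the well basin", {
  # H2 inside the bonded well: cutoff 0.814, flat zone (0.326, 0.733)
  g <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(0.70, 0, 0)))
  cm <- matrix(c(0L, 1L, 1L, 0L), 2)
  en <- grp_energy(g$coords, cm, g$elements)
  expect_identical(en$energy, 0)
  expect_identical(en$gradient, matrix(0, 2, 3))

  # bonded pair at twice the cutoff: positive energy; the gradient points
  # uphill, so the force -dE/dr pulls atom 1 toward +x (toward atom 2)
  far <- rbind(c(0, 0, 0), c(2 * 0.814, 0, 0))
  en2 <- grp_energy(far, cm, c("H", "H"))
  expect_gt(en2$energy, 0)
  expect_lt(en2$gradient[1, 1], 0)
  expect_gt(en2$gradient[2, 1], 0)

  # nonbonded pair inside the exclusion zone: force pushes atom 1 toward -x
  cm0 <- matrix(0L, 2, 2)
  close <- rbind(c(0, 0, 0), c(0.5, 0, 0))
  en3 <- grp_energy(close, cm0, c("H", "H"))
  expect_gt(en3$energy, 0)
  expect_gt(en3$gradient[1, 1], 0)
})

test_that("the analytic gradient matches central finite differences", {
  set.seed(5)
  sp <- parse_smiles("CCO")
  n <- nrow(sp$graph)
  x <- matrix(rnorm(n * 3, sd = 1.5), n, 3)
  en <- grp_energy(x, sp$graph, sp$elements)
  h <- 1e-5
  fd <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    for (d in 1:3) {
      xp <- x; xp[i, d] <- xp[i, d] + h
      xm <- x; xm[i, d] <- xm[i, d] - h
      fd[i, d] <- (grp_energy(xp, sp$graph, sp$elements)$energy -
                   grp_energy(xm, sp$graph, sp$elements)$energy) / (2 * h)
    }
  }
  expect_lt(max(abs(fd - en$gradient)), 1e-6)
})

test_that("the GRP energy is translation and rotation invariant", {
  sp <- parse_smiles("CC")
  set.seed(8)
  x <- geometry_from_graph(sp)$coords + matrix(rnorm(24, sd = 0.4), 8, 3)
  e0 <- grp_energy(x, sp$graph, sp$elements)$energy
  # translation
  e_t <- grp_energy(sweep(x, 2, c(3, -2, 7), `+`), sp$graph, sp$elements)$energy
  expect_equal(e_t, e0, tolerance = 1e-12)
  # rotation about z
  th <- 0.83
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  e_r <- grp_energy(x %*% t(R), sp$graph, sp$elements)$energy
  expect_equal(e_r, e0, tolerance = 1e-9)
})

test_that("optimize_to_graph realises target connectivities or reports mismatch", {
  g <- ideal_ethane()
  cm <- connectivity_from_geometry(g)

  # identity target succeeds and preserves the CM
  res0 <- optimize_to_graph(g, cm)
  expect_true(res0$ok)
  expect_identical(connectivity_from_geometry(res0$geometry), cm)

  # deleting the C-C bond yields two methyl fragments
  tgt <- cm; tgt[1, 2] <- tgt[2, 1] <- 0L
  res1 <- optimize_to_graph(g, tgt)
  expect_true(res1$ok)
  frag <- split_molecules(connectivity_from_geometry(res1$geometry), res1$geometry)
  expect_setequal(vapply(frag, function(p) p$species$smiles, ""), c("[CH3]", "[CH3]"))

  # an adversarial refiner that collapses all atoms triggers the CM check
  collapse <- refiner_hook(function(gm) geometry(gm$elements, gm$coords * 0 + 1e-4))
  res2 <- optimize_to_graph(g, cm, refiner = collapse)
  expect_false(res2$ok)
  expect_match(res2$reason, "refiner")

  # a refiner that drops atoms is rejected outright
  dropper <- refiner_hook(function(gm) geometry(gm$elements[-1], gm$coords[-1, , drop = FALSE]))
  res3 <- optimize_to_graph(g, cm, refiner = dropper)
  expect_false(res3$ok)
})

test_that("random valid graphs round-trip through the GRP from perturbed starts", {
  set.seed(21)
  n_trials <- 0L
  n_ok <- 0L
  for (rep in 1:25) {
    g <- random_molecule_graph(sample(2:6, 1), extra_edge = sample(c(TRUE, FALSE), 1),
                               full_h = TRUE)
    if (is.null(g)) next
    sp <- tryCatch(canonical_species(g$cm, g$elements), error = function(e) NULL)
    if (is.null(sp)) next
    template <- tryCatch(geometry_from_graph(sp), error = function(e) NULL)
    if (is.null(template)) next
    start <- geometry(template$elements,
                      template$coords + matrix(rnorm(length(template$coords), sd = 0.25),
                                               ncol = 3))
    res <- optimize_to_graph(start, sp$graph)
    n_trials <- n_trials + 1L
    if (res$ok) {
      n_ok <- n_ok + 1L
      expect_identical(connectivity_from_geometry(res$geometry), sp$graph)
    }
  }
  expect_gte(n_trials, 15L)
  expect_gte(n_ok / n_trials, 0.95)
})
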