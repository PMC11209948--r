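test_that("move sampling follows the library weights", {
  m1 <- graph_move("make", 2, data.frame(i = 1, j = 2, delta = 1), weight = 1)
  m2 <- graph_move("break", 2, data.frame(i = 1, j = 2, delta = -1), weight = 0)
  lib0 <- move_library(list(m1, m2))
  set.seed(1)
  draws <- replicate(200, sample_move(lib0)$name)
  expect_true(all(draws == "make"))

  # equal weights: binomial CI at n = 1e4 (0.5 +/- 0.02 is ~4 sigma)
  m2$weight <- 1
  lib1 <- move_library(list(m1, m2))
  set.seed(2)
  f <- mean(replicate(1e4, sample_move(lib1)$name) == "make")
  expect_lt(abs(f - 0.5), 0.02)

  # 3:1 weights within 3 sigma of 0.75
  m1$weight <- 3
  lib3 <- move_library(list(m1, m2))
  set.seed(3)
  f3 <- mean(replicate(1e4, sample_move(lib3)$name) == "make")
  sigma <- sqrt(0.75 * 0.25 / 1e4)
  expect_lt(abs(f3 - 0.75), 3 * sigma)

  expect_error(move_library(list()), "crn_move")
})

test_that("apply_move edits bonds and enforces the validity checks", {
  eth <- parse_smiles("CC")
  brk <- default_move_library()$moves[[2]]
  mk <- default_move_library()$moves[[1]]

  res <- apply_move(eth$graph, eth$elements, brk, c(1, 2))
  expect_true(res$accepted)
  comp <- split_molecules(res$cm, elements = eth$elements)
  expect_setequal(vapply(comp, function(p) p$species$smiles, ""), c("[CH3]", "[CH3]"))
  # input CM untouched
  expect_identical(eth$graph[1, 2], 1L)

  # a fifth bond on a saturated carbon is rejected by the valence check
  ch4 <- parse_smiles("C")
  h <- parse_smiles("[H]")
  cm <- matrix(0L, 6, 6)
  cm[1:5, 1:5] <- ch4$graph
  el <- c(ch4$elements, "H")
  res_bad <- apply_move(cm, el, mk, c(1, 6))
  expect_false(res_bad$accepted)
  expect_match(res_bad$reason, "valence")

  # break then make restores the input exactly
  res1 <- apply_move(eth$graph, eth$elements, brk, c(1, 2))
  res2 <- apply_move(res1$cm, eth$elements, mk, c(1, 2))
  expect_identical(res2$cm, eth$graph)

  # delta preconditions: making an existing bond / breaking a non-bond
  expect_false(apply_move(eth$graph, eth$elements, mk, c(1, 2))$accepted)
  expect_false(apply_move(res1$cm, eth$elements, brk, c(1, 2))$accepted)

  # element whitelists
  cc_only <- graph_move("cc-break", 2, data.frame(i = 1, j = 2, delta = -1),
                        allowed_elements = list("C", "C"))
  expect_true(apply_move(eth$graph, eth$elements, cc_only, c(1, 2))$accepted)
  expect_false(apply_move(eth$graph, eth$elements, cc_only, c(1, 3))$accepted)
})

test_that("enumerate_applications is exhaustive and symmetry-deduplicated", {
  brk <- default_move_library()$moves[[2]]
  mk <- default_move_library()$moves[[1]]

  h2 <- parse_smiles("[H][H]")
  expect_length(enumerate_applications(h2$graph, h2$elements, brk), 1)

  eth <- parse_smiles("CC")
  expect_length(enumerate_applications(eth$graph, eth$elements, brk), 7)

  # methane self-bonding: every pair fails H max valence or C saturation
  ch4 <- parse_smiles("C")
  expect_length(enumerate_applications(ch4$graph, ch4$elements, mk), 0)
})

test_that("forbidden patterns veto candidate matrices", {
  # forbid any O-O bond
  oo <- parse_smiles("OO")
  pat <- forbidden_patterns(list(list(
    cm = matrix(c(0L, 1L, 1L, 0L), 2), elements = c("O", "O"))))
  mk <- default_move_library()$moves[[1]]
  # two hydroxyl radicals: making the O-O bond is vetoed
  sys <- assemble_system(chem_system(list("[OH]", "[OH]")))
  o_idx <- which(sys$geometry$elements == "O")
  res <- apply_move(sys$cm, sys$geometry$elements, mk, o_idx, forbidden = pat)
  expect_false(res$accepted)
  expect_match(res$reason, "forbidden")
  res_ok <- apply_move(sys$cm, sys$geometry$elements, mk, o_idx)
  expect_true(res_ok$accepted)
})

test_that("moves conserve atoms and always yield valid matrices", {
  set.seed(9)
  lib <- default_move_library()
  for (rep in 1:12) {
    g <- random_molecule_graph(sample(2:4, 1), full_h = TRUE)
    if (is.null(g)) next
    for (move in lib$moves) {
      apps <- enumerate_applications(g$cm, g$elements, move)
      if (!length(apps)) next
      asg <- apps[[sample.int(length(apps), 1)]]
      res <- apply_move(g$cm, g$elements, move, asg)
      expect_true(res$accepted)
      expect_identical(dim(res$cm), dim(g$cm))       # atoms never change
      expect_silent(crnkit:::check_cm(res$cm))
      deg <- rowSums(res$cm)
      vmax <- unclass(valence_constraints())[g$elements]
      expect_true(all(deg <= vmax))
    }
  }
})

test_that("move-library files round-trip", {
  lib <- default_move_library(weights = c("bond-formation" = 2.5))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_move_library(lib, path)
  lib2 <- read_move_library(path)
  expect_length(lib2$moves, length(lib$moves))
  for (i in seq_along(lib$moves)) {
    expect_identical(lib2$moves[[i]]$name, lib$moves[[i]]$name)
    expect_identical(lib2$moves[[i]]$deltas, lib$moves[[i]]$deltas)
    expect_equal(lib2$moves[[i]]$weight, lib$moves[[i]]$weight)
  }
})
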