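test_that("step scoring reproduces the canonical worked example", {
  ref <- parse_pathway("AB> ABC> ABCD")
  pred <- parse_pathway("AC> ABC> ABCD")
  sc <- score_pathway(pred, ref)
  expect_equal(sc$x, 1L)
  expect_equal(sc$y, 2L)
  expect_equal(sc$fraction, 0.5)
  # identical pathways score full marks
  full <- score_pathway(ref, ref)
  expect_equal(full$x, full$y)
})

test_that("homomeric copies are interchangeable in scoring", {
  ref <- parse_pathway("AA'> AA'+A''A'''> AA'A''A'''")
  # prediction forms the 'other' pairing of the four identical copies
  pred <- parse_pathway("AA'''> AA'''+A'A''> AA'A''A'''")
  sc <- score_pathway(pred, ref)
  expect_equal(sc$y, 2L)
  expect_equal(sc$x, 2L)  # both dimers match by class signature
  # exhaustive check: any relabelling of copies gives the same score
  sc2 <- score_pathway(parse_pathway("A'A''> AA'A''> AA'A''A'''"), ref)
  expect_equal(sc2$x, 1L)  # one dimer matches, the trimer does not
})

test_that("partial references bound the score but keep the full denominator", {
  ref <- parse_pathway("CG+DF> ACDFG> ABCDEFG")  # 7 chains, 3 listed steps
  expect_true(ref$partial)
  pred_events <- list(
    list(a = "C", b = "G"), list(a = "D", b = "F"),
    list(a = c("C", "G"), b = c("D", "F")),
    list(a = c("C", "D", "F", "G"), b = "A"),
    list(a = c("A", "C", "D", "F", "G"), b = "B"),
    list(a = c("A", "B", "C", "D", "F", "G"), b = "E"))
  pred <- assembly_pathway(LETTERS[1:7], events = pred_events)
  sc <- score_pathway(pred, ref)
  expect_equal(sc$y, 5L)   # N - 2, not the number of listed steps
  expect_equal(sc$x, 3L)   # CG, DF, ACDFG
  # scoring against alternatives takes the best one
  alts <- parse_reference_pathways("AA'> AA'F or AA'> AA'G or AA'+FG> AA'FG")
  pred2 <- parse_pathway("FG> AFG> AA'FG", chains = c("A", "A'", "F", "G"))
  sc2 <- score_pathway(pred2, alts)
  expect_equal(sc2$x, 1L)  # FG matches only in the third alternative
})

test_that("complex RMSD is permutation-minimised and symmetric", {
  toy <- get_toy("tetramer")
  s <- toy$structure
  expect_equal(complex_rmsd(s, s, toy$classes)$rmsd, 0, tolerance = 1e-12)
  # a rigid motion of the whole complex is removed by superposition
  rot <- rotation_axis_angle_test(c(1, 2, 3), 0.7)
  moved <- s
  xyz <- as.matrix(s[, c("x", "y", "z")]) %*% t(rot) +
    matrix(c(10, -5, 2), nrow(s), 3, byrow = TRUE)
  moved$x <- xyz[, 1]; moved$y <- xyz[, 2]; moved$z <- xyz[, 3]
  expect_equal(complex_rmsd(moved, s, toy$classes)$rmsd, 0,
               tolerance = 1e-6)
  # swapping the two copies of a class is absorbed by the assignment
  swapped <- s
  swapped$chain[s$chain == "A"] <- "C"
  swapped$chain[s$chain == "C"] <- "A"
  res <- complex_rmsd(swapped, s, toy$classes)
  expect_equal(res$rmsd, 0, tolerance = 1e-9)
  expect_equal(unname(res$assignment[["A"]]), "C")
  # symmetry of the metric
  jig <- s
  jig$x <- jig$x + rnorm(nrow(jig), sd = 0.3)
  expect_equal(complex_rmsd(jig, s, toy$classes)$rmsd,
               complex_rmsd(s, jig, toy$classes)$rmsd, tolerance = 1e-9)
})

test_that("largest assembled subcomplex finds the displaced chain", {
  toy <- get_toy("tetramer")
  s <- toy$structure
  expect_equal(largest_assembled(s, s, toy$classes), 4L)
  displaced <- s
  displaced$x[displaced$chain == "D"] <-
    displaced$x[displaced$chain == "D"] + 20
  expect_equal(largest_assembled(displaced, s, toy$classes), 3L)
  scattered <- s
  for (k in seq_along(structure_chains(s))) {
    ch <- structure_chains(s)[k]
    displ <- c(0, 40, 80, 120)[k]
    scattered$y[scattered$chain == ch] <-
      scattered$y[scattered$chain == ch] + displ +
      k * scattered$x[scattered$chain == ch] * 0.2
  }
  expect_equal(largest_assembled(scattered, s, toy$classes), 1L)
  # monotone non-increasing when the cutoff tightens
  expect_lte(largest_assembled(displaced, s, toy$classes, cutoff = 1.0),
             largest_assembled(displaced, s, toy$classes, cutoff = 4.0))
})

test_that("topology differences are reported edge by edge", {
  toy <- get_toy("pentamer")
  s <- toy$structure
  td <- topology_delta(s, s)
  expect_true(td$correct)
  expect_equal(nrow(td$missing) + nrow(td$extra), 0L)
  # move chain E next to chain A: one extra interface, DE lost
  moved <- s
  a_ctr <- colMeans(as.matrix(s[s$chain == "A", c("x", "y", "z")]))
  e_ctr <- colMeans(as.matrix(s[s$chain == "E", c("x", "y", "z")]))
  shift <- a_ctr - e_ctr + c(8, 0, 0)
  for (i in 1:3) {
    col <- c("x", "y", "z")[i]
    moved[[col]][moved$chain == "E"] <-
      moved[[col]][moved$chain == "E"] + shift[i]
  }
  td2 <- topology_delta(moved, s)
  expect_false(td2$correct)
  expect_true(nrow(td2$extra) >= 1 || nrow(td2$missing) >= 1)
  # brute-force graph diff oracle
  gm <- interface_graph(moved)
  gn <- interface_graph(s)
  expect_equal(nrow(td2$missing),
               sum(!paste(gn$chain_a, gn$chain_b) %in%
                     paste(gm$chain_a, gm$chain_b)))
  expect_equal(nrow(td2$extra),
               sum(!paste(gm$chain_a, gm$chain_b) %in%
                     paste(gn$chain_a, gn$chain_b)))
})

test_that("vote-fraction stratification handles both strata and emptiness", {
  res <- tibble::tibble(winner_fraction = c(1.0, 0.5),
                        x = c(1L, 0L), y = c(1L, 1L))
  got <- stratify_vote_accuracy(res)
  expect_equal(got$mean_accuracy, c(1.0, 0.0))
  all_hi <- stratify_vote_accuracy(
    tibble::tibble(winner_fraction = c(0.9, 0.8), x = c(2L, 1L), y = 2L))
  expect_equal(all_hi$mean_accuracy[1], 0.75)
  expect_true(is.na(all_hi$mean_accuracy[2]))
  # random fixture equals hand-computed partition means
  set.seed(13)
  rf <- tibble::tibble(winner_fraction = runif(50), x = sample(0:3, 50, TRUE),
                       y = 3L)
  got2 <- stratify_vote_accuracy(rf, threshold = 0.6)
  hi <- rf$winner_fraction > 0.6
  expect_equal(got2$mean_accuracy[1], mean(rf$x[hi] / 3))
  expect_equal(got2$mean_accuracy[2], mean(rf$x[!hi] / 3))
})
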