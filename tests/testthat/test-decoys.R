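test_that("decoy transform tables round-trip through TSV", {
  fx <- get_suite(1)$trimer
  path <- withr::local_tempfile(fileext = ".tsv")
  write_decoy_transforms(fx$decoys, path)
  back <- load_decoy_transforms(path)
  for (col in c("r11", "r33", "tx", "ty", "tz")) {
    expect_equal(back[[col]], fx$decoys[[col]], tolerance = 1e-6)
  }
  expect_equal(back$decoy_id, fx$decoys$decoy_id)
})

test_that("loader rejects reflections and duplicate ids", {
  d <- decoy_table("A", "B", 1L, list(transform_identity()))
  d$r11 <- -1  # turn the identity into a reflection
  path <- withr::local_tempfile(fileext = ".tsv")
  write_decoy_transforms(d, path)
  expect_error(load_decoy_transforms(path), "reflection")
  d2 <- decoy_table("A", "B", c(1L, 2L),
                    list(transform_identity(), transform_identity()))
  d2$decoy_id[2] <- 1L
  expect_error(
    write_decoy_transforms(d2, withr::local_tempfile(fileext = ".tsv")),
    "duplicate")
})

test_that("ligand RMSD: identity pose is 0, pure shift equals the shift", {
  toy <- get_toy("trimer")$structure
  d <- decoy_table(
    "A", "B", 1:3,
    list(transform_identity(),
         rigid_transform(diag(3), c(5, 0, 0)),
         rigid_transform(diag(3), c(0, 3, 4))))
  r <- ligand_rmsd(d, toy)$rmsd
  expect_equal(r, c(0, 5, 5), tolerance = 1e-12)
})

test_that("ligand RMSD of a rotated pose matches direct computation", {
  toy <- get_toy("trimer")$structure
  set.seed(7)
  axis <- rnorm(3)
  rot <- rotation_axis_angle_test(axis, 0.3)
  tr <- rigid_transform(rot, c(1, -2, 0.5))
  d <- decoy_table("A", "B", 1L, list(tr))
  got <- ligand_rmsd(d, toy)$rmsd
  ca <- toy[toy$chain == "B" & toy$atom == "CA", c("x", "y", "z")]
  ca <- as.matrix(ca)
  posed <- ca %*% t(rot) + matrix(c(1, -2, 0.5), nrow(ca), 3, byrow = TRUE)
  expect_equal(got, sqrt(mean(rowSums((posed - ca)^2))))
})

test_that("greedy leader clustering matches a reference implementation", {
  fx <- get_suite(1)$trimer
  rk <- rank_and_z(fx$scores, "energy")
  got <- cluster_decoys(fx$decoys, rk, fx$structure, cutoff = 10)
  # reference: per pair, visit in rank order, keep if > cutoff from all kept
  key <- paste(fx$decoys$receptor, fx$decoys$ligand)
  want_n <- 0L
  for (pair in unique(key)) {
    sub <- fx$decoys[key == pair, ]
    r <- dplyr::inner_join(sub, rk, by = c("receptor", "ligand", "decoy_id"))
    sub <- sub[order(r$rank), ]
    rmat <- ligand_rmsd_matrix(sub, fx$structure)
    kept <- integer()
    for (i in seq_len(nrow(sub))) {
      if (!length(kept) || all(rmat[i, kept] > 10)) kept <- c(kept, i)
    }
    want_n <- want_n + length(kept)
  }
  expect_equal(nrow(got), want_n)
  # representatives are mutually separated by more than the cutoff
  gk <- paste(got$receptor, got$ligand)
  for (pair in unique(gk)) {
    sub <- got[gk == pair, ]
    if (nrow(sub) < 2) next
    rmat <- ligand_rmsd_matrix(sub, fx$structure)
    expect_true(all(rmat[upper.tri(rmat)] > 10))
  }
  # decoys all far apart -> nothing clustered
  all_kept <- cluster_decoys(fx$decoys, rk, fx$structure, cutoff = 1e-6)
  expect_equal(nrow(all_kept), nrow(fx$decoys))
})

test_that("ranks equal 1 + number of strictly better scores", {
  set.seed(42)
  n <- 1000
  sc <- tibble::tibble(receptor = "A", ligand = "B", decoy_id = 1:n,
                       e = rnorm(n))
  rk <- rank_and_z(sc, "e")
  expect_equal(sort(rk$rank), 1:n)
  idx <- sample(n, 50)
  expect_equal(rk$rank[idx],
               vapply(idx, function(i) 1L + sum(sc$e < sc$e[i]), 1L))
  # higher-is-better orientation flips the ordering
  rk2 <- rank_and_z(sc, "e", lower_is_better = FALSE)
  expect_equal(rk2$rank, n + 1L - rk$rank)
  # more favourable is always more negative z, in both orientations
  expect_lt(rk$z[which.min(rk$rank)], 0)
  expect_lt(rk2$z[which.min(rk2$rank)], 0)
  # z are standardised
  expect_equal(mean(rk$z), 0, tolerance = 1e-12)
  expect_equal(sd(rk$z), 1, tolerance = 1e-12)
})

test_that("rank edge cases: n = 1, zero variance, exact ties", {
  one <- tibble::tibble(receptor = "A", ligand = "B", decoy_id = 1L, e = 5)
  rk <- rank_and_z(one, "e")
  expect_equal(rk$rank, 1L)
  expect_equal(rk$z, 0)
  flat <- tibble::tibble(receptor = "A", ligand = "B", decoy_id = 1:3, e = 2)
  expect_warning(rkf <- rank_and_z(flat, "e"), "zero score variance")
  expect_equal(rkf$rank, 1:3)  # ties resolved by decoy id
  expect_equal(rkf$z, rep(0, 3))
})

test_that("sum of ranks equals brute-force summation and re-ranking", {
  set.seed(11)
  n <- 100
  base <- tibble::tibble(receptor = "A", ligand = "B", decoy_id = 1:n)
  rankings <- lapply(1:8, function(k) {
    sc <- dplyr::mutate(base, e = rnorm(n))
    rank_and_z(sc, "e")
  })
  got <- sum_of_ranks(rankings)
  sums <- Reduce(`+`, lapply(rankings, function(r) {
    r$rank[match(base$decoy_id, r$decoy_id)]
  }))
  expect_equal(got$value, as.numeric(sums))
  expect_equal(got$rank, rank_and_z(
    dplyr::mutate(base, s = as.numeric(sums)), "s")$rank)
  # single ranking is the identity
  single <- sum_of_ranks(rankings[1])
  expect_equal(single$rank, rankings[[1]]$rank)
  # two reversed rankings tie everywhere; ties resolved by decoy id
  rev2 <- list(rankings[[1]],
               rank_and_z(dplyr::mutate(base, e = -rankings[[1]]$value), "e"))
  expect_warning(tied <- sum_of_ranks(rev2), "zero score variance")
  expect_equal(tied$rank, 1:n)
})

test_that("pose probabilities follow the Boltzmann form", {
  expect_equal(pose_probabilities(c(1, 1)), c(0.5, 0.5))
  expect_equal(pose_probabilities(c(0, log(2))), c(2 / 3, 1 / 3))
  set.seed(3)
  dg <- rnorm(100, sd = 5)
  p <- pose_probabilities(dg, kT = 1.5)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # ordering of probabilities is the reverse ordering of energies,
  # i.e. rank(S_i) < rank(S_j) <=> p_i > p_j
  expect_equal(order(p, decreasing = TRUE), order(dg))
  # invariance under a uniform shift
  expect_equal(pose_probabilities(dg + 123, kT = 1.5), p)
  # extreme energies stay finite (max-shift stability)
  expect_false(anyNA(pose_probabilities(c(0, 5000), kT = 1)))
  expect_error(pose_probabilities(numeric(0)), "empty")
})

test_that("score tables round-trip with orientation pragmas", {
  sc <- tibble::tibble(receptor = "A", ligand = "B", decoy_id = 1:3,
                       energy = c(-1.5, 0.25, 3), shape = c(9, 7, 8))
  attr(sc, "orientation") <- c(energy = TRUE, shape = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_score_table(sc, path)
  back <- read_score_table(path)
  expect_equal(back$energy, sc$energy)
  expect_equal(attr(back, "orientation"), c(energy = TRUE, shape = FALSE))
  # orientation is honoured by ranking
  rk <- rank_and_z(back, "shape")
  expect_equal(rk$rank[rk$decoy_id == 1], 1L)  # highest shape score wins
})
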