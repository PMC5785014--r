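test_that("model trees enforce spanning-tree invariants", {
  chains <- c("A", "B", "C")
  ok <- data.frame(receptor = c("A", "B"), ligand = c("B", "C"),
                   decoy_id = 1L)
  expect_silent(model_tree(chains, ok))
  expect_error(model_tree(chains, ok[1, ]), "needs 2 edges")
  cyc <- data.frame(receptor = c("A", "B", "A"), ligand = c("B", "C", "C"),
                    decoy_id = 1L)
  expect_error(model_tree(c("A", "B", "C", "D"), cyc), "cycle")
})

test_that("random models are uniform over tree shapes and seeded", {
  tri <- decoy_table(rep(c("A", "A", "B"), each = 2),
                     rep(c("B", "C", "C"), each = 2),
                     rep(1:2, 3),
                     replicate(6, transform_identity(), simplify = FALSE))
  set.seed(123)
  shapes <- replicate(3000, {
    m <- random_model(c("A", "B", "C"), tri)
    paste(sort(paste(m$edges$receptor, m$edges$ligand)), collapse = ";")
  })
  tab <- table(shapes)
  expect_length(tab, 3L)
  # each of the 3 shapes near 1/3 (3 sigma of a binomial)
  expect_true(all(abs(tab / 3000 - 1 / 3) < 3 * sqrt(1 / 3 * 2 / 3 / 3000)))
  set.seed(99)
  m1 <- random_model(c("A", "B", "C"), tri)
  set.seed(99)
  m2 <- random_model(c("A", "B", "C"), tri)
  expect_identical(m1, m2)
})

test_that("realizing native-pose models reproduces the native structure", {
  fx <- get_suite(1)$pentamer
  native_edges <- data.frame(receptor = fx$design$a, ligand = fx$design$b,
                             decoy_id = 1L)
  sw <- native_edges$receptor > native_edges$ligand
  tmp <- native_edges$receptor[sw]
  native_edges$receptor[sw] <- native_edges$ligand[sw]
  native_edges$ligand[sw] <- tmp
  m <- model_tree(structure_chains(fx$structure), native_edges)
  s <- realize(m, fx$structure, fx$decoys)
  expect_equal(complex_rmsd(s, fx$structure, fx$classes)$rmsd, 0,
               tolerance = 1e-9)
  # single-edge model: ligand placement equals direct transform application
  pair <- fx$decoys[fx$decoys$receptor == "A" & fx$decoys$ligand == "B" &
                      fx$decoys$decoy_id == 3L, ]
  m1 <- model_tree(c("A", "B"), pair[c("receptor", "ligand", "decoy_id")])
  s1 <- realize(m1, fx$structure, fx$decoys)
  lig <- fx$structure[fx$structure$chain == "B", ]
  tr <- rigid_transform(matrix(as.numeric(
    pair[, c("r11", "r12", "r13", "r21", "r22", "r23", "r31", "r32",
             "r33")]), 3, 3, byrow = TRUE),
    as.numeric(pair[, c("tx", "ty", "tz")]))
  want <- transform_apply(tr, as.matrix(lig[, c("x", "y", "z")]))
  expect_equal(as.matrix(s1[s1$chain == "B", c("x", "y", "z")]), want,
               ignore_attr = TRUE)
})

test_that("clash counting matches brute force and the 3 A boundary", {
  s <- bead_structure(c("A", "B"), rbind(c(0, 0, 0), c(2.99, 0, 0)))
  expect_equal(clash_count(s, 3.0), 1L)
  s2 <- bead_structure(c("A", "B"), rbind(c(0, 0, 0), c(3.0, 0, 0)))
  expect_equal(clash_count(s2, 3.0), 0L)
  # brute-force oracle on an overlapped dimer
  set.seed(21)
  xyz <- rbind(matrix(rnorm(60, sd = 4), ncol = 3),
               matrix(rnorm(60, sd = 4), ncol = 3))
  s3 <- bead_structure(rep(c("A", "B"), each = 20), xyz)
  brute <- sum(as.matrix(dist(xyz))[1:20, 21:40] < 3.0)
  expect_equal(clash_count(s3, 3.0), brute)
})

test_that("fitness rewards native packing and is locally continuous", {
  toy <- get_toy("trimer")$structure
  apart <- toy
  apart$x[apart$chain == "B"] <- apart$x[apart$chain == "B"] + 500
  apart$x[apart$chain == "C"] <- apart$x[apart$chain == "C"] + 1000
  expect_equal(default_fitness(apart), 0)
  expect_lt(default_fitness(toy), default_fitness(apart))
  bumped <- toy
  bumped$x <- bumped$x + 1e-6
  expect_lt(abs(default_fitness(bumped) - default_fitness(toy)), 1e-3)
})

test_that("mutation preserves tree invariants and deletes edges uniformly", {
  fx <- get_suite(1)$tetramer
  m <- model_tree(c("A", "B", "C", "D"),
                  data.frame(receptor = c("A", "C", "A"),
                             ligand = c("B", "D", "C"), decoy_id = 1L))
  set.seed(31)
  deleted <- character()
  for (i in 1:2000) {
    mt <- mutate_model(m, fx$decoys)
    expect_silent(validate_model_tree(mt, fx$decoys))
    gone <- setdiff(paste(m$edges$receptor, m$edges$ligand,
                          m$edges$decoy_id),
                    paste(mt$edges$receptor, mt$edges$ligand,
                          mt$edges$decoy_id))
    if (length(gone)) deleted <- c(deleted, gone[1])
  }
  tab <- table(substr(deleted, 1, 3))
  expect_true(all(abs(tab / length(deleted) - 1 / 3) <
                    3 * sqrt(1 / 3 * 2 / 3 / length(deleted))))
})

test_that("model clustering is leader clustering in fitness order", {
  fx <- get_suite(1)$trimer
  edges <- lapply(c(1L, 2L, 20L), function(id) {
    data.frame(receptor = c("A", "B"), ligand = c("B", "C"),
               decoy_id = c(1L, id))
  })
  models <- lapply(edges, function(e) model_tree(c("A", "B", "C"), e))
  cl <- cluster_models(models, c(1, 2, 3), fx$structure, fx$decoys,
                       cutoff = 10)
  # models 1 and 2 differ by a near-native pose -> one representative
  # (the better-fitness one) plus the far-decoy model
  expect_equal(sort(cl$representatives), c(1L, 3L))
  expect_equal(cl$absorbed, 2L)
  cl2 <- cluster_models(models, c(1, 2, 3), fx$structure, fx$decoys,
                        cutoff = 1e-9)
  expect_equal(sort(cl2$representatives), c(1L, 2L, 3L))
})

test_that("GA defaults echo the published protocol", {
  cfg <- ga_config()
  expect_equal(cfg$population, 200L)
  expect_equal(cfg$mutations, 400L)
  expect_equal(cfg$clash_distance, 3.0)
  expect_equal(cfg$clash_max, 200L)
  expect_equal(cfg$generations, 2000L)
  expect_equal(cfg$extension, 1000L)
  expect_equal(cfg$cluster_cutoff, 10.0)
})

test_that("GA runs are seeded, monotone, and within population bounds", {
  fx <- get_suite(1)$trimer
  cfg <- ga_config_desk(population = 8L, mutations = 16L, generations = 12L,
                        extension = 4L, window = 4L, seed = 77L)
  run <- run_ga(cfg, structure_chains(fx$structure), fx$structure, fx$decoys)
  tr <- tidy(run)
  expect_true(all(diff(tr$best_fitness) <= 1e-12))  # elitism
  expect_true(all(tr$population <= 8L))
  for (g in run$generations) {
    for (m in g$models) {
      expect_silent(validate_model_tree(
        model_tree(run$chains, m), fx$decoys))
    }
  }
  run2 <- run_ga(cfg, structure_chains(fx$structure), fx$structure,
                 fx$decoys)
  expect_identical(run, run2)  # bit-identical at a fixed seed
})

test_that("GA run records round-trip through JSON", {
  fx <- get_suite(1)$trimer
  cfg <- ga_config_desk(population = 5L, mutations = 10L, generations = 4L,
                        extension = 0L, window = 2L, seed = 5L)
  run <- run_ga(cfg, structure_chains(fx$structure), fx$structure, fx$decoys)
  path <- withr::local_tempfile(fileext = ".json")
  ga_run_write(run, path)
  back <- ga_run_read(path)
  expect_equal(back$chains, run$chains)
  expect_equal(back$final_generation, run$final_generation)
  expect_equal(back$generations[[4]]$fitness, run$generations[[4]]$fitness)
  expect_equal(back$generations[[4]]$models, run$generations[[4]]$models,
               ignore_attr = TRUE)
  g <- glance(run)
  expect_equal(g$generations, 4L)
})
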