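test_that("the benchmark suite spans 3 to 6 chains with valid designs", {
  specs <- benchmark_specs()
  expect_gte(length(specs), 4L)
  sizes <- vapply(specs, function(sp) length(sp$chains), integer(1))
  expect_equal(range(sizes), c(3L, 6L))
  for (nm in names(specs)) {
    toy <- get_toy(nm)
    # builder verifies contact counts and clash freedom internally;
    # re-assert the headline invariants here
    expect_equal(clash_count(toy$structure, 3.0), 0L)
    expect_length(pathway_intermediates(toy$planted),
                  length(specs[[nm]]$chains) - 2L)
    # chains of one class share a sequence
    seqs <- chain_sequences(toy$structure)
    for (cl in unique(toy$classes$class)) {
      members <- toy$classes$chain[toy$classes$class == cl]
      expect_length(unique(seqs[members]), 1L)
    }
  }
})

test_that("designed contact counts are realised exactly", {
  toy <- get_toy("pentamer")
  for (k in seq_len(nrow(toy$design))) {
    got <- nrow(contact_residue_pairs(toy$structure, toy$design$a[k],
                                      toy$design$b[k], 5.0))
    expect_equal(got, toy$design$contacts[k])
  }
})

test_that("planted pathways equal the greedy transition oracle on counts", {
  # independent oracle: exhaustive greedy on the design table
  for (nm in c("trimer", "ring_apex")) {
    toy <- get_toy(nm)
    d <- toy$design
    strength <- function(ca, cb) {
      sum(d$contacts[(d$a %in% ca & d$b %in% cb) |
                       (d$a %in% cb & d$b %in% ca)])
    }
    comp <- as.list(chain_sort(unique(c(d$a, d$b))))
    inter <- list()
    while (length(comp) > 1) {
      best <- NULL
      for (i in seq_along(comp)) {
        for (j in seq_along(comp)) {
          if (j <= i) next
          st <- strength(comp[[i]], comp[[j]])
          if (st == 0) next
          key <- paste(sort(c(paste(comp[[i]], collapse = ""),
                              paste(comp[[j]], collapse = ""))),
                       collapse = " ")
          if (is.null(best) || st > best$st ||
              (st == best$st && key < best$key)) {
            best <- list(i = i, j = j, st = st, key = key)
          }
        }
      }
      merged <- chain_sort(c(comp[[best$i]], comp[[best$j]]))
      comp <- c(comp[-c(best$i, best$j)], list(merged))
      if (length(comp) > 1) inter[[length(inter) + 1]] <- merged
    }
    expect_equal(pathway_intermediates(toy$planted), inter)
  }
})

test_that("noise-free decoys include an exact native pose, ranked by strength", {
  fx <- get_suite(1)$trimer
  rmsds <- ligand_rmsd(fx$decoys, fx$structure)
  natives <- rmsds[rmsds$decoy_id == 1L, ]
  expect_true(all(natives$rmsd < 1e-9))
  rk <- rank_and_z(fx$scores, "energy")
  nat <- rk[rk$decoy_id == 1L, ]
  # the strong designed interface (A-B, 16 contacts) out-scores the whole
  # background; the weaker one (B-C, 10) is out-scored by part of it, so
  # native ranks order by designed interface strength
  expect_equal(nat$rank[nat$receptor == "A"], 1L)
  expect_lt(nat$rank[nat$receptor == "A"], nat$rank[nat$receptor == "B"])
})

test_that("the pure-RMSD score model ranks decoys by ligand RMSD", {
  toy <- get_toy("trimer")
  set.seed(202)
  dec <- generate_decoys(toy, synthetic_decoy_params(
    sigma_score = 0, score_model = "rmsd"))
  rk <- rank_and_z(dec$scores, "rmsd")
  rmsds <- ligand_rmsd(dec$decoys, toy$structure)
  joined <- dplyr::inner_join(rk, rmsds,
                              by = c("receptor", "ligand", "decoy_id"))
  for (pair in unique(paste(joined$receptor, joined$ligand))) {
    sub <- joined[paste(joined$receptor, joined$ligand) == pair, ]
    expect_equal(order(sub$rank), order(sub$rmsd, sub$decoy_id))
  }
})

test_that("score noise degrades the score-RMSD rank agreement", {
  toy <- get_toy("trimer")
  cors <- sapply(c(0, 2, 8), function(sg) {
    vals <- sapply(1:10, function(s) {
      set.seed(1000 + s)
      dec <- generate_decoys(toy, synthetic_decoy_params(sigma_score = sg))
      sub <- dplyr::inner_join(
        dec$scores, ligand_rmsd(dec$decoys, toy$structure),
        by = c("receptor", "ligand", "decoy_id"))
      sub <- sub[sub$receptor == "A" & sub$ligand == "B", ]
      cor(sub$energy, sub$rmsd, method = "spearman")
    })
    mean(vals)
  })
  expect_gt(cors[1], cors[3])  # monotone trend over the noise levels
})

test_that("benchmark files are lossless and byte-identical for a seed", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_benchmark(get_suite(3), dir1)
  suite2 <- generate_benchmark(seed = 3, params = benchmark_params(0))
  write_benchmark(suite2, dir2)
  files <- list.files(dir1)
  expect_true(length(files) >= 4 * 3 + 1)
  for (f in files) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  # round trip through the package readers
  s <- read_structure(file.path(dir1, "trimer.pdb"))
  expect_equal(structure_chains(s), c("A", "B", "C"))
  d <- load_decoy_transforms(file.path(dir1, "trimer_decoys.tsv"))
  expect_equal(nrow(d), nrow(get_suite(3)$trimer$decoys))
  sc <- read_score_table(file.path(dir1, "trimer_scores.tsv"))
  expect_equal(sc$energy, get_suite(3)$trimer$scores$energy,
               tolerance = 1e-6)
  refs <- read_reference_pathways(file.path(dir1, "reference_pathways.tsv"))
  expect_equal(nrow(refs), length(suite2))
})
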