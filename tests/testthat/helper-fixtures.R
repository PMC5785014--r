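# Shared fixtures, built in code.

# minimal atom-table constructor: one CA bead per row of `xyz`
bead_structure <- function(chains, xyz, res_name = "ALA") {
  xyz <- as.matrix(xyz)
  new_structure(tibble::tibble(
    chain = chains,
    serial = seq_len(nrow(xyz)),
    atom = "CA",
    element = "C",
    res_name = res_name,
    res_id = stats::ave(seq_along(chains), chains, FUN = seq_along),
    ins = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  ))
}

# cache the deterministic toy structures once per test run
toy_cache <- new.env(parent = emptyenv())
get_toy <- function(name) {
  if (is.null(toy_cache[[name]])) {
    toy_cache[[name]] <- build_toy_complex(benchmark_specs()[[name]])
  }
  toy_cache[[name]]
}

# benchmark fixture (decoys + scores) under the package's study conditions
suite_cache <- new.env(parent = emptyenv())
get_suite <- function(seed, sigma_score = 0) {
  key <- paste(seed, sigma_score)
  if (is.null(suite_cache[[key]])) {
    suite_cache[[key]] <- generate_benchmark(
      seed = seed, params = benchmark_params(sigma_score))
  }
  suite_cache[[key]]
}

# the documented study conditions of the synthetic benchmark
benchmark_params <- function(sigma_score = 0) {
  synthetic_decoy_params(sigma_score = sigma_score)
}

run_benchmark_fixture <- function(fixture, seed) {
  fixture_ga_predictions(fixture, ga_config_desk(seed = seed))
}

# reference corpus shipped with the package
reference_corpus <- function() {
  read_reference_pathways(system.file("extdata",
                                      "complex_assembly_pathways.tsv",
                                      package = "assemblypath"))
}

expect_pathway <- function(pathway, string) {
  expect_equal(format_pathway(pathway), string)
}

# random proper rotation from a uniform quaternion (test-local oracle)
random_rotation_test <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c + a * d), 2 * (b * d - a * c),
           2 * (b * c - a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d + a * b),
           2 * (b * d + a * c), 2 * (c * d - a * b), a^2 - b^2 - c^2 + d^2),
         3, 3)
}

# Rodrigues rotation (test-local oracle, independent of the package)
rotation_axis_angle_test <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  k <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * k + (1 - cos(angle)) * (k %*% k)
}

load_row_transform <- function(d, i) {
  rigid_transform(matrix(as.numeric(d[i, c("r11", "r12", "r13", "r21", "r22",
                                           "r23", "r31", "r32", "r33")]),
                         3, 3, byrow = TRUE),
                  as.numeric(d[i, c("tx", "ty", "tz")]))
}

# all-pairs ligand-RMSD matrix between the poses of one pair
ligand_rmsd_matrix <- function(decoys, native) {
  coords <- lapply(seq_len(nrow(decoys)), function(i) {
    ca <- native[native$chain == decoys$ligand[i] & native$atom == "CA",
                 c("x", "y", "z")]
    transform_apply(load_row_transform(decoys, i), as.matrix(ca))
  })
  n <- length(coords)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- sqrt(mean(rowSums((coords[[i]] - coords[[j]])^2)))
    }
  }
  m
}
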