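test_that("published-style pathway strings parse correctly", {
  p <- parse_pathway("BG> BGP")
  expect_equal(p$n_chains, 3L)
  expect_length(pathway_intermediates(p), 1L)
  expect_false(p$partial)

  # unicode primes and simultaneous dimers
  p2 <- parse_pathway("EE′+II′> EE′II′")
  expect_equal(p2$n_chains, 4L)
  expect_equal(vapply(pathway_intermediates(p2), paste, "", collapse = ""),
               c("EE'", "II'"))
  expect_false(p2$partial)

  # superscript copy numbers
  p3 <- parse_pathway("B^1^B^2^> B^1^B^2^B^3^> AB^1^B^2^B^3^")
  expect_equal(p3$chains, c("A", "B1", "B2", "B3"))

  # double primes count 4 intermediates on a 6-chain pathway
  p4 <- parse_pathway(
    "DD'> DD'D''> ADD'D''> AA'DD'D''> AA'A''DD'D''")
  expect_length(pathway_intermediates(p4), 4L)
  expect_false(p4$partial)
})

test_that("non-monotone and malformed pathways are rejected", {
  expect_error(parse_pathway("AB> AC> ABC"), "not a union")
  expect_error(parse_pathway("AB> AB+AC> ABC"), "twice")
  expect_error(parse_pathway("A*> AB"), "malformed")
})

test_that("partial pathways are flagged and keep only listed subcomplexes", {
  p <- parse_pathway("CG+DF> ACDFG> ABCDEFG")
  expect_true(p$partial)
  expect_equal(p$n_chains, 7L)
  expect_length(pathway_intermediates(p), 3L)
  # reference alternatives: universe is the union over alternatives
  alts <- parse_reference_pathways("AA'> AA'F or AA'> AA'G or AA'+FG> AA'FG")
  expect_length(alts, 3L)
  expect_equal(alts[[1]]$n_chains, 4L)
  expect_true(alts[[1]]$partial)     # stops before the complete complex
  expect_false(alts[[3]]$partial)
})

test_that("formatting is canonical and parse/format round-trips", {
  p <- parse_pathway("AA'> AA'C> AA'CC'")
  expect_pathway(p, "AA'> AA'C> AA'CC'")
  # random complete pathways round-trip
  set.seed(5)
  for (i in 1:100) {
    n <- sample(3:7, 1)
    chains <- LETTERS[1:n]
    comp <- as.list(chains)
    events <- list()
    while (length(comp) > 1) {
      ij <- sample(length(comp), 2)
      events[[length(events) + 1]] <- list(a = comp[[ij[1]]],
                                           b = comp[[ij[2]]])
      comp <- c(comp[-ij], list(c(comp[[ij[1]]], comp[[ij[2]]])))
    }
    p <- assembly_pathway(chains, events = events)
    expect_true(pathway_equal(p, parse_pathway(format_pathway(p))))
    expect_length(pathway_intermediates(p), n - 2L)
  }
})

test_that("the shipped reference corpus parses and round-trips", {
  refs <- reference_corpus()
  expect_equal(nrow(refs), 21L)
  for (k in seq_len(nrow(refs))) {
    for (alt in refs$pathways[[k]]) {
      expect_equal(alt$n_chains, refs$n_chains[k])
      expect_true(pathway_equal(
        alt, parse_pathway(format_pathway(alt), chains = alt$chains)))
    }
  }
})

test_that("pathway extraction follows rank order with Z tie-breaks", {
  # the canonical 3-chain example: A-B decoy rank 1, B-C decoy rank 125
  ranking <- tibble::tibble(
    receptor = c("A", "B"), ligand = c("B", "C"), decoy_id = c(7L, 3L),
    score = "s", value = c(-50, -1), rank = c(1L, 125L), z = c(-4, -0.1))
  m <- model_tree(c("A", "B", "C"),
                  data.frame(receptor = c("A", "B"), ligand = c("B", "C"),
                             decoy_id = c(7L, 3L)))
  expect_pathway(extract_pathway(m, ranking), "AB> ABC")

  # 2-chain model: single event, no intermediates
  m2 <- model_tree(c("A", "B"),
                   data.frame(receptor = "A", ligand = "B", decoy_id = 7L))
  p2 <- extract_pathway(m2, ranking[1, ])
  expect_length(pathway_intermediates(p2), 0L)

  # missing rank errors
  expect_error(extract_pathway(m, ranking[1, ]), "missing rank")
})

test_that("extraction equals a naive component-tracking oracle", {
  set.seed(9)
  chains <- LETTERS[1:5]
  for (rep in 1:25) {
    # random spanning tree over 5 chains with random ranks/z
    edges <- data.frame(receptor = character(), ligand = character(),
                        decoy_id = integer())
    comp <- as.list(chains)
    while (length(comp) > 1) {
      ij <- sample(length(comp), 2)
      a <- sample(comp[[ij[1]]], 1); b <- sample(comp[[ij[2]]], 1)
      edges <- rbind(edges, data.frame(receptor = min(a, b),
                                       ligand = max(a, b),
                                       decoy_id = sample(100, 1)))
      comp <- c(comp[-ij], list(c(comp[[ij[1]]], comp[[ij[2]]])))
    }
    ranking <- tibble::tibble(
      receptor = edges$receptor, ligand = edges$ligand,
      decoy_id = edges$decoy_id, score = "s", value = 0,
      rank = sample(200, nrow(edges)), z = rnorm(nrow(edges)))
    got <- extract_pathway(model_tree(chains, edges), ranking)
    # naive oracle: sort edges by rank, track components in a list
    ord <- order(ranking$rank, ranking$z)
    comp <- as.list(chains)
    inter <- list()
    for (k in ord) {
      ia <- which(vapply(comp, function(x) edges$receptor[k] %in% x, TRUE))
      ib <- which(vapply(comp, function(x) edges$ligand[k] %in% x, TRUE))
      merged <- chain_sort(c(comp[[ia]], comp[[ib]]))
      comp <- c(comp[-c(ia, ib)], list(merged))
      if (length(merged) < length(chains)) {
        inter[[length(inter) + 1]] <- merged
      }
    }
    expect_equal(pathway_intermediates(got), inter)
    expect_length(pathway_intermediates(got), 3L)
  }
})

test_that("extraction is invariant to edge storage order", {
  fx <- get_suite(1)$tetramer
  rk <- rank_and_z(fx$scores, "energy")
  edges <- data.frame(receptor = c("A", "C", "A"), ligand = c("B", "D", "C"),
                      decoy_id = 1L)
  m1 <- model_tree(c("A", "B", "C", "D"), edges)
  m2 <- model_tree(c("A", "B", "C", "D"), edges[c(3, 1, 2), ])
  expect_true(pathway_equal(extract_pathway(m1, rk),
                            extract_pathway(m2, rk)))
})
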