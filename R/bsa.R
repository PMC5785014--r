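#' Buried surface area of a chain pair
#'
#' BSA of chains A and B is the surface lost on association:
#' `BSA_AB = SASA_A + SASA_B - SASA_AB`, with SASA over the isolated chains
#' and the two-chain assembly at their native coordinates. Larger buried
#' area is the classic proxy for a more favourable association, hence an
#' earlier assembly step.
#'
#' @param structure A `cpx_structure`.
#' @param a,b Distinct chain labels.
#' @param options [sasa_options()].
#' @return One-row tibble with `chain_a`, `chain_b` (canonical order) and
#'   `area` (Angstrom^2).
#' @export
pairwise_bsa <- function(structure, a, b, options = sasa_options()) {
  if (identical(a, b)) stop("chain labels must differ")
  tr <- transition_bsa(structure, a, b, options)
  ab <- chain_sort(c(a, b))
  tibble::tibble(chain_a = ab[1], chain_b = ab[2], area = tr$area)
}

#' BSA of a merge between two subcomplexes
#'
#' For disjoint chain sets P and Q,
#' `BSA_{P:Q} = SASA_P + SASA_Q - SASA_{P united with Q}` over the
#' native-coordinate subassemblies.
#'
#' @param structure A `cpx_structure`.
#' @param part_a,part_b Disjoint chain-label sets present in `structure`.
#' @param options [sasa_options()].
#' @param cache Optional environment memoising SASA by chain subset.
#' @return One-row tibble with `part_a`, `part_b` (label strings), `area`.
#' @export
transition_bsa <- function(structure, part_a, part_b,
                           options = sasa_options(), cache = NULL) {
  part_a <- chain_sort(unique(part_a))
  part_b <- chain_sort(unique(part_b))
  if (length(intersect(part_a, part_b))) stop("overlapping parts")
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  area <- subset_sasa(structure, part_a, options, cache) +
    subset_sasa(structure, part_b, options, cache) -
    subset_sasa(structure, c(part_a, part_b), options, cache)
  tibble::tibble(part_a = component_key(part_a),
                 part_b = component_key(part_b), area = area)
}

subset_sasa <- function(structure, chains, options, cache) {
  key <- component_key(chain_sort(chains))
  if (!is.null(cache[[key]])) return(cache[[key]])
  val <- compute_sasa(subset_structure(structure, chains), options)$total
  cache[[key]] <- val
  val
}

#' BSA of every contacting chain pair
#'
#' @param structure A `cpx_structure`.
#' @param options [sasa_options()].
#' @param cutoff,min_pairs Interface criterion passed to [interface_graph()].
#' @return Tibble `chain_a`, `chain_b`, `n_pairs`, `strong`, `area`, sorted
#'   by decreasing area.
#' @export
bsa_edges <- function(structure, options = sasa_options(), cutoff = 5.0,
                      min_pairs = 1L) {
  g <- interface_graph(structure, cutoff = cutoff, min_pairs = min_pairs)
  if (nrow(g) == 0L) return(dplyr::mutate(g, area = numeric(0)))
  cache <- new.env(parent = emptyenv())
  g$area <- vapply(seq_len(nrow(g)), function(k) {
    transition_bsa(structure, g$chain_a[k], g$chain_b[k], options, cache)$area
  }, numeric(1))
  dplyr::arrange(g, dplyr::desc(.data$area), .data$chain_a, .data$chain_b)
}

#' Pairwise-BSA assembly-order prediction
#'
#' Contacting pairs are sorted in descending buried surface area and greedily
#' assembled into a spanning tree (an edge is skipped when it would close a
#' cycle) until N - 1 edges are accepted; the accepted-edge sequence is the
#' predicted merge order. Equal areas are broken by lexicographic pair
#' labels. This is the classic native-structure predictor; it can only order
#' pairwise interfaces, so it cannot express a step in which a subunit binds
#' a subcomplex more strongly than any single pair (the ring-plus-apex
#' failure mode).
#'
#' @param structure A `cpx_structure` with at least 3 chains.
#' @param options [sasa_options()].
#' @param cutoff,min_pairs Interface criterion.
#' @return A complete `assembly_pathway`; the BSA table is attached as
#'   attribute `"bsa"`.
#' @export
predict_pairwise_bsa_path <- function(structure, options = sasa_options(),
                                      cutoff = 5.0, min_pairs = 1L) {
  chains <- structure_chains(structure)
  if (length(chains) < 3L) stop("need at least 3 chains")
  edges <- bsa_edges(structure, options, cutoff, min_pairs)
  check_connected(chains, edges)
  edges <- edges[order(-edges$area, edges$chain_a, edges$chain_b), ,
                 drop = FALSE]
  idx <- stats::setNames(seq_along(chains), chains)
  uf <- uf_new(length(chains))
  members <- as.list(chains)
  events <- list()
  for (k in seq_len(nrow(edges))) {
    if (length(events) == length(chains) - 1L) break
    i <- uf_find(uf, idx[[edges$chain_a[k]]])
    j <- uf_find(uf, idx[[edges$chain_b[k]]])
    if (i == j) next  # cycle-forming edge skipped
    ev <- list(a = members[[i]], b = members[[j]], edge = NULL,
               area = edges$area[k])
    uf_union(uf, i, j)
    members[[uf_find(uf, i)]] <- chain_sort(c(ev$a, ev$b))
    events[[length(events) + 1L]] <- ev
  }
  p <- assembly_pathway(chains, events = events)
  attr(p, "bsa") <- edges
  p
}

check_connected <- function(chains, edges) {
  comps <- graph_components(chains, edges)
  if (length(comps) > 1L) {
    stop("interface graph is disconnected; components: ",
         paste(vapply(comps, component_key, character(1)), collapse = " | "))
  }
}

#' Enumerate connected subcomplexes of an interface graph
#'
#' All chain subsets of size 2 to N - 1 that induce a connected subgraph,
#' in deterministic order (by size, then lexicographically).
#'
#' @param graph Interface-graph tibble (columns `chain_a`, `chain_b`).
#' @param chains Chain universe; defaults to the labels in `graph`.
#' @return List of chain-label vectors.
#' @export
enumerate_subcomplexes <- function(graph, chains = NULL) {
  if (is.null(chains)) chains <- chain_sort(unique(c(graph$chain_a, graph$chain_b)))
  n <- length(chains)
  if (n < 3L) stop("need a graph over at least 3 nodes")
  out <- list()
  for (size in 2:(n - 1L)) {
    sets <- utils::combn(chains, size, simplify = FALSE)
    keep <- vapply(sets, function(s) subset_connected(s, graph), logical(1))
    sets <- sets[keep]
    keys <- vapply(sets, component_key, character(1))
    out <- c(out, sets[order(keys)])
  }
  out
}

subset_connected <- function(chains, edges) {
  e <- edges[edges$chain_a %in% chains & edges$chain_b %in% chains, ,
             drop = FALSE]
  length(graph_components(chains, e)) == 1L
}

#' Subcomplex-BSA assembly-order prediction
#'
#' Greedy stepwise assembly: starting from free monomers, repeatedly merge
#' the two current components (adjacent in the interface graph) whose merge
#' buries the largest surface area, until one component remains. Because a
#' merge is evaluated against whole subcomplexes, a subunit that forms a
#' large combined interface with several already-assembled chains can join
#' before a stronger single pairwise interface is completed.
#'
#' With `strategy = "global"` all transitions between connected subcomplexes
#' are sorted once in descending BSA and applied whenever both parts are
#' current components.
#'
#' @param structure A `cpx_structure` with at least 3 chains.
#' @param options [sasa_options()].
#' @param cutoff,min_pairs Interface criterion.
#' @param strategy `"greedy"` (stepwise, default) or `"global"`.
#' @return A complete `assembly_pathway`; the evaluated transitions are
#'   attached as attribute `"transitions"`.
#' @export
predict_subcomplex_bsa_path <- function(structure, options = sasa_options(),
                                        cutoff = 5.0, min_pairs = 1L,
                                        strategy = c("greedy", "global")) {
  strategy <- match.arg(strategy)
  chains <- structure_chains(structure)
  if (length(chains) < 3L) stop("need at least 3 chains")
  g <- interface_graph(structure, cutoff = cutoff, min_pairs = min_pairs)
  check_connected(chains, g)
  cache <- new.env(parent = emptyenv())
  if (strategy == "greedy") {
    predict_subcomplex_greedy(structure, chains, g, options, cache)
  } else {
    predict_subcomplex_global(structure, chains, g, options, cache)
  }
}

components_adjacent <- function(a, b, g) {
  any((g$chain_a %in% a & g$chain_b %in% b) |
        (g$chain_a %in% b & g$chain_b %in% a))
}

predict_subcomplex_greedy <- function(structure, chains, g, options, cache) {
  current <- as.list(chains)
  events <- list()
  log <- list()
  while (length(current) > 1L) {
    cand <- list()
    nc <- length(current)
    for (i in 1:(nc - 1L)) {
      for (j in (i + 1L):nc) {
        if (components_adjacent(current[[i]], current[[j]], g)) {
          cand[[length(cand) + 1L]] <- c(i, j)
        }
      }
    }
    if (!length(cand)) stop("no mergeable component pair (disconnected)")
    areas <- vapply(cand, function(ij) {
      transition_bsa(structure, current[[ij[1]]], current[[ij[2]]],
                     options, cache)$area
    }, numeric(1))
    keys <- vapply(cand, function(ij) {
      ka <- component_key(current[[ij[1]]])
      kb <- component_key(current[[ij[2]]])
      paste(min(ka, kb), max(ka, kb))
    }, character(1))
    best <- order(-areas, keys)[1L]
    ij <- cand[[best]]
    ev <- list(a = current[[ij[1]]], b = current[[ij[2]]], edge = NULL,
               area = areas[best])
    log[[length(log) + 1L]] <- tibble::tibble(
      part_a = component_key(chain_sort(ev$a)),
      part_b = component_key(chain_sort(ev$b)), area = areas[best])
    merged <- chain_sort(c(ev$a, ev$b))
    current <- c(current[-ij], list(merged))
    events[[length(events) + 1L]] <- ev
  }
  p <- assembly_pathway(chains, events = events)
  attr(p, "transitions") <- dplyr::bind_rows(log)
  p
}

predict_subcomplex_global <- function(structure, chains, g, options, cache) {
  subs <- c(as.list(chains), enumerate_subcomplexes(g, chains))
  trans <- list()
  for (i in seq_along(subs)) {
    for (j in seq_along(subs)) {
      if (j <= i) next
      a <- subs[[i]]; b <- subs[[j]]
      if (length(intersect(a, b))) next
      if (!components_adjacent(a, b, g)) next
      trans[[length(trans) + 1L]] <- list(a = a, b = b)
    }
  }
  areas <- vapply(trans, function(tr) {
    transition_bsa(structure, tr$a, tr$b, options, cache)$area
  }, numeric(1))
  keys <- vapply(trans, function(tr) {
    ka <- component_key(chain_sort(tr$a)); kb <- component_key(chain_sort(tr$b))
    paste(min(ka, kb), max(ka, kb))
  }, character(1))
  ord <- order(-areas, keys)
  current <- as.list(chains)
  events <- list()
  repeat {
    if (length(current) == 1L) break
    advanced <- FALSE
    for (k in ord) {
      tr <- trans[[k]]
      ia <- match(component_key(chain_sort(tr$a)),
                  vapply(current, component_key, character(1)))
      ib <- match(component_key(chain_sort(tr$b)),
                  vapply(current, component_key, character(1)))
      if (is.na(ia) || is.na(ib)) next
      ev <- list(a = current[[ia]], b = current[[ib]], edge = NULL,
                 area = areas[k])
      current <- c(current[-c(ia, ib)], list(chain_sort(c(ev$a, ev$b))))
      events[[length(events) + 1L]] <- ev
      advanced <- TRUE
      break
    }
    if (!advanced) stop("no applicable transition (disconnected)")
  }
  assembly_pathway(chains, events = events)
}
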