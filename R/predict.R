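#' Assembly-order prediction strategies
#'
#' Four strategies turn docking decoys and GA model populations into an
#' assembly pathway. Two are *non-blind* (they use the native structure to
#' pick a model): the low-RMSD decoy combination and the lowest-RMSD model.
#' Two are *blind* (no native needed): plurality voting over the final GA
#' generation, and consensus voting across generations. In every case the
#' pathway of a chosen model is read off its spanning-tree edges in
#' ascending score-rank order ([extract_pathway()]).
#'
#' @name predict-strategies
NULL

new_prediction <- function(strategy, score, pathway, tally = NULL,
                           provenance = list()) {
  structure(list(strategy = strategy, score = score, pathway = pathway,
                 tally = tally, provenance = provenance),
            class = "assembly_prediction")
}

#' @export
print.assembly_prediction <- function(x, ...) {
  cat("<assembly_prediction> [", x$strategy, ", score ", x$score, "]\n",
      "pathway: ", format_pathway(x$pathway), "\n", sep = "")
  if (!is.null(x$tally)) {
    fr <- attr(x$tally, "winner_fraction")
    cat("votes: ", attr(x$tally, "winner_votes"), "/",
        attr(x$tally, "total"), " (", sprintf("%.1f%%", 100 * fr), ")",
        if (isTRUE(attr(x$tally, "tie"))) " [tie, lexicographic winner]",
        "\n", sep = "")
  }
  invisible(x)
}

#' Tally pathway votes
#'
#' Each canonical pathway string gets one vote per model; the plurality
#' winner is the prediction. Exact vote ties are broken by the
#' lexicographically smallest pathway string and flagged.
#'
#' @param pathway_strings Character vector of canonical pathway strings.
#' @return A `vote_tally` tibble (`pathway`, `votes`) with attributes
#'   `total`, `winner`, `winner_votes`, `winner_fraction`, `tie`.
#' @export
vote_tally <- function(pathway_strings) {
  stopifnot(length(pathway_strings) >= 1L)
  tab <- table(pathway_strings)
  out <- tibble::tibble(pathway = names(tab), votes = as.integer(tab))
  out <- out[order(-out$votes, out$pathway), , drop = FALSE]
  tie <- nrow(out) > 1L && out$votes[2L] == out$votes[1L]
  structure(out, class = c("vote_tally", class(out)),
            total = sum(out$votes), winner = out$pathway[1L],
            winner_votes = out$votes[1L],
            winner_fraction = out$votes[1L] / sum(out$votes), tie = tie)
}

#' Bar chart of a vote tally
#' @param object A `vote_tally`.
#' @param max_pathways Show at most this many pathways.
#' @param ... Unused.
#' @export
autoplot.vote_tally <- function(object, max_pathways = 10L, ...) {
  df <- tibble::as_tibble(object)[seq_len(min(nrow(object), max_pathways)), ]
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$pathway,
                                                      .data$votes),
                                   y = .data$votes)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "votes") +
    ggplot2::theme_minimal()
}

ga_generation_models <- function(run, generation) {
  g <- run$generations[[generation]]
  lapply(g$models, function(e) model_tree(run$chains, e))
}

# Vote canonicalisation: with a chain-class map, two pathways whose
# intermediate subcomplexes have the same class-multiset signatures are the
# same prediction (homomeric copies are interchangeable, and the step score
# is order-insensitive within the intermediate set), so their votes pool.
pathway_vote_key <- function(pathway_string, chains, class_map) {
  if (is.null(class_map)) return(pathway_string)
  p <- parse_pathway(pathway_string, chains = chains)
  lookup <- class_lookup(class_map)
  sigs <- vapply(pathway_intermediates(p), component_signature,
                 character(1), lookup = lookup)
  paste(sort(sigs), collapse = " ; ")
}

tally_votes <- function(strings, chains, class_map) {
  keys <- vapply(unique(strings), pathway_vote_key, character(1),
                 chains = chains, class_map = class_map)
  all_keys <- unname(keys[strings])
  tab <- sort(table(all_keys), decreasing = TRUE)
  # representative instance string per vote class: most common, then
  # lexicographically smallest
  rep_of <- vapply(names(tab), function(k) {
    inst <- sort(table(strings[all_keys == k]), decreasing = TRUE)
    cand <- names(inst)[inst == max(inst)]
    min(cand)
  }, character(1))
  out <- tibble::tibble(pathway = unname(rep_of), votes = as.integer(tab))
  out <- out[order(-out$votes, out$pathway), , drop = FALSE]
  tie <- nrow(out) > 1L && out$votes[2L] == out$votes[1L]
  structure(out, class = c("vote_tally", class(out)),
            total = sum(out$votes), winner = out$pathway[1L],
            winner_votes = out$votes[1L],
            winner_fraction = out$votes[1L] / sum(out$votes), tie = tie)
}

#' Low-RMSD decoy combination prediction (non-blind)
#'
#' The native contacting pairs define the interface edges; every spanning
#' tree of that graph is enumerated, each edge is given its `k` lowest
#' ligand-RMSD decoys, all decoy combinations are realized, and the model
#' with the lowest complex RMSD to the native is selected; its pathway is
#' extracted from the score ranks.
#'
#' @param native Native `cpx_structure`.
#' @param decoys Decoy table.
#' @param ranking Ranking table for [extract_pathway()].
#' @param k Decoys per edge.
#' @param cutoff,min_pairs Interface criterion for the native edges.
#' @param class_map Chain-class table; defaults to exact-sequence classes.
#' @param tree_cap Abort if the graph has more spanning trees than this.
#' @return An `assembly_prediction` with the chosen model and its RMSD in
#'   `provenance`.
#' @export
predict_low_rmsd_decoy_combination <- function(native, decoys, ranking,
                                               k = 5L, cutoff = 5.0,
                                               min_pairs = 1L,
                                               class_map = NULL,
                                               tree_cap = 5000L) {
  chains <- structure_chains(native)
  g <- interface_graph(native, cutoff = cutoff, min_pairs = min_pairs)
  check_connected(chains, g)
  if (is.null(class_map)) class_map <- assign_chain_classes(native)
  trees <- spanning_trees(chains, g, cap = tree_cap)
  rmsds <- ligand_rmsd(decoys, native)
  pick <- dplyr::slice_min(dplyr::group_by(rmsds, .data$receptor,
                                           .data$ligand),
                           .data$rmsd, n = k, with_ties = FALSE)
  pick <- dplyr::ungroup(pick)
  best <- NULL
  best_rmsd <- Inf
  for (tr in trees) {
    ids_per_edge <- lapply(seq_len(nrow(tr)), function(i) {
      sel <- (pick$receptor == tr$chain_a[i] & pick$ligand == tr$chain_b[i]) |
        (pick$receptor == tr$chain_b[i] & pick$ligand == tr$chain_a[i])
      pick[sel, c("receptor", "ligand", "decoy_id"), drop = FALSE]
    })
    if (any(vapply(ids_per_edge, nrow, integer(1)) == 0L)) {
      stop("no decoys for interface edge ", tr$chain_a[which.min(
        vapply(ids_per_edge, nrow, integer(1)))])
    }
    combos <- expand.grid(lapply(ids_per_edge, function(x) seq_len(nrow(x))))
    for (ci in seq_len(nrow(combos))) {
      edges <- dplyr::bind_rows(lapply(seq_along(ids_per_edge), function(i) {
        ids_per_edge[[i]][combos[ci, i], ]
      }))
      model <- model_tree(chains, edges)
      s <- realize(model, decoys = decoys, subunits = native)
      r <- complex_rmsd(s, native, class_map)$rmsd
      if (r < best_rmsd) {
        best_rmsd <- r
        best <- model
      }
    }
  }
  new_prediction("low_rmsd_decoy_combination", unique(ranking$score),
                 extract_pathway(best, ranking),
                 provenance = list(model = best, rmsd = best_rmsd,
                                   n_trees = length(trees), k = k))
}

#' Enumerate spanning trees of an interface graph
#'
#' @param chains Node labels.
#' @param graph Edge tibble (`chain_a`, `chain_b`).
#' @param cap Maximum number of trees before aborting with an error.
#' @return List of edge tibbles, each a spanning tree, in deterministic
#'   order.
#' @export
spanning_trees <- function(chains, graph, cap = 5000L) {
  n <- length(chains)
  m <- nrow(graph)
  if (m < n - 1L) stop("graph has too few edges for a spanning tree")
  out <- list()
  combos <- utils::combn(m, n - 1L, simplify = FALSE)
  idx <- stats::setNames(seq_along(chains), chains)
  for (sel in combos) {
    uf <- uf_new(n)
    ok <- TRUE
    for (k in sel) {
      if (!uf_union(uf, idx[[graph$chain_a[k]]], idx[[graph$chain_b[k]]])) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      out[[length(out) + 1L]] <- graph[sel, c("chain_a", "chain_b")]
      if (length(out) > cap) {
        stop("more than ", cap, " spanning trees; raise `tree_cap` to proceed")
      }
    }
  }
  out
}

#' Lowest-RMSD model prediction (non-blind)
#'
#' Every model of the final GA generation is realized and compared to the
#' native structure; the pathway is extracted from the model with the
#' lowest complex RMSD (ties by fitness, then model index).
#'
#' @param run A `ga_run`.
#' @param native Native `cpx_structure`.
#' @param subunits,decoys Library structure and decoy table (to realize
#'   recorded models).
#' @param ranking Ranking table.
#' @param class_map Chain-class table; defaults to exact-sequence classes.
#' @return An `assembly_prediction` with the best RMSD in `provenance`.
#' @export
predict_lowest_rmsd <- function(run, native, subunits, decoys, ranking,
                                class_map = NULL) {
  models <- ga_generation_models(run, run$final_generation)
  if (!length(models)) stop("empty final generation")
  if (is.null(class_map)) class_map <- assign_chain_classes(native)
  fit <- run$generations[[run$final_generation]]$fitness
  rmsds <- vapply(models, function(m) {
    complex_rmsd(realize(m, subunits, decoys), native, class_map)$rmsd
  }, numeric(1))
  best <- order(rmsds, fit, seq_along(models))[1L]
  new_prediction("lowest_rmsd", unique(ranking$score),
                 extract_pathway(models[[best]], ranking),
                 provenance = list(model_index = best, rmsd = rmsds[best],
                                   generation = run$final_generation))
}

#' Final-generation voting prediction (blind)
#'
#' Each model of the final GA generation casts one vote for the pathway
#' extracted from its score ranks; the plurality pathway wins.
#'
#' @param run A `ga_run`.
#' @param ranking Ranking table.
#' @param class_map Optional chain-class tibble; when given, votes whose
#'   intermediate subcomplexes are class-equivalent pool together
#'   (homomeric copies are interchangeable).
#' @return An `assembly_prediction` carrying the full `vote_tally`.
#' @export
predict_final_generation <- function(run, ranking, class_map = NULL) {
  models <- ga_generation_models(run, run$final_generation)
  if (!length(models)) stop("empty final generation")
  strings <- vapply(models, function(m) {
    format_pathway(extract_pathway(m, ranking))
  }, character(1))
  tally <- tally_votes(strings, run$chains, class_map)
  new_prediction("final_generation", unique(ranking$score),
                 parse_pathway(attr(tally, "winner"),
                               chains = run$chains),
                 tally = tally,
                 provenance = list(generation = run$final_generation))
}

#' Consensus-across-generations prediction (blind)
#'
#' Votes are tallied over every model of every recorded generation from
#' `start_generation` (clamped to the available range) through the final
#' generation.
#'
#' @param run A `ga_run`.
#' @param ranking Ranking table.
#' @param start_generation First generation included (default 1000, the
#'   published choice; desk-scale runs clamp this to their length).
#' @param class_map Optional chain-class tibble, as in
#'   [predict_final_generation()].
#' @return An `assembly_prediction` carrying the full `vote_tally`.
#' @export
predict_consensus <- function(run, ranking, start_generation = 1000L,
                              class_map = NULL) {
  start <- max(1L, min(start_generation, run$final_generation))
  # pathway depends only on the edge set, so cache per model signature
  cache <- new.env(parent = emptyenv())
  strings <- character()
  for (g in start:run$final_generation) {
    for (m in ga_generation_models(run, g)) {
      sig <- model_signature(m)
      s <- cache[[sig]]
      if (is.null(s)) {
        s <- format_pathway(extract_pathway(m, ranking))
        cache[[sig]] <- s
      }
      strings[length(strings) + 1L] <- s
    }
  }
  tally <- tally_votes(strings, run$chains, class_map)
  new_prediction("consensus", unique(ranking$score),
                 parse_pathway(attr(tally, "winner"), chains = run$chains),
                 tally = tally,
                 provenance = list(start_generation = start,
                                   final_generation = run$final_generation))
}
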