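#' Chain classes implied by pathway labels
#'
#' In pathway notation, primed or numbered labels (`A'`, `B2`) are copies of
#' the base-letter protein, so the class of a label is its base letter.
#' Useful when scoring parsed reference pathways without structures.
#'
#' @param chains Character vector of chain labels.
#' @return Tibble with columns `chain`, `class`.
#' @export
label_classes <- function(chains) {
  tibble::tibble(chain = chains, class = substr(chains, 1L, 1L))
}

class_lookup <- function(class_map) {
  stats::setNames(class_map$class, class_map$chain)
}

component_signature <- function(comp, lookup) {
  cls <- lookup[comp]
  if (anyNA(cls)) stop("chain(s) missing from class map: ",
                       paste(comp[is.na(cls)], collapse = ", "))
  paste(sort(cls), collapse = "|")
}

#' Score a predicted pathway against reference pathways
#'
#' The score is X/Y: Y = N - 2 is the total number of assembly steps of a
#' complete binary pathway, and X counts predicted intermediate
#' subcomplexes that match a reference intermediate. Matching is a maximum
#' bipartite matching under class-multiset equality, so homomeric copies
#' are interchangeable (`AA'` matches `A''A'''`). With several reference
#' alternatives, the best-matching alternative counts. Intermediates of a
#' partial reference that are not listed still contribute to Y but can
#' never be hits.
#'
#' @param predicted A complete `assembly_pathway`.
#' @param references An `assembly_pathway` or list of alternatives.
#' @param class_map Tibble `chain`/`class` covering both label sets;
#'   defaults to base-letter classes ([label_classes()]).
#' @return A `pathway_score` list: `x`, `y`, `fraction`, `matched` (tibble
#'   of matched subcomplex pairs for the best alternative).
#' @export
score_pathway <- function(predicted, references, class_map = NULL) {
  if (inherits(references, "assembly_pathway")) references <- list(references)
  if (predicted$partial) stop("predictions must be complete pathways")
  n <- predicted$n_chains
  for (ref in references) {
    if (ref$n_chains != n) stop("chain-universe mismatch between predicted (",
                                n, ") and reference (", ref$n_chains, ")")
  }
  if (is.null(class_map)) {
    class_map <- label_classes(unique(c(
      predicted$chains, unlist(lapply(references, `[[`, "chains")))))
  }
  lookup <- class_lookup(class_map)
  pred_int <- pathway_intermediates(predicted)
  pred_sig <- vapply(pred_int, component_signature, character(1),
                     lookup = lookup)
  y <- n - 2L
  best_x <- 0L
  best_match <- tibble::tibble(predicted = character(), reference = character())
  for (ref in references) {
    ref_int <- pathway_intermediates(ref)
    ref_sig <- vapply(ref_int, component_signature, character(1),
                      lookup = lookup)
    adj <- lapply(pred_sig, function(s) which(ref_sig == s))
    m <- max_bipartite_matching(adj, length(ref_sig))
    x <- sum(m > 0L)
    if (x > best_x || (x == best_x && nrow(best_match) == 0L)) {
      best_x <- x
      hit <- which(m > 0L)
      best_match <- tibble::tibble(
        predicted = vapply(pred_int[hit], component_key, character(1)),
        reference = vapply(ref_int[m[hit]], component_key, character(1)))
    }
  }
  structure(list(x = as.integer(best_x), y = as.integer(y),
                 fraction = best_x / y, matched = best_match),
            class = "pathway_score")
}

#' @export
print.pathway_score <- function(x, ...) {
  cat("<pathway_score> ", x$x, "/", x$y, " assembly steps correct\n",
      sep = "")
  invisible(x)
}

# Kuhn's augmenting-path maximum bipartite matching.
# adj: list over left nodes of right-node index vectors.
# Returns per-left matched right index (0 = unmatched).
max_bipartite_matching <- function(adj, n_right) {
  match_right <- integer(n_right)  # right -> left
  try_kuhn <- function(u, visited) {
    for (v in adj[[u]]) {
      if (visited[v]) next
      visited[v] <- TRUE
      if (match_right[v] == 0L) {
        match_right[v] <<- u
        return(list(ok = TRUE, visited = visited))
      }
      res <- try_kuhn(match_right[v], visited)
      visited <- res$visited
      if (res$ok) {
        match_right[v] <<- u
        return(list(ok = TRUE, visited = visited))
      }
    }
    list(ok = FALSE, visited = visited)
  }
  for (u in seq_along(adj)) {
    try_kuhn(u, logical(n_right))
  }
  match_left <- integer(length(adj))
  for (v in seq_len(n_right)) {
    if (match_right[v] > 0L) match_left[match_right[v]] <- v
  }
  match_left
}

# all permutations of a vector (small n)
permutations_of <- function(v) {
  n <- length(v)
  if (n <= 1L) return(list(v))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in permutations_of(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}

# class-preserving bijections model chains -> native chains
class_bijections <- function(model_chains, native_chains, lookup,
                             max_assignments = 50000L) {
  mc <- split(model_chains, lookup[model_chains])
  nc <- split(native_chains, lookup[native_chains])
  if (!identical(sort(names(mc)), sort(names(nc))) ||
      !identical(lengths(mc)[sort(names(mc))], lengths(nc)[sort(names(nc))])) {
    return(NULL)  # composition mismatch
  }
  classes <- sort(names(mc))
  per_class <- lapply(classes, function(cl) permutations_of(nc[[cl]]))
  total <- prod(vapply(per_class, length, numeric(1)))
  if (total > max_assignments) {
    stop("too many chain assignments (", total, "); reduce chain copies")
  }
  grid <- expand.grid(lapply(per_class, seq_along))
  lapply(seq_len(nrow(grid)), function(r) {
    ass <- character()
    for (k in seq_along(classes)) {
      ass[mc[[classes[k]]]] <- per_class[[k]][[grid[r, k]]]
    }
    ass
  })
}

superposed_rmsd <- function(a, b) {
  bio3d::rmsd(as.numeric(t(a)), as.numeric(t(b)), fit = TRUE)
}

# minimum superposed CA RMSD over class-preserving bijections between two
# chain subsets; returns list(rmsd, assignment)
best_assignment_rmsd <- function(model, native, model_chains, native_chains,
                                 lookup) {
  bijections <- class_bijections(model_chains, native_chains, lookup)
  if (is.null(bijections)) stop("chain-class composition mismatch")
  best <- list(rmsd = Inf, assignment = NULL)
  mcoords <- lapply(stats::setNames(model_chains, model_chains),
                    function(ch) chain_coords(model, ch, ca_only = TRUE))
  ncoords <- lapply(stats::setNames(native_chains, native_chains),
                    function(ch) chain_coords(native, ch, ca_only = TRUE))
  for (ass in bijections) {
    ok <- all(vapply(names(ass), function(mch) {
      nrow(mcoords[[mch]]) == nrow(ncoords[[ass[[mch]]]])
    }, logical(1)))
    if (!ok) next
    a <- do.call(rbind, mcoords[names(ass)])
    b <- do.call(rbind, ncoords[unname(ass)])
    r <- superposed_rmsd(a, b)
    if (r < best$rmsd) best <- list(rmsd = r, assignment = ass)
  }
  if (!is.finite(best$rmsd)) stop("no assignment with matching CA counts")
  best
}

#' Complex RMSD with optimal chain assignment
#'
#' C-alpha RMSD after optimal rigid superposition (Kabsch), minimised over
#' all class-preserving permutations of identical chains (exhaustive;
#' intended for complexes of up to ~7 chains).
#'
#' @param model,native `cpx_structure` objects with the same chain-class
#'   composition.
#' @param class_map Tibble `chain`/`class`; defaults to exact-sequence
#'   classes of the native.
#' @return List with `rmsd` (Angstrom) and `assignment` (named character,
#'   model chain -> native chain).
#' @export
complex_rmsd <- function(model, native, class_map = NULL) {
  if (is.null(class_map)) class_map <- assign_chain_classes(native)
  lookup <- class_lookup(class_map)
  best_assignment_rmsd(model, native, structure_chains(model),
                       structure_chains(native), lookup)
}

#' Largest subcomplex assembled within an RMSD cutoff
#'
#' For k from N down to 2, every size-k subset of model chains is compared
#' (over class-preserving correspondences to native subsets) by superposed
#' C-alpha RMSD; the largest k achieving RMSD below `cutoff` is returned,
#' or 1 when no chain pair is assembled within the cutoff.
#'
#' @param model,native `cpx_structure` objects.
#' @param class_map Tibble `chain`/`class` (default: native sequence
#'   classes).
#' @param cutoff RMSD cutoff in Angstrom (default 4.0).
#' @return Integer in 1..N.
#' @export
largest_assembled <- function(model, native, class_map = NULL, cutoff = 4.0) {
  if (is.null(class_map)) class_map <- assign_chain_classes(native)
  lookup <- class_lookup(class_map)
  mch <- structure_chains(model)
  nch <- structure_chains(native)
  n <- length(mch)
  for (k in n:2) {
    msets <- utils::combn(mch, k, simplify = FALSE)
    nsets <- utils::combn(nch, k, simplify = FALSE)
    for (ms in msets) {
      msig <- paste(sort(lookup[ms]), collapse = "|")
      for (ns in nsets) {
        if (!identical(msig, paste(sort(lookup[ns]), collapse = "|"))) next
        r <- tryCatch(
          best_assignment_rmsd(model, native, ms, ns, lookup)$rmsd,
          error = function(e) Inf)
        if (r < cutoff) return(as.integer(k))
      }
    }
  }
  1L
}

#' Interface-topology difference between a model and the native
#'
#' Interface graphs (contact criterion, default 5 Angstrom) are compared
#' edge by edge after optionally relabelling the model chains with a chain
#' assignment. The topology is *correct* when no edge is missing or extra,
#' and *almost correct* when nothing is missing and at most two extra
#' interfaces are present.
#'
#' @param model,native `cpx_structure` objects over the same chain universe.
#' @param cutoff,min_pairs Interface criterion.
#' @param assignment Optional named character (model chain -> native chain),
#'   e.g. from [complex_rmsd()].
#' @return List with `missing`, `extra` (edge tibbles), `correct`,
#'   `almost_correct`.
#' @export
topology_delta <- function(model, native, cutoff = 5.0, min_pairs = 1L,
                           assignment = NULL) {
  if (!is.null(assignment)) {
    model$chain <- unname(assignment[model$chain])
  }
  gm <- interface_graph(model, cutoff = cutoff, min_pairs = min_pairs)
  gn <- interface_graph(native, cutoff = cutoff, min_pairs = min_pairs)
  key <- function(g) paste(g$chain_a, g$chain_b)
  missing <- gn[!key(gn) %in% key(gm), c("chain_a", "chain_b")]
  extra <- gm[!key(gm) %in% key(gn), c("chain_a", "chain_b")]
  list(missing = missing, extra = extra,
       correct = nrow(missing) == 0L && nrow(extra) == 0L,
       almost_correct = nrow(missing) == 0L && nrow(extra) <= 2L)
}

#' Step accuracy stratified by vote fraction
#'
#' Splits prediction results at a winner-vote-fraction threshold and
#' reports the mean step accuracy (X/Y) in each stratum; an empty stratum
#' yields `NA`, not 0.
#'
#' @param results Tibble with columns `winner_fraction`, `x`, `y`.
#' @param threshold Vote-fraction threshold (default 0.75).
#' @return Tibble `stratum`, `n`, `mean_accuracy`.
#' @export
stratify_vote_accuracy <- function(results, threshold = 0.75) {
  stopifnot(nrow(results) >= 1L)
  hi <- results$winner_fraction > threshold
  acc <- results$x / results$y
  tibble::tibble(
    stratum = c(paste0("> ", threshold), paste0("<= ", threshold)),
    n = c(sum(hi), sum(!hi)),
    mean_accuracy = c(if (any(hi)) mean(acc[hi]) else NA_real_,
                      if (any(!hi)) mean(acc[!hi]) else NA_real_)
  )
}
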