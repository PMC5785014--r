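#' Assembly pathways
#'
#' An assembly pathway is the ordered sequence of merge events that takes a
#' complex from free monomers to the complete assembly. It is written in a
#' compact text notation: states are separated by `">"`, subcomplexes within
#' a state by `"+"`, and a chain token is a letter with an optional suffix
#' (primes for identical copies, e.g. `A'`, or a copy number, e.g. `B2`).
#' `"AB> ABC"` reads "A and B bind first; C then joins AB". A complete
#' pathway over N chains passes through exactly N - 2 intermediate
#' subcomplexes; a pathway that only lists some of its merges is *partial*.
#'
#' @param chains Character vector of all chain labels in the complex.
#' @param events List of merge events, each a list with elements `a`, `b`
#'   (the two merged component chain sets) and optionally `edge`
#'   (`list(receptor, ligand, decoy_id)` for model-derived pathways).
#' @param states Optional list of states (each a list of chain-label
#'   vectors); derived from `events` when omitted.
#' @param partial Is the pathway only partially specified?
#' @return An `assembly_pathway` object.
#' @export
assembly_pathway <- function(chains, events = NULL, states = NULL,
                             partial = FALSE) {
  chains <- chain_sort(unique(as.character(chains)))
  if (length(chains) < 2L) stop("a pathway needs at least 2 chains")
  if (is.null(states)) {
    if (is.null(events)) stop("give events or states")
    states <- states_from_events(chains, events)
  }
  obj <- structure(
    list(chains = chains, n_chains = length(chains), events = events,
         states = states, partial = partial),
    class = "assembly_pathway"
  )
  validate_pathway(obj)
  obj
}

validate_pathway <- function(p) {
  # monotonicity: replay states from monomers
  current <- as.list(p$chains)
  for (st in p$states) {
    for (comp in st) {
      covered <- vapply(current, function(c0) all(c0 %in% comp), logical(1))
      inside <- vapply(current, function(c0) any(c0 %in% comp), logical(1))
      if (!identical(covered, inside) ||
          !setequal(unlist(current[covered]), comp)) {
        stop("state component {", paste(comp, collapse = ""),
             "} is not a union of components of the previous state")
      }
    }
    # merge listed components into the running partition
    for (comp in st) {
      keep <- vapply(current, function(c0) !any(c0 %in% comp), logical(1))
      current <- c(current[keep], list(chain_sort(comp)))
    }
  }
  invisible(p)
}

states_from_events <- function(chains, events) {
  comp_of <- stats::setNames(as.list(chains), chains)
  current <- as.list(chains)
  states <- list()
  for (ev in events) {
    merged <- chain_sort(c(ev$a, ev$b))
    keep <- vapply(current, function(c0) !any(c0 %in% merged), logical(1))
    current <- c(current[keep], list(merged))
    multi <- current[lengths(current) >= 2L]
    states[[length(states) + 1L]] <- canonical_components(multi)
  }
  states
}

canonical_components <- function(comps) {
  comps <- lapply(comps, chain_sort)
  keys <- vapply(comps, component_key, character(1))
  comps[order_by_chain_rank(keys, comps)]
}

component_key <- function(comp) paste(comp, collapse = "")

# order components by their first (smallest) chain, then second, ...
order_by_chain_rank <- function(keys, comps) {
  first <- vapply(comps, function(c0) c0[1L], character(1))
  ord <- chain_sort(unique(first))
  order(match(first, ord), keys)
}

#' @export
print.assembly_pathway <- function(x, ...) {
  cat("<assembly_pathway> ", x$n_chains, " chains",
      if (x$partial) " (partial)" else "", ": ", format_pathway(x), "\n",
      sep = "")
  invisible(x)
}

#' Intermediate subcomplexes of a pathway
#'
#' All subcomplexes that appear before the complete complex. For a complete
#' binary pathway over N chains this is exactly N - 2 sets; for a parsed
#' partial pathway, only the listed subcomplexes.
#'
#' @param pathway An `assembly_pathway`.
#' @return List of chain-label vectors.
#' @export
pathway_intermediates <- function(pathway) {
  comps <- list()
  seen <- character()
  for (st in pathway$states) {
    for (comp in st) {
      if (length(comp) >= 2L && !setequal(comp, pathway$chains)) {
        key <- component_key(chain_sort(comp))
        if (!key %in% seen) {
          seen <- c(seen, key)
          comps[[length(comps) + 1L]] <- chain_sort(comp)
        }
      }
    }
  }
  comps
}

is_complete_pathway <- function(pathway) {
  final <- pathway$states[[length(pathway$states)]]
  reaches_full <- any(vapply(final, function(s) setequal(s, pathway$chains),
                             logical(1)))
  reaches_full &&
    length(pathway_intermediates(pathway)) == pathway$n_chains - 2L
}

#' Format a pathway in canonical notation
#'
#' Chains within a subcomplex and subcomplexes within a state are sorted
#' canonically; states are joined with `"> "`. `parse_pathway()` of the
#' result reproduces the pathway.
#'
#' @param pathway An `assembly_pathway`.
#' @return A single string, e.g. `"AA'> AA'C> AA'CC'"`.
#' @export
format_pathway <- function(pathway) {
  paste(vapply(pathway$states, function(st) {
    paste(vapply(canonical_components(st), component_key, character(1)),
          collapse = "+")
  }, character(1)), collapse = "> ")
}

#' Parse a pathway string
#'
#' Accepts ASCII and typographic primes (`'`, ′, ″, ‴),
#' superscript copy numbers written as `B^1^` or plain digits (`B1`), `"+"`
#' between subcomplexes and `">"` between states. The chain universe is
#' taken from the final state (which must then be the complete complex)
#' unless `chains` is given, in which case the pathway may stop short of
#' the complete complex (a partial literature reference). Pathways that do
#' not specify every merge are flagged `partial`.
#'
#' @param text Pathway string.
#' @param chains Optional character vector with the full chain universe.
#' @return An `assembly_pathway`.
#' @export
parse_pathway <- function(text, chains = NULL) {
  txt <- normalize_pathway_text(text)
  state_strs <- trimws(strsplit(txt, ">", fixed = TRUE)[[1]])
  state_strs <- state_strs[state_strs != ""]
  if (!length(state_strs)) stop("empty pathway string")
  states <- lapply(state_strs, function(s) {
    comps <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    lapply(comps, tokenize_chains)
  })
  final <- states[[length(states)]]
  if (is.null(chains)) {
    if (length(final) != 1L) {
      stop("final state must be a single complete complex ",
           "(or pass the chain universe explicitly)")
    }
    universe <- final[[1]]
  } else {
    universe <- chain_sort(unique(chains))
    if (!all(unlist(states) %in% universe)) {
      stop("pathway uses chains outside the given universe")
    }
  }
  dup <- vapply(states, function(st) anyDuplicated(unlist(st)) > 0, logical(1))
  if (any(dup)) stop("a chain appears twice within one state")
  p <- assembly_pathway(universe, events = NULL, states = states,
                        partial = FALSE)
  p$partial <- !is_complete_pathway(p)
  p
}

normalize_pathway_text <- function(text) {
  txt <- enc2utf8(as.character(text))
  txt <- gsub("‴", "'''", txt)
  txt <- gsub("″", "''", txt)
  txt <- gsub("′", "'", txt)
  txt <- gsub("’", "'", txt)
  # superscript copy numbers: B^1^ or B^1 -> B1
  txt <- gsub("\\^([0-9]+)\\^?", "\\1", txt)
  sup <- c("¹" = "1", "²" = "2", "³" = "3", "⁴" = "4",
           "⁵" = "5", "⁶" = "6", "⁷" = "7", "⁸" = "8",
           "⁹" = "9", "⁰" = "0")
  for (k in names(sup)) txt <- gsub(k, sup[[k]], txt)
  # strip the dagger footnote marker seen in printed tables
  gsub("†", "", txt)
}

tokenize_chains <- function(s) {
  s <- gsub("[[:space:]]", "", s)
  m <- gregexpr("[A-Za-z](?:'{1,3}|[0-9]+)?", s, perl = TRUE)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(s)) stop("malformed subcomplex token: ", s)
  toks
}

#' Parse reference pathways with alternatives
#'
#' Reference tables may list alternative acceptable pathways joined by
#' `" or "`. Each alternative is parsed separately.
#'
#' @param text Pathway string, possibly with `" or "`-joined alternatives.
#' @param chains Optional chain universe; defaults to the union of chains
#'   over all alternatives (so an alternative may stop short of the
#'   complete complex).
#' @return List of `assembly_pathway` objects.
#' @export
parse_reference_pathways <- function(text, chains = NULL) {
  alts <- trimws(strsplit(text, "\\s+or\\s+")[[1]])
  if (is.null(chains)) {
    toks <- unlist(lapply(alts, function(a) {
      unlist(lapply(strsplit(normalize_pathway_text(a), "[>+]")[[1]],
                    tokenize_chains))
    }))
    chains <- chain_sort(unique(toks))
  }
  lapply(alts, parse_pathway, chains = chains)
}

#' Read a reference-pathway table
#'
#' Tab-separated file with columns `id`, `n_chains`, `pathway` (alternatives
#' joined by `" or "`). Comment lines start with `#`.
#'
#' @param path File path.
#' @return Tibble with columns `id`, `n_chains`, `pathway` (string) and
#'   `pathways` (list column of parsed alternatives).
#' @export
read_reference_pathways <- function(path) {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, quote = "")
  tibble::tibble(
    id = as.character(df$id),
    n_chains = as.integer(df$n_chains),
    pathway = as.character(df$pathway),
    pathways = purrr::map(as.character(df$pathway), parse_reference_pathways)
  )
}

#' Extract the assembly pathway of a spanning-tree model
#'
#' The model's edges (pairwise decoys) are sorted by score rank, ties by the
#' more favourable (more negative) Z-score, residual ties by pair label and
#' decoy id. Edges are then replayed in order with a union-find; each edge
#' merges the two components containing its endpoints, giving a complete
#' binary pathway: assembly starts with the best-ranked pairwise pose and
#' proceeds in ascending rank order.
#'
#' @param model A `model_tree` (see [model_tree()]).
#' @param ranking A decoy ranking table with columns `receptor`, `ligand`,
#'   `decoy_id`, `rank`, `z` (see [rank_and_z()]).
#' @return A complete `assembly_pathway`; each event carries its triggering
#'   edge.
#' @export
extract_pathway <- function(model, ranking) {
  edges <- model$edges
  key <- function(r, l, id) paste(r, l, id, sep = "\r")
  rk <- stats::setNames(ranking$rank, key(ranking$receptor, ranking$ligand,
                                          ranking$decoy_id))
  zs <- stats::setNames(ranking$z, names(rk))
  ek <- key(edges$receptor, edges$ligand, edges$decoy_id)
  if (anyNA(rk[ek])) {
    stop("missing rank for edge(s): ",
         paste(gsub("\r", "/", ek[is.na(rk[ek])]), collapse = ", "))
  }
  edges$rank <- unname(rk[ek])
  edges$z <- unname(zs[ek])
  pair_lab <- paste(pmin(edges$receptor, edges$ligand),
                    pmax(edges$receptor, edges$ligand))
  ord <- order(edges$rank, edges$z, pair_lab, edges$decoy_id)
  edges <- edges[ord, , drop = FALSE]
  chains <- model$chains
  idx <- stats::setNames(seq_along(chains), chains)
  uf <- uf_new(length(chains))
  members <- as.list(chains)
  events <- list()
  for (k in seq_len(nrow(edges))) {
    i <- uf_find(uf, idx[[edges$receptor[k]]])
    j <- uf_find(uf, idx[[edges$ligand[k]]])
    ev <- list(a = members[[i]], b = members[[j]],
               edge = list(receptor = edges$receptor[k],
                           ligand = edges$ligand[k],
                           decoy_id = edges$decoy_id[k]))
    uf_union(uf, i, j)
    r <- uf_find(uf, i)
    members[[r]] <- chain_sort(c(ev$a, ev$b))
    events[[length(events) + 1L]] <- ev
  }
  assembly_pathway(chains, events = events)
}

#' Do two pathways describe the same assembly order?
#' @param a,b `assembly_pathway` objects.
#' @export
pathway_equal <- function(a, b) {
  setequal(a$chains, b$chains) &&
    identical(format_pathway(a), format_pathway(b))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Tidy an assembly pathway into a step table
#'
#' @param x An `assembly_pathway`.
#' @param ... Unused.
#' @return Tibble with one row per state: `step`, `state` (string),
#'   `n_subcomplexes`.
#' @export
tidy.assembly_pathway <- function(x, ...) {
  tibble::tibble(
    step = seq_along(x$states),
    state = vapply(x$states, function(st) {
      paste(vapply(canonical_components(st), component_key, character(1)),
            collapse = "+")
    }, character(1)),
    n_subcomplexes = vapply(x$states, length, integer(1))
  )
}
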