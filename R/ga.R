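#' Spanning-tree models of a multimeric complex
#'
#' A model encodes a candidate complex as a spanning tree: nodes are chain
#' labels, each edge is one pairwise docking decoy. Realizing the model
#' composes the edge transforms from a root chain outward, producing full
#' coordinates.
#'
#' @param chains Character vector of chain labels (the nodes).
#' @param edges Data frame with columns `receptor`, `ligand`, `decoy_id`
#'   (one row per edge; `|edges| = |chains| - 1`).
#' @return A `model_tree` object.
#' @export
model_tree <- function(chains, edges) {
  chains <- chain_sort(unique(as.character(chains)))
  edges <- tibble::as_tibble(edges)[c("receptor", "ligand", "decoy_id")]
  obj <- structure(list(chains = chains, edges = edges), class = "model_tree")
  validate_model_tree(obj)
  obj
}

#' @export
print.model_tree <- function(x, ...) {
  cat("<model_tree> ", length(x$chains), " chains; edges: ",
      paste(sprintf("%s-%s#%d", x$edges$receptor, x$edges$ligand,
                    x$edges$decoy_id), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Validate the spanning-tree invariants of a model
#' @param model A `model_tree`.
#' @param decoys Optional decoy table; when given, every edge's decoy must
#'   exist in it.
#' @export
validate_model_tree <- function(model, decoys = NULL) {
  n <- length(model$chains)
  e <- model$edges
  if (nrow(e) != n - 1L) stop("a spanning tree over ", n, " chains needs ",
                              n - 1L, " edges, got ", nrow(e))
  if (!all(c(e$receptor, e$ligand) %in% model$chains)) {
    stop("edge endpoint not among model chains")
  }
  idx <- stats::setNames(seq_len(n), model$chains)
  uf <- uf_new(n)
  for (k in seq_len(nrow(e))) {
    if (!uf_union(uf, idx[[e$receptor[k]]], idx[[e$ligand[k]]])) {
      stop("model edges contain a cycle")
    }
  }
  if (!is.null(decoys)) {
    key <- paste(decoys$receptor, decoys$ligand, decoys$decoy_id)
    ek <- paste(e$receptor, e$ligand, e$decoy_id)
    if (!all(ek %in% key)) {
      stop("edge decoy missing from decoy table: ",
           paste(ek[!ek %in% key], collapse = ", "))
    }
  }
  invisible(model)
}

model_signature <- function(model) {
  e <- model$edges
  ord <- order(e$receptor, e$ligand, e$decoy_id)
  paste(e$receptor[ord], e$ligand[ord], e$decoy_id[ord],
        sep = "/", collapse = ";")
}

#' Draw a uniformly random spanning-tree model
#'
#' The tree shape is uniform over all spanning trees of the pair graph
#' (Aldous-Broder random walk); each edge gets a uniformly random decoy of
#' its pair. Uses the current RNG stream.
#'
#' @param chains Chain labels.
#' @param decoys Decoy table (defines which pairs are available).
#' @return A `model_tree`.
#' @export
random_model <- function(chains, decoys) {
  chains <- chain_sort(unique(chains))
  pairs <- unique(decoys[c("receptor", "ligand")])
  adj <- lapply(stats::setNames(chains, chains), function(ch) {
    c(pairs$ligand[pairs$receptor == ch], pairs$receptor[pairs$ligand == ch])
  })
  if (length(graph_components(chains, tibble::tibble(
    chain_a = pairs$receptor, chain_b = pairs$ligand))) != 1L) {
    stop("pair graph is disconnected: no spanning tree exists")
  }
  # Aldous-Broder: walk until all nodes visited; first-entry edges form a
  # uniform spanning tree
  current <- sample(chains, 1L)
  visited <- current
  tree <- list()
  while (length(visited) < length(chains)) {
    nxt <- sample(adj[[current]], 1L)
    if (!nxt %in% visited) {
      visited <- c(visited, nxt)
      tree[[length(tree) + 1L]] <- c(current, nxt)
    }
    current <- nxt
  }
  edges <- purrr::map_dfr(tree, function(uv) {
    sel <- (pairs$receptor == uv[1] & pairs$ligand == uv[2]) |
      (pairs$receptor == uv[2] & pairs$ligand == uv[1])
    pr <- pairs[sel, , drop = FALSE][1, ]
    ids <- decoys$decoy_id[decoys$receptor == pr$receptor &
                             decoys$ligand == pr$ligand]
    tibble::tibble(receptor = pr$receptor, ligand = pr$ligand,
                   decoy_id = ids[sample.int(length(ids), 1L)])
  })
  model_tree(chains, edges)
}

#' Realize a spanning-tree model into coordinates
#'
#' The lexicographically smallest chain is the root and keeps its library
#' coordinates; the tree is traversed outward, composing each edge's decoy
#' transform (inverted when the edge is walked ligand-to-receptor). Models
#' realized this way share the root frame, so realized structures are
#' directly comparable without superposition.
#'
#' @param model A `model_tree`.
#' @param subunits A `cpx_structure` with library coordinates of every chain.
#' @param decoys Decoy table providing the edge transforms.
#' @return A `cpx_structure`.
#' @export
realize <- function(model, subunits, decoys) {
  placements <- model_placements(model, decoys)
  parts <- lapply(model$chains, function(ch) {
    at <- subunits[subunits$chain == ch, , drop = FALSE]
    if (nrow(at) == 0L) stop("no library coordinates for chain ", ch)
    xyz <- transform_apply(placements[[ch]], as.matrix(at[, c("x", "y", "z")]))
    at$x <- xyz[, 1L]; at$y <- xyz[, 2L]; at$z <- xyz[, 3L]
    at
  })
  new_structure(dplyr::bind_rows(parts))
}

# per-chain global transforms implied by a model's tree
model_placements <- function(model, decoys) {
  e <- model$edges
  key <- paste(decoys$receptor, decoys$ligand, decoys$decoy_id)
  tr_of <- function(k) {
    i <- match(k, key)
    if (is.na(i)) stop("missing decoy ", gsub(" ", "/", k))
    row_transform(decoys, i)
  }
  root <- model$chains[1L]
  placements <- list()
  placements[[root]] <- transform_identity()
  todo <- root
  remaining <- seq_len(nrow(e))
  while (length(todo)) {
    ch <- todo[1L]; todo <- todo[-1L]
    hit <- remaining[e$receptor[remaining] == ch | e$ligand[remaining] == ch]
    for (k in hit) {
      other <- if (e$receptor[k] == ch) e$ligand[k] else e$receptor[k]
      t_edge <- tr_of(paste(e$receptor[k], e$ligand[k], e$decoy_id[k]))
      placements[[other]] <- if (e$receptor[k] == ch) {
        transform_compose(placements[[ch]], t_edge)
      } else {
        transform_compose(placements[[ch]], transform_invert(t_edge))
      }
      todo <- c(todo, other)
    }
    remaining <- setdiff(remaining, hit)
  }
  if (length(placements) != length(model$chains)) stop("tree is not connected")
  placements
}

#' Count inter-chain atomic clashes
#'
#' Number of heavy-atom pairs from different chains closer than `distance`
#' (default 3 Angstrom). Models exceeding a clash cap are discarded during
#' the genetic algorithm.
#'
#' @param structure A `cpx_structure`.
#' @param distance Clash distance in Angstrom.
#' @return Integer count.
#' @export
clash_count <- function(structure, distance = 3.0) {
  geom <- pair_geometry(structure, clash_distance = distance)
  geom$clashes
}

#' Default soft-sphere fitness for GA models (lower is better)
#'
#' A repulsion term, the sum of `(r0 - d)^2` over inter-chain atom pairs
#' closer than `r0`, minus a contact reward, the count of inter-chain
#' residue pairs within `contact_cutoff`. Compact, clash-free assemblies
#' with large, well-packed interfaces score low. The repulsion onset of
#' 4.4 Angstrom is a residue-bead soft-sphere diameter (non-bonded
#' C-alpha/C-alpha separations in folded proteins cluster near 4.5-5
#' Angstrom), so interfaces packed tighter than a physical residue contact
#' are penalised while regular interfaces are not.
#'
#' @param structure A `cpx_structure`.
#' @param r0 Repulsion onset distance (Angstrom).
#' @param w_repulsion,w_contact Term weights.
#' @param contact_cutoff Contact distance (Angstrom).
#' @return Numeric fitness (lower is better).
#' @export
default_fitness <- function(structure, r0 = 4.4, w_repulsion = 3,
                            w_contact = 1, contact_cutoff = 5.0) {
  geom <- pair_geometry(structure, r0 = r0, contact_cutoff = contact_cutoff)
  w_repulsion * geom$repulsion - w_contact * geom$contacts
}

# one pass over all inter-chain atom pairs: clash count, soft-sphere
# repulsion, contact residue-pair count
pair_geometry <- function(structure, clash_distance = 3.0, r0 = 4.4,
                          contact_cutoff = 5.0) {
  chains <- unique(structure$chain)
  clashes <- 0L
  repulsion <- 0
  contacts <- 0L
  if (length(chains) < 2L) return(list(clashes = 0L, repulsion = 0, contacts = 0L))
  per <- lapply(chains, function(ch) {
    rows <- structure$chain == ch
    list(xyz = as.matrix(structure[rows, c("x", "y", "z")]),
         res = paste0(structure$res_id[rows], structure$ins[rows]))
  })
  names(per) <- chains
  for (i in seq_along(chains)[-length(chains)]) {
    for (j in (i + 1L):length(chains)) {
      a <- per[[i]]; b <- per[[j]]
      d2 <- cross_dist2(a$xyz, b$xyz)
      clashes <- clashes + sum(d2 < clash_distance^2)
      close <- d2 < r0^2
      if (any(close)) {
        repulsion <- repulsion + sum((r0 - sqrt(d2[close]))^2)
      }
      hit <- which(d2 < contact_cutoff^2, arr.ind = TRUE)
      if (nrow(hit)) {
        contacts <- contacts +
          length(unique(paste(a$res[hit[, 1L]], b$res[hit[, 2L]])))
      }
    }
  }
  list(clashes = as.integer(clashes), repulsion = repulsion,
       contacts = as.integer(contacts))
}

#' Mutate a spanning-tree model
#'
#' One uniformly random edge is deleted, splitting the tree in two; a new
#' edge with a uniformly random decoy is added between a uniformly random
#' available pair spanning the cut. If no pair spans the cut, another edge
#' is tried; if no deletion admits a replacement the input is returned
#' unchanged with a warning. The input model is never modified.
#'
#' @param model A `model_tree`.
#' @param decoys Decoy table.
#' @return A new `model_tree`.
#' @export
mutate_model <- function(model, decoys) {
  e <- model$edges
  pairs <- unique(decoys[c("receptor", "ligand")])
  for (del in sample.int(nrow(e))) {
    rest <- e[-del, , drop = FALSE]
    comps <- graph_components(model$chains, tibble::tibble(
      chain_a = rest$receptor, chain_b = rest$ligand))
    side_a <- comps[[1L]]
    spanning <- (pairs$receptor %in% side_a) != (pairs$ligand %in% side_a)
    if (!any(spanning)) next
    cand <- pairs[spanning, , drop = FALSE]
    pick <- cand[sample.int(nrow(cand), 1L), ]
    ids <- decoys$decoy_id[decoys$receptor == pick$receptor &
                             decoys$ligand == pick$ligand]
    new_edge <- tibble::tibble(receptor = pick$receptor, ligand = pick$ligand,
                               decoy_id = ids[sample.int(length(ids), 1L)])
    return(model_tree(model$chains, dplyr::bind_rows(rest, new_edge)))
  }
  warning("no available pair spans any cut; model returned unchanged")
  model
}

#' GA configuration
#'
#' Defaults follow the published multimeric-docking protocol: population
#' M = 200, 2M = 400 mutations per generation, clash distance 3 Angstrom
#' with a cap of 200 clashes, 2000 generations plus a 1000-generation
#' extension when not converged, and 10 Angstrom model clustering.
#' Convergence means the best fitness improved by less than `tol` over the
#' trailing `window` generations. [ga_config_desk()] is a small profile for
#' interactive work and testing.
#'
#' @param population Population size M.
#' @param mutations Mutations per generation (default 2M).
#' @param clash_distance,clash_max Clash filter.
#' @param generations,extension Main and extension generation counts.
#' @param cluster_cutoff Model-clustering RMSD cutoff (Angstrom).
#' @param window,tol Convergence window (generations) and tolerance.
#' @param seed RNG seed for the run (integer or NULL).
#' @return A `ga_config` list.
#' @export
ga_config <- function(population = 200L, mutations = 2L * population,
                      clash_distance = 3.0, clash_max = 200L,
                      generations = 2000L, extension = 1000L,
                      cluster_cutoff = 10.0, window = 200L, tol = 1e-6,
                      seed = NULL) {
  cfg <- list(population = as.integer(population),
              mutations = as.integer(mutations),
              clash_distance = clash_distance,
              clash_max = as.integer(clash_max),
              generations = as.integer(generations),
              extension = as.integer(extension),
              cluster_cutoff = cluster_cutoff,
              window = as.integer(window), tol = tol,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  stopifnot(cfg$population > 0, cfg$mutations >= 1L, cfg$clash_distance > 0,
            cfg$clash_max >= 0L, cfg$generations > 0L, cfg$extension >= 0L,
            cfg$cluster_cutoff > 0, cfg$window >= 1L, cfg$tol >= 0)
  structure(cfg, class = "ga_config")
}

#' @rdname ga_config
#' @export
ga_config_desk <- function(population = 20L, mutations = 40L,
                           generations = 40L, extension = 20L,
                           window = 10L, clash_max = 20L,
                           cluster_cutoff = 0.5, seed = NULL, ...) {
  ga_config(population = population, mutations = mutations,
            generations = generations, extension = extension,
            window = window, clash_max = clash_max,
            cluster_cutoff = cluster_cutoff, seed = seed, ...)
}

#' Leader-cluster a set of models by realized-structure RMSD
#'
#' Models are visited in fitness order; each representative absorbs models
#' whose realized C-alpha RMSD (identity chain assignment, shared root
#' frame) is within `cutoff`.
#'
#' @param models List of `model_tree` objects.
#' @param fitness Numeric vector of fitness values (lower better).
#' @param subunits,decoys Library structure and decoy table for realization.
#' @param cutoff RMSD cutoff (Angstrom).
#' @return List with integer indices `representatives` and `absorbed`.
#' @export
cluster_models <- function(models, fitness, subunits, decoys, cutoff = 10.0) {
  stopifnot(cutoff > 0, length(models) == length(fitness))
  coords <- lapply(models, function(m) {
    s <- realize(m, subunits, decoys)
    as.matrix(s[s$atom == "CA", c("x", "y", "z")])
  })
  cluster_models_coords(coords, fitness, cutoff)
}

cluster_models_coords <- function(coords, fitness, cutoff) {
  ord <- order(fitness)
  reps <- integer()
  absorbed <- integer()
  for (i in ord) {
    if (length(reps)) {
      d <- vapply(reps, function(j) {
        sqrt(mean(rowSums((coords[[i]] - coords[[j]])^2)))
      }, numeric(1))
      if (any(d <= cutoff)) {
        absorbed <- c(absorbed, i)
        next
      }
    }
    reps <- c(reps, i)
  }
  list(representatives = reps, absorbed = absorbed)
}

#' Run the spanning-tree genetic algorithm
#'
#' Each generation: mutants are generated from uniformly chosen parents,
#' mutants whose realized structure exceeds the clash cap are discarded,
#' parents and surviving mutants are pooled (elitism: the best model can
#' never be lost), the pool is leader-clustered to remove redundancy,
#' refilled at random from absorbed members when below M, and the best M by
#' fitness survive. After `generations` generations the run stops if the
#' best fitness improved by less than `tol` over the trailing `window`
#' generations, otherwise it continues for `extension` more.
#'
#' @param config A [ga_config()].
#' @param chains Chain labels of the target complex.
#' @param subunits Library `cpx_structure` with all chains.
#' @param decoys Decoy table (typically clustered, see [cluster_decoys()]).
#' @param fitness Function `structure -> numeric` (lower better); default
#'   [default_fitness()].
#' @return A `ga_run` record: config, seed, per-generation populations
#'   (edge tables + fitness), convergence flag and final generation index.
#' @export
run_ga <- function(config, chains, subunits, decoys,
                   fitness = default_fitness) {
  if (!is.null(config$seed)) set.seed(config$seed)
  chains <- chain_sort(unique(chains))
  index <- ga_index(chains, subunits, decoys)
  custom_fitness <- !identical(fitness, default_fitness)
  cache <- new.env(parent = emptyenv())
  evaluate <- function(edges) {
    sig <- edge_signature(edges)
    hit <- cache[[sig]]
    if (!is.null(hit)) return(hit)
    val <- fast_eval(edges, index, clash_distance = config$clash_distance)
    if (custom_fitness) {
      val$fitness <- fitness(realize(model_tree(chains, edges),
                                     subunits, decoys))
    }
    cache[[sig]] <- val
    val
  }

  # initial population of valid (clash-filtered) random models
  population <- list()
  tries <- 0L
  while (length(population) < config$population) {
    tries <- tries + 1L
    if (tries > 100L * config$population) {
      stop("could not build a clash-valid initial population (decoy exhaustion)")
    }
    e <- fast_random_edges(index)
    if (evaluate(e)$clashes <= config$clash_max) {
      population[[length(population) + 1L]] <- e
    }
  }

  record <- list()
  best_trace <- numeric()
  one_generation <- function(population) {
    mutants <- list()
    for (k in seq_len(config$mutations)) {
      parent <- population[[sample.int(length(population), 1L)]]
      mt <- fast_mutate_edges(parent, index)
      if (evaluate(mt)$clashes <= config$clash_max) {
        mutants[[length(mutants) + 1L]] <- mt
      }
    }
    pool <- c(population, mutants)
    fit <- vapply(pool, function(e) evaluate(e)$fitness, numeric(1))
    coords <- lapply(pool, function(e) evaluate(e)$coords)
    cl <- cluster_models_coords(coords, fit, config$cluster_cutoff)
    keep <- cl$representatives
    if (length(keep) < config$population && length(cl$absorbed)) {
      refill <- sample(cl$absorbed,
                       min(config$population - length(keep),
                           length(cl$absorbed)))
      keep <- c(keep, refill)
    }
    keep <- keep[order(fit[keep])]
    keep <- keep[seq_len(min(config$population, length(keep)))]
    pool[keep]
  }
  run_block <- function(population, n_gen) {
    for (g in seq_len(n_gen)) {
      population <- one_generation(population)
      fit <- vapply(population, function(e) evaluate(e)$fitness, numeric(1))
      record[[length(record) + 1L]] <<- list(models = population,
                                             fitness = fit)
      best_trace[length(best_trace) + 1L] <<- min(fit)
    }
    population
  }
  population <- run_block(population, config$generations)
  converged <- has_converged(best_trace, config$window, config$tol)
  if (!converged && config$extension > 0L) {
    population <- run_block(population, config$extension)
    converged <- has_converged(best_trace, config$window, config$tol)
  }
  structure(list(config = config, seed = config$seed, chains = chains,
                 generations = record, converged = converged,
                 final_generation = length(record)),
            class = "ga_run")
}

# ---- fast internal GA engine -------------------------------------------
# Edge sets are plain data.frames (receptor, ligand, decoy_id); subunit
# coordinates, decoy transforms and pair adjacency are pre-indexed once per
# run. Produces results identical to the tibble-based public API.

ga_index <- function(chains, subunits, decoys) {
  lib <- lapply(stats::setNames(chains, chains), function(ch) {
    rows <- subunits$chain == ch
    if (!any(rows)) stop("no library coordinates for chain ", ch)
    list(xyz = as.matrix(subunits[rows, c("x", "y", "z")]),
         res = paste0(subunits$res_id[rows], subunits$ins[rows]),
         ca = which(subunits$atom[rows] == "CA"))
  })
  pair_df <- unique(as.data.frame(decoys[c("receptor", "ligand")]))
  adj <- lapply(stats::setNames(chains, chains), function(ch) {
    c(pair_df$ligand[pair_df$receptor == ch],
      pair_df$receptor[pair_df$ligand == ch])
  })
  if (length(graph_components(chains, tibble::tibble(
    chain_a = pair_df$receptor, chain_b = pair_df$ligand))) != 1L) {
    stop("pair graph is disconnected: no spanning tree exists")
  }
  ids <- lapply(seq_len(nrow(pair_df)), function(k) {
    decoys$decoy_id[decoys$receptor == pair_df$receptor[k] &
                      decoys$ligand == pair_df$ligand[k]]
  })
  names(ids) <- paste(pair_df$receptor, pair_df$ligand)
  transforms <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(decoys))) {
    tr <- row_transform(decoys, i)
    transforms[[paste(decoys$receptor[i], decoys$ligand[i],
                      decoys$decoy_id[i])]] <-
      list(R = tr$rotation, t = tr$translation)
  }
  list(chains = chains, lib = lib, pair_df = pair_df, adj = adj,
       decoy_ids = ids, transforms = transforms)
}

edge_signature <- function(edges) {
  ord <- order(edges$receptor, edges$ligand, edges$decoy_id)
  paste(edges$receptor[ord], edges$ligand[ord], edges$decoy_id[ord],
        sep = "/", collapse = ";")
}

fast_random_edges <- function(index) {
  chains <- index$chains
  current <- sample(chains, 1L)
  visited <- current
  rec <- lig <- character()
  id <- integer()
  while (length(visited) < length(chains)) {
    nxt <- sample(index$adj[[current]], 1L)
    if (!nxt %in% visited) {
      visited <- c(visited, nxt)
      key <- if (paste(current, nxt) %in% names(index$decoy_ids)) {
        c(current, nxt)
      } else c(nxt, current)
      ids <- index$decoy_ids[[paste(key[1], key[2])]]
      rec <- c(rec, key[1]); lig <- c(lig, key[2])
      id <- c(id, ids[sample.int(length(ids), 1L)])
    }
    current <- nxt
  }
  data.frame(receptor = rec, ligand = lig, decoy_id = id,
             stringsAsFactors = FALSE)
}

fast_mutate_edges <- function(edges, index) {
  n_edge <- nrow(edges)
  for (del in sample.int(n_edge)) {
    rest <- edges[-del, , drop = FALSE]
    side_a <- edge_component(index$chains[1L], rest, index$chains)
    pd <- index$pair_df
    spanning <- (pd$receptor %in% side_a) != (pd$ligand %in% side_a)
    # the deleted edge itself always spans its cut, so a pair always exists
    cand <- which(spanning)
    pick <- cand[sample.int(length(cand), 1L)]
    ids <- index$decoy_ids[[paste(pd$receptor[pick], pd$ligand[pick])]]
    out <- rbind(rest, data.frame(receptor = pd$receptor[pick],
                                  ligand = pd$ligand[pick],
                                  decoy_id = ids[sample.int(length(ids), 1L)],
                                  stringsAsFactors = FALSE))
    rownames(out) <- NULL
    return(out)
  }
}

# chains reachable from `start` over an edge data.frame
edge_component <- function(start, edges, chains) {
  seen <- start
  repeat {
    hit <- edges$receptor %in% seen | edges$ligand %in% seen
    nxt <- unique(c(edges$receptor[hit], edges$ligand[hit]))
    nxt <- setdiff(nxt, seen)
    if (!length(nxt)) return(seen)
    seen <- c(seen, nxt)
  }
}

fast_placements <- function(edges, index) {
  chains <- index$chains
  placements <- list()
  placements[[chains[1L]]] <- list(R = diag(3), t = c(0, 0, 0))
  todo <- chains[1L]
  remaining <- seq_len(nrow(edges))
  while (length(todo)) {
    ch <- todo[1L]; todo <- todo[-1L]
    hit <- remaining[edges$receptor[remaining] == ch |
                       edges$ligand[remaining] == ch]
    for (k in hit) {
      tr <- index$transforms[[paste(edges$receptor[k], edges$ligand[k],
                                    edges$decoy_id[k])]]
      g <- placements[[ch]]
      if (edges$receptor[k] == ch) {
        other <- edges$ligand[k]
        placements[[other]] <- list(R = g$R %*% tr$R,
                                    t = as.numeric(g$R %*% tr$t) + g$t)
      } else {
        other <- edges$receptor[k]
        rt <- t(tr$R)
        placements[[other]] <- list(
          R = g$R %*% rt,
          t = g$t - as.numeric((g$R %*% rt) %*% tr$t))
      }
      todo <- c(todo, other)
    }
    remaining <- setdiff(remaining, hit)
  }
  placements
}

fast_eval <- function(edges, index, clash_distance = 3.0, r0 = 4.4,
                      contact_cutoff = 5.0) {
  placements <- fast_placements(edges, index)
  chains <- index$chains
  coords <- lapply(chains, function(ch) {
    g <- placements[[ch]]
    sweep(index$lib[[ch]]$xyz %*% t(g$R), 2L, g$t, `+`)
  })
  names(coords) <- chains
  clashes <- 0L
  repulsion <- 0
  contacts <- 0L
  for (i in seq_along(chains)[-length(chains)]) {
    for (j in (i + 1L):length(chains)) {
      d2 <- cross_dist2(coords[[i]], coords[[j]])
      clashes <- clashes + sum(d2 < clash_distance^2)
      close <- d2 < r0^2
      if (any(close)) repulsion <- repulsion + sum((r0 - sqrt(d2[close]))^2)
      hit <- which(d2 < contact_cutoff^2, arr.ind = TRUE)
      if (nrow(hit)) {
        contacts <- contacts + length(unique(
          paste(index$lib[[chains[i]]]$res[hit[, 1L]],
                index$lib[[chains[j]]]$res[hit[, 2L]])))
      }
      # weights match default_fitness(): w_repulsion = 3, w_contact = 1
    }
  }
  ca <- do.call(rbind, lapply(chains, function(ch) {
    coords[[ch]][index$lib[[ch]]$ca, , drop = FALSE]
  }))
  list(clashes = as.integer(clashes),
       fitness = 3 * repulsion - contacts, coords = ca)
}

has_converged <- function(best_trace, window, tol) {
  n <- length(best_trace)
  if (n < window + 1L) return(FALSE)
  (best_trace[n - window] - best_trace[n]) < tol
}

#' @export
print.ga_run <- function(x, ...) {
  fit <- x$generations[[x$final_generation]]$fitness
  cat("<ga_run> ", x$final_generation, " generations, final population ",
      length(fit), ", best fitness ", signif(min(fit), 6),
      if (x$converged) " (converged)" else " (not converged)", "\n", sep = "")
  invisible(x)
}

#' Serialize / restore a GA run record as JSON
#'
#' The record (config, seed, per-generation edge lists and fitness) is
#' written as a documented JSON file and restores to an identical `ga_run`.
#'
#' @param run A `ga_run`.
#' @param path File path.
#' @export
ga_run_write <- function(run, path) {
  payload <- list(
    config = unclass(run$config),
    seed = run$seed,
    chains = run$chains,
    converged = run$converged,
    final_generation = run$final_generation,
    generations = lapply(run$generations, function(g) {
      list(fitness = g$fitness,
           models = lapply(g$models, function(m) {
             list(receptor = m$receptor, ligand = m$ligand,
                  decoy_id = m$decoy_id)
           }))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname ga_run_write
#' @export
ga_run_read <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg <- do.call(ga_config, p$config[setdiff(names(p$config), character())])
  gens <- lapply(p$generations, function(g) {
    list(models = lapply(g$models, function(m) {
      data.frame(receptor = unlist(m$receptor), ligand = unlist(m$ligand),
                 decoy_id = as.integer(unlist(m$decoy_id)),
                 stringsAsFactors = FALSE)
    }),
    fitness = as.numeric(unlist(g$fitness)))
  })
  structure(list(config = cfg, seed = p$seed,
                 chains = as.character(unlist(p$chains)), generations = gens,
                 converged = isTRUE(p$converged),
                 final_generation = as.integer(p$final_generation)),
            class = "ga_run")
}

#' @importFrom generics glance
#' @export
generics::glance

#' Per-generation summary of a GA run
#' @param x A `ga_run`.
#' @param ... Unused.
#' @return Tibble `generation`, `population`, `best_fitness`,
#'   `mean_fitness`.
#' @export
tidy.ga_run <- function(x, ...) {
  tibble::tibble(
    generation = seq_along(x$generations),
    population = vapply(x$generations, function(g) length(g$fitness),
                        integer(1)),
    best_fitness = vapply(x$generations, function(g) min(g$fitness),
                          numeric(1)),
    mean_fitness = vapply(x$generations, function(g) mean(g$fitness),
                          numeric(1))
  )
}

#' One-row summary of a GA run
#' @param x A `ga_run`.
#' @param ... Unused.
#' @export
glance.ga_run <- function(x, ...) {
  fit <- x$generations[[x$final_generation]]$fitness
  tibble::tibble(generations = x$final_generation,
                 converged = x$converged,
                 final_population = length(fit),
                 best_fitness = min(fit))
}

#' Fitness trace of a GA run
#' @param object A `ga_run`.
#' @param ... Unused.
#' @export
autoplot.ga_run <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$best_fitness,
                                    colour = "best")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_fitness,
                                    colour = "mean")) +
    ggplot2::labs(x = "generation", y = "fitness (lower is better)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
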