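#' Synthetic benchmark complexes with planted assembly orders
#'
#' The generator builds rigid pseudo-atom complexes whose pairwise
#' interface strengths are designed exactly: each designed interface
#' contributes a facing grid of beads, one bead pair per contact, 4.5
#' Angstrom apart with 6 Angstrom lateral spacing, so the contact count at
#' the 5 Angstrom criterion equals the designed number. Each chain also
#' carries a compact core block, padded so that chains of the same identity
#' class have identical sequences. The planted assembly order is the greedy
#' largest-transition pathway on the designed contact counts, i.e. the
#' order a subcomplex-buried-surface argument would predict from the
#' designed interface strengths.
#'
#' @param name Fixture name.
#' @param chains Chain labels.
#' @param classes Named character: chain -> class label.
#' @param interfaces Tibble with columns `a`, `b`, `contacts` (designed
#'   contacting residue pairs per interface).
#' @param centers Matrix of chain-centre coordinates (rows match `chains`).
#' @return A `toy_complex_spec` list.
#' @export
toy_complex_spec <- function(name, chains, classes, interfaces, centers) {
  stopifnot(length(chains) >= 3L, nrow(centers) == length(chains),
            all(c(interfaces$a, interfaces$b) %in% chains),
            all(interfaces$contacts >= 1L),
            all(chains %in% names(classes)))
  structure(list(name = name, chains = chains, classes = classes,
                 interfaces = tibble::as_tibble(interfaces),
                 centers = centers),
            class = "toy_complex_spec")
}

aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

# deterministic pseudo-sequence for an identity class
class_residues <- function(class_index, length) {
  aa3[((seq_len(length) - 1L) * 7L + class_index * 3L) %% 20L + 1L]
}

# fixed lattice of core-bead offsets (4x4x4, 5 A spacing), centred and
# ordered inside-out so small cores stay compact; the open spacing keeps
# accidental interfaces of random landings small
core_lattice <- function() {
  g <- expand.grid(x = 0:3, y = 0:3, z = 0:3)
  m <- as.matrix(g) * 5.0
  m <- sweep(m, 2L, colMeans(m), `-`)
  m[order(rowSums(m^2)), , drop = FALSE]
}

# facing bead grids for one designed interface
interface_grids <- function(pa, pb, contacts, gap = 4.5, spacing = 6.0,
                            spacing_w = 4.2) {
  u <- (pb - pa) / sqrt(sum((pb - pa)^2))
  # orthonormal basis perpendicular to u
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * u) * u
  v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  mid <- (pa + pb) / 2
  ncol <- ceiling(sqrt(contacts))
  k <- seq_len(contacts) - 1L
  col <- k %% ncol
  row <- k %/% ncol
  lateral <- outer(col - (ncol - 1) / 2, v * spacing) +
    outer(row - (max(row)) / 2, w * spacing_w)
  list(a = sweep(lateral, 2L, mid - (gap / 2) * u, `+`),
       b = sweep(lateral, 2L, mid + (gap / 2) * u, `+`))
}

#' Build a toy complex from a spec
#'
#' Deterministic (no randomness): geometry follows the spec exactly. The
#' designed contact counts, the absence of contacts between undesigned
#' pairs and the absence of clashes below 3 Angstrom are verified after
#' construction.
#'
#' @param spec A [toy_complex_spec()].
#' @return List with `structure` (a `cpx_structure`), `planted` (the
#'   planted `assembly_pathway`), `classes` (tibble `chain`/`class`) and
#'   `design` (the interface table).
#' @export
build_toy_complex <- function(spec) {
  chains <- spec$chains
  beads <- stats::setNames(vector("list", length(chains)), chains)
  for (k in seq_len(nrow(spec$interfaces))) {
    a <- spec$interfaces$a[k]; b <- spec$interfaces$b[k]
    gr <- interface_grids(spec$centers[match(a, chains), ],
                          spec$centers[match(b, chains), ],
                          spec$interfaces$contacts[k])
    beads[[a]] <- rbind(beads[[a]], gr$a)
    beads[[b]] <- rbind(beads[[b]], gr$b)
  }
  # pad with core beads so all chains of a class share one length
  core <- core_lattice()
  n_iface <- vapply(beads, function(x) if (is.null(x)) 0L else nrow(x),
                    integer(1))
  class_of <- spec$classes[chains]
  target <- vapply(chains, function(ch) {
    max(n_iface[names(class_of)[class_of == class_of[[ch]]]]) + 12L
  }, integer(1))
  class_levels <- sort(unique(unname(class_of)))
  atoms <- list()
  serial <- 0L
  for (ch in chains) {
    n_core <- target[[ch]] - n_iface[[ch]]
    ctr <- spec$centers[match(ch, chains), ]
    xyz <- rbind(beads[[ch]], sweep(core[seq_len(n_core), , drop = FALSE],
                                    2L, ctr, `+`))
    n <- nrow(xyz)
    cls_idx <- match(class_of[[ch]], class_levels)
    atoms[[ch]] <- tibble::tibble(
      chain = ch, serial = serial + seq_len(n), atom = "CA", element = "C",
      res_name = class_residues(cls_idx, n), res_id = seq_len(n), ins = "",
      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L])
    serial <- serial + n
  }
  s <- new_structure(dplyr::bind_rows(atoms))
  verify_toy_design(s, spec)
  planted <- greedy_counts_pathway(chains, spec$interfaces)
  list(structure = s, planted = planted,
       classes = tibble::tibble(chain = chains,
                                class = unname(class_of)),
       design = spec$interfaces, name = spec$name)
}

verify_toy_design <- function(s, spec) {
  design_key <- paste(pmin(spec$interfaces$a, spec$interfaces$b),
                      pmax(spec$interfaces$a, spec$interfaces$b))
  combos <- utils::combn(spec$chains, 2L)
  for (k in seq_len(ncol(combos))) {
    a <- combos[1L, k]; b <- combos[2L, k]
    n <- nrow(contact_residue_pairs(s, a, b, 5.0))
    want <- spec$interfaces$contacts[match(paste(min(a, b), max(a, b)),
                                           design_key)]
    want <- if (is.na(want)) 0L else want
    if (n != want) {
      stop("fixture ", spec$name, ": designed ", want, " contacts for ",
           a, "-", b, " but realised ", n)
    }
  }
  if (clash_count(s, 3.0) != 0L) {
    stop("fixture ", spec$name, " has inter-chain clashes below 3 A")
  }
  invisible(s)
}

# greedy largest-transition pathway on designed contact counts; ties broken
# by lexicographic component keys (the planted assembly order)
greedy_counts_pathway <- function(chains, interfaces) {
  strength <- function(ca, cb) {
    sel <- (interfaces$a %in% ca & interfaces$b %in% cb) |
      (interfaces$a %in% cb & interfaces$b %in% ca)
    sum(interfaces$contacts[sel])
  }
  current <- as.list(chain_sort(chains))
  events <- list()
  while (length(current) > 1L) {
    best <- NULL
    nc <- length(current)
    for (i in 1:(nc - 1L)) {
      for (j in (i + 1L):nc) {
        st <- strength(current[[i]], current[[j]])
        if (st == 0) next
        ka <- component_key(current[[i]]); kb <- component_key(current[[j]])
        key <- paste(min(ka, kb), max(ka, kb))
        if (is.null(best) || st > best$st ||
            (st == best$st && key < best$key)) {
          best <- list(i = i, j = j, st = st, key = key)
        }
      }
    }
    if (is.null(best)) stop("designed interface graph is disconnected")
    ev <- list(a = current[[best$i]], b = current[[best$j]], edge = NULL)
    current <- c(current[-c(best$i, best$j)],
                 list(chain_sort(c(ev$a, ev$b))))
    events[[length(events) + 1L]] <- ev
  }
  assembly_pathway(chain_sort(chains), events = events)
}

#' Parameters for synthetic decoy and score generation
#'
#' Per contacting pair the generator emits one exact native pose (optional),
#' `n_near` near-native poses (rotation noise `sigma_rot_deg` about the
#' ligand centroid plus translation noise `sigma_trans`), and `n_far`
#' random-orientation poses slid onto the receptor surface (random fake
#' interfaces). Scores emulate a binding energy (lower is better). With the
#' default `"energy"` model, native and near poses are scored from their
#' real geometry, `S = alpha * ligand_RMSD - gamma * contacts(pose) + eps`
#' with `eps ~ Normal(0, sigma_score)`, while far poses are scored against
#' a common background of fake-interface sizes,
#' `S = alpha * ligand_RMSD - gamma * f_j + eps` with
#' `f_j = background_max * (j - 0.5) / n_far`: every pair sees the same
#' ladder of competing pose energies. This implements the population/rank
#' argument directly — the deeper a pair's native funnel (more designed
#' contacts), the fewer background poses outscore it, so its score rank
#' orders by interface strength. The `"rmsd"` model instead scores every
#' pose as `alpha * ligand_RMSD + eps` (pure pose-quality ranking).
#'
#' @param n_near,n_far Decoy counts per pair.
#' @param sigma_trans Positional noise (Angstrom).
#' @param sigma_rot_deg Rotational noise (degrees).
#' @param alpha,gamma Score-model coefficients.
#' @param sigma_score Score noise standard deviation.
#' @param background_max Largest fake-interface size of the common score
#'   background (contact-pair units).
#' @param score_model `"energy"` or `"rmsd"`.
#' @param include_native Include the exact native pose as decoy 1?
#' @return A `synthetic_decoy_params` list.
#' @export
synthetic_decoy_params <- function(n_near = 6L, n_far = 36L,
                                   sigma_trans = 0.5, sigma_rot_deg = 3,
                                   alpha = 0.05, gamma = 1, sigma_score = 1,
                                   background_max = 14,
                                   score_model = c("energy", "rmsd"),
                                   include_native = TRUE) {
  score_model <- match.arg(score_model)
  stopifnot(n_near + n_far >= 2L, alpha > 0, sigma_score >= 0,
            sigma_trans >= 0, sigma_rot_deg >= 0, background_max > 0)
  structure(list(n_near = as.integer(n_near), n_far = as.integer(n_far),
                 sigma_trans = sigma_trans, sigma_rot_deg = sigma_rot_deg,
                 alpha = alpha, gamma = gamma, sigma_score = sigma_score,
                 background_max = background_max,
                 score_model = score_model,
                 include_native = isTRUE(include_native)),
            class = "synthetic_decoy_params")
}

#' Generate pairwise decoys and scores for a toy complex
#'
#' Uses the current RNG stream (seed with `set.seed()` for reproducible
#' decoy sets).
#'
#' @param toy Output of [build_toy_complex()] (or a `cpx_structure` plus
#'   `interfaces`).
#' @param params [synthetic_decoy_params()].
#' @param interfaces Designed interface table; defaults to `toy$design`.
#' @return List with `decoys` (decoy table) and `scores` (score table with
#'   one column named after the score model).
#' @export
generate_decoys <- function(toy, params = synthetic_decoy_params(),
                            interfaces = NULL) {
  s <- if (inherits(toy, "cpx_structure")) toy else toy$structure
  if (is.null(interfaces)) interfaces <- toy$design
  rows <- list()
  for (k in seq_len(nrow(interfaces))) {
    pair <- chain_sort(c(interfaces$a[k], interfaces$b[k]))
    receptor <- pair[1L]; ligand <- pair[2L]
    lig_xyz <- as.matrix(s[s$chain == ligand, c("x", "y", "z")])
    rec_xyz <- as.matrix(s[s$chain == receptor, c("x", "y", "z")])
    lig_ctr <- colMeans(lig_xyz)
    rec_ctr <- colMeans(rec_xyz)
    r_lig <- sqrt(max(rowSums(sweep(lig_xyz, 2L, lig_ctr, `-`)^2)))
    r_rec <- sqrt(max(rowSums(sweep(rec_xyz, 2L, rec_ctr, `-`)^2)))
    transforms <- list()
    if (params$include_native) {
      transforms[[length(transforms) + 1L]] <- transform_identity()
    }
    for (i in seq_len(params$n_near)) {
      axis <- stats::rnorm(3)
      angle <- stats::rnorm(1, 0, params$sigma_rot_deg * pi / 180)
      rot <- rotation_axis_angle(axis, angle)
      shift <- stats::rnorm(3, 0, params$sigma_trans)
      # rotate about the ligand centroid, then translate
      transforms[[length(transforms) + 1L]] <- rigid_transform(
        rot, lig_ctr - as.numeric(rot %*% lig_ctr) + shift)
    }
    for (i in seq_len(params$n_far)) {
      rot <- random_rotation()
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      touch <- stats::runif(1, 3.3, 4.7)
      posed0 <- lig_xyz %*% t(rot)
      ctr0 <- as.numeric(rot %*% lig_ctr)
      # slide the ligand along `dir` towards the receptor until the closest
      # inter-atom distance equals `touch` (bisection): random surface
      # landings with realistic fake interfaces
      lo <- 0
      hi <- r_rec + r_lig + 6
      for (it in 1:30) {
        mid <- (lo + hi) / 2
        shift <- rec_ctr + dir * mid - ctr0
        dmin <- sqrt(min(cross_dist2(
          sweep(posed0, 2L, shift, `+`), rec_xyz)))
        if (dmin < touch) lo <- mid else hi <- mid
      }
      target <- rec_ctr + dir * hi
      transforms[[length(transforms) + 1L]] <- rigid_transform(
        rot, target - ctr0)
    }
    rows[[k]] <- decoy_table(receptor, ligand,
                             seq_along(transforms), transforms)
  }
  decoys <- dplyr::bind_rows(rows)
  scores <- synthetic_scores(decoys, s, params)
  list(decoys = decoys, scores = scores)
}

synthetic_scores <- function(decoys, s, params) {
  with_rmsd <- ligand_rmsd(decoys, s)
  depth <- numeric(nrow(decoys))
  n_funnel <- params$n_near + as.integer(params$include_native)
  pair_native <- new.env(parent = emptyenv())
  if (params$score_model == "energy") {
    for (i in order(decoys$decoy_id)) {
      rec <- decoys$receptor[i]; lig <- decoys$ligand[i]
      if (decoys$decoy_id[i] <= n_funnel) {
        # native / near pose: real interface geometry, soft-core penalised
        # (a squeezed pose must not outscore the native one)
        posed <- s[s$chain %in% c(rec, lig), , drop = FALSE]
        sel <- posed$chain == lig
        xyz <- transform_apply(row_transform(decoys, i),
                               as.matrix(posed[sel, c("x", "y", "z")]))
        posed$x[sel] <- xyz[, 1L]; posed$y[sel] <- xyz[, 2L]
        posed$z[sel] <- xyz[, 3L]
        geom <- pair_geometry(posed)
        depth[i] <- geom$contacts - 3 * geom$repulsion
        # the native pose is each pair's energy optimum by construction;
        # perturbed poses cannot out-score it
        key <- paste(rec, lig)
        if (params$include_native) {
          if (decoys$decoy_id[i] == 1L) {
            pair_native[[key]] <- depth[i]
          } else if (!is.null(pair_native[[key]])) {
            depth[i] <- min(depth[i], pair_native[[key]])
          }
        }
      } else {
        # far pose: common fake-interface background ladder
        j <- decoys$decoy_id[i] - n_funnel
        depth[i] <- params$background_max * (j - 0.5) / params$n_far
      }
    }
  }
  value <- params$alpha * with_rmsd$rmsd - params$gamma * depth +
    stats::rnorm(nrow(decoys), 0, params$sigma_score)
  out <- decoys[c("receptor", "ligand", "decoy_id")]
  out[[params$score_model]] <- value
  attr(out, "orientation") <- stats::setNames(TRUE, params$score_model)
  out
}

#' Generate the synthetic benchmark suite
#'
#' Five deterministic fixtures spanning 3 to 6 chains, mirroring the
#' benchmark shapes seen in experimentally characterised assemblies:
#' a hetero-trimer, a homodimer-containing tetramer, a five-chain complex
#' with two homodimeric pairs plus a small late binder, a C5 ring with an
#' apex subunit binding a partial ring (the case that defeats pairwise-BSA
#' ordering), and a dimer-of-dimers with an additional homodimer. Each
#' fixture carries structures, decoys, scores and its planted pathway.
#'
#' @param seed Integer seed driving decoy/score randomness.
#' @param params [synthetic_decoy_params()].
#' @return Named list of fixtures; each has `name`, `structure`, `classes`,
#'   `design`, `planted`, `decoys`, `scores`.
#' @export
generate_benchmark <- function(seed = 1L,
                               params = synthetic_decoy_params()) {
  set.seed(as.integer(seed))
  suite <- lapply(benchmark_specs(), function(spec) {
    toy <- build_toy_complex(spec)
    dec <- generate_decoys(toy, params)
    c(toy, dec)
  })
  stats::setNames(suite, vapply(suite, `[[`, character(1), "name"))
}

circle_centers <- function(n, radius) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(radius * cos(th), radius * sin(th), 0)
}

#' @rdname generate_benchmark
#' @export
benchmark_specs <- function() {
  specs <- list()
  # 3-chain hetero-trimer, strictly ordered interfaces
  ctr <- circle_centers(3, 30)
  specs$trimer <- toy_complex_spec(
    "trimer", c("A", "B", "C"),
    c(A = "A", B = "B", C = "C"),
    tibble::tibble(a = c("A", "B"), b = c("B", "C"), contacts = c(16L, 10L)),
    ctr[c(1, 2, 3), ])
  # 4-chain with two homodimeric pairs (AB + CD joined by a weak bridge)
  ctr <- circle_centers(4, 35)
  specs$tetramer <- toy_complex_spec(
    "tetramer", c("A", "B", "C", "D"),
    c(A = "A", B = "B", C = "A", D = "B"),
    tibble::tibble(a = c("A", "C", "A"), b = c("B", "D", "C"),
                   contacts = c(16L, 12L, 7L)),  # AC bridge is the last step
    ctr[c(2, 1, 3, 4), ])  # circle order B, A, C, D
  # 5-chain: two dimers plus a small late-binding subunit
  ctr <- circle_centers(5, 40)
  specs$pentamer <- toy_complex_spec(
    "pentamer", c("A", "B", "C", "D", "E"),
    c(A = "A", B = "B", C = "A", D = "B", E = "E"),
    tibble::tibble(a = c("A", "C", "D", "A"), b = c("B", "D", "E", "C"),
                   contacts = c(16L, 13L, 10L, 7L)),
    ctr[c(2, 1, 3, 4, 5), ])  # circle order B, A, C, D, E
  # C5 ring (class-identical B..F) with apex A over three ring members
  ring <- circle_centers(5, 35)
  specs$ring_apex <- toy_complex_spec(
    "ring_apex", c("A", "B", "C", "D", "E", "F"),
    c(A = "A", B = "B", C = "B", D = "B", E = "B", F = "B"),
    tibble::tibble(
      a = c("B", "C", "D", "E", "B", "A", "A", "A", "A", "A"),
      b = c("C", "D", "E", "F", "F", "B", "C", "D", "E", "F"),
      contacts = c(12L, 12L, 12L, 12L, 12L, 5L, 5L, 5L, 2L, 2L)),
    rbind(c(11, 22, 34), ring))  # apex above the B-C-D arc
  # 6-chain dimer-of-dimers plus a homodimer
  ctr <- circle_centers(6, 40)
  specs$dimer_of_dimers <- toy_complex_spec(
    "dimer_of_dimers", c("A", "B", "C", "D", "E", "F"),
    c(A = "A", B = "B", C = "A", D = "B", E = "E", F = "E"),
    tibble::tibble(a = c("A", "C", "E", "A", "B"),
                   b = c("B", "D", "F", "C", "E"),
                   contacts = c(16L, 13L, 10L, 8L, 6L)),
    ctr[c(3, 4, 2, 1, 5, 6), ])  # circle order D, C, A, B, E, F
  specs
}

#' Write a benchmark suite to plain-text files
#'
#' Per fixture: `<name>.pdb`, `<name>_decoys.tsv`, `<name>_scores.tsv`;
#' plus a `reference_pathways.tsv` with the planted pathways. Re-reading
#' with the package readers is lossless; for a fixed generator seed the
#' files are byte-identical.
#'
#' @param suite Output of [generate_benchmark()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(suite, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  refs <- data.frame(id = character(), n_chains = integer(),
                     pathway = character())
  for (fx in suite) {
    write_structure(fx$structure, file.path(dir, paste0(fx$name, ".pdb")))
    write_decoy_transforms(fx$decoys,
                           file.path(dir, paste0(fx$name, "_decoys.tsv")))
    write_score_table(fx$scores,
                      file.path(dir, paste0(fx$name, "_scores.tsv")))
    refs <- rbind(refs, data.frame(
      id = fx$name, n_chains = fx$planted$n_chains,
      pathway = format_pathway(fx$planted)))
  }
  utils::write.table(refs, file.path(dir, "reference_pathways.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Run the GA pipeline on a benchmark fixture
#'
#' Ranks the fixture's scores, leader-clusters the decoys (ranks are then
#' recomputed on the clustered set actually searched), runs the GA and
#' returns the blind predictions. Votes are pooled over class-equivalent
#' pathways using the sequence-derived chain classes (a blind quantity).
#'
#' @param fixture One element of [generate_benchmark()].
#' @param config A [ga_config()]; default is the desk-scale profile.
#' @param score Score column name; defaults to the fixture's single score.
#' @param consensus_start First generation for the consensus tally;
#'   defaults to halfway through the run.
#' @param cluster_cutoff Decoy-clustering cutoff (Angstrom).
#' @return List with `run`, `ranking`, `final` and `consensus` predictions.
#' @export
fixture_ga_predictions <- function(fixture, config = ga_config_desk(),
                                   score = NULL, consensus_start = NULL,
                                   cluster_cutoff = 0.5) {
  if (is.null(score)) {
    score <- setdiff(names(fixture$scores),
                     c("receptor", "ligand", "decoy_id"))[1L]
  }
  rank_all <- rank_and_z(fixture$scores, score)
  clustered <- cluster_decoys(fixture$decoys, rank_all, fixture$structure,
                              cutoff = cluster_cutoff)
  keep <- paste(clustered$receptor, clustered$ligand, clustered$decoy_id)
  sub_scores <- fixture$scores[paste(fixture$scores$receptor,
                                     fixture$scores$ligand,
                                     fixture$scores$decoy_id) %in% keep, ,
                               drop = FALSE]
  attr(sub_scores, "orientation") <- attr(fixture$scores, "orientation")
  ranking <- rank_and_z(sub_scores, score)
  run <- run_ga(config, structure_chains(fixture$structure),
                fixture$structure, clustered)
  if (is.null(consensus_start)) {
    consensus_start <- max(1L, ceiling(run$final_generation / 2))
  }
  class_map <- assign_chain_classes(fixture$structure)
  list(run = run, ranking = ranking,
       final = predict_final_generation(run, ranking,
                                        class_map = class_map),
       consensus = predict_consensus(run, ranking,
                                     start_generation = consensus_start,
                                     class_map = class_map))
}
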