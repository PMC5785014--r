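#' Complex structures as atom tables
#'
#' A complex structure is stored as a tibble of atoms (class `cpx_structure`)
#' with one row per atom and columns:
#' \describe{
#'   \item{chain}{chain instance label (free-form string, e.g. `"A"`, `"A'"`)}
#'   \item{serial}{atom serial number, unique within the structure}
#'   \item{atom}{atom name (e.g. `"CA"`)}
#'   \item{element}{element symbol}
#'   \item{res_name}{3-letter residue code}
#'   \item{res_id}{residue number (integer)}
#'   \item{ins}{insertion code, `""` if none}
#'   \item{x,y,z}{coordinates in Angstrom}
#' }
#' All geometric operations in the package (SASA, contacts, clashes, RMSD)
#' work on this table.
#'
#' @param atoms A data frame with the columns above.
#' @return A `cpx_structure` tibble.
#' @export
new_structure <- function(atoms) {
  atoms <- tibble::as_tibble(atoms)
  req <- c("chain", "serial", "atom", "element", "res_name", "res_id", "ins",
           "x", "y", "z")
  missing <- setdiff(req, names(atoms))
  if (length(missing)) stop("atom table lacks columns: ", paste(missing, collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty structure (no atoms)")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite atom coordinates")
  }
  if (anyDuplicated(atoms$serial)) stop("duplicate atom serial numbers")
  class(atoms) <- unique(c("cpx_structure", class(atoms)))
  atoms
}

#' @export
print.cpx_structure <- function(x, ...) {
  ch <- structure_chains(x)
  cat("<cpx_structure> ", length(ch), " chains (", paste(ch, collapse = ", "),
      "), ", nrow(x), " atoms\n", sep = "")
  NextMethod()
}

#' Chain labels of a structure, in canonical order
#'
#' Canonical order sorts by base letter, then unprimed before primed before
#' numbered copies (`A < A' < A'' < A1 < B`).
#'
#' @param structure A `cpx_structure`.
#' @export
structure_chains <- function(structure) {
  chain_sort(unique(structure$chain))
}

#' Sort chain labels canonically
#' @param labels Character vector of chain labels.
#' @export
chain_sort <- function(labels) {
  labels <- as.character(labels)
  base <- substr(labels, 1L, 1L)
  suffix <- substring(labels, 2L)
  primes <- nchar(gsub("[^']", "", suffix))
  num <- suppressWarnings(as.numeric(gsub("'", "", suffix)))
  # ordering key: base letter, suffix kind (none < primes < number), value
  kind <- ifelse(suffix == "", 0L, ifelse(grepl("^'+$", suffix), 1L, 2L))
  value <- ifelse(kind == 1L, primes, ifelse(kind == 2L, num, 0))
  labels[order(base, kind, value, labels)]
}

# coordinates of a chain (optionally CA only) as an n x 3 matrix
chain_coords <- function(structure, chain, ca_only = FALSE) {
  rows <- structure$chain == chain
  if (!any(rows)) stop("unknown chain label: ", chain)
  if (ca_only) rows <- rows & structure$atom == "CA"
  if (!any(rows)) stop("chain ", chain, " has no CA atoms")
  as.matrix(structure[rows, c("x", "y", "z")])
}

#' Subset a structure to a set of chains
#' @param structure A `cpx_structure`.
#' @param chains Character vector of chain labels to keep.
#' @export
subset_structure <- function(structure, chains) {
  unknown <- setdiff(chains, unique(structure$chain))
  if (length(unknown)) stop("unknown chain label(s): ", paste(unknown, collapse = ", "))
  new_structure(structure[structure$chain %in% chains, , drop = FALSE])
}

#' One-letter sequences of each chain
#'
#' Sequences are extracted from the atom records (one letter per residue, in
#' order of appearance); unknown residue codes become `"X"`.
#'
#' @param structure A `cpx_structure`.
#' @return Named character vector, one sequence per chain.
#' @export
chain_sequences <- function(structure) {
  chains <- structure_chains(structure)
  out <- vapply(chains, function(ch) {
    sub <- structure[structure$chain == ch, , drop = FALSE]
    key <- paste(sub$res_id, sub$ins)
    first <- !duplicated(key)
    letters1 <- suppressWarnings(bio3d::aa321(sub$res_name[first]))
    letters1[is.na(letters1)] <- "X"
    paste(letters1, collapse = "")
  }, character(1))
  stats::setNames(out, chains)
}

#' Read a PDB file into a structure table
#'
#' Keeps protein `ATOM` records; `HETATM` records are excluded unless
#' `include_hetero = TRUE` (waters are always dropped). Hydrogens are dropped.
#' For alternate locations, the highest-occupancy conformer is kept, ties
#' resolved by first occurrence.
#'
#' @param path Path to a PDB file.
#' @param format Only `"pdb"` is supported.
#' @param include_hetero Keep non-water heavy `HETATM` records?
#' @return A `cpx_structure`.
#' @export
read_structure <- function(path, format = c("pdb"), include_hetero = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  at <- tibble::as_tibble(pdb$atom)
  if (!include_hetero) {
    at <- at[at$type == "ATOM", , drop = FALSE]
  } else {
    at <- at[at$type == "ATOM" | (at$type == "HETATM" & at$resid != "HOH"), ,
             drop = FALSE]
  }
  if (nrow(at) == 0L) stop("empty structure: no ATOM records in ", path)
  elem <- guess_element(at$elesy, at$elety)
  at <- at[elem != "H", , drop = FALSE]
  elem <- elem[elem != "H"]
  at$element <- elem
  # altloc policy: keep highest occupancy, ties -> first encountered
  alt <- at$alt
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(key, -occ, seq_len(nrow(at)))
  at <- at[ord[!duplicated(key[ord])], , drop = FALSE]
  at <- at[order(match(at$eleno, at$eleno), at$eleno), , drop = FALSE]
  ins <- at$insert
  ins[is.na(ins)] <- ""
  out <- tibble::tibble(
    chain = as.character(at$chain),
    serial = as.integer(at$eleno),
    atom = as.character(at$elety),
    element = at$element,
    res_name = as.character(at$resid),
    res_id = as.integer(at$resno),
    ins = ins,
    x = at$x, y = at$y, z = at$z
  )
  out <- out[order(match(out$chain, unique(out$chain)), out$serial), ,
             drop = FALSE]
  new_structure(out)
}

# element from the element-symbol column when present, else from atom name
guess_element <- function(elesy, elety) {
  elesy <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  fallback <- toupper(substr(gsub("[^A-Za-z].*", "", trimws(elety)), 1L, 1L))
  ifelse(elesy != "", elesy, fallback)
}

#' Write a structure to a PDB file
#'
#' Chain labels must be single characters (the PDB chain field is one column);
#' coordinates must fit the fixed-width 8.3 field, i.e. `|coord| < 10000`.
#' A read/write round trip preserves chains, labels and coordinates to the
#' format precision of 1e-3 Angstrom.
#'
#' @param structure A `cpx_structure`.
#' @param path Output path.
#' @export
write_structure <- function(structure, path) {
  if (!inherits(structure, "cpx_structure")) structure <- new_structure(structure)
  if (any(nchar(unique(structure$chain)) != 1L)) {
    stop("PDB output requires single-character chain labels; relabel chains first")
  }
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  if (any(abs(xyz) >= 10000)) {
    stop("coordinates exceed the PDB fixed-width field (|coord| must be < 10000 A)")
  }
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(xyz)),
    type = rep("ATOM", nrow(structure)),
    eleno = structure$serial,
    elety = structure$atom,
    resid = structure$res_name,
    chain = structure$chain,
    resno = structure$res_id,
    insert = ifelse(structure$ins == "", "", structure$ins),
    elesy = structure$element
  )
  invisible(path)
}

#' Group chains into identity classes by sequence
#'
#' Chains whose pairwise sequence identity is at least `min_identity` are
#' placed in the same class (single linkage); with the default
#' `min_identity = 1` only exact sequence matches share a class, which is the
#' convention behind primed labels (`A` and `A'` are copies of one protein).
#' For unequal-length sequences identity is `1 - d/L` where `d` is the
#' Levenshtein distance and `L` the longer length.
#'
#' @param structure A `cpx_structure`.
#' @param min_identity Fraction in \[0, 1\].
#' @return A tibble with columns `chain` and `class` (class label = smallest
#'   member label).
#' @export
assign_chain_classes <- function(structure, min_identity = 1.0) {
  seqs <- chain_sequences(structure)
  chains <- names(seqs)
  n <- length(chains)
  uf <- uf_new(n)
  if (n > 1L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        if (seq_identity(seqs[[i]], seqs[[j]]) >= min_identity) uf_union(uf, i, j)
      }
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(uf, i), integer(1))
  class_label <- vapply(roots, function(r) {
    chain_sort(chains[roots == r])[1]
  }, character(1))
  tibble::tibble(chain = chains, class = class_label)
}

seq_identity <- function(a, b) {
  if (identical(a, b)) return(1)
  l <- max(nchar(a), nchar(b))
  if (l == 0L) return(1)
  1 - as.numeric(utils::adist(a, b)) / l
}

#' Contacting residue pairs between two chains
#'
#' A residue pair is in contact when any two heavy atoms, one from each
#' residue, are closer than `cutoff` (default 5.0 Angstrom, the standard
#' interface criterion).
#'
#' @param structure A `cpx_structure`.
#' @param a,b Distinct chain labels.
#' @param cutoff Distance cutoff in Angstrom.
#' @return Tibble with columns `res_a`, `res_b` (residue identifiers
#'   `"<res_id><ins>"`) and `min_dist`.
#' @export
contact_residue_pairs <- function(structure, a, b, cutoff = 5.0) {
  if (identical(a, b)) stop("chain labels must differ")
  ca <- structure[structure$chain == a, , drop = FALSE]
  cb <- structure[structure$chain == b, , drop = FALSE]
  if (nrow(ca) == 0L) stop("unknown chain label: ", a)
  if (nrow(cb) == 0L) stop("unknown chain label: ", b)
  xa <- as.matrix(ca[, c("x", "y", "z")])
  xb <- as.matrix(cb[, c("x", "y", "z")])
  ra <- paste0(ca$res_id, ca$ins)
  rb <- paste0(cb$res_id, cb$ins)
  hits <- close_pairs(xa, xb, cutoff)
  if (nrow(hits) == 0L) {
    return(tibble::tibble(res_a = character(), res_b = character(),
                          min_dist = numeric()))
  }
  tibble::tibble(res_a = ra[hits[, 1L]], res_b = rb[hits[, 2L]],
                 d = hits[, 3L]) |>
    dplyr::group_by(.data$res_a, .data$res_b) |>
    dplyr::summarise(min_dist = min(.data$d), .groups = "drop") |>
    dplyr::arrange(.data$res_a, .data$res_b)
}

# all (i, j, dist) pairs with dist < cutoff between two coordinate sets,
# chunked so the cross-distance matrix stays bounded in memory
close_pairs <- function(xa, xb, cutoff, chunk = 2000L) {
  out <- list()
  na <- nrow(xa)
  for (start in seq(1L, na, by = chunk)) {
    idx <- start:min(start + chunk - 1L, na)
    d2 <- cross_dist2(xa[idx, , drop = FALSE], xb)
    hit <- which(d2 < cutoff^2, arr.ind = TRUE)
    if (nrow(hit)) {
      out[[length(out) + 1L]] <- cbind(idx[hit[, 1L]], hit[, 2L],
                                       sqrt(d2[hit]))
    }
  }
  if (!length(out)) return(matrix(numeric(), 0L, 3L))
  do.call(rbind, out)
}

# squared cross-distance matrix between n x 3 and m x 3 coordinate sets
cross_dist2 <- function(xa, xb) {
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb)
  d2[d2 < 0] <- 0
  d2
}

#' Interface graph of a complex
#'
#' An edge connects two chains when they have at least `min_pairs` contacting
#' residue pairs at `cutoff`; an edge with more than `strong_threshold`
#' residue pairs is flagged strong.
#'
#' @param structure A `cpx_structure`.
#' @param cutoff Contact distance cutoff (Angstrom).
#' @param min_pairs Minimum number of contacting residue pairs for an edge.
#' @param strong_threshold Residue-pair count above which an edge is "strong".
#' @return Tibble with columns `chain_a`, `chain_b` (canonical order),
#'   `n_pairs`, `strong`.
#' @export
interface_graph <- function(structure, cutoff = 5.0, min_pairs = 1L,
                            strong_threshold = 20L) {
  chains <- structure_chains(structure)
  if (length(chains) < 2L) stop("interface graph needs at least 2 chains")
  combos <- utils::combn(chains, 2L)
  rows <- purrr::map_dfr(seq_len(ncol(combos)), function(k) {
    a <- combos[1L, k]; b <- combos[2L, k]
    n <- nrow(contact_residue_pairs(structure, a, b, cutoff))
    tibble::tibble(chain_a = a, chain_b = b, n_pairs = n)
  })
  rows <- rows[rows$n_pairs >= min_pairs, , drop = FALSE]
  rows$strong <- rows$n_pairs > strong_threshold
  rows
}

# connected components of a chain set under an interface-graph edge table;
# returns list of character vectors
graph_components <- function(chains, edges) {
  idx <- stats::setNames(seq_along(chains), chains)
  uf <- uf_new(length(chains))
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      uf_union(uf, idx[[edges$chain_a[k]]], idx[[edges$chain_b[k]]])
    }
  }
  roots <- vapply(seq_along(chains), function(i) uf_find(uf, i), integer(1))
  unname(lapply(split(chains, roots), chain_sort))
}

# ---- union-find (path compression, union by size) ----
uf_new <- function(n) {
  e <- new.env(parent = emptyenv())
  e$parent <- seq_len(n)
  e$size <- rep(1L, n)
  e
}
uf_find <- function(uf, i) {
  while (uf$parent[i] != i) {
    uf$parent[i] <- uf$parent[uf$parent[i]]
    i <- uf$parent[i]
  }
  i
}
uf_union <- function(uf, i, j) {
  ri <- uf_find(uf, i); rj <- uf_find(uf, j)
  if (ri == rj) return(invisible(FALSE))
  if (uf$size[ri] < uf$size[rj]) { tmp <- ri; ri <- rj; rj <- tmp }
  uf$parent[rj] <- ri
  uf$size[ri] <- uf$size[ri] + uf$size[rj]
  invisible(TRUE)
}
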