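#' Pairwise docking decoy tables
#'
#' A decoy table holds candidate rigid-body binding poses for subunit pairs:
#' one row per decoy with columns `receptor`, `ligand`, `decoy_id`, the
#' rotation entries `r11..r33` (row-major) and the translation `tx, ty, tz`.
#' The transform places the ligand chain's library coordinates into the
#' receptor frame: `x -> R x + t`. Decoy ids are unique within a pair.
#'
#' @param receptor,ligand Chain labels (recycled).
#' @param decoy_id Integer ids.
#' @param transforms List of [rigid_transform()] objects.
#' @return A tibble in decoy-table layout.
#' @export
decoy_table <- function(receptor, ligand, decoy_id, transforms) {
  stopifnot(length(transforms) == length(decoy_id))
  rot <- t(vapply(transforms, function(tr) as.numeric(t(tr$rotation)),
                  numeric(9)))
  trl <- t(vapply(transforms, function(tr) tr$translation, numeric(3)))
  out <- tibble::tibble(
    receptor = receptor, ligand = ligand, decoy_id = as.integer(decoy_id))
  rotcols <- c("r11", "r12", "r13", "r21", "r22", "r23", "r31", "r32", "r33")
  out[rotcols] <- as.data.frame(rot)
  out[c("tx", "ty", "tz")] <- as.data.frame(trl)
  check_decoy_table(out)
  out
}

decoy_cols <- function() {
  c("receptor", "ligand", "decoy_id",
    "r11", "r12", "r13", "r21", "r22", "r23", "r31", "r32", "r33",
    "tx", "ty", "tz")
}

check_decoy_table <- function(d) {
  missing <- setdiff(decoy_cols(), names(d))
  if (length(missing)) stop("decoy table lacks columns: ",
                            paste(missing, collapse = ", "))
  key <- paste(d$receptor, d$ligand, d$decoy_id)
  if (anyDuplicated(key)) stop("duplicate (pair, decoy_id) in decoy table")
  invisible(d)
}

# transform of decoy-table row i
row_transform <- function(d, i) {
  rot <- matrix(as.numeric(d[i, c("r11", "r12", "r13", "r21", "r22", "r23",
                                  "r31", "r32", "r33")]),
                3, 3, byrow = TRUE)
  rigid_transform(rot, as.numeric(d[i, c("tx", "ty", "tz")]))
}

#' Write / read decoy transform tables
#'
#' Plain TSV with the decoy-table columns. On reading, each rotation is
#' re-orthonormalised when its drift from a proper rotation is at most 1e-3
#' and rejected otherwise (reflections are always rejected).
#'
#' @param decoys A decoy table.
#' @param path File path.
#' @export
write_decoy_transforms <- function(decoys, path) {
  check_decoy_table(decoys)
  df <- as.data.frame(decoys[decoy_cols()])
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "decoy_id"
  df[num] <- lapply(df[num], function(x) sprintf("%.9g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_decoy_transforms
#' @export
load_decoy_transforms <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  d <- tibble::as_tibble(df)
  d$receptor <- as.character(d$receptor)
  d$ligand <- as.character(d$ligand)
  d$decoy_id <- as.integer(d$decoy_id)
  check_decoy_table(d)
  for (i in seq_len(nrow(d))) {
    rot <- matrix(as.numeric(d[i, c("r11", "r12", "r13", "r21", "r22", "r23",
                                    "r31", "r32", "r33")]),
                  3, 3, byrow = TRUE)
    rot <- reorthonormalize(rot, max_drift = 1e-3)
    d[i, c("r11", "r12", "r13", "r21", "r22", "r23", "r31", "r32", "r33")] <-
      as.list(as.numeric(t(rot)))
  }
  d
}

#' Receptor-fixed ligand RMSD of a decoy pose
#'
#' The receptor chain is held at its native coordinates and the ligand chain
#' is placed by the decoy transform; the result is the C-alpha RMSD between
#' the posed and the native ligand chain, with no re-superposition. This is
#' the pairwise-decoy quality metric used for clustering, for synthetic
#' scores and for low-RMSD decoy selection.
#'
#' @param decoys Decoy table (any number of rows).
#' @param native A `cpx_structure` holding native coordinates of both chains.
#' @return `decoys` with an `rmsd` column appended.
#' @export
ligand_rmsd <- function(decoys, native) {
  check_decoy_table(decoys)
  out <- numeric(nrow(decoys))
  for (i in seq_len(nrow(decoys))) {
    ca <- chain_coords(native, decoys$ligand[i], ca_only = TRUE)
    posed <- transform_apply(row_transform(decoys, i), ca)
    out[i] <- sqrt(mean(rowSums((posed - ca)^2)))
  }
  dplyr::mutate(decoys, rmsd = out)
}

# CA coords of ligand under each decoy of one pair -> list of matrices
posed_ca <- function(decoys, native) {
  lapply(seq_len(nrow(decoys)), function(i) {
    ca <- chain_coords(native, decoys$ligand[i], ca_only = TRUE)
    transform_apply(row_transform(decoys, i), ca)
  })
}

#' Cluster decoys by ligand RMSD (greedy leader clustering)
#'
#' Within each pair, decoys are visited in rank order; the best-ranked
#' unassigned decoy becomes a representative and absorbs all decoys within
#' `cutoff` ligand RMSD of it. Representatives keep their original ids.
#' Redundancy reduction before the assembly search, mirroring the usual
#' docking post-processing (10 Angstrom cutoff).
#'
#' @param decoys Decoy table.
#' @param ranking Ranking table (see [rank_and_z()]) covering the decoys.
#' @param native A `cpx_structure` with the subunit library coordinates.
#' @param cutoff RMSD cutoff in Angstrom.
#' @return The representative subset of `decoys`.
#' @export
cluster_decoys <- function(decoys, ranking, native, cutoff = 10.0) {
  stopifnot(cutoff > 0)
  check_decoy_table(decoys)
  key <- paste(decoys$receptor, decoys$ligand)
  keep <- logical(nrow(decoys))
  for (pair in unique(key)) {
    idx <- which(key == pair)
    sub <- decoys[idx, , drop = FALSE]
    rk <- dplyr::inner_join(
      sub[c("receptor", "ligand", "decoy_id")], ranking,
      by = c("receptor", "ligand", "decoy_id"))
    if (nrow(rk) != nrow(sub)) stop("ranking does not cover pair ", pair)
    ord <- order(rk$rank)
    coords <- posed_ca(sub, native)
    reps <- integer()
    for (i in ord) {
      if (length(reps)) {
        d <- vapply(reps, function(j) {
          sqrt(mean(rowSums((coords[[i]] - coords[[j]])^2)))
        }, numeric(1))
        if (any(d <= cutoff)) next
      }
      reps <- c(reps, i)
    }
    keep[idx[reps]] <- TRUE
  }
  decoys[keep, , drop = FALSE]
}

#' Rank decoys by a score, with Z-scores
#'
#' Rank 1 is the most favourable decoy of its pair under the score's
#' orientation; Z-scores are standardised so that more favourable is always
#' more negative. Exact score ties are ordered by decoy id. Ranks are
#' computed within each (receptor, ligand) pair.
#'
#' @param scores Score table: tibble with `receptor`, `ligand`, `decoy_id`
#'   and one column per score.
#' @param score Score column name.
#' @param lower_is_better Orientation; defaults to the table's orientation
#'   attribute (see [write_score_table()]), else `TRUE` (energy convention).
#' @return Tibble `receptor`, `ligand`, `decoy_id`, `score`, `value`,
#'   `rank`, `z`.
#' @export
rank_and_z <- function(scores, score, lower_is_better = NULL) {
  if (!score %in% names(scores)) stop("no score column called ", score)
  if (is.null(lower_is_better)) {
    ori <- attr(scores, "orientation")
    lower_is_better <- if (!is.null(ori) && score %in% names(ori)) {
      ori[[score]]
    } else TRUE
  }
  vals <- scores[[score]]
  if (!all(is.finite(vals))) stop("non-finite score values in ", score)
  key <- paste(scores$receptor, scores$ligand)
  rank <- integer(nrow(scores))
  z <- numeric(nrow(scores))
  for (pair in unique(key)) {
    idx <- which(key == pair)
    v <- vals[idx]
    oriented <- if (lower_is_better) v else -v
    ord <- order(oriented, scores$decoy_id[idx])
    rank[idx[ord]] <- seq_along(idx)
    if (length(idx) == 1L) {
      z[idx] <- 0
    } else {
      s <- stats::sd(v)
      if (s == 0) {
        warning("zero score variance for pair ", pair, "; Z-scores set to 0")
        z[idx] <- 0
      } else {
        zz <- (v - mean(v)) / s
        z[idx] <- if (lower_is_better) zz else -zz
      }
    }
  }
  tibble::tibble(receptor = scores$receptor, ligand = scores$ligand,
                 decoy_id = scores$decoy_id, score = score, value = vals,
                 rank = rank, z = z)
}

#' Sum of score ranks as a combined score
#'
#' Per-decoy ranks from several scoring functions are summed; the sum is
#' treated as a new lower-is-better score and re-ranked (Z-scores computed
#' on the summed values). Combining ranks rather than raw scores puts
#' heterogeneous scoring functions on a common scale.
#'
#' @param rankings List of ranking tibbles from [rank_and_z()], all over the
#'   same decoys.
#' @return A ranking tibble with `score = "rank_sum"`.
#' @export
sum_of_ranks <- function(rankings) {
  stopifnot(length(rankings) >= 1L)
  base <- rankings[[1]][c("receptor", "ligand", "decoy_id")]
  total <- rankings[[1]]$rank
  for (r in rankings[-1]) {
    m <- dplyr::inner_join(base, r, by = c("receptor", "ligand", "decoy_id"))
    if (nrow(m) != nrow(base)) stop("rankings cover different decoy sets")
    total <- total + m$rank
  }
  sums <- dplyr::mutate(base, rank_sum = as.numeric(total))
  rank_and_z(sums, "rank_sum", lower_is_better = TRUE)
}

#' Boltzmann probabilities of binding poses
#'
#' `p_i = exp(-dG_i / kT) / sum_n exp(-dG_n / kT)`, computed with a max
#' shift for numerical stability. The ordering of the probabilities is the
#' reverse ordering of the free energies, which is why score *ranks* carry
#' the population information used for pathway extraction.
#'
#' @param delta_g Numeric vector of binding free energies.
#' @param kT Thermal energy in the same units (default 1: energies in kT).
#' @return Probability vector summing to 1.
#' @export
pose_probabilities <- function(delta_g, kT = 1) {
  stopifnot(kT > 0)
  if (!length(delta_g)) stop("empty energy list")
  if (!all(is.finite(delta_g))) stop("non-finite energies")
  e <- -delta_g / kT
  e <- e - max(e)
  w <- exp(e)
  w / sum(w)
}

#' Write / read score tables
#'
#' TSV with pragma comment lines declaring each score column's orientation
#' (`#!lower_better <name>` or `#!higher_better <name>`), then a header row
#' and the data. Undeclared score columns default to lower-is-better.
#'
#' @param scores Score table (tibble with `receptor`, `ligand`, `decoy_id`
#'   and score columns; orientation in attribute `"orientation"`).
#' @param path File path.
#' @export
write_score_table <- function(scores, path) {
  ori <- attr(scores, "orientation")
  score_cols <- setdiff(names(scores), c("receptor", "ligand", "decoy_id"))
  if (is.null(ori)) ori <- stats::setNames(rep(TRUE, length(score_cols)), score_cols)
  con <- file(path, "w")
  on.exit(close(con))
  for (sc in score_cols) {
    writeLines(sprintf("#!%s %s",
                       if (isTRUE(ori[[sc]])) "lower_better" else "higher_better",
                       sc), con)
  }
  df <- as.data.frame(scores[c("receptor", "ligand", "decoy_id", score_cols)])
  df[score_cols] <- lapply(df[score_cols], function(x) sprintf("%.9g", x))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  lines <- readLines(path)
  pragma <- grep("^#!", lines, value = TRUE)
  ori <- list()
  for (pl in pragma) {
    parts <- strsplit(trimws(sub("^#!", "", pl)), "\\s+")[[1]]
    ori[[parts[2]]] <- parts[1] == "lower_better"
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE)
  out <- tibble::as_tibble(df)
  out$receptor <- as.character(out$receptor)
  out$ligand <- as.character(out$ligand)
  out$decoy_id <- as.integer(out$decoy_id)
  attr(out, "orientation") <- unlist(ori)
  out
}
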