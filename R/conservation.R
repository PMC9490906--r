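#' Score cross-species homolog hits
#'
#' Adds a conservation score per hit and a retention flag. The default score
#' is `coverage * identity` (both in \[0,1\], so the product stays in \[0,1\]
#' and the conventional 0.6 retention threshold is meaningful); the
#' alternative `"mean"` formula uses `(coverage + identity) / 2`. Retention
#' is strict (`score > threshold`).
#'
#' @param hits data.frame with `query`, `species`, `identity`, `coverage`,
#'   `e_value`, optionally `subject`.
#' @param threshold retention threshold (default 0.6).
#' @param formula `"product"` (default) or `"mean"`.
#' @return Input with `score` and `retained` columns appended.
#' @export
conservation_score <- function(hits, threshold = 0.6,
                               formula = c("product", "mean")) {
  formula <- match.arg(formula)
  stopifnot(all(c("query", "species", "identity", "coverage") %in% names(hits)))
  if (any(hits$identity < 0 | hits$identity > 1 |
            hits$coverage < 0 | hits$coverage > 1))
    stopf("identity and coverage must lie in [0, 1]")
  hits$score <- switch(formula,
                       product = hits$coverage * hits$identity,
                       mean = (hits$coverage + hits$identity) / 2)
  hits$retained <- hits$score > threshold
  hits
}

#' Best hit per (query, species)
#'
#' Maximum score, ties broken by lower e-value then lexicographic subject id.
#'
#' @param records output of [conservation_score()].
#' @return One row per (query, species).
#' @export
best_hits <- function(records) {
  ev <- records$e_value %||% rep(0, nrow(records))
  sj <- records$subject %||% rep("", nrow(records))
  ord <- order(records$query, records$species, -records$score, ev, sj)
  r <- records[ord, , drop = FALSE]
  r <- r[!duplicated(r[, c("query", "species")]), , drop = FALSE]
  rownames(r) <- NULL
  r
}

#' Single-copy homolog set
#'
#' Queries with exactly one retained hit in every listed species (two
#' retained hits in any one species, or a species with none, excludes the
#' query).
#'
#' @param records output of [conservation_score()] (all hits, not
#'   best-per-species).
#' @param species character vector of required species.
#' @return Character vector of query ids.
#' @export
single_copy_set <- function(records, species) {
  if (!length(species)) stopf("empty species list")
  ret <- records[records$retained, , drop = FALSE]
  if (!nrow(ret)) return(character(0))
  counts <- table(ret$query, ret$species)
  queries <- rownames(counts)
  have <- intersect(species, colnames(counts))
  if (length(have) < length(species)) return(character(0))
  ok <- apply(counts[, species, drop = FALSE] == 1L, 1L, all)
  sort(queries[ok])
}

#' Pairwise species distances from conservation records
#'
#' For each species pair, the conservation shared by both is summarised per
#' query as `min(score_1, score_2)` and the distance is one minus its mean
#' over the query set; the focal (query) species has self-score 1, so its
#' distance to species `s` is `1 - mean(score_s)`. Queries are restricted to
#' those retained in every species (default: the single-copy set) so the
#' matrix is complete.
#'
#' @param records output of [conservation_score()].
#' @param focal name of the query species (appears in the matrix).
#' @param species subject species to include (default: all in `records`).
#' @param queries query ids to average over (default: [single_copy_set()]).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
species_distances <- function(records, focal = "T.aestivum", species = NULL,
                              queries = NULL) {
  species <- species %||% sort(unique(records$species))
  queries <- queries %||% single_copy_set(records, species)
  if (!length(queries)) stopf("no queries cover all species")
  rec <- best_hits(records[records$query %in% queries & records$retained, ,
                           drop = FALSE])
  score <- matrix(NA_real_, length(queries), length(species),
                  dimnames = list(queries, species))
  score[cbind(match(rec$query, queries), match(rec$species, species))] <- rec$score
  taxa <- c(focal, species)
  d <- matrix(0, length(taxa), length(taxa), dimnames = list(taxa, taxa))
  full <- cbind(1, score)  # focal self-score = 1
  colnames(full) <- taxa
  for (i in seq_along(taxa)) for (j in seq_along(taxa)) {
    if (i < j) {
      v <- 1 - mean(pmin(full[, i], full[, j]))
      d[i, j] <- d[j, i] <- v
    }
  }
  d
}

#' Neighbor-joining species tree
#'
#' Standard NJ agglomeration (via ape) on a symmetric zero-diagonal distance
#' matrix; negative branch lengths are clamped to zero and flagged
#' (`attr(, "clamped")`). On additive distances NJ recovers the generating
#' topology and branch lengths exactly.
#'
#' @param d symmetric distance matrix, `n >= 3` taxa.
#' @return An [ape] `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stopf("need at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-9) stopf("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stopf("distance matrix diagonal must be zero")
  tr <- ape::nj(as.dist(d))
  clamped <- sum(tr$edge.length < 0)
  if (clamped) {
    warnf("nj_tree: clamped %d negative branch length(s) to 0", clamped)
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  attr(tr, "clamped") <- clamped
  tr
}

#' Write a tree in Newick format
#'
#' @param tree a `phylo` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
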