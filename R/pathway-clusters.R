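#' Pathway over-representation analysis
#'
#' Hypergeometric upper-tail test of query-gene enrichment in each pathway
#' (equivalently a one-sided Fisher exact test), BH-adjusted across tested
#' pathways. Pathway gene sets are intersected with the universe before
#' testing; enrichment additionally requires a minimum number of query genes
#' in the pathway.
#'
#' @param query_genes Character vector, a subset of `universe`.
#' @param db A `pathway_db`.
#' @param universe Character vector of testable genes (e.g. all genes
#'   surviving expression filters).
#' @param min_overlap Minimum query genes in the pathway (default 3).
#' @param q_max FDR threshold for enrichment (default 0.1).
#' @return Data frame (class `ora_result`) with columns `pathway`,
#'   `k_overlap`, `K_pathway`, `n_query`, `N_universe`, `p`, `q`,
#'   `enriched`; attribute `enriched` names the enriched pathways.
#' @export
over_representation <- function(query_genes, db, universe,
                                min_overlap = 3, q_max = 0.1) {
  if (!length(universe)) stop("universe is empty")
  universe <- unique(universe)
  query_genes <- unique(query_genes)
  if (!all(query_genes %in% universe))
    stop("query genes must be a subset of the universe")
  n <- length(query_genes); N <- length(universe)
  sets <- lapply(db, intersect, universe)
  keep <- lengths(sets) > 0
  sets <- sets[keep]
  K <- lengths(sets)
  k <- vapply(sets, function(s) length(intersect(s, query_genes)), 0L)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  enriched <- k >= min_overlap & q < q_max
  res <- data.frame(pathway = names(sets), k_overlap = k, K_pathway = K,
                    n_query = n, N_universe = N, p = p, q = q,
                    enriched = enriched, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(res) <- c("ora_result", "data.frame")
  attr(res, "enriched") <- res$pathway[enriched]
  res
}

#' Overlap coefficient between two gene sets
#'
#' \eqn{|A \cap B| / \min(|A|, |B|)}: 1 when either set contains the other,
#' 0 when disjoint.
#'
#' @param a,b Non-empty character vectors (treated as sets).
#' @return Numeric in \[0, 1\].
#' @export
overlap_coefficient <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) || !length(b)) stop("overlap coefficient needs non-empty sets")
  length(intersect(a, b)) / min(length(a), length(b))
}

overlap_distance_matrix <- function(sets) {
  n <- length(sets)
  d <- matrix(0, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- 1 - overlap_coefficient(sets[[i]], sets[[j]])
  d
}

#' Cluster pathways on overlap-coefficient similarity
#'
#' Agglomerative hierarchical clustering of pathways with distance
#' 1 - overlap coefficient. The tree is cut at every k from `k_min` to
#' n - 1, average silhouette width is computed on the same distance matrix,
#' and the chosen k is the largest one whose average silhouette is within
#' `tolerance` of the maximum (maximising both silhouette and cluster
#' count). Singleton clusters contribute silhouette 0.
#'
#' @param pathways Named list of gene sets (>= 3).
#' @param k_min Smallest k in the sweep (default 2).
#' @param linkage `hclust` agglomeration method (default "average").
#' @param tolerance Silhouette tolerance for preferring larger k
#'   (default 0.01).
#' @return A `cluster_solution`: `k` (candidate ks), `avg_silhouette`,
#'   `chosen_k`, `labels` (pathway -> cluster at the chosen k), `linkage`,
#'   `tolerance`, `hclust`, `distance`.
#' @export
cluster_pathways <- function(pathways, k_min = 2, linkage = "average",
                             tolerance = 0.01) {
  n <- length(pathways)
  if (n < 3) stop("need at least 3 pathways to cluster")
  d <- overlap_distance_matrix(pathways)
  if (all(d == 0))
    stop("all pathways are identical under the overlap coefficient")
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  ks <- seq(k_min, n - 1)
  sil <- vapply(ks, function(k) {
    labels <- stats::cutree(hc, k = k)
    mean(cluster::silhouette(labels, dmatrix = d)[, "sil_width"])
  }, 0)
  chosen <- max(ks[sil >= max(sil) - tolerance])
  structure(list(k = ks, avg_silhouette = sil, chosen_k = chosen,
                 labels = stats::cutree(hc, k = chosen),
                 linkage = linkage, tolerance = tolerance, hclust = hc,
                 distance = d),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("cluster_solution: k swept %d-%d, chosen k = %d (avg silhouette %.3f, %s linkage)\n",
              min(x$k), max(x$k), x$chosen_k,
              x$avg_silhouette[x$k == x$chosen_k], x$linkage))
  invisible(x)
}

#' Build clusters of pathways (redundant CP set)
#'
#' One CP per cluster label, with member genes the union of its member
#' pathways' genes intersected with the dysregulated gene list. Dysregulated
#' genes mapping to no enriched pathway are pooled into a leftover CP of
#' their own. Genes may appear in several CPs (`redundant = TRUE`).
#'
#' @param solution A `cluster_solution` whose labels cover `pathways`.
#' @param pathways Named list of enriched pathway gene sets.
#' @param dysregulated_genes Character vector of all dysregulated genes.
#' @return A `cp_set`: list of CPs (`cp_id`, `pathways`, `genes`),
#'   `redundant` flag and `leftover_cp_id` (NA when absent).
#' @export
build_cps <- function(solution, pathways, dysregulated_genes) {
  stopifnot(inherits(solution, "cluster_solution"))
  labels <- solution$labels
  if (!all(names(pathways) %in% names(labels)))
    stop("cluster labels must cover all enriched pathways")
  cps <- lapply(sort(unique(labels)), function(lab) {
    members <- names(labels)[labels == lab]
    genes <- sort(intersect(unique(unlist(pathways[members])),
                            dysregulated_genes))
    list(cp_id = sprintf("CP%02d", lab), pathways = members, genes = genes)
  })
  mapped <- unique(unlist(lapply(cps, `[[`, "genes")))
  leftover <- sort(setdiff(dysregulated_genes,
                           unique(unlist(pathways))))
  leftover_id <- NA_character_
  if (length(leftover)) {
    leftover_id <- sprintf("CP%02d", max(unique(labels)) + 1L)
    cps[[length(cps) + 1L]] <- list(cp_id = leftover_id,
                                    pathways = character(0),
                                    genes = leftover)
  }
  names(cps) <- vapply(cps, `[[`, "", "cp_id")
  structure(list(cps = cps, redundant = TRUE, leftover_cp_id = leftover_id),
            class = "cp_set")
}

#' @export
print.cp_set <- function(x, ...) {
  cat(sprintf("cp_set: %d CPs (%s), %d distinct genes%s\n",
              length(x$cps),
              if (x$redundant) "redundant" else "non-redundant",
              length(unique(unlist(lapply(x$cps, `[[`, "genes")))),
              if (!is.na(x$leftover_cp_id))
                sprintf(", leftover CP: %s", x$leftover_cp_id) else ""))
  invisible(x)
}

#' Resolve multi-CP genes into a non-redundant CP set
#'
#' For every gene appearing in more than one CP, a relevance score is
#' computed per candidate CP: the number of CP co-members whose absolute
#' Spearman correlation with the gene exceeds `rho_threshold` (on the
#' discovery cohort, self excluded), normalised by the co-member count. The
#' gene is assigned to the arg-max relevance CP; ties prefer the larger
#' correlated count, then the smaller CP id. The result has every gene in
#' exactly one CP.
#'
#' @param cps A redundant `cp_set`.
#' @param expression Discovery [expression_cohort] covering all CP genes.
#' @param rho_threshold Absolute Spearman correlation threshold
#'   (default 0.3).
#' @return List with `cps` (non-redundant `cp_set`) and `relevance` (data
#'   frame of the per-gene, per-candidate-CP relevance records).
#' @export
deredundant_cps <- function(cps, expression, rho_threshold = 0.3) {
  stopifnot(inherits(cps, "cp_set"), inherits(expression, "expression_cohort"))
  if (!cps$redundant) stop("cps is already non-redundant")
  all_genes <- unique(unlist(lapply(cps$cps, `[[`, "genes")))
  missing <- setdiff(all_genes, expression$genes)
  if (length(missing))
    stop(sprintf("gene absent from expression: %s", missing[1]))

  membership <- lapply(cps$cps, `[[`, "genes")
  counts <- table(unlist(membership))
  multi <- names(counts)[counts > 1]
  rel_records <- list()
  assign_to <- stats::setNames(rep(NA_character_, length(multi)), multi)
  cp_ids <- names(cps$cps)
  expr <- expression$values

  for (g in multi) {
    cand <- cp_ids[vapply(membership, function(m) g %in% m, TRUE)]
    best <- NULL
    for (cp in cand) {
      co <- setdiff(membership[[cp]], g)
      if (length(co)) {
        rho <- suppressWarnings(
          stats::cor(expr[g, ], t(expr[co, , drop = FALSE]),
                     method = "spearman"))
        cc <- sum(abs(rho) > rho_threshold, na.rm = TRUE)
        r <- cc / length(co)
      } else {
        cc <- 0L; r <- 0
      }
      rec <- list(gene = g, cp_id = cp, correlated_count = cc,
                  cp_size = length(co), R = r,
                  rho_threshold = rho_threshold)
      rel_records[[length(rel_records) + 1L]] <- rec
      better <- is.null(best) || r > best$R ||
        (r == best$R && cc > best$correlated_count) ||
        (r == best$R && cc == best$correlated_count &&
           match(cp, cp_ids) < match(best$cp_id, cp_ids))
      if (better) best <- rec
    }
    assign_to[g] <- best$cp_id
  }

  new_cps <- lapply(cps$cps, function(cp) {
    keep <- vapply(cp$genes, function(g)
      !(g %in% multi) || assign_to[g] == cp$cp_id, TRUE)
    cp$genes <- cp$genes[keep]
    cp
  })
  relevance <- do.call(rbind, lapply(rel_records, as.data.frame))
  if (is.null(relevance))
    relevance <- data.frame(gene = character(0), cp_id = character(0),
                            correlated_count = integer(0),
                            cp_size = integer(0), R = numeric(0),
                            rho_threshold = numeric(0))
  list(cps = structure(list(cps = new_cps, redundant = FALSE,
                            leftover_cp_id = cps$leftover_cp_id),
                       class = "cp_set"),
       relevance = relevance)
}
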