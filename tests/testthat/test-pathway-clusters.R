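test_that("over-representation matches exhaustive enumeration", {
  # N = 10, K = 4, n = 5, k = 3: p enumerates to 66/252
  universe <- sprintf("u%02d", 1:10)
  db <- structure(list(P = universe[1:4]), class = "pathway_db")
  query <- universe[c(1, 2, 3, 5, 6)]   # 3 of 5 inside the pathway
  res <- over_representation(query, db, universe, min_overlap = 3)
  expect_equal(res$p, 66 / 252, tolerance = 1e-12)
  expect_equal(res$p, ora_p_by_enumeration(10, 4, 5, 3), tolerance = 1e-12)

  # zero overlap: upper tail at 0 is 1
  db0 <- structure(list(P = universe[7:10]), class = "pathway_db")
  res0 <- over_representation(universe[1:3], db0, universe)
  expect_equal(res0$p, 1)

  # enumeration sweep across universes up to 20 genes
  for (spec in list(c(12, 5, 4), c(16, 6, 5), c(20, 7, 6))) {
    N <- spec[1]; K <- spec[2]; n <- spec[3]
    for (k in 0:min(K, n)) {
      p_pkg <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      expect_equal(p_pkg, ora_p_by_enumeration(N, K, n, k),
                   tolerance = 1e-12)
    }
  }

  # two query genes in the pathway: excluded from enrichment regardless of q
  universe <- sprintf("u%03d", 1:200)
  db2 <- structure(list(tiny = universe[1:2], big = universe[1:50]),
                   class = "pathway_db")
  res <- over_representation(universe[1:10], db2, universe)
  expect_lt(res$q[res$pathway == "tiny"], 0.1)
  expect_false(res$enriched[res$pathway == "tiny"])
  expect_error(over_representation("a", db2, character(0)), "empty")
})

test_that("overlap coefficient follows its closed form", {
  expect_equal(overlap_coefficient(c("x", "y"), c("x", "y", "z")), 1)
  expect_equal(overlap_coefficient(c("a", "b"), c("c", "d")), 0)
  expect_equal(overlap_coefficient(c("x", "y", "z"), c("y", "z", "w", "v")),
               2 / 3)
  expect_error(overlap_coefficient(character(0), "a"), "non-empty")
  # symmetry and the containment characterisation
  a <- c("p", "q", "r"); b <- c("q", "r", "s", "t")
  expect_equal(overlap_coefficient(a, b), overlap_coefficient(b, a))
  expect_equal(overlap_coefficient(a, c(a, "extra")), 1)
})

test_that("pathway clustering recovers block structure and silhouettes match the definition", {
  # 9 pathways in 3 disjoint blocks, within-block overlap coefficient 1
  blocks <- list()
  for (b in 1:3) {
    g <- sprintf("b%d_g%02d", b, 1:10)
    blocks[[sprintf("B%d_full", b)]] <- g
    blocks[[sprintf("B%d_sub1", b)]] <- g[1:8]
    blocks[[sprintf("B%d_sub2", b)]] <- g[1:6]
  }
  sol <- cluster_pathways(blocks)
  expect_equal(sol$chosen_k, 3)
  expect_equal(sol$avg_silhouette[sol$k == 3], 1)
  expect_equal(length(unique(sol$labels[1:3])), 1)

  # silhouette curve equals the by-definition oracle on a 6-pathway toy
  set.seed(5)
  toy <- lapply(1:6, function(i)
    sample(sprintf("g%03d", 1:60), sample(8:15, 1)))
  names(toy) <- sprintf("P%d", 1:6)
  sol <- cluster_pathways(toy)
  d <- 1 - outer(seq_along(toy), seq_along(toy),
                 Vectorize(function(i, j)
                   overlap_coefficient(toy[[i]], toy[[j]])))
  hc <- hclust(as.dist(d), method = "average")
  for (i in seq_along(sol$k)) {
    labels <- cutree(hc, k = sol$k[i])
    expect_equal(sol$avg_silhouette[i], silhouette_by_definition(labels, d),
                 tolerance = 1e-12)
  }

  # two clusters of sizes 2 and 4, within-distance 0, between-distance 1
  small <- sprintf("s%02d", 1:6); big <- sprintf("t%02d", 1:8)
  six <- list(A1 = small, A2 = small[1:4],
              B1 = big, B2 = big[1:6], B3 = big[1:5], B4 = big[1:7])
  sol <- cluster_pathways(six)
  expect_equal(sol$chosen_k, 2)

  # identical pathways: degenerate all-zero distance matrix
  same <- list(P1 = c("a", "b", "c"), P2 = c("a", "b", "c"),
               P3 = c("a", "b", "c"))
  expect_error(cluster_pathways(same), "identical")
  expect_error(cluster_pathways(same[1:2]), "at least 3")
})

test_that("planted block counts 2-6 are recovered by silhouette k-selection", {
  for (nb in 2:6) {
    db <- simulate_pathway_blocks(nb, paths_per_block = 4, seed = nb)
    sol <- cluster_pathways(db)
    expect_equal(sol$chosen_k, nb)
    expect_equal(unname(vapply(split(names(sol$labels), sol$labels),
                               length, 0L)),
                 rep(4L, nb))
  }
})

test_that("CP construction pools cluster members and leftovers", {
  paths <- list(P1 = c("a", "b"), P2 = c("b", "c"),
                P3 = c("x", "y"), P4 = c("y", "z"))
  labels <- c(P1 = 1L, P2 = 1L, P3 = 2L, P4 = 2L)
  sol <- structure(list(labels = labels, chosen_k = 2),
                   class = "cluster_solution")
  dys <- c("a", "b", "c", "x", "y", "z", "lonely1", "lonely2")
  cps <- build_cps(sol, paths, dys)
  expect_true(cps$redundant)
  expect_equal(cps$cps$CP01$genes, c("a", "b", "c"))
  expect_equal(cps$cps$CP02$genes, c("x", "y", "z"))
  expect_equal(cps$cps[[cps$leftover_cp_id]]$genes,
               c("lonely1", "lonely2"))

  # a gene sitting in pathways of two different clusters lands in both CPs
  paths2 <- list(P1 = c("a", "shared"), P2 = c("x", "shared"))
  sol2 <- structure(list(labels = c(P1 = 1L, P2 = 2L), chosen_k = 2),
                    class = "cluster_solution")
  cps2 <- build_cps(sol2, paths2, c("a", "x", "shared"))
  expect_true("shared" %in% cps2$cps$CP01$genes)
  expect_true("shared" %in% cps2$cps$CP02$genes)
  expect_true(is.na(cps2$leftover_cp_id))

  # single cluster: one CP (plus leftovers when present)
  sol1 <- structure(list(labels = c(P1 = 1L, P2 = 1L), chosen_k = 1),
                    class = "cluster_solution")
  cps1 <- build_cps(sol1, paths2, c("a", "x", "shared"))
  expect_length(cps1$cps, 1)
})

test_that("relevance-based deredundancy assigns each gene to one CP", {
  # CP1: gene + 4 co-members, 2 perfectly correlated -> R = 2/4
  # CP2: gene + 10 co-members, 3 perfectly correlated -> R = 3/10
  set.seed(11)
  n <- 200
  base <- rnorm(n)
  mk <- function(corr) if (corr) base else rnorm(n)
  cp1_genes <- sprintf("c1_%d", 1:4)
  cp2_genes <- sprintf("c2_%d", 1:10)
  rows <- rbind(g = base,
                do.call(rbind, lapply(c(TRUE, TRUE, FALSE, FALSE), mk)),
                do.call(rbind, lapply(c(TRUE, TRUE, TRUE, rep(FALSE, 7)),
                                      mk)))
  rownames(rows) <- c("g", cp1_genes, cp2_genes)
  colnames(rows) <- sprintf("s%02d", 1:n)
  # guard: the uncorrelated rows are below the rho threshold
  rng <- abs(cor(base, t(rows[c(cp1_genes[3:4], cp2_genes[4:10]), ]),
                 method = "spearman"))
  stopifnot(all(rng < 0.3))
  co <- expression_cohort(rows)
  cps <- structure(list(
    cps = list(CP01 = list(cp_id = "CP01", pathways = "P1",
                           genes = c("g", cp1_genes)),
               CP02 = list(cp_id = "CP02", pathways = "P2",
                           genes = c("g", cp2_genes))),
    redundant = TRUE, leftover_cp_id = NA_character_),
    class = "cp_set")
  out <- deredundant_cps(cps, co)
  expect_false(out$cps$redundant)
  expect_true("g" %in% out$cps$cps$CP01$genes)
  expect_false("g" %in% out$cps$cps$CP02$genes)
  rel <- out$relevance[out$relevance$gene == "g", ]
  expect_equal(rel$R[rel$cp_id == "CP01"], 0.5)
  expect_equal(rel$R[rel$cp_id == "CP02"], 0.3)

  # exact partition identity: sum of CP sizes = number of distinct genes
  all_genes <- unique(unlist(lapply(cps$cps, `[[`, "genes")))
  expect_equal(sum(lengths(lapply(out$cps$cps, `[[`, "genes"))),
               length(all_genes))

  # single-CP genes keep their CP
  expect_true(all(cp1_genes %in% out$cps$cps$CP01$genes))

  # all-noise correlations: R = 0 everywhere, tie falls to the smaller CP id
  noise <- matrix(rnorm(6 * n), 6, n,
                  dimnames = list(c("h", sprintf("n%d", 1:5)),
                                  sprintf("s%02d", 1:n)))
  stopifnot(all(abs(cor(noise["h", ], t(noise[-1, ]),
                        method = "spearman")) < 0.3))
  cps_n <- structure(list(
    cps = list(CP01 = list(cp_id = "CP01", pathways = "P1",
                           genes = c("h", "n1", "n2")),
               CP02 = list(cp_id = "CP02", pathways = "P2",
                           genes = c("h", "n3", "n4", "n5"))),
    redundant = TRUE, leftover_cp_id = NA_character_),
    class = "cp_set")
  out_n <- deredundant_cps(cps_n, expression_cohort(noise))
  expect_true("h" %in% out_n$cps$cps$CP01$genes)
  expect_false("h" %in% out_n$cps$cps$CP02$genes)

  expect_error(deredundant_cps(cps, subset_samples(co, 1:10)), NA)
  bad <- expression_cohort(rows[-1, , drop = FALSE])
  expect_error(deredundant_cps(cps, bad), "absent from expression: g")
})
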