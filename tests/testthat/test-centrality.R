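starGraph <- function(nLeaves) {
  A <- matrix(0, nLeaves + 1, nLeaves + 1)
  A[1, 2:(nLeaves + 1)] <- 1
  A[2:(nLeaves + 1), 1] <- 1
  graphFromAdjacency(A)
}

test_that("betweenness matches closed forms on star and path", {
  bt <- nodeBetweenness(starGraph(5))
  expect_equal(unname(bt["1"]), 10)         # C(5,2) leaf pairs
  expect_true(all(bt[-1] == 0))
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1
  expect_equal(unname(nodeBetweenness(graphFromAdjacency(A))["2"]), 1)
})

test_that("betweenness equals exhaustive path enumeration on random graphs", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(5:10, 1)
    A <- randomAdjacency(n, 0.4)
    g <- graphFromAdjacency(A)
    expect_equal(unname(nodeBetweenness(g)), bruteBetweenness(A),
                 tolerance = 1e-10)
  }
})

test_that("K4 spectrum and eigengap follow the known closed form", {
  A <- matrix(1, 4, 4); diag(A) <- 0
  sp <- spectralSummary(graphFromAdjacency(A))
  expect_equal(sp$values, c(3, -1, -1, -1), tolerance = 1e-10)
  # all gaps beyond the first are 0: smallest candidate wins
  expect_equal(sp$iStar, 2)
  # cycle: uniform leading eigenvector
  n <- 8
  C <- matrix(0, n, n)
  for (i in seq_len(n)) {
    C[i, i %% n + 1] <- 1; C[i %% n + 1, i] <- 1
  }
  spc <- spectralSummary(graphFromAdjacency(C))
  expect_lt(diff(range(spc$vectors[, 1])), 1e-10)
})

test_that("eigenpairs satisfy the eigen equation to tight tolerance", {
  cfg <- simulationConfig(nCells = 150, imageSize = 320, rngSeed = 6)
  g <- buildTissueGraph(generateTessellation(cfg)$mask)
  sp <- spectralSummary(g)
  interior <- interiorCells(g)
  A <- adjacencyMatrix(g)[interior, interior]
  for (i in c(1, 2, sp$iStar, length(interior))) {
    resid <- max(abs(A %*% sp$vectors[, i] -
                       sp$values[i] * sp$vectors[, i]))
    expect_lt(resid, 1e-8)
  }
  expect_true(all(sp$vectors[, 1] >= -1e-10))
})

test_that("local influence separates two cliques joined by one edge", {
  n <- 8
  A <- matrix(0, n, n)
  A[1:4, 1:4] <- 1; A[5:8, 5:8] <- 1; diag(A) <- 0
  A[4, 5] <- A[5, 4] <- 1
  g <- graphFromAdjacency(A)
  sp <- spectralSummary(g)
  expect_equal(sp$iStar, 2)
  li <- localInfluence(sp)
  # direct recomputation from an independent eigendecomposition
  e <- eigen(A, symmetric = TRUE)
  oracle <- sqrt(rowSums(e$vectors[, 1:2]^2))
  expect_equal(unname(li$local_influence), oracle, tolerance = 1e-10)
  # the second eigenvector separates the cliques by sign
  expect_lt(sp$vectors[1, 2] * sp$vectors[8, 2], 0)
})

test_that("local influence reduces to |v1| when only one eigenvector is used", {
  A <- matrix(0, 2, 2); A[1, 2] <- A[2, 1] <- 1
  sp <- spectralSummary(graphFromAdjacency(A))
  expect_equal(sp$iStar, 1)
  li <- localInfluence(sp)
  expect_equal(li$local_influence, abs(sp$vectors[, 1]),
               ignore_attr = TRUE)
})

test_that("group centrality means split ACh-only, BK-only and multisensitive", {
  g <- starGraph(5)
  tbl <- centralityTable(g)
  gc <- groupCentrality(tbl, respondersA = c("1", "2", "3"),
                        respondersB = c("3", "4"))
  expect_equal(gc$n, c(2, 1, 1))
  multi <- gc[gc$group == "multisensitive", ]
  expect_equal(multi$betweenness, tbl$betweenness[tbl$cell_id == "3"])
  # disjoint responder sets: empty multisensitive group flagged
  gc2 <- groupCentrality(tbl, c("1", "2"), c("4", "5"))
  expect_true(gc2$empty[gc2$group == "multisensitive"])
  # all nodes in one group: group mean equals the global mean
  gc3 <- groupCentrality(tbl, tbl$cell_id, character(0))
  expect_equal(gc3$betweenness[1], mean(tbl$betweenness))
})

test_that("centrality permutation null matches exhaustive enumeration", {
  set.seed(13)
  A <- randomAdjacency(7, 0.5)
  g <- graphFromAdjacency(A)
  tbl <- centralityTable(g)
  # exact null mean of a size-2 group mean = mean over all C(7,2) pairs,
  # which equals the global mean by linearity
  exact <- mean(tbl$betweenness)
  pn <- centralityPermutationNull(g, list(grp = c("1", "2")),
                                  nPerm = 2000, seed = 5, table = tbl)
  rec <- pn$grp$betweenness
  se <- rec$nullSd / sqrt(length(rec$null))
  expect_lt(abs(rec$nullMean - exact), 4 * se + 1e-12)
  # group = all nodes: every permutation equals the observed value
  pnAll <- centralityPermutationNull(g, list(all = as.character(1:7)),
                                     nPerm = 10, seed = 2, table = tbl)
  expect_true(all(pnAll$all$betweenness$null ==
                    pnAll$all$betweenness$observed))
  # reproducibility
  pn2 <- centralityPermutationNull(g, list(grp = c("1", "2")),
                                   nPerm = 50, seed = 5, table = tbl)
  pn3 <- centralityPermutationNull(g, list(grp = c("1", "2")),
                                   nPerm = 50, seed = 5, table = tbl)
  expect_identical(pn2, pn3)
})
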