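smallCfg <- function(...) {
  args <- utils::modifyList(
    list(nCells = 64, imageSize = 160, duration = 60, rngSeed = 5),
    list(...))
  do.call(simulationConfig, args)
}

test_that("tessellation is deterministic and respects cell count", {
  cfg <- smallCfg()
  t1 <- generateTessellation(cfg)
  t2 <- generateTessellation(cfg)
  expect_identical(t1$mask, t2$mask)
  labs <- setdiff(unique(as.vector(t1$mask)), 0L)
  expect_equal(length(labs), 64)
  expect_setequal(labs, 1:64)
})

test_that("elongation stretches cells along x", {
  cfgRound <- simulationConfig(nCells = 64, imageSize = 200, rngSeed = 3)
  cfgLong <- simulationConfig(nCells = 64, imageSize = 200, rngSeed = 3,
                              elongation = 3)
  rRound <- mean(generateTessellation(cfgRound)$geometry$aspect_ratio)
  rLong <- mean(generateTessellation(cfgLong)$geometry$aspect_ratio)
  expect_gt(rLong, rRound)
  # unjittered square lattice: near-square cells
  cfgSq <- simulationConfig(nCells = 64, imageSize = 160, rngSeed = 3,
                            gridJitter = 0)
  rSq <- generateTessellation(cfgSq)$geometry$aspect_ratio
  expect_lt(max(abs(rSq - 1)), 0.12)
})

test_that("tessellation interior cells average about six neighbours", {
  cfg <- simulationConfig(nCells = 220, imageSize = 512, rngSeed = 11)
  g <- buildTissueGraph(generateTessellation(cfg)$mask)
  interior <- interiorCells(g)
  deg <- rowSums(adjacencyMatrix(g))[interior]
  expect_gt(mean(deg), 5.5)
  expect_lt(mean(deg), 6.5)
})

test_that("sensitivity assignment hits the configured overlap", {
  cfg <- smallCfg(overlapFrac = 0.05)
  g <- buildTissueGraph(generateTessellation(cfg)$mask)
  sens <- assignSensitivities(g, cfg)$sensitivity
  nI <- length(interiorCells(g))
  expect_equal(sum(sens == "both"), round(0.05 * nI))
  # zero overlap: disjoint sets
  sens0 <- assignSensitivities(g, smallCfg(overlapFrac = 0))$sensitivity
  expect_equal(sum(sens0 == "both"), 0)
  # boundary cells never sensitive
  expect_true(all(sens[boundaryCells(g)] == "none"))
})

test_that("multisensitive cells occupy inter-community bottlenecks", {
  cfg <- simulationConfig(nCells = 150, imageSize = 320, rngSeed = 17,
                          overlapFrac = 0.05, growthProb = 0.9)
  g <- buildTissueGraph(generateTessellation(cfg)$mask)
  sens <- assignSensitivities(g, cfg)$sensitivity
  interior <- interiorCells(g)
  multi <- names(sens)[sens == "both"]
  expect_gt(length(multi), 0)
  A <- adjacencyMatrix(g)[interior, interior]
  gi <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  btw <- igraph::betweenness(gi)
  D <- igraph::distances(gi)
  aOnly <- names(sens)[sens == "ACh"]
  bOnly <- names(sens)[sens == "BK"]
  # multisensitive cells sit closer to the opposite population than
  # typical unisensitive cells do, and are more central than average
  dMulti <- vapply(multi, function(id)
    max(min(D[id, aOnly]), min(D[id, bOnly])), numeric(1))
  dA2B <- vapply(aOnly, function(id) min(D[id, bOnly]), numeric(1))
  expect_lte(mean(dMulti), mean(dA2B))
  expect_gt(mean(btw[multi]), mean(btw))
  # with bridge placement disabled the multisensitive set is an ordinary
  # random subset of the sensitive pool
  cfg2 <- simulationConfig(nCells = 150, imageSize = 320, rngSeed = 17,
                           overlapFrac = 0.05, growthProb = 0.9,
                           bridgePlacement = FALSE)
  sens2 <- assignSensitivities(g, cfg2)$sensitivity
  expect_equal(sum(sens2 == "both"), length(multi))
})

test_that("an insensitive cell with no noise and no base rate stays flat", {
  cfg <- smallCfg(noiseSd = 0, baseRate = 0, couplingBeta = 0)
  g <- buildTissueGraph(generateTessellation(cfg)$mask)
  ids <- cellIds(g)
  sens <- factor(rep("none", length(ids)),
                 levels = c("ACh", "BK", "both", "none"))
  names(sens) <- ids
  sim <- simulateTraces(sens, g, cfg, "ACh", 1e-6)
  expect_equal(nrow(sim$events), 0)
  expect_true(all(traceMatrix(sim$traces) == 1))
})

test_that("uncoupled event counts match the closed-form Poisson mean", {
  # without coupling or refractoriness the per-frame hazard is constant,
  # so the expected count is duration x (base + s r(C)); compare the
  # simulated mean over replicates at 3 Monte Carlo standard errors
  cfg <- simulationConfig(nCells = 16, imageSize = 100, duration = 120,
                          couplingBeta = 0, refractory = 0, baseRate = 0.002,
                          stimulusOnset = 20, rngSeed = 1)
  g <- buildTissueGraph(generateTessellation(cfg)$mask)
  ids <- cellIds(g)
  sens <- factor(rep("none", length(ids)),
                 levels = c("ACh", "BK", "both", "none"))
  names(sens) <- ids
  nRep <- 50
  counts <- vapply(seq_len(nRep), function(i) {
    cfg@rngSeed <- 1000 + i
    nrow(simulateTraces(sens, g, cfg, "ACh", 1e-6, render = FALSE)$events)
  }, numeric(1))
  nTrials <- length(ids) * round(cfg@duration * cfg@frameRate)
  pFrame <- cfg@baseRate / cfg@frameRate
  expected <- nTrials * pFrame
  se <- sqrt(nTrials * pFrame * (1 - pFrame))
  expect_lt(abs(mean(counts) - expected), 3 * se / sqrt(nRep))
})

test_that("identical seeds give identical traces and ground truth", {
  cfg <- smallCfg(duration = 40)
  sim1 <- simulateTissue(cfg, "ACh", 1e-6)
  sim2 <- simulateTissue(cfg, "ACh", 1e-6)
  expect_identical(traceMatrix(sim1$traces), traceMatrix(sim2$traces))
  expect_identical(sim1$events, sim2$events)
  expect_identical(sim1$sensitivity, sim2$sensitivity)
})

test_that("all ground-truth onsets lie inside the recording", {
  cfg <- smallCfg(duration = 60)
  sim <- simulateTissue(cfg, "ACh", 1e-5)
  expect_true(all(sim$events$onset >= 0))
  expect_true(all(sim$events$onset <= cfg@duration))
})

test_that("event probability rises with the active-neighbour count", {
  # aggregate over replicates: P(onset in next window | k active
  # neighbours now) must be nondecreasing in k (positive rank correlation)
  cfg <- simulationConfig(nCells = 80, imageSize = 220, duration = 90,
                          couplingBeta = 1.5, rngSeed = 2)
  g <- buildTissueGraph(generateTessellation(cfg)$mask)
  sens <- assignSensitivities(g, cfg)$sensitivity
  winF <- round(cfg@couplingWindow * cfg@frameRate)
  ids <- cellIds(g)
  A <- adjacencyMatrix(g)
  tallies <- matrix(0, 2, 8)  # rows: events, at-risk; cols: k = 0..7
  for (rep in 1:12) {
    cfg@rngSeed <- 300 + rep
    ev <- simulateTraces(sens, g, cfg, "ACh", 3e-6,
                         render = FALSE)$events
    sensIds <- ids[sens[ids] %in% c("ACh", "both")]
    onsetsOf <- split(ev$onset, factor(as.character(ev$cell_id),
                                       levels = ids))
    for (id in sensIds) {
      nbr <- ids[A[id, ] > 0]
      nbrOn <- sort(unlist(onsetsOf[nbr]))
      own <- onsetsOf[[id]]
      for (t0 in seq(cfg@stimulusOnset + 5, cfg@duration - 5, by = 2)) {
        k <- length(unique(nbrOn[nbrOn > t0 - cfg@couplingWindow &
                                   nbrOn <= t0]))
        fires <- any(own > t0 & own <= t0 + cfg@couplingWindow)
        kk <- min(k, 7) + 1
        tallies[1, kk] <- tallies[1, kk] + fires
        tallies[2, kk] <- tallies[2, kk] + 1
      }
    }
  }
  seen <- which(tallies[2, ] >= 30)
  p <- tallies[1, seen] / tallies[2, seen]
  expect_gte(suppressWarnings(stats::cor(seq_along(p), p,
                                         method = "spearman")), 0)
  expect_gt(p[length(p)], p[1])
})

test_that("too coarse a hazard time step is rejected", {
  cfg <- smallCfg(baseRate = 20)
  g <- buildTissueGraph(generateTessellation(cfg)$mask)
  ids <- cellIds(g)
  sens <- factor(rep("none", length(ids)),
                 levels = c("ACh", "BK", "both", "none"))
  names(sens) <- ids
  expect_error(simulateTraces(sens, g, cfg), "time step")
})

test_that("excessive overlap demands fail with a diagnostic", {
  cfg <- smallCfg(overlapFrac = 0.9)
  g <- buildTissueGraph(generateTessellation(cfg)$mask)
  expect_error(assignSensitivities(g, cfg), "multisensitive")
})
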