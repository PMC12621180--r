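pathGraph <- function(n) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) { A[i, i + 1] <- 1; A[i + 1, i] <- 1 }
  graphFromAdjacency(A)
}

eventRow <- function(cell, t, fdhm = 2, fit_ok = TRUE) {
  data.frame(cell_id = as.character(cell), peak_time = t,
             amplitude = 1, rise_time = 0.5, fall_time = 1.5,
             fdhm = fdhm, fit_ok = fit_ok)
}

test_that("influence window is three times the median valid FDHM", {
  ev <- rbind(eventRow(1, 10, fdhm = 1), eventRow(1, 20, fdhm = 2),
              eventRow(2, 30, fdhm = 3))
  expect_equal(influenceWindow(ev), 6)
  expect_equal(influenceWindow(eventRow(1, 5, fdhm = 2)), 6)
  # failed fits are excluded from the median
  ev2 <- rbind(ev, eventRow(2, 40, fdhm = 100, fit_ok = FALSE))
  expect_equal(influenceWindow(ev2), 6)
  expect_error(influenceWindow(eventRow(1, 1, fit_ok = FALSE)), "FDHM")
})

test_that("positive cases count distinct recent neighbours once", {
  g <- pathGraph(3)
  tw <- 4
  # target 2 fires at t=10; neighbour 1 fired twice inside the window,
  # neighbour 3 outside it
  ev <- rbind(eventRow(1, 7), eventRow(1, 8.5), eventRow(3, 3),
              eventRow(2, 10))
  cases <- buildCases(ev, g, tw)
  pos2 <- cases[cases$target == "2" & cases$label == "positive", ]
  expect_equal(nrow(pos2), 1)
  expect_equal(pos2$k, 1)   # neighbour 1 counted once, 3 too old
})

test_that("negative windows group neighbour bursts and spare responders", {
  g <- pathGraph(3)
  tw <- 4
  # neighbours of 2 fire in a burst; 2 never responds:
  # window [3, 7] captures events at 3, 4.5, 6 (k = 2 distinct cells),
  # next window [9, 13] captures the event at 9 (k = 1)
  ev <- rbind(eventRow(1, 3), eventRow(3, 4.5), eventRow(1, 6),
              eventRow(1, 9))
  cases <- buildCases(ev, g, tw)
  neg2 <- cases[cases$target == "2" & cases$label == "negative", ]
  expect_equal(nrow(neg2), 2)
  expect_equal(sort(neg2$k), c(1, 2))
  expect_equal(sort(neg2$ref_time), c(3, 9))
  # a responding target suppresses the negative case for that window
  ev2 <- rbind(ev, eventRow(2, 5))
  cases2 <- buildCases(ev2, g, tw)
  neg2b <- cases2[cases2$target == "2" & cases2$label == "negative", ]
  expect_equal(neg2b$ref_time, 9)
})

test_that("case counts match a hand-enumerated script on a 4-cell path", {
  g <- pathGraph(4)
  tw <- 3
  ev <- rbind(eventRow(1, 10), eventRow(3, 11), eventRow(2, 12),
              eventRow(4, 20), eventRow(3, 21.5))
  cases <- buildCases(ev, g, tw)
  # by hand:
  # target 1 (nbr 2): ev@12 -> window [12,15], 1 silent -> negative k=1
  # target 2 (nbrs 1,3): event@12 preceded by 1@10 & 3@11 -> positive k=2;
  #   negatives: windows [10,13] has target event -> none; [21.5,24.5]
  #   (3@21.5) target silent -> negative k=1
  # target 3 (nbrs 2,4): event@11 no prior nbr events in [8,11) -> no
  #   case; event@21.5 preceded by 4@20 -> positive k=1; negatives:
  #   [12,15] (2@12) target silent -> negative k=1
  # target 4 (nbr 3): ev@11 -> [11,14] silent -> negative k=1;
  #   ev@21.5 -> [21.5,24.5] silent -> negative k=1
  expect_equal(sum(cases$label == "positive"), 2)
  expect_equal(sum(cases$label == "negative"), 5)
  expect_equal(cases$k[cases$target == "2" &
                         cases$label == "positive"], 2)
})

test_that("neighbour categories follow the target's community", {
  g <- pathGraph(4)
  partition <- list(communities = list(c("1", "2")), isolated = "4")
  tw <- 3
  ev <- rbind(eventRow(1, 10), eventRow(3, 10.5), eventRow(2, 12))
  cases <- buildCases(ev, g, tw, partition)
  pos <- cases[cases$label == "positive" & cases$target == "2", ]
  expect_equal(pos$category, "mixed")   # nbrs 1 (cluster) + 3 (not)
  ev2 <- rbind(eventRow(1, 10), eventRow(2, 12))
  pos2 <- buildCases(ev2, g, tw, partition)
  pos2 <- pos2[pos2$label == "positive" & pos2$target == "2", ]
  expect_equal(pos2$category, "cluster")
})

test_that("probability curve and regression match exact counts", {
  mk <- function(k, label, n) {
    do.call(rbind, replicate(n, data.frame(
      target = "t", k = k, label = label, category = NA_character_,
      ref_time = 0, amplitude = 1, rise_time = 1, fall_time = 1,
      fdhm = 1), simplify = FALSE))
  }
  cases <- rbind(mk(1, "positive", 2), mk(1, "negative", 8),
                 mk(2, "positive", 4), mk(2, "negative", 6),
                 mk(3, "positive", 6), mk(3, "negative", 4))
  pc <- probabilityByK(cases)
  expect_equal(pc$curve$p, c(0.2, 0.4, 0.6))
  expect_equal(pc$slope, 0.2, tolerance = 1e-12)
  expect_equal(pc$r2, 1, tolerance = 1e-12)
  # aggregation restricted to shared k
  casesB <- rbind(mk(1, "positive", 1), mk(1, "negative", 1),
                  mk(5, "positive", 1))
  pc2 <- probabilityByK(list(cases, casesB))
  expect_equal(pc2$curve$k, 1)
})

test_that("characteristic means group by k and category", {
  cases <- data.frame(
    target = "t", k = c(1, 1, 2), label = "positive",
    category = c("cluster", "cluster", "non-cluster"),
    ref_time = 0, amplitude = c(1, 2, 5), rise_time = c(1, 3, 5),
    fall_time = c(2, 4, 6), fdhm = c(1, 1, 9))
  ch <- characteristicsByK(cases)
  row1 <- ch[ch$category == "cluster" & ch$k == 1, ]
  expect_equal(row1$amplitude, 1.5)
  expect_equal(row1$n, 2)
  row2 <- ch[ch$category == "non-cluster" & ch$k == 2, ]
  expect_equal(row2$fdhm, 9)
})

test_that("temporal permutation preserves per-cell event counts", {
  set.seed(12)
  g <- pathGraph(5)
  ev <- do.call(rbind, lapply(1:5, function(cl)
    do.call(rbind, lapply(sort(runif(cl + 1, 0, 100)), function(t)
      eventRow(cl, t)))))
  pn <- temporalPermutationNull(ev, g, tw = 5, nPerm = 15, seed = 4)
  expect_length(pn$slopes, 15)
  expect_equal(length(pn$nullCurves), 15)
  # reproducible
  pn2 <- temporalPermutationNull(ev, g, tw = 5, nPerm = 15, seed = 4)
  expect_identical(pn$nullMeanByK, pn2$nullMeanByK)
})

test_that("a single active cell yields an identity permutation", {
  g <- pathGraph(3)
  ev <- rbind(eventRow(2, 10), eventRow(2, 30), eventRow(2, 50))
  pn <- temporalPermutationNull(ev, g, tw = 5, nPerm = 5, seed = 1)
  for (cv in pn$nullCurves)
    expect_identical(cv, pn$observed$curve)
})
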