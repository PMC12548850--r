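# Anchor adequacy metrics, k-means re-estimation, genetic refinement.

test_that("ratio metric is the max of the four width/height ratios", {
  expect_equal(ratio_metric(cbind(10, 13), cbind(10, 13))[1, 1], 1)
  expect_equal(ratio_metric(cbind(20, 20), cbind(10, 10))[1, 1], 2)
  expect_equal(ratio_metric(cbind(10, 40), cbind(20, 20))[1, 1], 2)
  expect_error(ratio_metric(cbind(-1, 5), cbind(1, 1)), "positive")
})

test_that("AAT and BPR agree with brute-force enumeration", {
  an <- anchor_set(rbind(c(10, 10), c(20, 20), c(80, 80)))
  set.seed(1)
  boxes <- cbind(runif(50, 5, 120), runif(50, 5, 120))

  r <- sapply(seq_len(nrow(an$wh)), function(j) {
    sapply(seq_len(nrow(boxes)), function(i) {
      max(boxes[i, 1] / an$wh[j, 1], an$wh[j, 1] / boxes[i, 1],
          boxes[i, 2] / an$wh[j, 2], an$wh[j, 2] / boxes[i, 2])
    })
  })
  expect_equal(aat(boxes, an), mean(rowSums(r < 4) / 3))
  expect_equal(bpr(boxes, an), mean(apply(r, 1, min) < 4))

  # exact anchors: both saturate
  exact <- anchor_set(rbind(c(10, 10), c(10, 10), c(10, 10)))
  expect_equal(aat(cbind(10, 10), exact), 1)
  expect_equal(bpr(cbind(10, 10), exact), 1)
  # hopeless anchor
  expect_equal(bpr(cbind(10, 10), anchor_set(cbind(100, 100))), 0)
  expect_equal(aat(cbind(10, 10), anchor_set(cbind(100, 100))), 0)
  expect_error(bpr(matrix(0, 0, 2), an), "non-empty")
})

test_that("BPR is monotone in anchor-set inclusion and in the threshold", {
  set.seed(2)
  boxes <- cbind(runif(80, 5, 200), runif(80, 5, 200))
  base <- rbind(c(12, 14), c(40, 40))
  bigger <- rbind(base, c(120, 130))
  expect_gte(bpr(boxes, anchor_set(bigger)), bpr(boxes, anchor_set(base)))

  thr <- c(1.5, 2, 3, 4, 6)
  vals <- vapply(thr, function(t) bpr(boxes, anchor_set(base, ratio_threshold = t)),
                 numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("k-means recovers separated clusters and is deterministic", {
  # k distinct boxes, one per cluster
  pts <- rbind(c(10, 12), c(30, 28), c(80, 90))
  km <- kmeans_anchors(pts, k = 3, seed = 1)
  expect_equal(km$wh, anchor_set(pts)$wh)

  set.seed(3)
  c1 <- cbind(rnorm(40, 20, 0.8), rnorm(40, 25, 0.8))
  c2 <- cbind(rnorm(40, 120, 0.8), rnorm(40, 100, 0.8))
  km2 <- kmeans_anchors(rbind(c1, c2), k = 2, seed = 4)
  expect_lt(max(abs(km2$wh[1, ] - c(20, 25))), 1)
  expect_lt(max(abs(km2$wh[2, ] - c(120, 100))), 1)

  again <- kmeans_anchors(rbind(c1, c2), k = 2, seed = 4)
  expect_identical(km2$wh, again$wh)

  expect_error(kmeans_anchors(rbind(c(1, 1), c(1, 1)), k = 2), "distinct")
})

test_that("k-means objective trace is nonincreasing", {
  set.seed(5)
  boxes <- cbind(runif(100, 5, 300), runif(100, 5, 300))
  km <- kmeans_anchors(boxes, k = 5, iters = 30, seed = 2)
  trace <- attr(km, "objective_trace")
  expect_length(trace, 30)
  expect_true(all(diff(trace) <= 1e-12))
})

test_that("k-means reaches the exhaustive-assignment optimum on tiny inputs", {
  # 9 boxes in 3 tight groups; enumerate all 3^9 assignments for the true
  # minimum of the normalized within-cluster sum of squares
  set.seed(6)
  centers <- rbind(c(15, 18), c(60, 50), c(150, 160))
  boxes <- do.call(rbind, lapply(1:3, function(g) {
    sweep(matrix(rnorm(6, 0, 2), 3, 2), 2, centers[g, ], `+`)
  }))
  axis_max <- apply(boxes, 2, max)
  bn <- sweep(boxes, 2, axis_max, `/`)
  n <- nrow(bn); k <- 3
  best <- Inf
  assign_cost <- function(asg) {
    tot <- 0
    for (j in seq_len(k)) {
      sel <- asg == j
      if (any(sel)) {
        ctr <- colMeans(bn[sel, , drop = FALSE])
        tot <- tot + sum(sweep(bn[sel, , drop = FALSE], 2, ctr)^2)
      }
    }
    tot
  }
  grid <- expand.grid(rep(list(1:k), n))
  for (r in seq_len(nrow(grid))) {
    best <- min(best, assign_cost(as.integer(grid[r, ])))
  }
  objectives <- vapply(1:10, function(s) {
    km <- kmeans_anchors(boxes, k = 3, iters = 30, seed = s)
    tail(attr(km, "objective_trace"), 1)
  }, numeric(1))
  expect_lt(min(objectives) - best, 1e-6)

  # independent cross-check with the reference implementation
  ref <- stats::kmeans(bn, centers = 3, nstart = 20)
  expect_lt(abs(best - ref$tot.withinss), 1e-9)
})

test_that("genetic refinement is elitist and improves a mis-scaled init", {
  set.seed(7)
  boxes <- cbind(runif(60, 10, 60), runif(60, 10, 60))
  good <- kmeans_anchors(boxes, k = 9, seed = 0)

  # boxes drawn exactly at the init anchors: fitness already maximal
  exact_boxes <- good$wh
  ga0 <- ga_refine(good, exact_boxes, generations = 50, seed = 1)
  expect_gte(attr(ga0, "fitness"), anchor_fitness(exact_boxes, good))

  bad <- anchor_set(good$wh * 3, good$ratio_threshold, good$bpr_cutoff)
  improved <- 0L
  for (s in 1:50) {
    ga <- ga_refine(bad, boxes, generations = 120, seed = s)
    trace <- attr(ga, "fitness_trace")
    expect_true(all(diff(trace) >= 0))  # elitism: best-ever nondecreasing
    if (attr(ga, "fitness") > anchor_fitness(boxes, bad)) improved <- improved + 1L
  }
  expect_gte(improved, 49L)

  # determinism
  g1 <- ga_refine(bad, boxes, generations = 40, seed = 3)
  g2 <- ga_refine(bad, boxes, generations = 40, seed = 3)
  expect_identical(g1$wh, g2$wh)
  # zero generations returns the init
  expect_equal(ga_refine(bad, boxes, generations = 0)$wh, bad$wh)
})

test_that("anchor check keeps adequate defaults and never lowers BPR", {
  # boxes sampled tightly around the nine defaults pass the gate
  def <- default_anchors()
  set.seed(8)
  near <- def$wh[sample(9, 200, replace = TRUE), ] * runif(400, 0.9, 1.1)
  res <- check_anchors(near)
  expect_false(attr(res, "recalculated"))
  expect_equal(res$wh, def$wh)

  # all boxes tiny: recalculated anchors stay small
  tiny <- cbind(runif(100, 2, 7), runif(100, 2, 7))
  res2 <- check_anchors(tiny, k = 9, generations = 150, seed = 1)
  expect_true(attr(res2, "recalculated"))
  expect_lt(max(res2$wh), 40)
  expect_gte(bpr(tiny, res2), bpr(tiny, def))
})
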