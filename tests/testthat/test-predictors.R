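# The inclined-potential and nearest-neighbour scorers, the descending
# ranking operator and the overall dispatch rule.

toy_net <- function() {
  weighted_network(data.frame(a = c("Q", "Q"), b = c("P1", "P2"),
                              weight = c(0.9, 0.4)))
}
toy_ann <- annotation_set(list(P1 = c(1L, 7L), P2 = c(7L, 21L)))

test_that("inclined potential accumulates neighbour weights per category", {
  prof <- inclined_potential("Q", toy_net(), toy_ann)
  expected <- numeric(24)
  expected[1] <- 0.9; expected[7] <- 1.3; expected[21] <- 0.4
  expect_equal(prof$scores, expected)
  expect_equal(prof$ranking[1:3], c(7L, 1L, 21L))
  expect_false(prof$unpredictable)
  expect_equal(prof$method, "network")
})

test_that("an isolated or unannotated-neighbourhood node is flagged unpredictable", {
  net <- weighted_network(data.frame(a = "a", b = "b", weight = 1),
                          nodes = c("a", "b", "iso"))
  ann <- annotation_set(list(z = 1L))
  expect_equal(nrow(net_neighbors(net, "iso")), 0L)
  prof <- inclined_potential("iso", net, ann)
  expect_true(prof$unpredictable)
  prof2 <- inclined_potential("a", net, ann)  # neighbour b unannotated
  expect_true(prof2$unpredictable)
  expect_error(inclined_potential("nowhere", net, ann), "not in the network")
})

test_that("scores scale linearly with edge weights and the ranking is scale invariant", {
  net <- toy_net()
  net2 <- weighted_network(transform(net$edges, weight = weight * 2))
  p1 <- inclined_potential("Q", net, toy_ann)
  p2 <- inclined_potential("Q", net2, toy_ann)
  expect_equal(p2$scores, 2 * p1$scores)
  expect_equal(p2$ranking, p1$ranking)
})

test_that("inclined potential matches the per-neighbour per-category brute-force oracle", {
  for (s in 1:3) {
    sim <- generate_network(synthetic_config(seed = s, n_proteins = 60,
                                             edge_density = 0.08))
    nodes <- withr::with_seed(s, sample(sim$network$nodes, 12))
    for (q in nodes) {
      prof <- inclined_potential(q, sim$network, sim$annotations)
      expect_equal(prof$scores, oracle_inclined(q, sim$network,
                                                sim$annotations),
                   tolerance = 1e-12)
      # conservation: total potential equals sum of w * |functions|
      nb <- net_neighbors(sim$network, q)
      expected_total <- sum(vapply(seq_len(nrow(nb)), function(i) {
        fns <- sim$annotations[[nb$id[i]]]
        if (is.null(fns)) 0 else nb$weight[i] * length(fns)
      }, numeric(1)))
      expect_equal(sum(prof$scores), expected_total, tolerance = 1e-9)
    }
  }
})

test_that("the descending ranking operator orders scores and resolves ties per config", {
  s <- numeric(24)
  s[15] <- 9; s[1] <- 5; s[5] <- 2
  expect_equal(rank_functions(s)$ranking[1:3], c(15L, 1L, 5L))
  expect_equal(rank_functions(rep(1, 24))$ranking, 1:24)
  r1 <- rank_functions(rep(1, 24), tie = "random", seed = 1)
  r2 <- rank_functions(rep(1, 24), tie = "random", seed = 2)
  expect_equal(sort(r1$ranking), 1:24)
  expect_false(identical(r1$ranking, r2$ranking))
  expect_identical(r1$ranking,
                   rank_functions(rep(1, 24), tie = "random", seed = 1)$ranking)
  # ranking sorts scores non-increasingly in all cases
  withr::with_seed(3, {
    sc <- sample(0:5, 24, replace = TRUE)
    rk <- rank_functions(sc)$ranking
    expect_true(all(diff(sc[rk]) <= 0))
  })
})

test_that("cosine similarity matches closed forms and rejects degenerate input", {
  v <- c(3, 4, 12)
  expect_equal(cosine_similarity(v, v), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1), c(1, 0)), 1 / sqrt(2))
  expect_error(cosine_similarity(c(0, 0), c(1, 0)), "zero-norm")
  expect_error(cosine_similarity(c(a = 1, b = 0), c(b = 1, a = 0)),
               "names disagree")
  expect_error(cosine_similarity(1:2, 1:3), "length")
})

test_that("the nearest-neighbour potential takes the best carrier per category", {
  # training vectors constructed to have cosine 0.9 and 0.6 to the query
  q <- c(1, 0)
  A <- c(0.9, sqrt(1 - 0.81))
  B <- c(0.6, sqrt(1 - 0.36))
  mat <- rbind(A = A, B = B)
  ann <- annotation_set(list(A = 3L, B = c(3L, 8L)))
  prof <- hybrid_potential(q, mat, ann)
  expect_equal(prof$scores[3], 0.9, tolerance = 1e-12)
  expect_equal(prof$scores[8], 0.6, tolerance = 1e-12)
  expect_equal(sum(prof$scores > 0), 2L)
  expect_equal(prof$ranking[1], 3L)
  expect_equal(prof$method, "hybrid")
  # sum aggregation accumulates over carriers instead
  prof_sum <- hybrid_potential(q, mat, ann, agg = "sum")
  expect_equal(prof_sum$scores[3], 1.5, tolerance = 1e-12)
})

test_that("a single training protein ties its categories at its similarity", {
  mat <- rbind(A = c(1, 2, 3))
  ann <- annotation_set(list(A = c(2L, 5L)))
  prof <- hybrid_potential(c(2, 4, 6), mat, ann)
  expect_equal(prof$scores[2], prof$scores[5])
  expect_equal(prof$scores[2], 1, tolerance = 1e-12)
  expect_equal(prof$ranking[1:2], c(2L, 5L))
})

test_that("a query identical to a training vector puts that protein's functions first", {
  withr::with_seed(8, {
    mat <- matrix(runif(5 * 10), nrow = 5,
                  dimnames = list(paste0("t", 1:5), NULL))
    ann <- annotation_set(list(t1 = c(4L, 9L), t2 = 1L, t3 = 2L,
                               t4 = 3L, t5 = 6L))
    prof <- hybrid_potential(mat["t1", ], mat, ann)
    expect_equal(prof$scores[4], 1, tolerance = 1e-12)
    expect_equal(prof$scores[9], 1, tolerance = 1e-12)
    expect_equal(sort(prof$ranking[1:2]), c(4L, 9L))
  })
})

test_that("overall prediction dispatches network first, then hybrid, then fails", {
  net <- toy_net()
  ann <- annotation_set(list(P1 = c(1L, 7L), P2 = c(7L, 21L), Q = 2L))
  mat <- rbind(Q = c(1, 0), P1 = c(1, 0.1), S1 = c(0, 1))
  train_ann <- annotation_set(list(P1 = 1L, S1 = 5L))

  p_net <- predict_overall("Q", net = net, ann = ann)
  expect_equal(p_net$method, "network")
  # the query's own annotation was hidden: scores match the toy example
  expect_equal(p_net$scores[7], 1.3)

  p_hyb <- predict_overall("S0", net = net, ann = ann,
                           query_features = c(0, 1), train_mat = mat,
                           train_ann = train_ann)
  expect_equal(p_hyb$method, "hybrid")

  # network node whose neighbours are unannotated falls through to hybrid
  net2 <- weighted_network(data.frame(a = "Q", b = "dark", weight = 1))
  p_fall <- predict_overall("Q", net = net2, ann = ann,
                            query_features = c(1, 0), train_mat = mat,
                            train_ann = train_ann)
  expect_equal(p_fall$method, "hybrid")

  expect_error(predict_overall("ghost", net = net2, ann = ann),
               "unpredictable")
})
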