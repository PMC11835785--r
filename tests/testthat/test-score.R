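test_that("local BIC matches the hand-computed single-node case", {
  # 4 rows all in one state: ML log-likelihood 0, penalty (log 4)/2
  cohort <- cohort_from_counts(c(false = 4L, true = 0L))
  sc <- bic_score(network_structure("x"), cohort)
  expect_equal(sc$total, -log(4) / 2, tolerance = 1e-12)
  expect_identical(sc$score_name, "bic")
  expect_identical(sc$n, 4L)
})

test_that("the BIC total decomposes into per-node local scores", {
  gt <- build_ground_truth()
  cohort <- sample_cohort(gt, 500, seed = 21)
  sc <- bic_score(gt$structure, cohort)
  expect_equal(sc$total, sum(sc$per_node), tolerance = 1e-9)

  # adding an arc changes only the child's local score
  st0 <- network_structure(gt$structure$nodes)
  st1 <- network_structure(gt$structure$nodes, arcs = rbind(c("sex", "smoking")))
  s0 <- bic_score(st0, cohort)
  s1 <- bic_score(st1, cohort)
  others <- setdiff(gt$structure$nodes, "smoking")
  expect_equal(s0$per_node[others], s1$per_node[others], tolerance = 1e-12)
})

test_that("a deterministic dependence beats independence under BIC", {
  # A and B identical coin flips: likelihood gain n log 2 dwarfs the
  # penalty (log n)/2
  set.seed(5)
  a <- sample(c("false", "true"), 100, replace = TRUE)
  cohort <- binary_cohort(A = a, B = a)
  with_arc <- bic_score(network_structure(c("A", "B"),
                                          arcs = rbind(c("A", "B"))), cohort)
  without <- bic_score(network_structure(c("A", "B")), cohort)
  expect_gt(with_arc$total, without$total)
  p <- mean(a == "true")
  expect_equal(with_arc$total - without$total,
               -100 * (p * log(p) + (1 - p) * log(1 - p)) - log(100) / 2,
               tolerance = 1e-9)
})

test_that("I-equivalent two-variable structures score identically", {
  set.seed(6)
  cohort <- binary_cohort(
    A = sample(c("false", "true"), 200, replace = TRUE, prob = c(0.3, 0.7)),
    B = sample(c("false", "true"), 200, replace = TRUE, prob = c(0.6, 0.4)))
  ab <- bic_score(network_structure(c("A", "B"), arcs = rbind(c("A", "B"))),
                  cohort)
  ba <- bic_score(network_structure(c("A", "B"), arcs = rbind(c("B", "A"))),
                  cohort)
  expect_equal(ab$total, ba$total, tolerance = 1e-9)
})

test_that("hill climbing leaves independent variables unconnected", {
  empty_on <- 0L
  for (s in 1:10) {
    set.seed(300 + s)
    df <- as.data.frame(replicate(5, sample(c("false", "true"), 2000,
                                            replace = TRUE),
                                  simplify = FALSE))
    names(df) <- paste0("V", 1:5)
    cohort <- as_cohort(df, binary_schema(paste0("V", 1:5)))
    st <- hill_climb(cohort)
    empty_on <- empty_on + (nrow(st$arcs) == 0L)
  }
  expect_gte(empty_on, 9L)
})

test_that("hill climbing honors constraints and never loses score", {
  set.seed(31)
  df <- as.data.frame(replicate(3, sample(c("false", "true"), 500,
                                          replace = TRUE), simplify = FALSE))
  names(df) <- c("A", "B", "C")
  cohort <- as_cohort(df, binary_schema(c("A", "B", "C")))
  cons <- arc_constraints(whitelist = rbind(c("A", "B")),
                          blacklist = rbind(c("C", "A")))
  st <- hill_climb(cohort, cons)
  # whitelist is inviolable even on pure-noise data
  expect_true(bnaf:::has_arc(st$arcs, "A", "B"))
  expect_false(bnaf:::has_arc(st$arcs, "C", "A"))
  expect_true(is_acyclic(st$nodes, st$arcs))
  start <- network_structure(st$nodes, arcs = cons$whitelist,
                             whitelist = cons$whitelist,
                             blacklist = cons$blacklist)
  expect_gte(bic_score(st, cohort)$total, bic_score(start, cohort)$total)
})

test_that("hill climbing recovers a strong generating dependence", {
  gt <- build_ground_truth()
  hits <- 0L
  for (s in 1:3) {
    rec <- structure_recovery_report(gt, n = 20000, seed = 400 + s)
    hits <- hits + rec$bmi_fat_recovered
    expect_true(is_acyclic(rec$structure$nodes, rec$structure$arcs))
  }
  expect_gte(hits, 2L)
})

test_that("max_parents caps the in-degree", {
  gt <- build_ground_truth()
  cohort <- sample_cohort(gt, 2000, seed = 77)
  st <- hill_climb(cohort, max_parents = 1L)
  indeg <- table(factor(st$arcs[, 2], levels = st$nodes))
  expect_true(all(indeg <= 1L))
})
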