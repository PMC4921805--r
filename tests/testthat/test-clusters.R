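test_that("cluster chaining follows the adjacent-gap rule on known cases", {
  ev <- data.frame(
    variant = c("V1", "V2", "V3"), pos = c(10, 55, 120), branch = "b1"
  )
  cl <- detect_clusters(ev, max_gap = 50)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$members[[1]], c("V1", "V2"))
  expect_equal(cl$span, 46L)

  # a chain of six with adjacent gaps <= 50 may span far more than 50 bp
  pos6 <- c(2866271, 2866290, 2866320, 2866340, 2866350, 2866356)
  ev6 <- data.frame(variant = paste0("V", 351:356), pos = pos6, branch = "E-V257")
  cl6 <- detect_clusters(ev6)
  expect_equal(nrow(cl6), 1L)
  expect_equal(cl6$n_members, 6L)
  expect_equal(cl6$span, 86L)

  # variants on all-different branches never cluster
  ev3 <- data.frame(pos = c(10, 12, 14), branch = c("x", "y", "z"))
  expect_equal(nrow(detect_clusters(ev3)), 0L)

  # a homoplasic variant clusters independently on each branch it recurs on
  evh <- data.frame(
    variant = c("Va", "Vb", "Va", "Vc"),
    pos = c(100, 110, 100, 120),
    branch = c("b1", "b1", "b2", "b2")
  )
  clh <- detect_clusters(evh)
  expect_equal(nrow(clh), 2L)
  expect_true(all(vapply(clh$members, function(m) "Va" %in% m, TRUE)))
})

test_that("cluster chaining matches exhaustive subset enumeration", {
  set.seed(88)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    pos <- sort(sample.int(300, n))
    branch <- paste0("b", sample.int(3, n, replace = TRUE))
    cl <- detect_clusters(
      data.frame(variant = as.character(seq_len(n)), pos = pos, branch = branch)
    )
    got <- lapply(seq_len(nrow(cl)), function(i) {
      sort(as.integer(cl$members[[i]]))
    })
    want <- oracle_cluster_sets(pos, branch, 50)
    expect_setequal(
      vapply(got, paste, "", collapse = ","),
      vapply(want, paste, "", collapse = ",")
    )
  }
})

test_that("cluster spans are inclusive", {
  expect_equal(cluster_span(2866271, 2866356), 86L)
  expect_equal(cluster_span(100, 100), 1L)
  expect_error(cluster_span(10, 5))
})

test_that("the permutation null matches its enumerable expectation and is reproducible", {
  # n=2, L=100, B=2: P(pair within 50 bp) = 3725/4950, P(same branch) = 1/2,
  # both variants clustered when it happens
  pn <- permutation_null(2, 100, 2, reps = 4000, seed = 9)
  expect_equal(pn$lambda, 2 * (3725 / 4950) * 0.5, tolerance = 0.05)

  # single variant can never cluster
  expect_equal(permutation_null(1, 100, 3, reps = 50, seed = 1)$lambda, 0)

  # forced saturation: one branch, gap covering the whole locus
  sat <- permutation_null(5, 100, 1, reps = 20, max_gap = 99, seed = 1)
  expect_equal(sat$lambda, 5)

  expect_identical(
    permutation_null(10, 500, 5, reps = 50, seed = 3)$counts,
    permutation_null(10, 500, 5, reps = 50, seed = 3)$counts
  )
  expect_error(permutation_null(200, 100, 2, reps = 10), "distinct")
})

test_that("lambda grows with gap size and variant count; the tail shrinks with the observation", {
  l_gap <- vapply(
    c(10, 50, 200),
    function(g) permutation_null(30, 5000, 5, reps = 1500, max_gap = g, seed = 4)$lambda,
    numeric(1)
  )
  expect_true(all(diff(l_gap) > 0))
  l_n <- vapply(
    c(10, 30, 90),
    function(n) permutation_null(n, 5000, 5, reps = 1500, seed = 4)$lambda,
    numeric(1)
  )
  expect_true(all(diff(l_n) > 0))
  p <- vapply(0:10, function(k) as.numeric(poisson_tail_p(k, 2)), numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("the Poisson tail is exact in closed form and survives deep tails", {
  expect_equal(as.numeric(poisson_tail_p(0, 5)), 1)
  expect_equal(as.numeric(poisson_tail_p(2, 1)), 1 - exp(-1) * 2)
  deep <- poisson_tail_p(25, 1)
  expect_gt(as.numeric(deep), 0)
  expect_lt(as.numeric(deep), 1e-20)
  expect_equal(
    attr(deep, "log10_p"),
    ppois(24, 1, lower.tail = FALSE, log.p = TRUE) / log(10)
  )
  # far beyond double-precision probabilities the log stays informative
  extreme <- poisson_tail_p(500, 0.5)
  expect_lt(attr(extreme, "log10_p"), -1000)
  expect_error(poisson_tail_p(3, 0), "positive")
})

test_that("the excess test guards a zero lambda from finite replicates", {
  # max_gap = 0 with distinct positions: clustering is impossible
  pn <- permutation_null(5, 1000, 2, reps = 40, max_gap = 0, seed = 2)
  expect_equal(pn$lambda, 0)
  expect_equal(excess_test(pn, 0)$p, 1)
  ex <- excess_test(pn, 3)
  expect_true(ex$lambda_guarded)
  expect_equal(ex$lambda, 1 / 80)
  expect_lt(ex$p, 1e-4)
})

test_that("the Poisson approximation to the permutation null is roughly calibrated", {
  # the clustered count is compound (a chance pair adds 2 variants), so the
  # Poisson tail is mildly anticonservative; bound the miscalibration
  pn <- permutation_null(134, 61165, 30, reps = 3000, seed = 15)
  set.seed(16)
  p <- vapply(1:500, function(i) {
    pos <- sample.int(61165, 134)
    br <- sample.int(30, 134, replace = TRUE)
    as.numeric(poisson_tail_p(ltrconv:::count_clustered(pos, br, 50), pn$lambda))
  }, numeric(1))
  expect_lte(mean(p < 0.05), 0.12)
  expect_lte(mean(p < 0.01), 0.03)
})

test_that("the two-sided Fisher probability equals the point-probability sum", {
  expect_equal(fisher_exact_two_sided(2, 0, 0, 2), 1 / 3)
  expect_equal(fisher_exact_two_sided(5, 5, 5, 5), 1)
  expect_lt(fisher_exact_two_sided(25, 109, 350, 42035), 1e-16)
  expect_error(fisher_exact_two_sided(0, 0, 0, 0), "zero")

  # independent route: stats::fisher.test on random tables
  set.seed(7)
  for (rep in 1:25) {
    tab <- matrix(rpois(4, 8), 2)
    if (sum(tab) == 0) next
    expect_equal(
      fisher_exact_two_sided(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
      stats::fisher.test(tab)$p.value,
      tolerance = 1e-10
    )
  }
})

test_that("clustered proportions are computed over distinct member variants", {
  ev <- data.frame(
    variant = paste0("V", 1:4), pos = c(1, 10, 200, 205), branch = "b"
  )
  cl <- detect_clusters(ev)
  pr <- clustered_proportion(cl, 10)
  expect_equal(pr$k, 4L)
  expect_equal(pr$percent, 40)

  none <- detect_clusters(data.frame(pos = c(1, 500), branch = c("a", "b")))
  expect_equal(clustered_proportion(none, 12)$percent, 0)

  # published-scale arithmetic
  expect_equal(100 * 25 / 134, 18.66, tolerance = 0.01)
  expect_equal(round(100 * 36 / 51, 2), 70.59)
})
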