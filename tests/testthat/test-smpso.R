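test_that("Pareto dominance follows the strict componentwise rule", {
  expect_true(dominates(c(1, 1), c(2, 2)))
  expect_false(dominates(c(1, 2), c(2, 1)))
  expect_false(dominates(c(2, 1), c(1, 2)))
  expect_false(dominates(c(1, 1), c(1, 1)))
  expect_true(dominates(c(1, 2), c(1, 3)))
})

test_that("the archive rejects dominated candidates and prunes by crowding", {
  a <- greenhits:::new_archive(capacity = 10)
  a <- update_archive(a, 1, c(1, 1))
  # dominated candidate: unchanged
  a2 <- update_archive(a, 2, c(2, 2))
  expect_equal(a2$objectives, a$objectives)
  # candidate dominating two entries replaces both
  b <- greenhits:::new_archive(capacity = 10)
  b <- update_archive(b, 1, c(3, 3))
  b <- update_archive(b, 2, c(4, 2.5))
  b <- update_archive(b, 3, c(1, 1))
  expect_equal(nrow(b$objectives), 1L)
  expect_equal(as.numeric(b$objectives), c(1, 1))

  # capacity 3, four nondominated points: hand-computed crowding distances
  # front {(0,10),(1,6),(4,3),(10,0)}; interior distances
  # (1,6): (4-0)/10 + (10-3)/10 = 1.1 ; (4,3): (10-1)/10 + (6-0)/10 = 1.5
  # so (1,6) is pruned
  cc <- greenhits:::new_archive(capacity = 3)
  pts <- list(c(0, 10), c(1, 6), c(4, 3), c(10, 0))
  for (i in seq_along(pts)) cc <- update_archive(cc, i, pts[[i]])
  expect_equal(nrow(cc$objectives), 3L)
  kept <- apply(cc$objectives, 1, paste, collapse = ",")
  expect_false("1,6" %in% kept)
  expect_true(all(c("0,10", "4,3", "10,0") %in% kept))
})

test_that("crowding distance marks boundaries infinite and orders interiors", {
  d <- crowding_distance(rbind(c(0, 10), c(1, 6), c(4, 3), c(10, 0)))
  expect_equal(d[c(1, 4)], c(Inf, Inf))
  expect_equal(d[2], 1.1, tolerance = 1e-12)
  expect_equal(d[3], 1.5, tolerance = 1e-12)
})

test_that("the constriction factor matches its closed form", {
  expect_equal(constriction(2, 2.5), 2 / abs(2 - 4.5 - sqrt(4.5^2 - 4 * 4.5)))
  expect_equal(constriction(2, 2.5), 0.5, tolerance = 1e-12)
  expect_equal(constriction(1.5, 1.5), 1)   # phi <= 4: no constriction
})

test_that("velocity updates respect the speed constraint and fixed points", {
  space <- search_space(names = c("a", "b"), lower = c(0, 0), upper = c(10, 4))
  # leader = pbest = position, zero velocity: the particle does not move
  set.seed(1)
  upd <- greenhits:::velocity_position_update(c(5, 2), c(0, 0), c(5, 2),
                                              c(5, 2), space)
  expect_equal(upd$position, c(5, 2))
  expect_equal(upd$velocity, c(0, 0))
  # clamping contract over random updates
  set.seed(2)
  delta <- (space$upper - space$lower) / 2
  for (i in 1:200) {
    upd <- greenhits:::velocity_position_update(
      runif(2, 0, 10), runif(2, -5, 5), runif(2, 0, 10), runif(2, 0, 10), space)
    expect_true(all(abs(upd$velocity) <= delta + 1e-12))
    expect_true(all(upd$position >= space$lower - 1e-12 &
                      upd$position <= space$upper + 1e-12))
  }
})

test_that("positions decode to clamped round-half-up integers", {
  space <- search_space(names = c("a", "b"), lower = c(1, 100), upper = c(5, 500))
  expect_identical(decode_position(c(3, 250), space), c(a = 3L, b = 250L))
  expect_identical(decode_position(c(3.5, 250.5), space), c(a = 4L, b = 251L))
  expect_identical(decode_position(c(0.4, 600), space), c(a = 1L, b = 500L))
})

test_that("the optimizer recovers the exact Pareto front of an integer toy problem", {
  # f(x) = (x^2, (x-2)^2) over x in [-10, 20]: the front is x in {0, 1, 2}
  space <- search_space(names = "x", lower = -10, upper = 20)
  f <- function(hp) { x <- hp[["x"]]; c(x^2, (x - 2)^2) }
  res <- smpso_optimize(f, space, swarm_size = 20, iterations = 25, seed = 3)
  # brute-force front over all 31 integer candidates
  all_obj <- t(vapply(-10:20, function(x) c(x^2, (x - 2)^2), c(0, 0)))
  nondom <- vapply(seq_len(nrow(all_obj)), function(i)
    !any(vapply(seq_len(nrow(all_obj)), function(j)
      dominates(all_obj[j, ], all_obj[i, ]), TRUE)), TRUE)
  front <- all_obj[nondom, , drop = FALSE]
  got <- res$archive$objectives[order(res$archive$objectives[, 1]), , drop = FALSE]
  expect_equal(got, front[order(front[, 1]), , drop = FALSE],
               ignore_attr = TRUE)
  # archive is mutually nondominated
  n <- nrow(got)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) expect_false(dominates(got[i, ], got[j, ]))
  }
})

test_that("a single-point search space yields exactly that point", {
  space <- search_space(names = "x", lower = 3, upper = 3)
  res <- smpso_optimize(function(hp) c(hp[["x"]], -hp[["x"]]), space,
                        swarm_size = 4, iterations = 3, seed = 1)
  expect_equal(nrow(res$archive$objectives), 1L)
  expect_equal(as.numeric(res$archive$objectives), c(3, -3))
  # memoization: the one decoded candidate is evaluated once
  expect_equal(res$n_evaluations, 1L)
})

test_that("optimization runs are bit-reproducible from the seed", {
  space <- search_space(names = c("x", "y"), lower = c(0, 0), upper = c(8, 8))
  f <- function(hp) c(hp[["x"]] + 0.3 * hp[["y"]], (hp[["x"]] - 5)^2 + hp[["y"]])
  r1 <- smpso_optimize(f, space, swarm_size = 10, iterations = 10, seed = 99)
  r2 <- smpso_optimize(f, space, swarm_size = 10, iterations = 10, seed = 99)
  expect_identical(r1$archive, r2$archive)
  expect_identical(r1$n_evaluations, r2$n_evaluations)
})

test_that("failed evaluations are logged and kept out of the archive", {
  space <- search_space(names = "x", lower = 0, upper = 1)
  f <- function(hp) {
    if (hp[["x"]] == 0) stop("synthetic divergence")
    c(hp[["x"]], hp[["x"]])
  }
  expect_warning(
    res <- smpso_optimize(f, space, swarm_size = 6, iterations = 4, seed = 2),
    "candidate evaluation failed")
  expect_gte(res$n_failures, 1L)
  expect_true(all(res$archive$objectives[, 1] != 0))
})

test_that("the knee-point rule picks the balanced archive entry", {
  arch <- greenhits:::new_archive(capacity = 10)
  space <- search_space(names = "x", lower = 0, upper = 10)
  arch <- update_archive(arch, 1, c(0, 1))
  arch <- update_archive(arch, 2, c(1, 0))
  arch <- update_archive(arch, 3, c(0.2, 0.2))
  hp <- select_final(arch, space)
  expect_equal(as.numeric(attr(hp, "objectives")), c(0.2, 0.2))
  # singleton archive: that entry
  single <- greenhits:::new_archive(capacity = 5)
  single <- update_archive(single, 7, c(0.5, 0.5))
  expect_identical(as.integer(select_final(single, space)), 7L)
  expect_error(select_final(greenhits:::new_archive(3), space), "empty")
})
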