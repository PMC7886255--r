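# The zero-run observability solver, traced against the worked examples.

# the two 4x6 singleton instances and the mixed set over 6 genes
first_instance <- function() load_fixture("example2_first")
second_instance <- function() load_fixture("example2_second")
mixed_set <- function() load_fixture("example3_attractors")

test_that("phase combinations enumerate the cartesian product in order", {
  combos <- enumerate_combinations(mixed_set())
  expect_length(combos, 4L)
  expected <- list(
    c("010110", "001010", "001011", "010010"),
    c("010110", "001010", "001011", "101010"),
    c("010110", "001010", "110101", "010010"),
    c("010110", "001010", "110101", "101010"))
  for (i in 1:4)
    expect_equal(unname(combos[[i]]), bits_from_strings(expected[[i]]),
                 ignore_attr = TRUE)
  # all-singleton set: a single combination equal to the stacked states
  s <- first_instance()
  expect_length(enumerate_combinations(s), 1L)
  expect_equal(unname(enumerate_combinations(s)[[1]]),
               do.call(rbind, lapply(s$attractors, as.vector)),
               ignore_attr = TRUE)
  # periods 2 and 3: 6 combinations, each state pair exactly once
  set.seed(3)
  s23 <- random_attractor_set(8, 2, c(2L, 3L))
  combos <- enumerate_combinations(s23)
  expect_length(combos, 6L)
  keys <- vapply(combos, function(A) paste(apply(A, 1, paste0, collapse = ""),
                                           collapse = "|"), "")
  expect_false(anyDuplicated(keys) > 0)
})

test_that("pairwise XOR matrices match the worked examples", {
  bi1 <- pair_xor_matrix(enumerate_combinations(first_instance())[[1]])
  expect_equal(unname(bi1), bits_from_strings(
    c("111101", "000111", "101011", "111010", "010110", "101100")),
    ignore_attr = TRUE)
  bi2 <- pair_xor_matrix(enumerate_combinations(second_instance())[[1]])
  expect_equal(unname(bi2), bits_from_strings(
    c("111110", "001111", "110100", "110001", "001010", "111011")),
    ignore_attr = TRUE)
  expect_equal(attr(bi1, "pair_index")[1, ], c(i = 1L, k = 2L))
  expect_equal(attr(bi1, "pair_index")[6, ], c(i = 3L, k = 4L))
  # identical rows XOR to zero
  A <- rbind(c(1, 0, 1), c(1, 0, 1))
  expect_equal(unname(pair_xor_matrix(A)), rbind(c(0L, 0L, 0L)),
               ignore_attr = TRUE)
  expect_error(pair_xor_matrix(rbind(c(1, 0))), "two attractors")
})

test_that("qualifying zero runs are pooled over rows, duplicates kept", {
  bi1 <- pair_xor_matrix(enumerate_combinations(first_instance())[[1]])
  rt1 <- find_zero_runs(bi1, 2)
  expect_equal(unname(rt1$runs), cbind(c(1L, 5L), c(3L, 6L)))
  expect_equal(rt1$covered, c(1L, 2L, 3L, 5L, 6L))
  bi2 <- pair_xor_matrix(enumerate_combinations(second_instance())[[1]])
  rt2 <- find_zero_runs(bi2, 2)
  expect_equal(unname(rt2$runs), cbind(c(1L, 5L, 3L, 1L), c(2L, 6L, 5L, 2L)))
  # an all-ones matrix has no runs at all
  rt3 <- find_zero_runs(matrix(1L, 3, 5), 1)
  expect_equal(nrow(rt3$runs), 0L)
  expect_length(rt3$covered, 0L)
})

test_that("coverage gap certifies the threshold case", {
  bi1 <- pair_xor_matrix(enumerate_combinations(first_instance())[[1]])
  expect_equal(coverage_gap(find_zero_runs(bi1, 2)), 4L)
  bi2 <- pair_xor_matrix(enumerate_combinations(second_instance())[[1]])
  expect_length(coverage_gap(find_zero_runs(bi2, 2)), 0L)
  empty <- find_zero_runs(matrix(1L, 2, 5), 2)
  expect_equal(coverage_gap(empty), 1:5)
})

test_that("run pruning sorts, deduplicates starts and removes contained runs", {
  mk <- function(runs) list(runs = runs, covered = integer(0), pruned = NULL,
                            threshold = 2L, n = 9L)
  # the worked sorting example: [[1,5],[4,7],[3,9],[3,6],[2,8]]
  rt <- mk(cbind(c(1L, 4L, 3L, 3L, 2L), c(5L, 7L, 9L, 6L, 8L)))
  pruned <- prune_runs(rt)$pruned
  # same-start dedup keeps [3,9]; containment then removes [4,7] inside [3,9]
  expect_equal(unname(pruned), cbind(c(1L, 2L, 3L), c(5L, 8L, 9L)))
  expect_true(all(diff(pruned[, 1]) > 0) && all(diff(pruned[, 2]) > 0))
  # second instance: pruned list [[1,2],[3,5],[5,6]]
  bi2 <- pair_xor_matrix(enumerate_combinations(second_instance())[[1]])
  rt2 <- prune_runs(find_zero_runs(bi2, 2))
  expect_equal(unname(rt2$pruned), cbind(c(1L, 3L, 5L), c(2L, 5L, 6L)))
  expect_equal(unname(prune_runs(mk(cbind(c(1L, 2L), c(4L, 3L))))$pruned),
               cbind(1L, 4L))
})

test_that("pruned-run formula gives the per-combination minimum", {
  mk <- function(runs, n) list(runs = runs, covered = seq_len(n),
                               pruned = runs, threshold = 2L, n = n)
  expect_equal(min_window_length(mk(cbind(c(1L, 3L, 5L), c(2L, 5L, 6L)), 6), 4), 2)
  expect_equal(min_window_length(mk(cbind(c(1L, 2L), c(5L, 6L)), 6), 4), 6)
  # a run spanning every column: the pair is indistinguishable
  expect_equal(min_window_length(mk(cbind(1L, 6L), 6), 4), Inf)
  expect_error(min_window_length(list(runs = NULL, pruned = NULL), 4), "prune")
})

test_that("window recovery returns exactly the distinguishing windows", {
  A1 <- enumerate_combinations(first_instance())[[1]]
  expect_equal(unname(recover_windows(A1, 2)), cbind(c(3L, 4L), c(4L, 5L)))
  A2 <- enumerate_combinations(second_instance())[[1]]
  w2 <- recover_windows(A2, 2)
  expect_true(any(w2[, 1] == 2 & w2[, 2] == 3))
  # identical rows can never be told apart
  expect_equal(nrow(recover_windows(rbind(c(1, 0, 1), c(1, 0, 1)), 2)), 0L)
  expect_equal(nrow(recover_windows(A1, 7)), 0L)  # longer than n
})

test_that("solve reproduces the worked instances end to end", {
  r1 <- ao_solve(first_instance())
  expect_equal(r1$min_length, 2L)
  expect_equal(r1$windows$start, c(3L, 4L))
  expect_equal(r1$windows$end, c(4L, 5L))

  r2 <- ao_solve(second_instance())
  expect_equal(r2$min_length, 2L)
  expect_true(any(r2$windows$start == 2 & r2$windows$end == 3))

  r3 <- ao_solve(mixed_set(), exhaustive = TRUE)
  expect_equal(r3$per_combination, c(4, 6, 3, 2))
  expect_equal(r3$min_length, 2L)
  expect_true(r3$feasible)

  r7 <- ao_solve(load_fixture("seven_gene_attractors"))
  expect_equal(r7$min_length, 2L)
  expect_true(any(r7$windows$start == 3 & r7$windows$end == 4))

  # a single attractor needs no observation at all
  r0 <- ao_solve(attractor_set(list(c(1, 0, 1))))
  expect_equal(r0$min_length, 0L)
  expect_true(r0$feasible)
  expect_error(ao_solve(list()), "attractor_set")
})

test_that("solve via the base generic matches ao_solve", {
  s <- mixed_set()
  expect_equal(solve(s)$min_length, ao_solve(s)$min_length)
})

test_that("reported windows pass the direct distinctness check", {
  set.seed(11)
  for (rep in 1:20) {
    s <- random_small_set()
    r <- ao_solve(s)
    expect_true(nrow(r$windows) > 0)
    combos <- enumerate_combinations(s)
    for (j in seq_len(nrow(r$windows))) {
      expect_equal(r$windows$end[j] - r$windows$start[j] + 1L, r$min_length)
      expect_true(window_distinguishes(combos[[r$windows$combination[j]]],
                                       r$windows$start[j], r$min_length))
    }
  }
})
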