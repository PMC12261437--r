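# E/M updates and the full EM quantifier.

cond_from <- function(read_id, tx, q, m) {
  cond <- tibble::tibble(read_id = read_id, tx = as.integer(tx), q = q)
  cond$tname <- sprintf("T%d", cond$tx)
  attr(cond, "catalog") <- tibble::tibble(
    tname = sprintf("T%d", seq_len(m)), length = rep(1000L, m)
  )
  attr(cond, "model") <- "nocov"
  cond
}

test_that("the E-step normalises responsibilities per read", {
  # unique read: responsibility 1 regardless of theta
  c1 <- cond_from("r1", 1, 1, 2)
  expect_equal(e_step(c1, c(0.1, 0.9))$r, 1)
  # equal conditionals: responsibilities follow theta
  c2 <- cond_from(c("r1", "r1"), c(1, 2), c(1, 1), 2)
  expect_equal(e_step(c2, c(0.75, 0.25))$r, c(0.75, 0.25))
  # uniform theta: responsibilities follow the conditionals
  c3 <- cond_from(c("r1", "r1"), c(1, 2), c(0.7, 0.3), 2)
  expect_equal(e_step(c3, c(0.5, 0.5))$r, c(0.7, 0.3))
})

test_that("the M-step averages responsibilities into abundances", {
  r1 <- cond_from(c("a", "b", "c", "d"), c(1, 1, 2, 2), rep(1, 4), 2)
  r1$r <- 1
  expect_equal(m_step(r1, 2), c(0.5, 0.5))
  r2 <- cond_from(c("a", "b"), c(1, 1), c(1, 1), 3)
  r2$r <- 1
  expect_equal(m_step(r2, 3), c(1, 0, 0))
  r3 <- cond_from(c("a", "b", "b"), c(1, 1, 2), c(1, 1, 1), 2)
  r3$r <- c(1, 0.5, 0.5)
  expect_equal(m_step(r3, 2), c(0.75, 0.25))
})

test_that("EM reaches the analytic fixed points", {
  # one read unique to A plus one ambiguous A/B read with equal
  # conditionals: the ambiguous term is constant, likelihood ~ theta_A,
  # maximised at the corner (2, 0)
  c1 <- cond_from(c("r1", "r2", "r2"), c(1, 1, 2), c(1, 1, 1), 2)
  f1 <- em_quantify(c1, max_iters = 1e5, tol = 1e-9)
  expect_equal(f1$counts, c(2, 0), tolerance = 1e-8)

  # symmetric instance: 2 unique A, 2 unique B, 4 ambiguous -> (4, 4)
  c2 <- cond_from(
    c("a1", "a2", "b1", "b2", "m1", "m1", "m2", "m2", "m3", "m3", "m4", "m4"),
    c(1, 1, 2, 2, 1, 2, 1, 2, 1, 2, 1, 2),
    rep(1, 12), 2
  )
  f2 <- em_quantify(c2)
  expect_equal(f2$counts, c(4, 4))

  # all unique: exact allocation after the first iteration (the second
  # pass only confirms stationarity)
  c3 <- cond_from(c("r1", "r2", "r3"), c(1, 1, 3), c(1, 0.5, 1), 3)
  f3 <- em_quantify(c3)
  expect_equal(f3$counts, c(2, 0, 1))
  expect_lte(f3$n_iters, 2L)
})

test_that("the log-likelihood never decreases and counts are conserved", {
  for (seed in 1:8) {
    cond <- random_conditionals(n_reads = 40, m = 5, seed = seed)
    fit <- em_quantify(cond, max_iters = 500, tol = 1e-6)
    expect_true(all(diff(fit$loglik_trace) >= -1e-9))
    expect_equal(sum(fit$counts), fit$n_assigned, tolerance = 1e-6)
    expect_equal(sum(fit$theta), 1, tolerance = 1e-12)
  }
})

test_that("EM matches a simplex grid-search oracle on tiny instances", {
  for (seed in 1:6) {
    m <- 2 + seed %% 2
    cond <- random_conditionals(n_reads = sample(3:6, 1), m = m, seed = seed)
    fit <- em_quantify(cond, max_iters = 1e5, tol = 1e-10)
    oracle <- grid_loglik_oracle(cond, m)
    expect_gte(utils::tail(fit$loglik_trace, 1), oracle - 1e-6)
  }
})

test_that("relabelling transcripts permutes the output identically", {
  cond <- random_conditionals(n_reads = 30, m = 4, seed = 23)
  fit <- em_quantify(cond, max_iters = 2000, tol = 1e-8)
  perm <- c(3L, 1L, 4L, 2L)
  cond2 <- cond
  cond2$tx <- perm[cond$tx]
  attr(cond2, "catalog") <- tibble::tibble(
    tname = sprintf("T%d", seq_len(4)), length = rep(1000L, 4)
  )
  fit2 <- em_quantify(cond2, max_iters = 2000, tol = 1e-8)
  expect_equal(fit2$counts[perm], fit$counts, tolerance = 1e-12)
})

test_that("reads with zero denominator fall back to uniform assignment", {
  cond <- cond_from(c("r1", "r1"), c(1, 2), c(1, 1), 3)
  e <- e_step(cond, c(0, 0, 1))
  expect_equal(e$r, c(0.5, 0.5))
})

test_that("unique-mapping synthetic data is recovered exactly", {
  sim <- simulate_reads(n_transcripts = 10, n_reads = 2000,
                        prefix_pairs = NULL, seed = 41)
  cond <- alignment_conditionals(sim$alignments, model = "nocov")
  fit <- em_quantify(cond)
  expect_equal(fit$counts, sim$truth$true_count, tolerance = 1e-9)
})

test_that("degenerate inputs are rejected", {
  expect_error(em_quantify(cond_from(character(), integer(), numeric(), 2)),
               "nothing to quantify")
})
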