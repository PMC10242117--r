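test_that("empirical moments match hand counts", {
  b <- rbind(c(1L, 1L), c(-1L, -1L))
  mom <- empirical_moments(b)
  expect_equal(mom$mean, c(0, 0))
  expect_equal(mom$corr[1, 2], 1)

  b2 <- rbind(c(1L, -1L), c(-1L, 1L))
  expect_equal(empirical_moments(b2)$corr[1, 2], -1)
})

test_that("empirical distribution is a plain tally", {
  expect_equal(empirical_distribution(c(0L, 0L, 1L), 1), c(2 / 3, 1 / 3))
  expect_equal(empirical_distribution(0:7, 3), rep(1 / 8, 8))
  set.seed(11)
  s <- sample(0:7, 200, TRUE)
  expect_equal(empirical_distribution(s, 3),
               as.numeric(table(factor(s, levels = 0:7))) / 200)
})

test_that("state energies agree with the defining double sum", {
  # hand evaluation: h = (1, -1), J12 = 0.5, state (+1, +1)
  p <- mem_params(c(1, -1), matrix(c(0, 0.5, 0.5, 0), 2))
  expect_equal(state_energy(3L, p), -0.5)
  # null model
  p0 <- mem_params(numeric(3), matrix(0, 3, 3))
  expect_equal(state_energy(0:7, p0), rep(0, 8))
  # random instance vs oracle loop
  pr <- random_params(4, seed = 21)
  expect_equal(state_energy(0:15, pr),
               vapply(0:15, oracle_energy, numeric(1), h = pr$h, J = pr$J),
               tolerance = 1e-12)
  # global sign flip leaves energies unchanged when h = 0:
  # state k and its complement 15 - k have equal energy
  ph <- mem_params(numeric(4), random_params(4, seed = 22)$J)
  e <- state_energy(0:15, ph)
  expect_equal(e, rev(e), tolerance = 1e-12)
})

test_that("boltzmann distribution matches closed forms and brute force", {
  p0 <- mem_params(numeric(3), matrix(0, 3, 3))
  expect_equal(boltzmann_distribution(p0), rep(1 / 8, 8))

  a <- 0.7
  p1 <- mem_params(a, matrix(0, 1, 1))
  expect_equal(boltzmann_distribution(p1)[2], exp(a) / (exp(a) + exp(-a)))

  for (seed in 1:5) {
    pr <- random_params(3, seed = 100 + seed)
    expect_equal(boltzmann_distribution(pr), oracle_boltzmann(pr$h, pr$J),
                 tolerance = 1e-12)
  }
  # probabilities sum to one
  pr <- random_params(6, seed = 200)
  expect_equal(sum(boltzmann_distribution(pr)), 1, tolerance = 1e-12)
})

test_that("model moments match closed forms and Monte-Carlo", {
  expect_equal(model_moments(mem_params(0.9, matrix(0, 1, 1)))$mean, tanh(0.9))
  p0 <- mem_params(numeric(3), matrix(0, 3, 3))
  mm <- model_moments(p0)
  expect_equal(mm$mean, rep(0, 3))
  expect_equal(mm$corr[upper.tri(mm$corr)], rep(0, 3))

  pr <- random_params(4, seed = 31)
  set.seed(32)
  draws <- sample.int(16, 1e5, TRUE, prob = boltzmann_distribution(pr)) - 1L
  sig <- decode_states(draws, 4)
  mm <- model_moments(pr)
  se <- 3 / sqrt(1e5)
  expect_true(all(abs(mm$mean - colMeans(sig)) < 3 * se))
  expect_true(all(abs(mm$corr - crossprod(sig) / 1e5) < 3 * se))
})

test_that("kl divergence follows its definition", {
  expect_equal(kl_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), 1)
  expect_identical(kl_divergence(c(0.5, 0.5), c(1, 0)), Inf)
  set.seed(41)
  p <- runif(8); p <- p / sum(p)
  q <- runif(8); q <- q / sum(q)
  expect_equal(kl_divergence(p, q), sum(p * log2(p / q)), tolerance = 1e-12)
  expect_gte(kl_divergence(p, q), 0)
})

test_that("fitting exact model moments recovers the generating parameters", {
  target0 <- model_moments(mem_params(numeric(3), matrix(0, 3, 3)))
  fit0 <- fit_mem(target0)
  expect_identical(fit0$n_iter, 0L)
  expect_true(fit0$converged)
  expect_equal(fit0$params$h, numeric(3))

  truth <- random_params(5, seed = 51)
  fit <- fit_mem(model_moments(truth), tol = 1e-7)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$params$h - truth$h), abs(fit$params$J - truth$J)), 1e-3)
})

test_that("independent spins fit to zero couplings", {
  set.seed(52)
  m <- runif(4, -0.5, 0.5)
  target <- new_moments_for_test(m)
  fit <- fit_mem(target, tol = 1e-7)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$params$J)), 1e-3)
  expect_equal(fit$params$h, atanh(m), tolerance = 1e-3)
})

test_that("converged fits reproduce their target moments within tol", {
  set.seed(53)
  b <- sample_mem_sequence(random_params(4, seed = 54, h_sd = 0.2, j_sd = 0.25),
                           2000, mode = "iid")
  fit <- fit_mem(b, tol = 1e-6)
  expect_true(fit$converged)
  expect_lte(glance(fit)$max_mismatch, 1e-6)
  expect_gte(fit$d2_bits, 0)
})

test_that("the pairwise fit never loses to the independent fit on D2", {
  for (seed in 1:4) {
    truth <- random_params(4, seed = 60 + seed, h_sd = 0.2, j_sd = 0.4)
    b <- sample_mem_sequence(truth, 3000, mode = "iid", seed = 70 + seed)
    emp <- empirical_distribution(encode_states(b), 4)
    full <- fit_mem(b)
    indep <- fit_mem(b, pairwise = FALSE)
    expect_true(full$converged)
    expect_lte(full$d2_bits, indep$d2_bits + 1e-9)
  }
})

test_that("negating the data negates h and preserves J", {
  set.seed(81)
  b <- sample_mem_sequence(random_params(4, seed = 82, h_sd = 0.3, j_sd = 0.3),
                           1500, mode = "iid")
  f1 <- fit_mem(b, tol = 1e-6)
  f2 <- fit_mem(-b, tol = 1e-6)
  expect_equal(f2$params$h, -f1$params$h, tolerance = 1e-4)
  expect_equal(f2$params$J, f1$params$J, tolerance = 1e-4)
})

test_that("non-convergence is reported honestly, not raised", {
  truth <- random_params(4, seed = 91)
  fit <- fit_mem(model_moments(truth), max_iter = 3L)
  expect_false(fit$converged)
  expect_identical(fit$n_iter, 3L)
})

test_that("fit serialization writes valid JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  b <- sample_mem_sequence(random_params(3, seed = 95), 500, mode = "iid", seed = 96)
  fit <- fit_mem(b)
  write_mem_fit(fit, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$h, fit$params$h, tolerance = 1e-12)
  expect_equal(back$d2_bits, fit$d2_bits, tolerance = 1e-12)
  expect_identical(back$converged, fit$converged)
})
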