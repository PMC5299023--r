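test_that("a scaled dictionary member is recovered in one iteration", {
  target <- 2.5 * matrix(default_bank$dict[, 17], 21, 50)
  dec <- mp_decompose(target, default_bank, theta = 0.8,
                      expanded = default_expanded)
  expect_identical(dec$n_iter, 1L)
  expect_equal(dec$entries$gamma[1], 2.5, tolerance = 1e-12)
  expect_equal(dec$corr_track[1], 1, tolerance = 1e-12)
  expect_lt(sqrt(sum(dec$residual^2)), 1e-10)
})

test_that("two atoms with disjoint support are both recovered exactly", {
  # narrow temporal-support atom shifted to opposite ends of the patch
  col <- which(default_bank$dict_info$omega_t == 125 &
                 default_bank$dict_info$omega_s == 0 &
                 default_bank$dict_info$part == "real")[1]
  a <- matrix(default_bank$dict[, col], 21, 50)
  left <- strfgabor:::shift_patch(a, -20, 0)
  right <- strfgabor:::shift_patch(a, 20, 0)
  expect_equal(sum(left * right), 0) # orthogonal by construction
  target <- 1.4 * left - 0.6 * right
  dec <- mp_decompose(target, default_bank, theta = 0.999,
                      expanded = default_expanded)
  expect_lte(dec$n_iter, 2L)
  expect_equal(sort(abs(dec$entries$gamma)), c(0.6, 1.4), tolerance = 1e-10)
  expect_gt(tail(dec$corr_track, 1), 1 - 1e-10)
})

test_that("correlation is non-decreasing, residual norm non-increasing, residual orthogonal to the picked atom", {
  set.seed(42)
  for (rep in 1:25) {
    target <- matrix(rnorm(21 * 50), 21, 50)
    dec <- mp_decompose(target, default_bank, theta = 0.99, max_iter = 6,
                        expanded = default_expanded)
    expect_true(all(diff(dec$corr_track) >= -1e-12))
    # energy bookkeeping: each iteration removes exactly gamma^2 of energy
    expect_equal(sum(dec$residual^2),
                 sum(target^2) - sum(dec$entries$gamma^2),
                 tolerance = 1e-9)
    last_col <- dec$entries$column[dec$n_iter]
    expect_lt(abs(sum(default_expanded$mat[, last_col] * as.vector(dec$residual))), 1e-10)
  }
})

test_that("reconstruct() rebuilds the MP reconstruction and handles edge cases", {
  set.seed(7)
  target <- matrix(rnorm(21 * 50), 21, 50)
  dec <- mp_decompose(target, default_bank, theta = 0.9, max_iter = 5,
                      expanded = default_expanded)
  expect_equal(reconstruct(dec, default_bank), dec$reconstruction,
               tolerance = 1e-12)
  empty <- dec
  empty$entries <- dec$entries[0, ]
  expect_equal(reconstruct(empty, default_bank), matrix(0, 21, 50))
  bad <- dec
  bad$entries$dict_col <- 10000L
  expect_error(reconstruct(bad, default_bank), "unknown")
})

test_that("targets in the dictionary span are reconstructed to high fidelity", {
  set.seed(11)
  cols <- sample(ncol(default_bank$dict), 3)
  target <- matrix(default_bank$dict[, cols] %*% c(1.2, -0.7, 0.5), 21, 50)
  dec <- mp_decompose(target, default_bank, theta = 0.999, max_iter = 50,
                      expanded = default_expanded)
  expect_gte(cor(as.vector(reconstruct(dec, default_bank)), as.vector(target)),
             0.999)
})

test_that("mp_decompose validates its inputs", {
  expect_error(mp_decompose(matrix(0, 21, 50), default_bank,
                            expanded = default_expanded), "all zero")
  t1 <- matrix(rnorm(21 * 50), 21, 50)
  expect_error(mp_decompose(t1, default_bank, theta = 0), "theta")
  expect_error(mp_decompose(t1, default_bank, theta = 1.2), "theta")
  expect_error(mp_decompose(matrix(1, 5, 5), default_bank), "21 x 50")
})

test_that("kappa_atom follows the L1-of-normalized definition", {
  expect_equal(kappa_atom(3, 0), 1, tolerance = 1e-15)
  expect_equal(kappa_atom(0, 2), 1, tolerance = 1e-15)
  expect_equal(kappa_atom(1, 1), sqrt(2), tolerance = 1e-15)
  # scale and sign invariance
  set.seed(3)
  for (i in 1:20) {
    v <- rnorm(2)
    k <- kappa_atom(v[1], v[2])
    expect_gte(k, 1)
    expect_lte(k, sqrt(2) + 1e-15)
    expect_equal(kappa_atom(7.3 * v[1], 7.3 * v[2]), k, tolerance = 1e-12)
    expect_equal(kappa_atom(-v[1], v[2]), k, tolerance = 1e-12)
  }
  expect_warning(kzero <- kappa_atom(0, 0), "DC")
  expect_identical(kzero, 1)
})

test_that("kappa of a decomposition is the mean of per-entry kappas", {
  fake <- function(ot, os) {
    structure(
      list(entries = data.frame(omega_t = ot, omega_s = os),
           frame_period_ms = 2, channel_spacing = 1),
      class = "mp_decomposition"
    )
  }
  expect_equal(kappa_decomposition(fake(c(62.5, 125), c(0, 0))), 1)
  # 125 Hz * 2 ms = 0.25 cyc/sample matches 0.25 cyc/Bark: fully diagonal
  expect_equal(kappa_decomposition(fake(c(62.5, 125), c(0, 0.25))),
               (1 + sqrt(2)) / 2, tolerance = 1e-14)
  expect_error(kappa_decomposition(fake(numeric(0), numeric(0))), "empty")
})

test_that("atom importance sums absolute weights across decompositions", {
  target <- -0.9 * matrix(default_bank$dict[, 9], 21, 50)
  dec1 <- mp_decompose(target, default_bank, theta = 0.8,
                       expanded = default_expanded)
  eta1 <- atom_importance(list(dec1), default_bank)
  expect_equal(eta1$eta[9], 0.9, tolerance = 1e-10)
  expect_equal(sum(eta1$eta > 0), 1L)

  dec2 <- dec1
  dec2$entries$gamma <- 0.25
  dec3 <- dec1
  dec3$entries$gamma <- 0.5
  eta2 <- atom_importance(list(dec2, dec3), default_bank)
  expect_equal(eta2$eta[9], 0.75, tolerance = 1e-12)

  eta0 <- atom_importance(list(), default_bank)
  expect_true(all(eta0$eta == 0))
})

test_that("atom count histogram tabulates decomposition sizes", {
  expect_length(atom_count_histogram(list()), 0)
  fake <- function(n) structure(list(n_iter = as.integer(n)), class = "mp_decomposition")
  h <- atom_count_histogram(list(fake(1), fake(1), fake(2)))
  expect_identical(as.integer(h[["1"]]), 2L)
  expect_identical(as.integer(h[["2"]]), 1L)
  # dictionary members need exactly one atom at theta = 0.8
  targets <- lapply(c(3, 20, 40), function(j) matrix(default_bank$dict[, j], 21, 50))
  decs <- lapply(targets, mp_decompose, bank = default_bank, theta = 0.8,
                 expanded = default_expanded)
  expect_identical(as.integer(atom_count_histogram(decs)[["1"]]), 3L)
})

test_that("kappa_vs_theta matches per-threshold decompositions and is 1 for separable targets", {
  set.seed(5)
  # separable targets: combinations of axis-aligned atoms only
  axis_cols <- which(default_bank$dict_info$omega_t == 0 |
                       default_bank$dict_info$omega_s == 0)
  targets <- lapply(1:3, function(i) {
    cols <- sample(axis_cols, 2)
    matrix(default_bank$dict[, cols] %*% rnorm(2), 21, 50)
  })
  curve <- kappa_vs_theta(targets, default_bank, theta_grid = c(0.7, 0.9))
  expect_equal(curve$kappa, c(1, 1), tolerance = 1e-12)

  # prefix consistency: a one-point grid equals a direct decomposition
  mixed <- matrix(rnorm(21 * 50), 21, 50)
  one <- kappa_vs_theta(list(mixed), default_bank, theta_grid = 0.8)
  direct <- mp_decompose(mixed, default_bank, theta = 0.8,
                         expanded = default_expanded)
  expect_equal(one$kappa, direct$kappa, tolerance = 1e-12)
  expect_error(kappa_vs_theta(targets, default_bank, c(0.9, 0.7)), "increasing")
})
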