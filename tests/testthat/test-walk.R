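# Dense reconstruction of the implicitly-represented normalised tensors,
# used to probe stochasticity directly.
dense_pm <- function(tensor) {
  pm <- normalize_protein_mode(tensor)
  n <- tensor$n
  lapply(seq_len(tensor$m), function(k) {
    L <- as.matrix(pm$layers[[k]])
    L[, pm$zero_cols[[k]]] <- 1 / n
    L
  })
}

test_that("protein-mode normalisation makes every column stochastic", {
  # column with entries (2, 3) -> (0.4, 0.6)
  L <- Matrix::sparseMatrix(i = c(1, 3, 2, 2), j = c(2, 2, 1, 3),
                            x = c(2, 3, 2, 3), dims = c(3, 3))
  tens <- similarity_tensor(list(L), "physical")
  pm <- normalize_protein_mode(tens)
  expect_equal(as.vector(pm$layers[[1]][, 2]), c(0.4, 0, 0.6))

  set.seed(31)
  for (rep in 1:5) {
    tens <- random_tensor(sample(4:9, 1), p = 0.3)
    dl <- dense_pm(tens)
    for (k in seq_len(tens$m)) {
      expect_equal(colSums(dl[[k]]), rep(1, tens$n), tolerance = 1e-12)
    }
    # all-zero columns became uniform 1/n
    pm <- normalize_protein_mode(tens)
    for (k in seq_len(tens$m)) {
      for (j in pm$zero_cols[[k]]) {
        expect_equal(dl[[k]][, j], rep(1 / tens$n, tens$n))
      }
    }
  }
})

test_that("layer-mode normalisation makes every fiber stochastic", {
  # fiber (1, 1, 2) -> (0.25, 0.25, 0.5); zero fibers -> 1/3 each
  lay <- function(x) {
    Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = c(x, x), dims = c(3, 3))
  }
  tens <- similarity_tensor(list(lay(1), lay(1), lay(2)))
  lm <- normalize_layer_mode(tens)
  expect_equal(vapply(lm$P, function(P) P[1, 2], numeric(1)),
               c(0.25, 0.25, 0.5))
  expect_equal(lm$U[1, 3], 0)   # fiber (1,3,.) implicit uniform

  set.seed(32)
  for (rep in 1:5) {
    tens <- random_tensor(sample(4:9, 1), p = 0.3)
    dl <- dense_layer_norm(tens$layers)
    fiber_sums <- Reduce(`+`, dl)
    expect_equal(max(abs(fiber_sums - 1)), 0, tolerance = 1e-12)
  }
})

test_that("sparse contraction equals the dense triple-loop oracle", {
  set.seed(33)
  for (rep in 1:10) {
    n <- sample(3:10, 1)
    m <- sample(2:3, 1)
    tens <- random_tensor(n, m = m, p = 0.35)
    pair <- normalize_tensor(tens)
    x <- runif(n); x <- x / sum(x)
    xn <- runif(n); xn <- xn / sum(xn)
    y <- runif(m); y <- y / sum(y)
    dpm <- dense_pm(tens)
    dlm <- dense_layer_norm(tens$layers)
    expect_equal(rwrt:::.contract_x(pair, x, y),
                 contract_x_oracle(dpm, x, y), tolerance = 1e-12)
    expect_equal(rwrt:::.contract_y(pair, x, xn),
                 contract_y_oracle(dlm, x, xn), tolerance = 1e-12)
  }
})

test_that("restart vectors are simplex distributions with sane structure", {
  net <- make_net(c("A\tB", "B\tC", "C\tD"))
  dom <- make_domains(c("A\td1", "A\td2", "B\td1", "B\td2", "C\td9"),
                      net$index)
  cat1 <- make_complexes(c("A B", "C D"), net$index)
  iA <- index_of(net$index, "A")
  x0 <- restart_vector(iA, dom, cat1, net)
  expect_equal(sum(x0), 1)
  expect_true(all(x0 >= 0))
  # identical domain set and identical module set -> maximal raw weight 2
  d_AB <- 1 + 1   # cosine 1 on domains, cosine 1 on modules
  expect_equal(x0[index_of(net$index, "B")],
               d_AB / (2 + d_AB))  # self d_AA = 2 as well, C/D contribute 0
  # protein with no domains/modules falls back to its closed neighborhood
  net2 <- make_net(c("A\tB", "B\tC", "C\tA", "C\tD"))
  x0c <- restart_vector(index_of(net2$index, "C"), NULL, NULL, net2)
  nb <- index_of(net2$index, c("A", "B", "C", "D"))
  expect_equal(unname(x0c[nb]), rep(1 / 4, 4))
})

test_that("the walk anchors to the restart vector as alpha goes to 0", {
  fx <- degenerate_fixtures()
  pair <- normalize_tensor(fx$multigraph)
  x0 <- c(0.5, 0.25, 0.125, 0.0625, 0.0625)   # dyadic: sums to 1 exactly
  w0 <- run_walk(pair, x0, walk_config(alpha = 0))
  expect_identical(w0$x, x0)            # exact at alpha = 0
  w01 <- run_walk(pair, x0, walk_config(alpha = 0.01))
  expect_lt(sum(abs(w01$x - x0)), 0.05)
  w5 <- run_walk(pair, x0, walk_config(alpha = 0.5))
  expect_gt(sum(abs(w5$x - x0)), sum(abs(w01$x - x0)))
})

test_that("walks converge to a fixed point on the simplex", {
  fx <- degenerate_fixtures()
  pair <- normalize_tensor(fx$multigraph)
  x0 <- c(1, 0, 0, 0, 0)
  cfg <- walk_config()
  w <- run_walk(pair, x0, cfg)
  expect_true(w$converged)
  expect_equal(sum(w$x), 1, tolerance = 1e-12)
  expect_equal(sum(w$y), 1, tolerance = 1e-12)
  # re-applying one iteration moves X* by less than tol
  v <- cfg$alpha * rwrt:::.contract_x(pair, w$x, w$y) +
    (1 - cfg$alpha) * x0
  v <- v / sum(v)
  expect_lt(sum(abs(v - w$x)), cfg$tol)
  # non-convergence warns and reports the residual
  expect_warning(run_walk(pair, x0, walk_config(tol = 1e-14, max_iter = 2)),
                 "did not converge")
})

test_that("residuals decrease after burn-in", {
  fx <- small_synth()
  tens <- build_tensor_from_dataset(fx$dataset)
  pair <- normalize_tensor(tens)
  n <- tens$n
  x0 <- restart_vector(1, fx$dataset$domains, fx$dataset$catalog,
                       fx$dataset$net)
  # manual iteration to trace residuals
  cfg <- walk_config()
  x <- x0; y <- rep(1 / 3, 3)
  res <- numeric(30)
  for (t in 1:30) {
    xn <- cfg$alpha * rwrt:::.contract_x(pair, x, y) + (1 - cfg$alpha) * x0
    xn <- xn / sum(xn)
    yraw <- rwrt:::.contract_y(pair, x, xn)
    y <- yraw / sum(yraw)
    res[t] <- sum(abs(xn - x))
    x <- xn
  }
  expect_true(all(diff(res[25:30]) <= 1e-12))
})

test_that("similarity matrix rows are simplex rows, independent of order", {
  fx <- small_synth()
  M <- functional_similarity(fx$dataset)
  expect_equal(unname(rowSums(M) + attr(M, "self_score")),
               rep(1, nrow(M)), tolerance = 1e-9)
  expect_true(all(M >= 0))
  expect_true(all(diag(M) == 0))
  # within-community mass dominates between-community mass
  mod <- fx$truth$module_of[rownames(M)]
  same <- outer(mod, mod, "==")
  diag(same) <- FALSE
  expect_gt(mean(M[same]), 5 * mean(M[!same]))
  # determinism: a second run is bit-identical
  M2 <- functional_similarity(fx$dataset)
  expect_identical(M, M2)
})

test_that("network statistics match hand-computed graphs", {
  k4 <- make_net(c("A\tB", "A\tC", "A\tD", "B\tC", "B\tD", "C\tD"))
  s4 <- network_stats(k4)
  expect_equal(unname(s4["clustering_coefficient"]), 1)
  expect_equal(unname(s4["density"]), 1)
  expect_equal(unname(s4["heterogeneity"]), 0)
  star <- make_net(c("H\tA", "H\tB", "H\tC", "H\tD"))
  expect_equal(unname(network_stats(star)["clustering_coefficient"]), 0)
  # empty graph -> zeros
  empty <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(unname(network_stats(empty)), rep(0, 4))
})

test_that("similarity serialisation round-trips above threshold", {
  fx <- small_synth()
  M <- functional_similarity(fx$dataset)
  path <- tempfile(fileext = ".tsv")
  write_similarity(M, path, threshold = 1e-4)
  M2 <- read_similarity(path, index = fx$dataset$net$index)
  expect_equal(M2[M > 1e-4], M[M > 1e-4], tolerance = 1e-12)
  expect_true(all(M2[M <= 1e-4] == 0))
})
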