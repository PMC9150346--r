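test_that("topology layer matches closed-neighborhood arithmetic", {
  # identical closed neighborhoods -> similarity 1
  tri <- make_net(c("A\tB", "B\tC", "C\tA"))
  L <- topology_layer(tri)
  expect_equal(unique(round(L@x, 12)), 1)

  # N_i = {i,a}, N_j = {j,a}: 4 * 1 / ((2+1)(2+1)) = 4/9
  star <- make_net(c("i\ta", "j\ta"))
  Ls <- topology_layer(star)
  expect_equal(Ls["i", "j"], 4 / 9)

  # disjoint closed neighborhoods -> entry absent
  two <- make_net(c("A\tB", "C\tD"))
  expect_equal(topology_layer(two)["A", "C"], 0)
})

test_that("topology layer agrees with a brute-force oracle and stays in (0,1]", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(5:10, 1)
    pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
    keep <- runif(nrow(pairs)) < 0.4
    if (!any(keep)) next
    edges <- pairs[keep, , drop = FALSE]
    ids <- sprintf("n%02d", 1:n)
    net <- make_net(paste(ids[edges[, 1]], ids[edges[, 2]], sep = "\t"))
    L <- as.matrix(topology_layer(net))
    eidx <- cbind(index_of(net$index, ids[edges[, 1]]),
                  index_of(net$index, ids[edges[, 2]]))
    m <- n_proteins(net)
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (i == j) next
      expect_equal(L[i, j], eq1_oracle(eidx, m, i, j), tolerance = 1e-12)
    }
    expect_true(all(L >= 0 & L <= 1 + 1e-12))
  }
})

test_that("domain similarity matches the exact-factorisation oracle", {
  # worked example: D_A = {1..5}, D_B = {5,6,7}, DC = {5}
  for (nt in c(10, 20, 100, 1000)) {
    expect_equal(domain_similarity(as.character(1:5), as.character(5:7), nt),
                 ds_oracle(1, 5, 3, nt), tolerance = 1e-9)
  }
  # all domains shared, D_i = D_j = DT
  expect_equal(domain_similarity(letters[1:6], letters[1:6], 6),
               ds_oracle(6, 6, 6, 6), tolerance = 1e-9)
  expect_error(domain_similarity(letters[1:5], letters[3:8], 6),
               "undefined binomial")
})

test_that("log-space and direct-float domain similarity agree for small DT", {
  set.seed(7)
  for (rep in 1:50) {
    nt <- sample(3:30, 1)
    ni <- sample(1:nt, 1)
    nj <- sample(1:nt, 1)
    rng <- max(0, ni + nj - nt):min(ni, nj)
    nc <- if (length(rng) == 1) rng else sample(rng, 1)
    direct <- -log((choose(nt, nc) * choose(nt - nc, ni - nc) *
                      choose(nt - ni, nj - nc)) /
                     (choose(nt, ni) * choose(nt, nj)))
    expect_equal(rwrt:::.ds_value(nc, ni, nj, nt), direct,
                 tolerance = 1e-9)
  }
})

test_that("co-structure layer normalises over the evaluated pair set", {
  # contexts: A,B share much; C overlaps A in one domain only
  net <- make_net(c("A\tB", "C\tD"))
  dom <- make_domains(c("A\td1", "A\td2", "A\td3", "B\td1", "B\td2",
                        "C\td3", "C\td4", "D\td5"), net$index)
  L <- costructure_layer(net, dom)
  vals <- L[upper.tri(L)]
  vals <- vals[vals > 0]
  expect_equal(max(vals), 1)               # max pair -> 1 by normalisation
  # monotonicity: layer order preserves DS order
  ctx <- domain_context(net, dom)
  Bm <- as.matrix(ctx$incidence)
  ds <- function(i, j) {
    di <- which(Bm[i, ] > 0); dj <- which(Bm[j, ] > 0)
    ds_oracle(length(intersect(di, dj)), length(di), length(dj), ctx$dt_size)
  }
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  idx <- index_of(net$index, c("A", "B", "C"))
  for (p in pairs) for (q in pairs) {
    dsp <- ds(idx[p[1]], idx[p[2]]); dsq <- ds(idx[q[1]], idx[q[2]])
    lp <- as.matrix(L)[idx[p[1]], idx[p[2]]]
    lq <- as.matrix(L)[idx[q[1]], idx[q[2]]]
    if (dsp > dsq) expect_gte(lp, lq)
  }
})

test_that("degenerate co-structure normalisation sets single pairs to 1", {
  net <- make_net(c("A\tB", "C\tD"))
  dom <- make_domains(c("A\td1", "C\td1"), net$index)
  # only pair (A, C) shares a context domain -> degenerate min = max
  expect_message(L <- costructure_layer(net, dom), "degenerate")
  expect_equal(L["A", "C"], 1)

  empty <- make_domains(character(0), net$index)
  expect_warning(L0 <- costructure_layer(net, empty), "empty")
  expect_equal(length(L0@x), 0)
})

test_that("module density follows 2|E|/(|V|(|V|-1))", {
  net <- make_net(c("A\tB", "B\tC", "C\tA", "C\tD"))
  idx <- function(...) index_of(net$index, c(...))
  expect_equal(module_density(idx("A", "B", "C"), net), 1)      # triangle
  expect_equal(module_density(idx("A", "B", "D"), net), 1 / 3)
  expect_equal(module_density(idx("B", "C", "D"), net), 2 / 3)  # 2 edges
  expect_equal(module_density(idx("A", "D"), net), 0)
  expect_error(module_density(idx("A"), net), "at least 2")
})

test_that("co-module layer reproduces hand-computed associations", {
  # modules: {A,B} triangle-dense? scores from the graph below
  net <- make_net(c("A\tB", "B\tC", "C\tA", "D\tE"))
  cat1 <- make_complexes(c("A B", "A B C", "D E"), net$index)
  sc <- module_scores(cat1, net)
  expect_equal(sc, c(1, 1, 1))
  L <- comodule_layer(cat1, net)
  # A and C share only module 2: (1)^2 / ((1+1) * 1) = 1/2
  expect_equal(L["A", "C"], 0.5)
  # D, E share their single module -> 1; no cross-module entries
  expect_equal(L["D", "E"], 1)
  expect_equal(L["A", "D"], 0)

  # weighted example: i in {A(0.5), B(1.0)}, j in {A(0.5)} -> 1/3
  expect_equal(eq5_oracle(1, 2, list(c(1, 2), 1), c(0.5, 1.0)), 1 / 3)
  net2 <- make_net(c("a\tb", "a\tc", "b\tc", "a\td", "c\td"))
  # module m1 = {a,b,d} has edges ab, ad -> 2/3; m2 = {a,c,b} -> 1
  cat2 <- make_complexes(c("a b d", "a c b"), net2$index)
  s2 <- module_scores(cat2, net2)
  L2 <- comodule_layer(cat2, net2)
  expect_equal(L2["d", "c"], 0)                       # no shared module
  expect_equal(L2["a", "d"],
               eq5_oracle(index_of(net2$index, "a"),
                          index_of(net2$index, "d"),
                          cat2$modules, s2))
})

test_that("tensor assembly enforces symmetry and handles missing layers", {
  fx <- small_synth()
  tens <- build_tensor_from_dataset(fx$dataset)
  expect_equal(tens$m, 3)
  for (L in tens$layers) {
    expect_lt(max(abs(L - Matrix::t(L))), 1e-12)
    expect_true(all(L@x > 0))
    expect_true(all(Matrix::diag(L) == 0))
  }
  # no domains, no complexes -> only the topology layer populated
  net <- make_net(c("A\tB", "B\tC"))
  t0 <- build_tensor(net)
  expect_gt(length(t0$layers[[1]]@x), 0)
  expect_equal(length(t0$layers[[2]]@x), 0)
  expect_equal(length(t0$layers[[3]]@x), 0)
  expect_error(similarity_tensor(list(Matrix::sparseMatrix(
    i = 1, j = 2, x = -1, dims = c(3, 3), symmetric = TRUE))),
    "nonnegative")
})

test_that("layer construction is permutation-equivariant", {
  set.seed(202)
  lines <- c("A\tB", "B\tC", "C\tD", "D\tA", "B\tD")
  dom_lines <- c("A\td1", "B\td1", "C\td2", "D\td2", "A\td3")
  cpx_lines <- c("A B D", "C D")
  build <- function(perm_ids) {
    # relabel proteins by a permutation map and rebuild
    map <- setNames(perm_ids, c("A", "B", "C", "D"))
    sub <- function(s) {
      vapply(strsplit(s, "\t|\\s+"), function(v) {
        paste(ifelse(v %in% names(map), map[v], v), collapse = "\t")
      }, character(1))
    }
    net <- make_net(sub(lines))
    build_tensor(net, make_domains(sub(dom_lines), net$index),
                 make_complexes(gsub("\t", " ", sub(cpx_lines)), net$index))
  }
  t1 <- build(c("A", "B", "C", "D"))
  t2 <- build(c("Q", "Z", "K", "M"))   # relabelled copy
  map_back <- setNames(c("A", "B", "C", "D"), c("Q", "Z", "K", "M"))
  for (k in 1:3) {
    M1 <- as.matrix(t1$layers[[k]])
    M2 <- as.matrix(t2$layers[[k]])
    lab <- map_back[colnames(M2)]        # original label of each new column
    M2o <- M2[order(lab), order(lab)]
    dimnames(M1) <- dimnames(M2o) <- NULL
    expect_equal(M1, M2o, tolerance = 1e-12)
  }
})

test_that("tensor serialisation round-trips", {
  fx <- small_synth()
  tens <- build_tensor_from_dataset(fx$dataset)
  path <- tempfile(fileext = ".tsv")
  write_tensor(tens, path)
  again <- read_tensor(path, index = tens$index)
  for (k in 1:3) {
    expect_lt(max(abs(tens$layers[[k]] - again$layers[[k]])), 1e-12)
  }
})
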