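# Coupled bi-random walk with restart on the similarity tensor.  Per target
# protein the walk maintains two simplex vectors: X over proteins (functional
# similarity scores) and Y over layers (evidence-channel significance), and
# iterates
#     X^{t+1} = alpha * (T~  x_2 X^t x_3 Y^t) + (1 - alpha) * X^0
#     Y^{t+1} =          T~' x_1 X^t x_2 X^{t+1}
# where T~ is protein-mode (column) stochastic and T~' is layer-mode (fiber)
# stochastic.  Zero columns/fibers are normalised to uniform 1/n resp. 1/m;
# those uniform blocks are never materialised -- their contribution to a
# contraction is added analytically, which keeps everything sparse.

#' Walk configuration
#'
#' @param alpha restart mix in `[0, 1]`; weight `alpha` on the diffusion term
#'   and `1 - alpha` on the restart distribution (default 0.5).
#' @param tol L1 convergence tolerance on successive `X` iterates
#'   (default `1e-6`).
#' @param max_iter iteration cap (default 100).
#' @param pool_size number of top-similarity annotated proteins forming the
#'   candidate partner pool (default 20).
#' @param cc_threshold cohesiveness threshold; candidates with a cohesiveness
#'   coefficient `<=` this value are removed as pretenders (default 1/3).
#' @param mfs_threshold binarisation threshold for [network_stats()] on a
#'   similarity matrix; `NULL` means `1/n`.
#' @return an object of class `walk_config`.
#' @export
walk_config <- function(alpha = 0.5, tol = 1e-6, max_iter = 100L,
                        pool_size = 20L, cc_threshold = 1 / 3,
                        mfs_threshold = NULL) {
  stopifnot(alpha >= 0, alpha <= 1, tol > 0, max_iter >= 1, pool_size >= 1,
            cc_threshold >= 0, cc_threshold <= 1)
  structure(list(alpha = alpha, tol = tol, max_iter = as.integer(max_iter),
                 pool_size = as.integer(pool_size),
                 cc_threshold = cc_threshold, mfs_threshold = mfs_threshold),
            class = "walk_config")
}

#' Protein-mode (column) stochastic normalisation
#'
#' Each column `(j, k)` of the tensor is scaled to sum to 1 over the first
#' protein mode; columns with zero sum become uniform `1/n`, represented
#' implicitly by the `zero_cols` index sets.
#'
#' @param tensor a [similarity_tensor()].
#' @return list with `layers` (column-normalised sparse matrices) and
#'   `zero_cols` (per layer, integer indices of all-zero columns).
#' @export
normalize_protein_mode <- function(tensor) {
  layers <- lapply(tensor$layers, function(L) {
    cs <- colSums(L)
    L %*% Diagonal(x = ifelse(cs > 0, 1 / cs, 0))
  })
  zero_cols <- lapply(tensor$layers, function(L) which(colSums(L) == 0))
  list(layers = layers, zero_cols = zero_cols)
}

#' Layer-mode (fiber) stochastic normalisation
#'
#' Each fiber `(i, j, .)` is scaled to sum to 1 over the layer mode; fibers
#' that are zero in every layer become uniform `1/m`, represented implicitly
#' through the support indicator `U` (the uniform correction for a
#' contraction is `(1/m) * (total mass - mass on U)`).
#'
#' @param tensor a [similarity_tensor()].
#' @return list with `P` (per-layer fiber-normalised sparse matrices) and
#'   `U` (sparse 0/1 indicator of the union support).
#' @export
normalize_layer_mode <- function(tensor) {
  n <- tensor$n
  S <- .as_triplet(Reduce(`+`, tensor$layers))
  skey <- as.double(S@i) + as.double(n) * as.double(S@j)
  P <- lapply(tensor$layers, function(L) {
    Lt <- .as_triplet(L)
    if (!length(Lt@x)) {
      return(sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                          dims = c(n, n)))
    }
    pos <- match(as.double(Lt@i) + as.double(n) * as.double(Lt@j), skey)
    sparseMatrix(i = Lt@i + 1L, j = Lt@j + 1L, x = Lt@x / S@x[pos],
                 dims = c(n, n))
  })
  U <- sparseMatrix(i = S@i + 1L, j = S@j + 1L, x = 1, dims = c(n, n))
  list(P = P, U = U)
}

#' Normalise a tensor both ways for the walk
#'
#' @param tensor a [similarity_tensor()].
#' @return an object of class `normalized_tensor` bundling
#'   [normalize_protein_mode()] and [normalize_layer_mode()] plus `n`, `m`.
#' @export
normalize_tensor <- function(tensor) {
  structure(c(list(n = tensor$n, m = tensor$m),
              protein = list(normalize_protein_mode(tensor)),
              layer = list(normalize_layer_mode(tensor))),
            class = "normalized_tensor")
}

# Sparse contraction sum_j sum_k t~(i,j,k) x_j y_k including the implicit
# uniform columns.  Column-stochasticity makes the result sum to sum(x).
.contract_x <- function(pair, x, y) {
  n <- pair$n
  v <- numeric(n)
  for (k in seq_len(pair$m)) {
    zk <- pair$protein$zero_cols[[k]]
    v <- v + y[k] * (as.vector(pair$protein$layers[[k]] %*% x) +
                       sum(x[zk]) / n)
  }
  v
}

# Layer-mode contraction y_k = sum_ij t~'(i,j,k) x_i x'_j with the implicit
# uniform fibers added analytically; the raw result sums to sum(x)*sum(x').
.contract_y <- function(pair, x, xn) {
  uxn <- pair$layer$U %*% xn
  mass_on_support <- as.numeric(crossprod(x, uxn))
  off <- (sum(x) * sum(xn) - mass_on_support) / pair$m
  vapply(seq_len(pair$m), function(k) {
    as.numeric(crossprod(x, pair$layer$P[[k]] %*% xn)) + off
  }, numeric(1))
}

#' Run the coupled walk for one restart distribution
#'
#' Iterates the two-step update until the L1 change in `X` drops below
#' `cfg$tol` or `cfg$max_iter` is reached.  `Y` starts uniform (`1/m`); both
#' vectors are rescaled to the simplex after every update (the raw updates
#' already sum to 1 up to floating-point error, so this is projection by
#' scaling, not a change of direction).  With `alpha = 0` the walk returns
#' the restart vector itself.
#'
#' @param pair a [normalize_tensor()] result.
#' @param x0 restart distribution (length `n`, nonnegative; rescaled to sum
#'   to 1).
#' @param cfg a [walk_config()].
#' @return list with `x` (converged similarity vector), `y` (layer
#'   significance), `iters`, `converged`, `residual`.
#' @export
run_walk <- function(pair, x0, cfg = walk_config()) {
  stopifnot(length(x0) == pair$n, all(x0 >= 0), sum(x0) > 0)
  x0 <- x0 / sum(x0)
  x <- x0
  y <- rep(1 / pair$m, pair$m)
  res <- Inf
  iters <- 0L
  for (t in seq_len(cfg$max_iter)) {
    xn <- cfg$alpha * .contract_x(pair, x, y) + (1 - cfg$alpha) * x0
    xn <- xn / sum(xn)
    yraw <- .contract_y(pair, x, xn)
    y <- if (sum(yraw) > 0) yraw / sum(yraw) else rep(1 / pair$m, pair$m)
    res <- sum(abs(xn - x))
    x <- xn
    iters <- t
    if (res < cfg$tol) break
  }
  if (res >= cfg$tol) {
    warning(sprintf("walk did not converge in %d iterations (residual %.3g)",
                    cfg$max_iter, res))
  }
  list(x = x, y = y, iters = iters, converged = res < cfg$tol, residual = res)
}

# Restart machinery (cosine overlap of own domain sets plus own module
# memberships) precomputed once for all targets.
.restart_context <- function(n, domains, catalog) {
  if (is.null(domains) || !length(domains$universe)) {
    Dm <- sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                       dims = c(n, 1))
  } else {
    Dm <- sparseMatrix(i = rep.int(seq_len(n), lengths(domains$domains_of)),
                       j = match(unlist(domains$domains_of),
                                 domains$universe),
                       x = 1, dims = c(n, length(domains$universe)))
  }
  if (is.null(catalog) || !length(catalog$modules)) {
    Cm <- sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                       dims = c(n, 1))
  } else {
    Cm <- sparseMatrix(i = unlist(catalog$modules),
                       j = rep.int(seq_along(catalog$modules),
                                   lengths(catalog$modules)),
                       x = 1, dims = c(n, length(catalog$modules)))
  }
  list(Dm = Dm, dsz = rowSums(Dm), Cm = Cm, csz = rowSums(Cm))
}

.restart_from_context <- function(i, ctx, Nc) {
  d <- numeric(length(ctx$dsz))
  if (ctx$dsz[i] > 0) {
    ov <- as.vector(ctx$Dm %*% ctx$Dm[i, ])
    den <- sqrt(ctx$dsz * ctx$dsz[i])
    d <- d + ifelse(den > 0, ov / den, 0)
  }
  if (ctx$csz[i] > 0) {
    ov <- as.vector(ctx$Cm %*% ctx$Cm[i, ])
    den <- sqrt(ctx$csz * ctx$csz[i])
    d <- d + ifelse(den > 0, ov / den, 0)
  }
  s <- sum(d)
  if (s == 0) {                          # fall back: uniform on closed nbhd
    nb <- which(Nc[, i] > 0)
    d[nb] <- 1 / length(nb)
    return(d)
  }
  d / s
}

#' Restart distribution for a target protein
#'
#' Initial similarity scores `d_ij` are the cosine overlap of the two
#' proteins' own domain sets plus the cosine overlap of their own
#' module-membership sets (each term 0 when undefined), normalised to sum
#' to 1.  A target with no domain and no module evidence falls back to a
#' uniform distribution over its closed PPI neighborhood.
#'
#' @param i target protein index.
#' @param domains a `domain_annotation` or `NULL`.
#' @param catalog a `complex_catalog` or `NULL`.
#' @param net the `ppi_net` (used for the fallback neighborhood).
#' @return length-`n` nonnegative vector summing to 1.
#' @export
restart_vector <- function(i, domains, catalog, net) {
  n <- net$index$n
  ctx <- .restart_context(n, domains, catalog)
  .restart_from_context(i, ctx, adjacency(net) + Diagonal(n))
}

#' Functional similarity matrix from per-target walks
#'
#' Runs one walk per target protein; row `i` of the result is the converged
#' similarity vector for target `i`.  Rows sum to 1 before the diagonal
#' (self-similarity) is zeroed; the removed diagonal is kept in the
#' `"self_score"` attribute.  Targets are independent, so the result does
#' not depend on evaluation order.
#'
#' @param dataset an [rwrt_dataset()] (annotations not required).
#' @param cfg a [walk_config()].
#' @param tensor optional prebuilt [similarity_tensor()]; built from the
#'   dataset when `NULL`.
#' @return dense `n x n` matrix with protein identifiers as dimnames, zero
#'   diagonal, attributes `self_score` (diagonal before zeroing) and
#'   `iterations`.
#' @export
functional_similarity <- function(dataset, cfg = walk_config(),
                                  tensor = NULL) {
  net <- dataset$net
  n <- net$index$n
  if (is.null(tensor)) tensor <- build_tensor_from_dataset(dataset)
  pair <- normalize_tensor(tensor)
  ctx <- .restart_context(n, dataset$domains, dataset$catalog)
  Nc <- adjacency(net) + Diagonal(n)
  M <- matrix(0, n, n, dimnames = list(net$index$ids, net$index$ids))
  iters <- integer(n)
  failed <- 0L
  for (i in seq_len(n)) {
    x0 <- .restart_from_context(i, ctx, Nc)
    w <- withCallingHandlers(
      run_walk(pair, x0, cfg),
      warning = function(cnd) {
        failed <<- failed + 1L
        invokeRestart("muffleWarning")
      })
    M[i, ] <- w$x
    iters[i] <- w$iters
  }
  if (failed > 0) {
    warning(failed, " walk(s) did not converge within ", cfg$max_iter,
            " iterations")
  }
  self <- diag(M)
  diag(M) <- 0
  attr(M, "self_score") <- self
  attr(M, "iterations") <- iters
  M
}

#' Descriptive network statistics
#'
#' Average degree, clustering coefficient (mean local clustering, isolated
#' and degree-1 vertices counted as 0), density, and degree heterogeneity
#' (coefficient of variation of the degree sequence, `sd/mean`).  A
#' functional-similarity matrix is first symmetrised (`(M + t(M))/2`) and
#' binarised at `threshold` (default `1/n`, strict inequality).
#'
#' @param x a `ppi_net` or a square similarity matrix.
#' @param threshold binarisation threshold for matrix input.
#' @return named numeric vector `average_degree`, `clustering_coefficient`,
#'   `density`, `heterogeneity`.
#' @export
network_stats <- function(x, threshold = NULL) {
  if (inherits(x, "ppi_net")) {
    A <- adjacency(x) > 0
  } else {
    M <- (x + t(x)) / 2
    if (is.null(threshold)) threshold <- 1 / nrow(M)
    A <- M > threshold
    diag(A) <- FALSE
  }
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           diag = FALSE)
  if (igraph::vcount(g) == 0 || igraph::ecount(g) == 0) {
    return(c(average_degree = 0, clustering_coefficient = 0, density = 0,
             heterogeneity = 0))
  }
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "localaverage", isolates = "zero")
  het <- if (mean(deg) > 0) sd(deg) / mean(deg) else 0
  c(average_degree = mean(deg),
    clustering_coefficient = if (is.nan(cc)) 0 else cc,
    density = igraph::edge_density(g),
    heterogeneity = het)
}

#' Serialise / load a functional similarity matrix
#'
#' TSV of `(target_id, partner_id, score)` rows for scores above
#' `threshold`; the loader restores a dense matrix (absent pairs are 0).
#'
#' @param M similarity matrix with identifier dimnames.
#' @param path file path.
#' @param threshold write scores strictly above this value (default 0).
#' @export
write_similarity <- function(M, path, threshold = 0) {
  keep <- which(M > threshold, arr.ind = TRUE)
  tab <- data.frame(target_id = rownames(M)[keep[, 1]],
                    partner_id = colnames(M)[keep[, 2]],
                    score = M[keep])
  tab <- tab[order(tab$target_id, tab$partner_id, method = "radix"), ]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_similarity
#' @param index optional [protein_index()]; inferred from the file if `NULL`.
#' @export
read_similarity <- function(path, index = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (is.null(index)) index <- protein_index(c(tab$target_id, tab$partner_id))
  M <- matrix(0, index$n, index$n, dimnames = list(index$ids, index$ids))
  M[cbind(index_of(index, tab$target_id),
          index_of(index, tab$partner_id))] <- tab$score
  M
}
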