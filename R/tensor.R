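# Construction of the functional similarity tensor: three sparse symmetric
# n x n layers over the same protein index.
#   layer 1 "physical"     -- closed-neighborhood overlap of the PPI graph
#   layer 2 "co-structure" -- min-max normalised domain-context similarity
#   layer 3 "co-module"    -- density-weighted complex co-membership
# Diagonal entries are excluded everywhere: self-similarity would dominate
# the walk and is never used by the annotation step.

.layer_names <- c("physical", "co-structure", "co-module")

.empty_layer <- function(n, ids = NULL) {
  sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
               dims = c(n, n),
               dimnames = if (is.null(ids)) NULL else list(ids, ids))
}

.as_triplet <- function(M) as(as(M, "generalMatrix"), "TsparseMatrix")

#' Sparse functional-similarity tensor
#'
#' Container for `m` symmetric nonnegative association layers over a common
#' protein set.  Normally produced by [build_tensor()]; the constructor
#' validates symmetry, nonnegativity, finiteness and a zero diagonal.
#'
#' @param layers list of `n x n` sparse matrices.
#' @param layer_names character vector naming the layers.
#' @param index optional [protein_index()].
#' @return an object of class `similarity_tensor` with fields `n`, `m`,
#'   `layers`, `layer_names`, `index`.
#' @export
similarity_tensor <- function(layers, layer_names = NULL, index = NULL) {
  stopifnot(is.list(layers), length(layers) >= 1)
  n <- nrow(layers[[1]])
  if (is.null(layer_names)) layer_names <- .layer_names[seq_along(layers)]
  layers <- lapply(layers, function(L) {
    L <- drop0(as(as(L, "CsparseMatrix"), "generalMatrix"))
    stopifnot(nrow(L) == n, ncol(L) == n)
    if (length(L@x)) {
      if (any(!is.finite(L@x)) || any(L@x < 0)) {
        stop("tensor layers must be finite and nonnegative")
      }
    }
    if (any(diag(L) != 0)) stop("tensor layers must have a zero diagonal")
    if (max(abs(L - t(L))) > 1e-12) stop("tensor layers must be symmetric")
    L
  })
  structure(list(n = n, m = length(layers), layers = layers,
                 layer_names = layer_names, index = index),
            class = "similarity_tensor")
}

#' @export
print.similarity_tensor <- function(x, ...) {
  nnz <- vapply(x$layers, function(L) length(L@x), numeric(1))
  cat("similarity_tensor:", x$n, "proteins x", x$m, "layers\n")
  cat("  nonzeros:", paste(sprintf("%s=%d", x$layer_names, nnz),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Topology layer: closed-neighborhood overlap similarity
#'
#' For proteins `i`, `j` with closed PPI neighborhoods `N_i`, `N_j` (the
#' protein together with its direct interactors) and `c = |N_i n N_j|`, the
#' similarity is
#' \deqn{t(i,j) = 4 c^2 / ((|N_i| + c)(|N_j| + c)),}
#' computed for every pair (interacting or not) with `c > 0`; all other
#' pairs are implicit zeros.  Values lie in `(0, 1]`, with 1 attained exactly
#' when the two closed neighborhoods coincide.
#'
#' @param net a `ppi_net`.
#' @return sparse symmetric matrix with zero diagonal.
#' @export
topology_layer <- function(net) {
  n <- net$index$n
  Nc <- adjacency(net) + Diagonal(n)
  sz <- colSums(Nc)
  C <- .as_triplet(Nc %*% Nc)           # entries = |N_i n N_j| (0/1 inputs)
  i <- C@i + 1L; j <- C@j + 1L; cmn <- C@x
  keep <- i != j & cmn > 0
  i <- i[keep]; j <- j[keep]; cmn <- cmn[keep]
  sparseMatrix(i = i, j = j, x = 4 * cmn^2 / ((sz[i] + cmn) * (sz[j] + cmn)),
               dims = c(n, n), dimnames = list(net$index$ids, net$index$ids))
}

# log-space hypergeometric-style domain content similarity; vectorised over
# equal-length count vectors.  Arguments are |DC|, |D_i|, |D_j|, |DT|.
.ds_value <- function(nc, ni, nj, nt) {
  bad <- nc > pmin(ni, nj) | ni > nt | nj > nt | (ni + nj - nc) > nt
  if (any(bad)) {
    k <- which(bad)[1]
    stop(sprintf(paste0("undefined binomial in domain similarity: ",
                        "|DC|=%d |Di|=%d |Dj|=%d |DT|=%d"),
                 nc[k], ni[k], nj[k], nt))
  }
  -(lchoose(nt, nc) + lchoose(nt - nc, ni - nc) + lchoose(nt - ni, nj - nc) -
      lchoose(nt, ni) - lchoose(nt, nj))
}

#' Domain content similarity of two domain sets
#'
#' The probability of observing an overlap of size `|DC| = |D_i n D_j|`
#' between two sets of sizes `|D_i|` and `|D_j|` drawn from a universe of
#' `DT_size` domain types is the hypergeometric-style ratio
#' \deqn{\frac{\binom{|DT|}{|DC|}\binom{|DT|-|DC|}{|D_i|-|DC|}
#'       \binom{|DT|-|D_i|}{|D_j|-|DC|}}
#'      {\binom{|DT|}{|D_i|}\binom{|DT|}{|D_j|}}}
#' and the similarity is its negative logarithm: rare (large) overlaps score
#' high.  Binomial coefficients are evaluated in log-space (log-gamma), so
#' domain universes of thousands of types do not overflow.
#'
#' @param d_i,d_j character vectors of domain types (sets).
#' @param dt_size total number of domain types in the network.
#' @return nonnegative similarity value, symmetric in its arguments.
#' @export
#' @examples
#' domain_similarity(as.character(1:5), as.character(5:7), 20)
domain_similarity <- function(d_i, d_j, dt_size) {
  d_i <- unique(as.character(d_i)); d_j <- unique(as.character(d_j))
  .ds_value(length(intersect(d_i, d_j)), length(d_i), length(d_j),
            as.integer(dt_size))
}

#' Domain contexts: closed-neighborhood domain sets
#'
#' The domain context `D_i` of protein `i` is the set of distinct domain
#' types carried by `i` itself and by its direct PPI neighbors.
#'
#' @param net a `ppi_net`.
#' @param domains a `domain_annotation`.
#' @return list with `incidence` (sparse 0/1 protein x domain-type matrix of
#'   contexts), `sizes` (`|D_i|`), and `dt_size` (`|DT|`, the network-wide
#'   domain universe).
#' @export
domain_context <- function(net, domains) {
  n <- net$index$n
  universe <- domains$universe
  if (!length(universe)) {
    return(list(incidence = sparseMatrix(i = integer(0), j = integer(0),
                                         x = numeric(0), dims = c(n, 0)),
                sizes = numeric(n), dt_size = 0L))
  }
  pidx <- rep.int(seq_len(n), lengths(domains$domains_of))
  didx <- match(unlist(domains$domains_of), universe)
  Dm <- sparseMatrix(i = pidx, j = didx, x = 1,
                     dims = c(n, length(universe)))
  B <- .as_triplet((adjacency(net) + Diagonal(n)) %*% Dm)
  B <- sparseMatrix(i = B@i + 1L, j = B@j + 1L, x = 1,  # binarise
                    dims = c(n, length(universe)))
  list(incidence = B, sizes = rowSums(B), dt_size = length(universe))
}

#' Co-structure layer: normalised domain-context similarity
#'
#' [domain_similarity()] is evaluated for every unordered pair of proteins
#' whose domain contexts share at least one domain type (pairs with empty
#' overlap carry no shared-domain evidence and stay implicit zeros), then
#' min-max normalised over exactly that evaluated pair set so entries lie in
#' `[0, 1]`.  If all evaluated pairs have identical similarity the layer
#' degenerates to all ones (a message is emitted); if no pair shares a
#' domain the layer is empty (with a warning).
#'
#' @param net a `ppi_net`.
#' @param domains a `domain_annotation`.
#' @return sparse symmetric matrix with zero diagonal.
#' @export
costructure_layer <- function(net, domains) {
  n <- net$index$n
  ctx <- domain_context(net, domains)
  if (ctx$dt_size == 0) {
    warning("no domain annotations: co-structure layer is empty")
    return(.empty_layer(n, net$index$ids))
  }
  P <- .as_triplet(ctx$incidence %*% t(ctx$incidence))  # |D_i n D_j|
  i <- P@i + 1L; j <- P@j + 1L; nc <- P@x
  keep <- i != j & nc > 0
  i <- i[keep]; j <- j[keep]; nc <- nc[keep]
  if (!length(i)) {
    warning("no protein pair shares a context domain: co-structure layer is empty")
    return(.empty_layer(n, net$index$ids))
  }
  ds <- .ds_value(nc, ctx$sizes[i], ctx$sizes[j], ctx$dt_size)
  rng <- range(ds)
  if (rng[1] == rng[2]) {
    message("degenerate co-structure normalisation: all evaluated pairs equal")
    val <- rep(1, length(ds))
  } else {
    val <- (ds - rng[1]) / (rng[2] - rng[1])
  }
  drop0(sparseMatrix(i = i, j = j, x = val, dims = c(n, n),
                     dimnames = list(net$index$ids, net$index$ids)))
}

#' Density of a protein module
#'
#' `Score(M_k) = 2 |E_k| / (|V_k| (|V_k| - 1))` where `E_k` counts physical
#' PPI edges with both ends inside the module.
#'
#' @param module integer vector of protein indices, at least 2.
#' @param net a `ppi_net`.
#' @return density in `[0, 1]`.
#' @export
module_density <- function(module, net) {
  v <- unique(as.integer(module))
  if (length(v) < 2) stop("module density needs at least 2 members")
  A <- adjacency(net)
  e <- sum(A[v, v]) / 2
  2 * e / (length(v) * (length(v) - 1))
}

#' Density scores of every module in a catalog
#' @param catalog a `complex_catalog`.
#' @param net a `ppi_net`.
#' @return numeric vector of densities.
#' @export
module_scores <- function(catalog, net) {
  vapply(catalog$modules, module_density, numeric(1), net = net)
}

#' Co-module layer: density-weighted complex co-membership
#'
#' With `s_i` the sum of density scores of the modules containing `i` and
#' `sh_ij` the sum over modules containing both `i` and `j`,
#' \deqn{t(i,j) = sh_{ij}^2 / (s_i s_j),}
#' zero (absent) whenever a marginal sum or the shared sum is zero.  Since
#' `sh_ij <= min(s_i, s_j)`, values never exceed 1; a pair whose only module
#' memberships coincide scores exactly 1.
#'
#' @param catalog a `complex_catalog`.
#' @param net a `ppi_net`.
#' @return sparse symmetric matrix with zero diagonal.
#' @export
comodule_layer <- function(catalog, net) {
  n <- net$index$n
  if (!length(catalog$modules)) return(.empty_layer(n, net$index$ids))
  scores <- module_scores(catalog, net)
  W <- sparseMatrix(i = unlist(catalog$modules),
                    j = rep.int(seq_along(catalog$modules),
                                lengths(catalog$modules)),
                    x = 1, dims = c(n, length(catalog$modules)))
  s <- as.vector(W %*% scores)
  Sh <- .as_triplet(W %*% Diagonal(x = scores) %*% t(W))
  i <- Sh@i + 1L; j <- Sh@j + 1L; sh <- Sh@x
  keep <- i != j & sh > 0 & s[i] > 0 & s[j] > 0
  i <- i[keep]; j <- j[keep]; sh <- sh[keep]
  drop0(sparseMatrix(i = i, j = j, x = sh^2 / (s[i] * s[j]), dims = c(n, n),
                     dimnames = list(net$index$ids, net$index$ids)))
}

#' Assemble the functional similarity tensor
#'
#' Stacks the topology, co-structure and co-module layers over the network's
#' protein index.  Missing evidence (`domains` or `catalog` `NULL`, or
#' carrying no usable records) yields an empty corresponding layer; it is an
#' error for all three layers to be empty.
#'
#' @param net a `ppi_net`.
#' @param domains a `domain_annotation` or `NULL`.
#' @param catalog a `complex_catalog` or `NULL`.
#' @return a [similarity_tensor()] with `m = 3`.
#' @export
build_tensor <- function(net, domains = NULL, catalog = NULL) {
  n <- net$index$n
  L1 <- topology_layer(net)
  L2 <- if (is.null(domains)) .empty_layer(n, net$index$ids) else
    suppressWarnings(costructure_layer(net, domains))
  L3 <- if (is.null(catalog)) .empty_layer(n, net$index$ids) else
    comodule_layer(catalog, net)
  layers <- list(L1, L2, L3)
  if (all(vapply(layers, function(L) length(L@x) == 0, logical(1)))) {
    stop("all three tensor layers are empty")
  }
  similarity_tensor(layers, .layer_names, net$index)
}

#' @rdname build_tensor
#' @param dataset an [rwrt_dataset()].
#' @export
build_tensor_from_dataset <- function(dataset) {
  build_tensor(dataset$net, dataset$domains, dataset$catalog)
}

#' Serialise / load a similarity tensor
#'
#' Four-column TSV `i_id  j_id  layer  value` with `i_id < j_id`
#' (lexicographically); the loader re-symmetrises.
#'
#' @param tensor a `similarity_tensor` with a protein index.
#' @param path file path.
#' @export
write_tensor <- function(tensor, path) {
  stopifnot(!is.null(tensor$index))
  ids <- tensor$index$ids
  rows <- lapply(seq_len(tensor$m), function(k) {
    L <- .as_triplet(tensor$layers[[k]])
    keep <- L@i < L@j
    data.frame(i_id = ids[L@i[keep] + 1L], j_id = ids[L@j[keep] + 1L],
               layer = tensor$layer_names[k], value = L@x[keep])
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$layer, tab$i_id, tab$j_id, method = "radix"), ]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tensor
#' @param index optional [protein_index()]; inferred from the file if `NULL`.
#' @param layer_names expected layer names, in order.
#' @export
read_tensor <- function(path, index = NULL, layer_names = .layer_names) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (is.null(index)) index <- protein_index(c(tab$i_id, tab$j_id))
  if (!all(tab$layer %in% layer_names)) {
    stop("unknown layer name(s): ",
         paste(setdiff(unique(tab$layer), layer_names), collapse = ", "))
  }
  n <- index$n
  layers <- lapply(layer_names, function(nm) {
    sub <- tab[tab$layer == nm, , drop = FALSE]
    if (!nrow(sub)) return(.empty_layer(n, index$ids))
    i <- index_of(index, sub$i_id); j <- index_of(index, sub$j_id)
    sparseMatrix(i = c(i, j), j = c(j, i), x = rep(sub$value, 2),
                 dims = c(n, n), dimnames = list(index$ids, index$ids))
  })
  similarity_tensor(layers, layer_names, index)
}
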