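# Readers for the four evidence sources: a physical PPI edge list, GO (BP)
# annotations, per-protein domain content, and a protein-complex catalog.
# The PPI file defines the protein universe: every matrix and tensor is
# indexed by the ProteinIndex built from it, and annotation/domain/complex
# records for proteins outside the network are silently restricted.
# Identifiers are matched as exact strings after whitespace trimming; no
# identifier mapping is attempted.

#' Protein index
#'
#' Bidirectional map between protein identifier strings and dense integer
#' indices `1..n`.  Identifiers are sorted lexicographically (byte order), so
#' the index is reproducible across runs for the same input.
#'
#' @param ids character vector of protein identifiers; duplicates allowed.
#' @return An object of class `protein_index`: a list with `ids` (ordered
#'   unique identifiers) and `n`.
#' @seealso [index_of()]
#' @export
#' @examples
#' idx <- protein_index(c("YBR009C", "YAL001C", "YBR009C"))
#' idx$ids
protein_index <- function(ids) {
  ids <- trimws(as.character(ids))
  ids <- ids[!is.na(ids) & nzchar(ids)]
  if (!length(ids)) stop("protein index needs at least one identifier")
  ids <- sort(unique(ids), method = "radix")
  structure(list(ids = ids, n = length(ids)), class = "protein_index")
}

#' @export
print.protein_index <- function(x, ...) {
  cat("protein_index with", x$n, "proteins\n")
  invisible(x)
}

#' Map protein identifiers to dense indices
#'
#' @param index a [protein_index()].
#' @param ids character vector of identifiers.
#' @return integer positions in `index$ids`; `NA` for unknown identifiers.
#' @export
index_of <- function(index, ids) match(trimws(as.character(ids)), index$ids)

.read_lines <- function(path, comment = "#") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl(paste0("^\\s*([", comment, "]|$)"), lines)
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a protein-protein interaction network
#'
#' Reads a whitespace/tab-separated edge list (two identifier columns;
#' `#`-comment lines allowed).  Self-interactions and repeated interactions
#' are removed.  The protein index covers exactly the proteins appearing in
#' at least one retained edge.
#'
#' @param path path to the edge-list file.
#' @param format only `"tsv-edgelist"` is supported.
#' @return An object of class `ppi_net`: a list with `index` (a
#'   `protein_index`) and `edges`, an integer matrix with columns `i < j`.
#' @export
read_ppi <- function(path, format = "tsv-edgelist") {
  format <- match.arg(format)
  src <- .read_lines(path)
  if (!length(src$lines)) stop("empty edge list: ", path)
  fields <- strsplit(trimws(src$lines), "[\t ]+")
  nf <- lengths(fields)
  if (any(nf < 2)) {
    stop("malformed edge line ", src$lineno[which(nf < 2)[1]],
         ": expected at least 2 fields")
  }
  a <- vapply(fields, `[`, character(1), 1L)
  b <- vapply(fields, `[`, character(1), 2L)
  keep <- a != b                        # drop self-interactions
  a <- a[keep]; b <- b[keep]
  if (!length(a)) stop("no edges left after removing self-interactions")
  index <- protein_index(c(a, b))
  i <- index_of(index, a)
  j <- index_of(index, b)
  lo <- pmin(i, j); hi <- pmax(i, j)
  dup <- duplicated(cbind(lo, hi))      # drop repeated interactions
  edges <- cbind(i = lo[!dup], j = hi[!dup])
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  structure(list(index = index, edges = edges), class = "ppi_net")
}

#' @export
print.ppi_net <- function(x, ...) {
  cat("ppi_net:", x$index$n, "proteins,", nrow(x$edges), "interactions\n")
  invisible(x)
}

#' Number of proteins / interactions in a network
#' @param net a `ppi_net`.
#' @return integer count.
#' @export
n_proteins <- function(net) net$index$n

#' @rdname n_proteins
#' @export
n_interactions <- function(net) nrow(net$edges)

#' Sparse symmetric adjacency matrix of a PPI network
#'
#' @param net a `ppi_net`.
#' @return an `n x n` sparse 0/1 matrix with zero diagonal, dimnames set to
#'   protein identifiers.
#' @export
adjacency <- function(net) {
  n <- net$index$n
  e <- net$edges
  sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]), x = 1,
               dims = c(n, n), dimnames = list(net$index$ids, net$index$ids))
}

#' Write a PPI network back to an edge list
#'
#' Inverse of [read_ppi()]: re-reading the written file yields an identical
#' edge set and protein index.
#'
#' @param net a `ppi_net`.
#' @param path output path.
#' @export
write_ppi <- function(net, path) {
  ids <- net$index$ids
  writeLines(paste(ids[net$edges[, 1]], ids[net$edges[, 2]], sep = "\t"), path)
  invisible(path)
}

.make_annotation <- function(pidx, term, index, universe = NULL) {
  n <- index$n
  ok <- !is.na(pidx) & !is.na(term) & nzchar(term)
  pidx <- pidx[ok]; term <- term[ok]
  pair <- !duplicated(paste0(pidx, "\r", term))
  pidx <- pidx[pair]; term <- term[pair]
  terms_of <- vector("list", n)
  for (k in seq_len(n)) terms_of[[k]] <- character(0)
  if (length(pidx)) {
    sp <- split(term, pidx)
    for (nm in names(sp)) {
      terms_of[[as.integer(nm)]] <- sort(sp[[nm]], method = "radix")
    }
  }
  proteins_of <- lapply(split(pidx, term), function(v) sort(unique(v)))
  if (is.null(universe)) universe <- sort(names(proteins_of), method = "radix")
  structure(list(terms_of = terms_of, proteins_of = proteins_of,
                 terms = universe, index = index),
            class = "fn_annotation")
}

#' Read GO (Biological Process) annotations
#'
#' Accepts either a two-column TSV (`protein<TAB>GO:NNNNNNN`) or a GAF 2.x
#' file (detected automatically, or forced via `format`).  For GAF input only
#' the BP aspect (`P`) is kept; evidence codes are ignored.  Annotations of
#' proteins absent from `index` are dropped, and GO terms that annotate fewer
#' than `min_count` or more than `max_count` indexed proteins are removed
#' (bounds inclusive): very specific and very general functions carry little
#' predictive signal.
#'
#' @param path annotation file.
#' @param index the network's [protein_index()].
#' @param format `"auto"`, `"tsv"` or `"gaf"`.
#' @param namespace annotation namespace; only `"BP"` is supported.
#' @param min_count,max_count inclusive bounds on the number of annotated
#'   proteins per retained term (defaults 10 and 200).
#' @return An object of class `fn_annotation`: per-protein term sets
#'   (`terms_of`, a list of length `n`), the transposed map `proteins_of`,
#'   and the filtered term universe `terms`.
#' @export
read_annotations <- function(path, index, format = c("auto", "tsv", "gaf"),
                             namespace = "BP",
                             min_count = 10L, max_count = 200L) {
  format <- match.arg(format)
  namespace <- match.arg(namespace, "BP")
  stopifnot(min_count <= max_count, min_count >= 0)
  src <- .read_lines(path, comment = "#!")
  fields <- strsplit(src$lines, "\t", fixed = TRUE)
  if (format == "auto") {
    format <- if (length(fields) && lengths(fields)[1] >= 15) "gaf" else "tsv"
  }
  if (format == "gaf") {
    nf <- lengths(fields)
    if (any(nf < 9)) {
      stop("malformed GAF line ", src$lineno[which(nf < 9)[1]])
    }
    prot <- vapply(fields, `[`, character(1), 2L)
    term <- vapply(fields, `[`, character(1), 5L)
    aspect <- vapply(fields, `[`, character(1), 9L)
    keep <- aspect == "P"
    prot <- prot[keep]; term <- term[keep]
  } else {
    fields <- strsplit(trimws(src$lines), "[\t ]+")
    nf <- lengths(fields)
    if (any(nf < 2)) {
      stop("malformed annotation line ", src$lineno[which(nf < 2)[1]],
           ": expected 2 fields")
    }
    prot <- vapply(fields, `[`, character(1), 1L)
    term <- vapply(fields, `[`, character(1), 2L)
  }
  pidx <- index_of(index, prot)
  ok <- !is.na(pidx)
  pidx <- pidx[ok]; term <- term[ok]
  pair <- !duplicated(paste0(pidx, "\r", term))
  pidx <- pidx[pair]; term <- term[pair]
  counts <- table(term)
  retained <- names(counts)[counts >= min_count & counts <= max_count]
  if (!length(retained)) {
    stop("no GO terms annotate between ", min_count, " and ", max_count,
         " indexed proteins")
  }
  keep <- term %in% retained
  .make_annotation(pidx[keep], term[keep], index)
}

#' Mask the annotations of held-out proteins
#'
#' Used by the cross-validation harness: the listed proteins' term sets are
#' emptied (and removed from the term-to-protein map) while the filtered term
#' universe is kept fixed, so evaluation backgrounds do not shift between
#' folds.
#'
#' @param ann an `fn_annotation`.
#' @param targets integer protein indices to mask.
#' @return a new `fn_annotation`.
#' @export
mask_annotations <- function(ann, targets) {
  targets <- as.integer(targets)
  terms_of <- ann$terms_of
  for (i in targets) terms_of[[i]] <- character(0)
  proteins_of <- lapply(ann$proteins_of, function(v) setdiff(v, targets))
  proteins_of <- proteins_of[lengths(proteins_of) > 0]
  structure(list(terms_of = terms_of, proteins_of = proteins_of,
                 terms = ann$terms, index = ann$index),
            class = "fn_annotation")
}

#' @export
print.fn_annotation <- function(x, ...) {
  cat("fn_annotation:", sum(lengths(x$terms_of) > 0), "annotated proteins,",
      length(x$terms), "GO terms in universe\n")
  invisible(x)
}

#' Indices of annotated proteins
#' @param ann an `fn_annotation`.
#' @return integer vector of protein indices with at least one term.
#' @export
annotated_proteins <- function(ann) which(lengths(ann$terms_of) > 0)

#' Read per-protein domain content
#'
#' Two-column TSV `protein<TAB>domain` (e.g. PFAM accessions).  Proteins not
#' in `index` are ignored; indexed proteins absent from the file get an empty
#' domain set.  Duplicated rows collapse (set semantics).
#'
#' @param path domain file; may be empty (all sets empty).
#' @param index the network's [protein_index()].
#' @return An object of class `domain_annotation`: `domains_of` (list of
#'   length `n` of character vectors) and `universe` (all domain identifiers
#'   seen on indexed proteins).
#' @export
read_domains <- function(path, index) {
  src <- .read_lines(path)
  n <- index$n
  domains_of <- vector("list", n)
  for (k in seq_len(n)) domains_of[[k]] <- character(0)
  if (length(src$lines)) {
    fields <- strsplit(trimws(src$lines), "[\t ]+")
    nf <- lengths(fields)
    if (any(nf < 2)) {
      stop("malformed domain line ", src$lineno[which(nf < 2)[1]],
           ": expected 2 fields")
    }
    prot <- vapply(fields, `[`, character(1), 1L)
    dom <- vapply(fields, `[`, character(1), 2L)
    pidx <- index_of(index, prot)
    ok <- !is.na(pidx)
    sp <- split(dom[ok], pidx[ok])
    for (nm in names(sp)) {
      domains_of[[as.integer(nm)]] <- sort(unique(sp[[nm]]), method = "radix")
    }
  }
  universe <- sort(unique(unlist(domains_of)), method = "radix")
  if (is.null(universe)) universe <- character(0)
  structure(list(domains_of = domains_of, universe = universe, index = index),
            class = "domain_annotation")
}

#' @export
print.domain_annotation <- function(x, ...) {
  cat("domain_annotation:", sum(lengths(x$domains_of) > 0),
      "proteins with domains,", length(x$universe), "domain types\n")
  invisible(x)
}

#' Read a protein-complex catalog
#'
#' One complex per line, whitespace-separated member identifiers (CYC2008
#' style).  Members are restricted to indexed proteins; complexes with fewer
#' than two surviving members are dropped (a message reports how many).
#'
#' @param path catalog file.
#' @param index the network's [protein_index()].
#' @return An object of class `complex_catalog`: `modules`, a list of integer
#'   protein-index vectors.
#' @export
read_complexes <- function(path, index) {
  src <- .read_lines(path)
  members <- lapply(strsplit(trimws(src$lines), "[\t ]+"), function(m) {
    v <- index_of(index, m)
    sort(unique(v[!is.na(v)]))
  })
  modules <- members[lengths(members) >= 2]
  dropped <- length(members) - length(modules)
  if (dropped > 0) {
    message(dropped, " complex(es) dropped (< 2 members in the network)")
  }
  structure(list(modules = modules, index = index), class = "complex_catalog")
}

#' @export
print.complex_catalog <- function(x, ...) {
  cat("complex_catalog:", length(x$modules), "modules covering",
      length(unique(unlist(x$modules))), "proteins\n")
  invisible(x)
}

#' Bundle the four evidence sources into one dataset
#'
#' Light container used by the pipeline functions ([build_tensor()],
#' [functional_similarity()], [loocv()], ...).  All components must share the
#' network's protein index.
#'
#' @param net a `ppi_net`.
#' @param annotations an `fn_annotation` (may be `NULL` for walk-only use).
#' @param domains a `domain_annotation` or `NULL`.
#' @param catalog a `complex_catalog` or `NULL`.
#' @return an object of class `rwrt_dataset`.
#' @export
rwrt_dataset <- function(net, annotations = NULL, domains = NULL,
                         catalog = NULL) {
  stopifnot(inherits(net, "ppi_net"))
  for (x in list(annotations, domains, catalog)) {
    if (!is.null(x) && !identical(x$index$ids, net$index$ids)) {
      stop("all dataset components must share the network's protein index")
    }
  }
  structure(list(net = net, annotations = annotations, domains = domains,
                 catalog = catalog),
            class = "rwrt_dataset")
}

#' @export
print.rwrt_dataset <- function(x, ...) {
  print(x$net)
  if (!is.null(x$annotations)) print(x$annotations)
  if (!is.null(x$domains)) print(x$domains)
  if (!is.null(x$catalog)) print(x$catalog)
  invisible(x)
}
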