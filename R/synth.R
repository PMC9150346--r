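# Synthetic data generator.  Emulates the statistical structure the method
# assumes: a planted-partition PPI graph whose blocks play the role of
# functional modules, domain pools enriched within modules, GO terms planted
# per module with annotation noise, and a complex catalog that subsamples the
# modules.  Every stage draws from its own deterministically derived
# sub-seed, so regenerating one stage never shifts the others.

#' Synthetic dataset configuration
#'
#' Defaults describe the reference fixture used throughout the test suite:
#' 200 proteins in 10 equal modules, dense within-module wiring
#' (`p_within = 0.8`) against a sparse background (`p_between = 0.02`), and
#' 10% noise on both the domain and the annotation channel.
#'
#' @param n_proteins number of proteins.
#' @param n_modules number of planted modules (requires
#'   `n_proteins >= 2 * n_modules`).
#' @param p_within,p_between within- and between-module edge probabilities
#'   (`p_within > p_between` for planted-structure fixtures).
#' @param domains_per_module size of each module's shared domain pool.
#' @param domain_noise probability a protein carries one extra domain from
#'   another module's pool.
#' @param terms_per_module number of GO terms planted per module.
#' @param annotation_noise probability a planted protein-term assignment is
#'   perturbed (half of the events drop the term, half replace it with a
#'   term from another module).
#' @param complex_coverage fraction of each module emitted as its complex
#'   record.
#' @param seed integer seed (mandatory).
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_proteins = 200L, n_modules = 10L,
                         p_within = 0.8, p_between = 0.02,
                         domains_per_module = 3L, domain_noise = 0.1,
                         terms_per_module = 3L, annotation_noise = 0.1,
                         complex_coverage = 0.8, seed) {
  if (missing(seed)) stop("a seed is mandatory for synthetic data")
  probs <- c(p_within, p_between, domain_noise, annotation_noise,
             complex_coverage)
  stopifnot(all(probs >= 0), all(probs <= 1),
            n_proteins >= 2 * n_modules, n_modules >= 1,
            domains_per_module >= 1, terms_per_module >= 1)
  structure(list(n_proteins = as.integer(n_proteins),
                 n_modules = as.integer(n_modules),
                 p_within = p_within, p_between = p_between,
                 domains_per_module = as.integer(domains_per_module),
                 domain_noise = domain_noise,
                 terms_per_module = as.integer(terms_per_module),
                 annotation_noise = annotation_noise,
                 complex_coverage = complex_coverage,
                 seed = as.integer(seed)),
            class = "synth_config")
}

.stage_seed <- function(seed, stage) {
  (as.integer(seed) + 99991L * stage) %% .Machine$integer.max
}

#' Generate a synthetic dataset on disk
#'
#' Writes the four standard-format files (`ppi.tsv`, `annotations.tsv`,
#' `domains.tsv`, `complexes.txt`) plus returns the ground truth.  Output is
#' byte-identical for a given configuration and seed.  Proteins left
#' isolated by the edge sampling are attached to one random same-module
#' partner so every protein appears in the network.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with `files` (named paths), `module_of` (named
#'   module id per protein), `planted_terms` and `planted_domains` (per
#'   module), and `config`.
#' @export
generate_synthetic <- function(cfg, dir) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- cfg$n_proteins
  K <- cfg$n_modules
  ids <- sprintf("P%04d", seq_len(n))
  module_of <- rep(seq_len(K), length.out = n)
  module_of <- sort(module_of)                 # contiguous blocks
  members <- split(seq_len(n), module_of)

  ## stage 1: planted-partition graph
  set.seed(.stage_seed(cfg$seed, 1L))
  pr <- which(upper.tri(diag(n)), arr.ind = TRUE)
  i <- pr[, 1]; j <- pr[, 2]
  p <- ifelse(module_of[i] == module_of[j], cfg$p_within, cfg$p_between)
  keep <- runif(length(p)) < p
  ei <- i[keep]; ej <- j[keep]
  deg <- tabulate(c(ei, ej), nbins = n)
  for (v in which(deg == 0)) {                 # no isolated proteins
    mates <- setdiff(members[[module_of[v]]], v)
    w <- if (length(mates) == 1) mates else sample(mates, 1)
    ei <- c(ei, min(v, w)); ej <- c(ej, max(v, w))
  }
  ord <- order(ei, ej)
  edges <- unique(cbind(ei[ord], ej[ord]))

  ## stage 2: module domain pools
  set.seed(.stage_seed(cfg$seed, 2L))
  planted_domains <- lapply(seq_len(K), function(k) {
    sprintf("D%04d", (k - 1) * cfg$domains_per_module +
              seq_len(cfg$domains_per_module))
  })
  dom_prot <- integer(0); dom_id <- character(0)
  for (v in seq_len(n)) {
    d <- planted_domains[[module_of[v]]]
    if (K > 1 && runif(1) < cfg$domain_noise) {
      other <- unlist(planted_domains[-module_of[v]])
      d <- c(d, sample(other, 1))
    }
    dom_prot <- c(dom_prot, rep(v, length(d)))
    dom_id <- c(dom_id, d)
  }

  ## stage 3: planted GO terms with annotation noise
  set.seed(.stage_seed(cfg$seed, 3L))
  planted_terms <- lapply(seq_len(K), function(k) {
    sprintf("GO:%07d", 900000 + (k - 1) * cfg$terms_per_module +
              seq_len(cfg$terms_per_module))
  })
  ann_prot <- integer(0); ann_term <- character(0)
  for (v in seq_len(n)) {
    terms <- planted_terms[[module_of[v]]]
    out <- character(0)
    for (tm in terms) {
      u <- runif(1)
      if (u < cfg$annotation_noise / 2) {
        next                                    # dropped
      } else if (u < cfg$annotation_noise && K > 1) {
        out <- c(out, sample(unlist(planted_terms[-module_of[v]]), 1))
      } else {
        out <- c(out, tm)
      }
    }
    out <- unique(out)
    ann_prot <- c(ann_prot, rep(v, length(out)))
    ann_term <- c(ann_term, out)
  }

  ## stage 4: complexes subsample the modules
  set.seed(.stage_seed(cfg$seed, 4L))
  complexes <- lapply(members, function(mem) {
    size <- max(2L, round(cfg$complex_coverage * length(mem)))
    sort(if (size >= length(mem)) mem else sample(mem, size))
  })

  files <- c(ppi = file.path(dir, "ppi.tsv"),
             annotations = file.path(dir, "annotations.tsv"),
             domains = file.path(dir, "domains.tsv"),
             complexes = file.path(dir, "complexes.txt"))
  writeLines(paste(ids[edges[, 1]], ids[edges[, 2]], sep = "\t"),
             files[["ppi"]])
  writeLines(paste(ids[ann_prot], ann_term, sep = "\t"),
             files[["annotations"]])
  writeLines(paste(ids[dom_prot], dom_id, sep = "\t"), files[["domains"]])
  writeLines(vapply(complexes, function(mem) {
    paste(ids[mem], collapse = " ")
  }, character(1)), files[["complexes"]])

  invisible(list(files = files, module_of = setNames(module_of, ids),
                 planted_terms = planted_terms,
                 planted_domains = planted_domains, config = cfg))
}

#' Generate and load a synthetic dataset in one step
#'
#' Runs [generate_synthetic()] and reads the emitted files back through the
#' package's own readers, so the returned dataset is exactly what a user
#' would obtain from files on disk.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory (a fresh temporary directory by default).
#' @param min_count,max_count GO-term filter bounds passed to
#'   [read_annotations()].
#' @return list with `dataset` (an [rwrt_dataset()]) and `truth` (the
#'   generator output).
#' @export
synthetic_dataset <- function(cfg, dir = tempfile("rwrt-synth-"),
                              min_count = 10L, max_count = 200L) {
  truth <- generate_synthetic(cfg, dir)
  net <- read_ppi(truth$files[["ppi"]])
  dataset <- rwrt_dataset(
    net,
    annotations = read_annotations(truth$files[["annotations"]], net$index,
                                   format = "tsv", min_count = min_count,
                                   max_count = max_count),
    domains = read_domains(truth$files[["domains"]], net$index),
    catalog = suppressMessages(read_complexes(truth$files[["complexes"]],
                                              net$index)))
  list(dataset = dataset, truth = truth)
}

#' Edge-case fixtures
#'
#' A small suite of degenerate datasets used to probe boundary behaviour:
#' a single-edge network; a network containing an annotation-free protein
#' hanging off the annotated core by one edge; an empty domain file; a
#' one-module complex catalog; and a hand-weighted five-node, three-layer
#' multigraph (returned in memory as a [similarity_tensor()]) for
#' contraction oracles.
#'
#' @param dir directory for the emitted text files.
#' @return list with `dir`, `files` (named paths) and `multigraph`.
#' @export
degenerate_fixtures <- function(dir = tempfile("rwrt-fixtures-")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(single_edge = file.path(dir, "single_edge.tsv"),
             isolated = file.path(dir, "isolated.tsv"),
             isolated_annotations = file.path(dir, "isolated_annotations.tsv"),
             empty_domains = file.path(dir, "empty_domains.tsv"),
             one_module = file.path(dir, "one_module.txt"))
  writeLines("A\tB", files[["single_edge"]])
  writeLines(c("A\tB", "B\tC", "C\tA", "C\tD"), files[["isolated"]])
  writeLines(c("A\tGO:0900001", "B\tGO:0900001", "C\tGO:0900001"),
             files[["isolated_annotations"]])
  writeLines(character(0), files[["empty_domains"]])
  writeLines("A B C", files[["one_module"]])

  ids <- sprintf("N%d", 1:5)
  lay <- function(i, j, x) {
    sparseMatrix(i = c(i, j), j = c(j, i), x = rep(x, 2), dims = c(5, 5),
                 dimnames = list(ids, ids))
  }
  multigraph <- similarity_tensor(
    list(lay(c(1, 2, 1, 3), c(2, 3, 3, 4), c(0.6, 0.8, 0.5, 0.7)),
         lay(c(1, 4), c(2, 5), c(0.9, 0.4)),
         lay(c(2, 3, 4), c(3, 5, 5), c(0.3, 0.2, 0.9))),
    index = protein_index(ids))
  list(dir = dir, files = files, multigraph = multigraph)
}
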