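# Annotation of a target protein from its similarity row: assemble a pool of
# high-similarity annotated partners, drop low-cohesiveness pretenders, pool
# and rank the survivors' GO terms, and keep the top K, with K set to the
# number of functions of the most similar surviving partner.

#' Candidate partner pool for a target
#'
#' The `pool_size` annotated proteins with the highest similarity to the
#' target; ties broken by protein-index order, zero-score proteins never
#' included, the target itself excluded.
#'
#' @param i target protein index.
#' @param M functional similarity matrix (see [functional_similarity()]).
#' @param ann an `fn_annotation`.
#' @param pool_size pool size (default 20).
#' @return data frame with columns `partner` (index) and `score`, ordered by
#'   decreasing score; zero rows when no annotated protein has positive
#'   similarity.
#' @export
candidate_partners <- function(i, M, ann, pool_size = 20L) {
  stopifnot(pool_size >= 1)
  sc <- M[i, ]
  elig <- setdiff(annotated_proteins(ann), i)
  elig <- elig[sc[elig] > 0]
  if (!length(elig)) {
    return(data.frame(partner = integer(0), score = numeric(0)))
  }
  elig <- elig[order(-sc[elig], elig)]
  sel <- elig[seq_len(min(pool_size, length(elig)))]
  data.frame(partner = sel, score = unname(sc[sel]))
}

#' Cohesiveness coefficient of a module member
#'
#' `CC(j) = fs_in / (fs_in + fs_out)` where `fs_in` sums `j`'s similarity to
#' the other module members and `fs_out` its similarity to everything outside
#' the module (both from `j`'s own row of `M`, diagonal excluded).  Returns 0
#' when both sums are 0.
#'
#' @param j protein index of the member being assessed.
#' @param module integer vector of module member indices (including `j`).
#' @param M functional similarity matrix.
#' @return value in `[0, 1]`.
#' @export
cohesiveness <- function(j, module, M) {
  module <- unique(as.integer(module))
  fs_in <- sum(M[j, setdiff(module, j)])
  fs_out <- sum(M[j, ]) - sum(M[j, module])
  if (fs_in + fs_out == 0) return(0)
  fs_in / (fs_in + fs_out)
}

#' Remove low-cohesiveness pretenders from a partner pool
#'
#' The candidate module is the target plus all candidates; every candidate
#' whose cohesiveness coefficient is `<= cc_threshold` (computed against the
#' full initial module, single simultaneous pass) is removed.  If all
#' candidates would be removed, the single highest-similarity candidate is
#' retained so the prediction is never empty (a message is emitted).
#'
#' @param i target protein index.
#' @param candidates data frame from [candidate_partners()] (non-empty).
#' @param M functional similarity matrix.
#' @param cc_threshold removal boundary, inclusive (default 1/3).
#' @return the surviving rows of `candidates`, with a `cc` column appended.
#' @export
filter_pretenders <- function(i, candidates, M, cc_threshold = 1 / 3) {
  stopifnot(nrow(candidates) > 0)
  module <- c(i, candidates$partner)
  cc <- vapply(candidates$partner, cohesiveness, numeric(1),
               module = module, M = M)
  candidates$cc <- cc
  keep <- cc > cc_threshold
  if (!any(keep)) {
    message("all candidates fell at or below the cohesiveness threshold; ",
            "retaining the most similar one")
    return(candidates[1, , drop = FALSE])
  }
  candidates[keep, , drop = FALSE]
}

#' Rank candidate functions of the surviving partners
#'
#' The ranking score of a function is the summed target-partner similarity
#' over the surviving partners annotated with it:
#' `RS(f) = sum_{k: f in GO(fsp_k)} M[target, fsp_k]`.  Ties are broken by
#' GO identifier (lexicographic), so rankings are deterministic.
#'
#' @param i target protein index.
#' @param survivors data frame from [filter_pretenders()].
#' @param M functional similarity matrix.
#' @param ann an `fn_annotation`.
#' @return data frame `term`, `rs`, sorted by decreasing `rs`.
#' @export
rank_functions <- function(i, survivors, M, ann) {
  terms <- ann$terms_of[survivors$partner]
  if (!sum(lengths(terms))) {
    return(data.frame(term = character(0), rs = numeric(0)))
  }
  sc <- rep.int(M[i, survivors$partner], lengths(terms))
  rs <- vapply(split(sc, unlist(terms)), sum, numeric(1))
  out <- data.frame(term = names(rs), rs = unname(rs))
  out[order(-out$rs, out$term, method = "radix"), , drop = FALSE]
}

#' Choose the prediction depth K
#'
#' `K` is the number of known functions of the surviving partner with the
#' highest similarity to the target (ties broken by protein-index order,
#' which the candidate ordering already encodes).
#'
#' @param survivors data frame from [filter_pretenders()], ordered by
#'   decreasing similarity.
#' @param ann an `fn_annotation`.
#' @return integer `K >= 0`.
#' @export
choose_k <- function(survivors, ann) {
  if (!nrow(survivors)) return(0L)
  length(ann$terms_of[[survivors$partner[1]]])
}

#' Predict functions for a target protein
#'
#' Composes [candidate_partners()], [filter_pretenders()],
#' [rank_functions()] and [choose_k()]: the prediction is the top
#' `min(K, available)` ranked terms.  The prediction is empty only when no
#' annotated protein has positive similarity to the target.
#'
#' @param i target protein index.
#' @param M functional similarity matrix.
#' @param ann an `fn_annotation` (with the target masked, in cross-validation
#'   use).
#' @param cfg a [walk_config()] supplying `pool_size` and `cc_threshold`.
#' @return an object of class `rwrt_prediction`: `target`, `target_id`,
#'   `candidates`, `survivors`, `ranked` (all ranked terms with scores), `K`,
#'   and `predicted` (character vector of the top-`K` terms).
#' @export
predict_functions <- function(i, M, ann, cfg = walk_config()) {
  candidates <- candidate_partners(i, M, ann, cfg$pool_size)
  if (!nrow(candidates)) {
    message("no annotated protein with positive similarity to target ", i,
            "; empty prediction")
    survivors <- cbind(candidates, cc = numeric(0))
    ranked <- data.frame(term = character(0), rs = numeric(0))
    k <- 0L
  } else {
    survivors <- filter_pretenders(i, candidates, M, cfg$cc_threshold)
    ranked <- rank_functions(i, survivors, M, ann)
    k <- choose_k(survivors, ann)
  }
  structure(list(target = i,
                 target_id = if (!is.null(rownames(M))) rownames(M)[i] else
                   as.character(i),
                 candidates = candidates, survivors = survivors,
                 ranked = ranked, K = as.integer(k),
                 predicted = head(ranked$term, min(k, nrow(ranked)))),
            class = "rwrt_prediction")
}

#' @export
print.rwrt_prediction <- function(x, ...) {
  cat("prediction for", x$target_id, "--", nrow(x$survivors), "of",
      nrow(x$candidates), "partners kept, K =", x$K, "\n")
  if (length(x$predicted)) {
    top <- head(x$ranked, x$K)
    cat(paste(sprintf("  %-12s RS = %.4f", top$term, top$rs),
              collapse = "\n"), "\n")
  }
  invisible(x)
}
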