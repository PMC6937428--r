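#' Read a protein embedding matrix from TSV
#'
#' @param path TSV with a protein id column followed by numeric embedding
#'   columns; `#` lines ignored.
#' @return numeric matrix with protein ids as rownames.
#' @export
read_protein_embedding <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate protein ids in embedding")
  M <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- ids
  if (any(rowSums(M^2) == 0)) stop("zero-norm embedding vector")
  M
}

#' Write a protein embedding matrix to TSV
#' @param embedding numeric matrix with ids as rownames.
#' @param path output path.
#' @export
write_protein_embedding <- function(embedding, path) {
  df <- data.frame(protein = rownames(embedding), embedding,
                   check.names = FALSE)
  names(df) <- c("protein", paste0("v", seq_len(ncol(embedding))))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ids may repeat (multiset semantics); ids missing from the embedding are
# dropped, with the count recorded in attr "n_dropped"
resolve_set <- function(embedding, ids) {
  found <- ids[ids %in% rownames(embedding)]
  attr(found, "n_dropped") <- length(ids) - length(found)
  found
}

#' Median cosine similarity between two protein sets
#'
#' The median over all |A| x |B| pairwise cosine similarities between the
#' embedding vectors of the two sets (self-pairs included when the sets
#' overlap; the median of an even count is the midpoint of the two
#' central values). Ids not present in the embedding are dropped; if
#' either set is empty after the intersection the result is `NA` — the
#' "no gene set" marker.
#'
#' @param embedding numeric matrix, protein ids as rownames.
#' @param set_a,set_b character id vectors (duplicates allowed and kept).
#' @return scalar in [-1, 1], or `NA_real_`.
#' @export
median_cosine <- function(embedding, set_a, set_b) {
  a <- resolve_set(embedding, set_a)
  b <- resolve_set(embedding, set_b)
  if (!length(a) || !length(b)) return(NA_real_)
  V <- embedding / sqrt(rowSums(embedding^2))
  stats::median(tcrossprod(V[a, , drop = FALSE], V[b, , drop = FALSE]))
}

#' Permutation test of network proximity for one candidate pair
#'
#' Observed statistic: [median_cosine()] between the drug-target set and
#' the disease-gene set. Null: `n_perm` replicates each draw |A| and |B|
#' protein ids with replacement from all embedded proteins and recompute
#' the statistic. The p-value uses the add-one estimator
#' `(1 + #{replicate >= observed}) / (1 + n_perm)`, so it is strictly
#' positive and at most 1. Deterministic given `seed`.
#'
#' @param embedding numeric matrix, protein ids as rownames.
#' @param set_a,set_b character id vectors.
#' @param n_perm number of permutation replicates (default 10000).
#' @param seed integer seed.
#' @param drug,disease optional labels carried into the result.
#' @return one-row data.frame (class `proximity_result`): `drug`,
#'   `disease`, `observed`, `p_value`, `n_perm`, `n_dropped_a`,
#'   `n_dropped_b`, `significant` (`NA` until [bonferroni_flag()]),
#'   `seed`. For pairs lacking a usable gene set, `observed` and
#'   `p_value` are `NA`.
#' @export
proximity_test <- function(embedding, set_a, set_b, n_perm = 10000L,
                           seed = 1L, drug = NA_character_,
                           disease = NA_character_) {
  a <- resolve_set(embedding, set_a)
  b <- resolve_set(embedding, set_b)
  res <- data.frame(drug = drug, disease = disease,
                    observed = NA_real_, p_value = NA_real_,
                    n_perm = as.integer(n_perm),
                    n_dropped_a = attr(a, "n_dropped"),
                    n_dropped_b = attr(b, "n_dropped"),
                    significant = NA, seed = as.integer(seed),
                    stringsAsFactors = FALSE)
  class(res) <- c("proximity_result", "data.frame")
  if (!length(a) || !length(b)) return(res)

  V <- embedding / sqrt(rowSums(embedding^2))
  n <- nrow(V)
  small <- n <= 2048L
  if (small) G <- tcrossprod(V)  # full Gram is cheap at fixture scale
  med <- function(ia, ib) {
    if (small) stats::median(G[ia, ib])
    else stats::median(tcrossprod(V[ia, , drop = FALSE],
                                  V[ib, , drop = FALSE]))
  }
  obs <- med(match(a, rownames(V)), match(b, rownames(V)))

  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  ge <- 0L
  for (i in seq_len(n_perm)) {
    ia <- sample.int(n, length(a), replace = TRUE)
    ib <- sample.int(n, length(b), replace = TRUE)
    if (med(ia, ib) >= obs) ge <- ge + 1L
  }
  res$observed <- obs
  res$p_value <- (1 + ge) / (1 + n_perm)
  res
}

#' Bonferroni significance flags for a batch of proximity tests
#'
#' Marks a result significant when its p-value is below
#' `alpha / n_testable`, where `n_testable` counts only the pairs with a
#' computable statistic (pairs lacking gene sets are excluded from the
#' denominator and stay `NA`).
#'
#' @param results data.frame of stacked [proximity_test()] rows.
#' @param alpha family-wise error target (default 0.05).
#' @return `results` with the `significant` column filled in.
#' @export
bonferroni_flag <- function(results, alpha = 0.05) {
  testable <- !is.na(results$p_value)
  n_test <- sum(testable)
  results$significant <- NA
  if (n_test)
    results$significant[testable] <-
      results$p_value[testable] < alpha / n_test
  results
}

#' Read entity -> protein gene-set mappings
#'
#' @param path two-column TSV (entity id, protein id); `#` lines ignored.
#' @return named list of character vectors, one per entity id.
#' @export
read_gene_sets <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          colClasses = "character")
  if (ncol(df) < 2) stop("gene-set file needs two columns")
  split(df[[2]], df[[1]])
}
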