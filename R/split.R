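#' Stratified train/validation/test split of triples
#'
#' Triples whose unordered endpoint pair appears in the gold-standard
#' indication list (under any theme) form the "indication" stratum and are
#' split 60/20/20 by default; all remaining triples form the background
#' stratum, split 90/5/5. Each stratum is shuffled uniformly at random
#' under the seed, so the split is deterministic given the seed. Fold
#' sizes use floor allocation with the remainder going to training.
#'
#' @param kg a [knowledge_graph()].
#' @param gold a [gold_standard()] of (drug, disease) pairs; may be empty.
#' @param indication_fracs,background_fracs length-3 numeric vectors
#'   (train, validation, test) summing to 1.
#' @param seed integer seed.
#' @param by_pair if `TRUE`, all triples sharing one unordered endpoint
#'   pair go to the same fold (the pair, not the triple, is the sampling
#'   unit).
#' @return An object of class `data_split`: list with data.frames `train`,
#'   `validation`, `test` (same columns as `kg$triples`) and the `seed`.
#' @export
split_triples <- function(kg, gold = gold_standard(),
                          indication_fracs = c(0.6, 0.2, 0.2),
                          background_fracs = c(0.9, 0.05, 0.05),
                          seed = 1L, by_pair = FALSE) {
  stopifnot(length(indication_fracs) == 3, length(background_fracs) == 3)
  if (abs(sum(indication_fracs) - 1) > 1e-8 ||
      abs(sum(background_fracs) - 1) > 1e-8)
    stop("split fractions must each sum to 1")
  tr <- kg$triples
  gk <- pair_key(gold$drug, gold$disease)
  is_ind <- pair_key(tr$head, tr$tail) %in% gk

  split_one <- function(rows, fracs) {
    n <- nrow(rows)
    if (n == 0)
      return(list(rows, rows, rows))
    if (n < 3) stop("stratum with fewer than 3 triples (n = ", n, ")")
    if (by_pair) {
      keys <- pair_key(rows$head, rows$tail)
      uk <- sample(unique(keys))
      m <- length(uk)
      n_val <- floor(fracs[2] * m); n_test <- floor(fracs[3] * m)
      fold_of <- rep("train", m)
      if (n_val) fold_of[seq_len(n_val)] <- "validation"
      if (n_test) fold_of[n_val + seq_len(n_test)] <- "test"
      f <- stats::setNames(fold_of, uk)[keys]
      lapply(c("train", "validation", "test"),
             function(x) rows[f == x, , drop = FALSE])
    } else {
      idx <- sample(n)
      n_val <- floor(fracs[2] * n); n_test <- floor(fracs[3] * n)
      list(rows[idx[seq_len(n - n_val - n_test) + n_val + n_test], ,
                drop = FALSE],
           rows[idx[seq_len(n_val)], , drop = FALSE],
           rows[idx[n_val + seq_len(n_test)], , drop = FALSE])
    }
  }

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  si <- split_one(tr[is_ind, , drop = FALSE], indication_fracs)
  sb <- split_one(tr[!is_ind, , drop = FALSE], background_fracs)
  out <- list(
    train = rbind(si[[1]], sb[[1]]),
    validation = rbind(si[[2]], sb[[2]]),
    test = rbind(si[[3]], sb[[3]]),
    seed = seed)
  for (f in c("train", "validation", "test")) rownames(out[[f]]) <- NULL
  structure(out, class = "data_split")
}

#' @export
print.data_split <- function(x, ...) {
  cat("data_split: train", nrow(x$train), "/ validation",
      nrow(x$validation), "/ test", nrow(x$test),
      "triples (seed", paste0(x$seed, ")\n"))
  invisible(x)
}

# save/restore global RNG state so seeded helpers do not clobber callers
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_set <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}
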