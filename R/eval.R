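#' Score and rank all candidate treatment pairs
#'
#' Every drug x disease pair not in the exclusion list is scored with the
#' unclamped test-time score under the treatment theme `"T"` and returned
#' sorted by descending score; ties break lexicographically by
#' (drug, disease).
#'
#' @param model a [ukge_model()]; must embed theme `"T"` and all ids.
#' @param drugs,diseases character id vectors.
#' @param exclude a [gold_standard()] of pairs to omit (e.g. known
#'   indications), or `NULL`.
#' @return data.frame: `drug`, `disease`, `score`, `rank`.
#' @export
score_treatment_candidates <- function(model, drugs, diseases,
                                       exclude = NULL) {
  if (!"T" %in% rownames(model$relations))
    stop("treatment theme \"T\" absent from model")
  grid <- expand.grid(drug = drugs, disease = diseases,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  if (!is.null(exclude) && nrow(exclude)) {
    drop <- paste(grid$drug, grid$disease) %in%
      paste(exclude$drug, exclude$disease)
    grid <- grid[!drop, , drop = FALSE]
  }
  if (!nrow(grid)) {
    grid$score <- numeric(0); grid$rank <- integer(0)
    return(grid)
  }
  grid$score <- test_score(model, grid$drug, "T", grid$disease)
  grid <- grid[order(-grid$score, grid$drug, grid$disease), , drop = FALSE]
  grid$rank <- seq_len(nrow(grid))
  rownames(grid) <- NULL
  grid
}

#' Direct treatment-support baseline
#'
#' The no-embedding baseline: the support of the (drug, `"T"`, disease)
#' triple if present in the graph (either orientation), else 0.
#'
#' @param kg a [knowledge_graph()].
#' @param drug,disease entity ids (vectorised).
#' @return numeric vector of supports.
#' @export
baseline_treatment_support <- function(kg, drug, disease) {
  tr <- kg$triples
  tr <- tr[tr$theme == "T", , drop = FALSE]
  key <- pair_key(tr$head, tr$tail)
  # several "T" rows for one pair cannot occur within a category, but be
  # safe and take the max
  sup <- tapply(tr$support, key, max)
  out <- unname(sup[pair_key(drug, disease)])
  out[is.na(out)] <- 0
  out
}

#' ROC / PR evaluation against a gold standard
#'
#' Computes ROC and precision-recall curves over the sorted unique score
#' thresholds. AUROC is the Mann-Whitney concordance probability (ties
#' counted half), which equals the trapezoidal area under the ROC curve.
#' AUPR uses step-wise interpolation (sum of precision times recall
#' increment), avoiding the optimism of linear PR interpolation.
#'
#' @param scores_pos,scores_neg numeric score vectors for gold-standard
#'   positives and sampled negatives; both nonempty.
#' @return object of class `eval_result`: list with `auroc`, `aupr`,
#'   `roc_points` (fpr, tpr), `pr_points` (recall, precision), `n_pos`,
#'   `n_neg`.
#' @export
evaluate_gold_standard <- function(scores_pos, scores_neg) {
  np <- length(scores_pos); nn <- length(scores_neg)
  if (!np || !nn) stop("both score lists must be nonempty")
  r <- rank(c(scores_pos, scores_neg))  # midranks: half-credit ties
  auroc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)

  sc <- c(scores_pos, scores_neg)
  lab <- rep(c(1L, 0L), c(np, nn))
  thr <- sort(unique(sc), decreasing = TRUE)
  # predictions at threshold t: score >= t; cumulative counts over the
  # descending unique thresholds
  o <- order(-sc)
  sl <- lab[o]
  grp <- match(sc[o], thr)               # ties collapse to one threshold
  tp <- cumsum(sl); fp <- cumsum(1L - sl)
  last <- cumsum(tabulate(grp, nbins = length(thr)))  # last index per thr
  tp <- tp[last]; fp <- fp[last]
  tpr <- tp / np; fpr <- fp / nn
  prec <- tp / (tp + fp)
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  pr <- data.frame(recall = c(0, tpr), precision = c(prec[1], prec))
  aupr <- sum(diff(pr$recall) * pr$precision[-1])
  structure(list(auroc = auroc, aupr = aupr, roc_points = roc,
                 pr_points = pr, n_pos = np, n_neg = nn),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("eval_result: AUROC %.4f | AUPR %.4f (%d positives, %d negatives)\n",
              x$auroc, x$aupr, x$n_pos, x$n_neg))
  invisible(x)
}

#' Sample negative drug-disease pairs
#'
#' Draws `n` distinct pairs not present in the gold standard, with the
#' drug and the disease each drawn uniformly from the universes of drugs
#' and diseases appearing in the gold standard.
#'
#' @param gold a nonempty [gold_standard()].
#' @param n number of pairs.
#' @param seed integer seed.
#' @return data.frame: `drug`, `disease`.
#' @export
sample_negative_pairs <- function(gold, n, seed = 1L) {
  if (!nrow(gold)) stop("gold standard is empty")
  drugs <- sort(unique(gold$drug)); diseases <- sort(unique(gold$disease))
  n_valid <- length(drugs) * length(diseases) - nrow(gold)
  if (n > n_valid)
    stop("only ", n_valid, " valid negative pairs exist, need ", n)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  bad <- paste(gold$drug, gold$disease)
  out_d <- character(0); out_z <- character(0)
  while (length(out_d) < n) {
    k <- n - length(out_d)
    cd <- drugs[sample.int(length(drugs), k, replace = TRUE)]
    cz <- diseases[sample.int(length(diseases), k, replace = TRUE)]
    key <- paste(cd, cz)
    ok <- !key %in% bad & !key %in% paste(out_d, out_z) & !duplicated(key)
    out_d <- c(out_d, cd[ok]); out_z <- c(out_z, cz[ok])
  }
  data.frame(drug = out_d, disease = out_z, stringsAsFactors = FALSE)
}

cosine_matrix <- function(M) {
  nrm <- sqrt(rowSums(M^2))
  if (any(nrm == 0))
    stop("zero-norm vector for: ",
         paste(rownames(M)[nrm == 0], collapse = ", "))
  V <- M / nrm
  S <- tcrossprod(V)
  diag(S) <- 1
  pmin(pmax(S, -1), 1)
}

#' Pairwise cosine similarity of theme embeddings, with clustering
#'
#' Cosine similarity between all relation vectors, then agglomerative
#' hierarchical clustering on the distance `1 - cosine`; the returned
#' order is the dendrogram leaf order, useful for heatmap display.
#'
#' @param model a [ukge_model()] with at least 2 relations.
#' @param linkage linkage method passed to [stats::hclust()] (default
#'   `"average"`).
#' @return object of class `theme_similarity`: list with `matrix`
#'   (symmetric, unit diagonal), `order` (theme codes in leaf order),
#'   `linkage`, and the `hclust` object.
#' @export
theme_similarity <- function(model, linkage = "average") {
  if (nrow(model$relations) < 2) stop("need at least 2 themes")
  S <- cosine_matrix(model$relations)
  hc <- stats::hclust(stats::as.dist(1 - S), method = linkage)
  structure(list(matrix = S, order = rownames(S)[hc$order],
                 linkage = linkage, hclust = hc),
            class = "theme_similarity")
}

precision_at_recall_one <- function(scores, labels, recall_levels) {
  o <- order(-scores)
  s <- scores[o]; y <- labels[o]
  npos <- sum(y)
  grp_last <- which(!duplicated(s, fromLast = TRUE))  # threshold blocks
  tp <- cumsum(y)[grp_last]
  fp <- cumsum(!y)[grp_last]
  rec <- tp / npos
  prec <- tp / (tp + fp)
  vapply(recall_levels, function(lvl) {
    hit <- which(rec >= lvl)
    if (!length(hit)) NA_real_ else prec[hit[1]]
  }, numeric(1))
}

#' Precision at fixed recall levels, per theme
#'
#' Scores every (drug, disease) pair under each theme's relation vector
#' (unclamped test-time score by default) and reports, for each theme and
#' each recall level, the precision at the smallest prediction set
#' achieving that recall against the treatment labels. Unreachable recall
#' levels yield `NA`.
#'
#' @param model a [ukge_model()].
#' @param pairs data.frame with columns `drug`, `disease`.
#' @param labels logical vector (`TRUE` = known treatment), at least one
#'   `TRUE`.
#' @param recall_levels numeric levels in (0, 1].
#' @param themes theme codes to evaluate (default: all relations in the
#'   model).
#' @param bounded score with the training-mode bounded confidence instead
#'   of the unclamped score.
#' @return numeric matrix, themes x recall levels.
#' @export
per_theme_precision_at_recall <- function(model, pairs, labels,
                                          recall_levels = c(0.25, 0.5,
                                                            0.75, 1),
                                          themes = rownames(model$relations),
                                          bounded = FALSE) {
  labels <- as.logical(labels)
  stopifnot(nrow(pairs) == length(labels))
  if (!any(labels)) stop("labels contain no positive")
  out <- matrix(NA_real_, length(themes), length(recall_levels),
                dimnames = list(themes, paste0("recall_", recall_levels)))
  for (th in themes) {
    sc <- if (bounded) train_confidence(model, pairs$drug, th,
                                        pairs$disease)
          else test_score(model, pairs$drug, th, pairs$disease)
    out[th, ] <- precision_at_recall_one(sc, labels, recall_levels)
  }
  out
}
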