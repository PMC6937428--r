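#' Construct an uncertain knowledge-graph embedding model
#'
#' Holds one d-dimensional vector per entity and per theme, plus the two
#' global scalars of the bounded rectifier. The plausibility of a triple
#' (h, r, t) is the bilinear score `sum(r * h * t)`; the predicted
#' confidence maps it into [0, 1] via `min(max(w * g + b, 0), 1)`.
#'
#' @param entity_vectors numeric matrix, one row per entity id (rownames).
#' @param relation_vectors numeric matrix, one row per theme code
#'   (rownames), same number of columns.
#' @param w,b global rectifier scale and offset.
#' @return object of class `ukge_model`.
#' @export
ukge_model <- function(entity_vectors, relation_vectors, w = 1, b = 0) {
  stopifnot(is.matrix(entity_vectors), is.matrix(relation_vectors),
            ncol(entity_vectors) == ncol(relation_vectors),
            !is.null(rownames(entity_vectors)),
            !is.null(rownames(relation_vectors)),
            is.finite(w), is.finite(b))
  structure(list(entities = entity_vectors, relations = relation_vectors,
                 w = w, b = b, d = ncol(entity_vectors)),
            class = "ukge_model")
}

#' @export
print.ukge_model <- function(x, ...) {
  cat("ukge_model: d =", x$d, "|", nrow(x$entities), "entities,",
      nrow(x$relations), "relations | w =", signif(x$w, 4),
      "b =", signif(x$b, 4), "\n")
  invisible(x)
}

check_embedded <- function(model, head, theme, tail) {
  miss <- setdiff(unique(c(head, tail)), rownames(model$entities))
  if (length(miss))
    stop("entity not embedded in model: ",
         paste(utils::head(miss, 5), collapse = ", "))
  missr <- setdiff(unique(theme), rownames(model$relations))
  if (length(missr))
    stop("theme not embedded in model: ", paste(missr, collapse = ", "))
  invisible(TRUE)
}

#' Bilinear plausibility score of triples
#'
#' `g(h, r, t) = sum_k r_k h_k t_k` — symmetric under head/tail exchange.
#' Vectorised over triples.
#'
#' @param model a [ukge_model()].
#' @param head,theme,tail character vectors of equal length (recycled).
#' @return numeric vector of plausibility scores.
#' @export
plausibility <- function(model, head, theme, tail) {
  check_embedded(model, head, theme, tail)
  n <- max(length(head), length(theme), length(tail))
  head <- rep_len(head, n); theme <- rep_len(theme, n)
  tail <- rep_len(tail, n)
  unname(rowSums(model$relations[theme, , drop = FALSE] *
                 model$entities[head, , drop = FALSE] *
                 model$entities[tail, , drop = FALSE]))
}

#' Bounded rectifier
#'
#' `phi(x) = min(max(w x + b, 0), 1)` — maps plausibility to a [0, 1]
#' confidence during training; monotone nondecreasing in `x` when
#' `w >= 0`.
#'
#' @param model a [ukge_model()] (supplies `w`, `b`).
#' @param x numeric vector.
#' @export
bounded_confidence <- function(model, x) {
  pmin(pmax(model$w * x + model$b, 0), 1)
}

#' Training-mode predicted confidence of triples
#'
#' The composition `phi(g(l))`; always in [0, 1].
#'
#' @inheritParams plausibility
#' @export
train_confidence <- function(model, head, theme, tail) {
  bounded_confidence(model, plausibility(model, head, theme, tail))
}

#' Test-time ranking score of triples
#'
#' `w * g(l) + b` with the min-max bounding removed, so distinct
#' plausibilities never tie; agrees with [train_confidence()] whenever the
#' unclamped value lies in [0, 1].
#'
#' @inheritParams plausibility
#' @export
test_score <- function(model, head, theme, tail) {
  model$w * plausibility(model, head, theme, tail) + model$b
}

#' Sample negative triples by tail corruption
#'
#' For each input triple the head and theme are kept, the tail is replaced
#' by an entity drawn uniformly from the candidate pool excluding the
#' original tail, and the support is set to 0.
#'
#' @param triples data.frame with columns `head`, `theme`, `tail`.
#' @param entities character vector of candidate entity ids (usually all
#'   graph entities).
#' @param type_constrained if `TRUE`, draw replacements only among
#'   entities of the original tail's type; requires `entity_types` (named
#'   character vector id -> type).
#' @param entity_types optional named type vector, needed when
#'   `type_constrained = TRUE`.
#' @return data.frame of corrupted triples with `support = 0`.
#' @export
sample_negative <- function(triples, entities, type_constrained = FALSE,
                            entity_types = NULL) {
  if (length(entities) < 2) stop("need at least 2 entities to corrupt")
  n <- nrow(triples)
  if (type_constrained) {
    if (is.null(entity_types)) stop("entity_types required")
    new_tail <- vapply(triples$tail, function(tl) {
      pool <- setdiff(names(entity_types)[entity_types ==
                                            entity_types[[tl]]], tl)
      if (!length(pool)) stop("no alternative tail of type ",
                              entity_types[[tl]])
      pool[sample.int(length(pool), 1)]
    }, character(1), USE.NAMES = FALSE)
  } else {
    # rejection-free: draw from n-1 slots, skip over the original tail
    pos <- match(triples$tail, entities)
    draw <- sample.int(length(entities) - 1L, n, replace = TRUE)
    draw <- draw + (draw >= pos)
    new_tail <- entities[draw]
  }
  data.frame(head = triples$head, theme = triples$theme, tail = new_tail,
             support = 0, stringsAsFactors = FALSE)
}

#' Squared-error objective over positive and negative triples
#'
#' Sum over positives of `(f(l) - s_l)^2` plus sum over negatives of
#' `f(l)^2`, with `f` the bounded training-mode confidence. Zero exactly
#' when every positive is predicted at its support and every negative
#' at 0.
#'
#' @param model a [ukge_model()].
#' @param positives data.frame with `head`, `theme`, `tail`, `support`
#'   (may be empty).
#' @param negatives data.frame with `head`, `theme`, `tail` (may be
#'   empty); target 0.
#' @return nonnegative scalar.
#' @export
ukge_loss <- function(model, positives, negatives = NULL) {
  total <- 0
  if (!is.null(positives) && nrow(positives)) {
    f <- train_confidence(model, positives$head, positives$theme,
                          positives$tail)
    total <- total + sum((f - positives$support)^2)
  }
  if (!is.null(negatives) && nrow(negatives)) {
    f <- train_confidence(model, negatives$head, negatives$theme,
                          negatives$tail)
    total <- total + sum(f^2)
  }
  total
}

# analytic gradient of ukge_loss w.r.t. all parameters, for one batch.
# Returns list(entities, relations, w, b) of the same shapes as the model.
# The clamp's exact subgradient is 0 outside the active region; with
# leaky = TRUE, clamped examples whose target lies on the inner side keep
# a full-slope gradient so they can re-enter the active region (the
# optimizer's escape from the dead-rectifier trap; the objective itself
# is unchanged).
ukge_gradient <- function(model, positives, negatives = NULL,
                          leaky = FALSE) {
  batch <- positives
  target <- positives$support
  if (!is.null(negatives) && nrow(negatives)) {
    batch <- rbind(positives[c("head", "theme", "tail")],
                   negatives[c("head", "theme", "tail")])
    target <- c(target, rep(0, nrow(negatives)))
  }
  gE <- model$entities * 0
  gR <- model$relations * 0
  if (!nrow(batch))
    return(list(entities = gE, relations = gR, w = 0, b = 0))
  H <- model$entities[batch$head, , drop = FALSE]
  Tl <- model$entities[batch$tail, , drop = FALSE]
  Rm <- model$relations[batch$theme, , drop = FALSE]
  g <- rowSums(Rm * H * Tl)
  pre <- model$w * g + model$b
  f <- pmin(pmax(pre, 0), 1)
  resid <- f - target
  active <- as.numeric(pre > 0 & pre < 1)
  if (leaky)
    active <- as.numeric(active > 0 |
                           (pre <= 0 & resid < 0) |
                           (pre >= 1 & resid > 0))
  coef <- 2 * resid * active          # dL/d(pre)
  cw <- coef * model$w                # dL/dg
  addE <- rowsum(rbind(cw * (Rm * Tl), cw * (Rm * H)),
                 c(batch$head, batch$tail))
  gE[rownames(addE), ] <- gE[rownames(addE), , drop = FALSE] + addE
  addR <- rowsum(cw * (H * Tl), batch$theme)
  gR[rownames(addR), ] <- gR[rownames(addR), , drop = FALSE] + addR
  list(entities = gE, relations = gR,
       w = sum(coef * g), b = sum(coef))
}
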