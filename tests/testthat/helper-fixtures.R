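# Shared fixtures: small random graphs and models built in code.

# random typed graph with multi-edges; themes drawn compatibly with the
# endpoint types
random_kg <- function(n_drugs = 4, n_diseases = 4, n_genes = 6,
                      n_triples = 30, seed = 1) {
  set.seed(seed)
  ids <- c(sprintf("d%02d", seq_len(n_drugs)),
           sprintf("z%02d", seq_len(n_diseases)),
           sprintf("g%02d", seq_len(n_genes)))
  types <- stats::setNames(rep(c("drug", "disease", "gene"),
                               c(n_drugs, n_diseases, n_genes)), ids)
  vocab <- gnbr_themes()
  rows <- list()
  while (length(rows) < n_triples) {
    hv <- sample(ids, 1); tv <- sample(setdiff(ids, hv), 1)
    cat_of <- kgrepurpose:::type_pair_category(types[[hv]], types[[tv]])
    if (is.na(cat_of)) next
    th <- sample(vocab$code[vocab$category == cat_of], 1)
    rows[[length(rows) + 1]] <- data.frame(
      head = hv, theme = th, tail = tv, support = round(runif(1), 6))
  }
  knowledge_graph(types, do.call(rbind, rows))
}

# small random embedding model over given ids/themes
random_model <- function(entities = sprintf("e%02d", 1:8),
                         themes = c("T", "U", "Sa"), d = 8, seed = 1,
                         w = NULL, b = NULL) {
  set.seed(seed)
  E <- matrix(rnorm(length(entities) * d, sd = 0.5), ncol = d,
              dimnames = list(entities, NULL))
  R <- matrix(rnorm(length(themes) * d, sd = 0.5), ncol = d,
              dimnames = list(themes, NULL))
  ukge_model(E, R,
             w = if (is.null(w)) runif(1, 0.5, 1.5) else w,
             b = if (is.null(b)) runif(1, -0.3, 0.3) else b)
}

# independent BFS component labelling (oracle for the igraph-backed LCC)
bfs_components <- function(ids, edge_head, edge_tail) {
  comp <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  k <- 0L
  for (s in ids) {
    if (!is.na(comp[[s]])) next
    k <- k + 1L
    queue <- s
    comp[[s]] <- k
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- c(edge_tail[edge_head == v], edge_head[edge_tail == v])
      nb <- nb[is.na(comp[nb])]
      comp[nb] <- k
      queue <- c(queue, nb)
    }
  }
  comp
}

# O(n^2) concordance AUROC oracle (half credit for ties)
auroc_pairwise <- function(pos, neg) {
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

# central finite-difference gradient of ukge_loss over all parameters
numeric_gradient <- function(model, positives, negatives, eps = 1e-6) {
  loss_at <- function(m) ukge_loss(m, positives, negatives)
  gE <- model$entities * 0
  for (i in seq_along(gE)) {
    mp <- model; mp$entities[i] <- mp$entities[i] + eps
    mm <- model; mm$entities[i] <- mm$entities[i] - eps
    gE[i] <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
  }
  gR <- model$relations * 0
  for (i in seq_along(gR)) {
    mp <- model; mp$relations[i] <- mp$relations[i] + eps
    mm <- model; mm$relations[i] <- mm$relations[i] - eps
    gR[i] <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
  }
  mp <- model; mp$w <- mp$w + eps; mm <- model; mm$w <- mm$w - eps
  gw <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
  mp <- model; mp$b <- mp$b + eps; mm <- model; mm$b <- mm$b - eps
  gb <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
  list(entities = gE, relations = gR, w = gw, b = gb)
}

# random batch of compatible triples drawn from a model's vocabulary
random_batch <- function(model, n, seed = 1, with_support = TRUE) {
  set.seed(seed)
  ids <- rownames(model$entities)
  h <- sample(ids, n, replace = TRUE)
  t <- vapply(h, function(x) sample(setdiff(ids, x), 1), character(1),
              USE.NAMES = FALSE)
  out <- data.frame(head = h,
                    theme = sample(rownames(model$relations), n,
                                   replace = TRUE),
                    tail = t, stringsAsFactors = FALSE)
  if (with_support) out$support <- runif(n)
  out
}

# the worked drug-disease explanation graph: a drug that treats one
# disease which shares a causal gene mutation with a second disease
acz_als_kg <- function() {
  knowledge_graph(
    c(acetazolamide = "drug", glaucoma = "disease", OPTN = "gene",
      ALS = "disease"),
    data.frame(
      head = c("acetazolamide", "glaucoma", "OPTN"),
      theme = c("T", "U", "U"),
      tail = c("glaucoma", "OPTN", "ALS"),
      support = c(0.937, 0.904, 0.906)))
}
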