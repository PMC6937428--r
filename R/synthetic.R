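#' Configuration for the synthetic knowledge-graph generator
#'
#' Defaults describe a desk-scale graph: 20 drugs, 20 diseases, 50 genes,
#' an 8-dimensional planted latent structure, four themes per category,
#' 20% edge density and support noise with standard deviation 0.05.
#'
#' @param n_drugs,n_diseases,n_genes entity counts.
#' @param latent_dim dimension of the planted latent vectors (>= 2).
#' @param n_themes_per_category number of themes drawn from the default
#'   vocabulary for each of the four categories (scalar or length 4, in
#'   the order Dr-Dz, Dr-G, Dz-G, G-G). The treatment theme `"T"` is
#'   always included.
#' @param edge_density probability in (0, 1] that any candidate
#'   (pair, theme) combination is realised as a triple.
#' @param noise_sd standard deviation of the Gaussian noise added to
#'   noise-free supports before clamping to [0, 1].
#' @param n_planted_indications number of true treatment pairs planted.
#' @param latent_sparsity probability that a latent coordinate is active;
#'   sparse nonnegative latents make the typical triple weakly supported
#'   and a small aligned minority strongly supported, the support profile
#'   of literature-mined graphs.
#' @param seed integer seed.
#' @export
synthetic_config <- function(n_drugs = 20, n_diseases = 20, n_genes = 50,
                             latent_dim = 8,
                             n_themes_per_category = c(4, 4, 4, 4),
                             edge_density = 0.4, noise_sd = 0.05,
                             n_planted_indications = 20,
                             latent_sparsity = 0.3, seed = 1L) {
  if (length(n_themes_per_category) == 1)
    n_themes_per_category <- rep(n_themes_per_category, 4)
  cfg <- list(n_drugs = n_drugs, n_diseases = n_diseases, n_genes = n_genes,
              latent_dim = latent_dim,
              n_themes_per_category = n_themes_per_category,
              edge_density = edge_density, noise_sd = noise_sd,
              n_planted_indications = n_planted_indications,
              latent_sparsity = latent_sparsity,
              seed = as.integer(seed))
  stopifnot(n_drugs > 0, n_diseases > 0, n_genes > 0, latent_dim >= 2,
            edge_density > 0, edge_density <= 1, noise_sd >= 0,
            n_planted_indications >= 0,
            latent_sparsity > 0, latent_sparsity <= 1,
            length(n_themes_per_category) == 4,
            all(n_themes_per_category >= 1))
  structure(cfg, class = "synthetic_config")
}

# all unordered (a, b) id pairs across two id vectors (a != b; for the
# within-set case only i < j pairs)
cross_pairs <- function(a, b) {
  if (identical(a, b)) {
    idx <- which(upper.tri(matrix(0, length(a), length(a))), arr.ind = TRUE)
    data.frame(head = a[idx[, 1]], tail = a[idx[, 2]])
  } else {
    g <- expand.grid(head = a, tail = b, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
    g[c("head", "tail")]
  }
}

#' Generate a synthetic support-scored knowledge graph
#'
#' Plants a bilinear ground truth: every entity and theme gets a sparse
#' nonnegative latent vector (half-normal magnitudes, each coordinate
#' active with probability `latent_sparsity`), the noise-free support of
#' a candidate triple (h, r, t) is
#' `clamp(w_true * sum(r * h * t) + b_true, 0, 1)`, and observed supports
#' add Gaussian noise before clamping. Candidate (pair, theme)
#' combinations are sampled independently at `edge_density` within each
#' category. The `n_planted_indications` drug-disease pairs with the
#' highest noise-free treatment ("T") score are recorded as the planted
#' true indications and their (drug, "T", disease) triples are forced
#' into the edge set.
#'
#' Sparse nonnegative latents give the support profile of literature
#' mining: the typical triple (and hence any randomly corrupted triple)
#' is weakly supported while a small aligned minority is strongly
#' supported — consistent with the training assumption that corrupted
#' negatives have support 0. The affine scale (`w_true > 0`, `b_true`)
#' maps a zero latent match to 0.05 and the weakest planted pair to 0.92,
#' so planted treatment supports are at least 0.9 by construction; the
#' extreme upper tail may saturate at 1, as literature supports do.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `kg` (a [knowledge_graph()]) and `truth`
#'   (list: `entity_vectors`, `relation_vectors`, `w_true`, `b_true`,
#'   `planted_pairs` as a [gold_standard()]).
#' @export
generate_kg <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(config$seed)

  drugs <- sprintf("drug%03d", seq_len(config$n_drugs))
  diseases <- sprintf("disease%03d", seq_len(config$n_diseases))
  genes <- sprintf("gene%03d", seq_len(config$n_genes))
  ent <- stats::setNames(
    rep(c("drug", "disease", "gene"),
        c(config$n_drugs, config$n_diseases, config$n_genes)),
    c(drugs, diseases, genes))

  vocab <- gnbr_themes()
  cats <- theme_categories()
  themes <- do.call(rbind, lapply(seq_along(cats), function(i)
    utils::head(vocab[vocab$category == cats[i], ],
                config$n_themes_per_category[i])))
  rownames(themes) <- NULL
  codes <- unique(themes$code)

  d <- config$latent_dim
  p <- config$latent_sparsity
  # every vector keeps at least two active coordinates so no entity or
  # theme is latently inert (which would make planting degenerate)
  sparse_nonneg <- function(n, ids) {
    m <- abs(matrix(stats::rnorm(n * d), ncol = d,
                    dimnames = list(ids, NULL)))
    mask <- matrix(stats::rbinom(n * d, 1, p), ncol = d)
    thin <- which(rowSums(mask) < 2)
    for (i in thin)
      mask[i, sample.int(d, 2)] <- 1
    m * mask
  }
  E <- sparse_nonneg(length(ent), names(ent))
  R <- sparse_nonneg(length(codes), codes)

  pair_sets <- list(
    "Dr-Dz" = cross_pairs(drugs, diseases),
    "Dr-G" = cross_pairs(drugs, genes),
    "Dz-G" = cross_pairs(diseases, genes),
    "G-G" = cross_pairs(genes, genes))

  # candidate (pair, theme) combinations per category
  cand <- do.call(rbind, lapply(cats, function(cc) {
    th <- themes$code[themes$category == cc]
    p <- pair_sets[[cc]]
    data.frame(head = rep(p$head, length(th)),
               theme = rep(th, each = nrow(p)),
               tail = rep(p$tail, length(th)))
  }))
  raw <- unname(rowSums(R[cand$theme, , drop = FALSE] *
                        E[cand$head, , drop = FALSE] *
                        E[cand$tail, , drop = FALSE]))

  # noise-free "T" scores over all drug-disease pairs set the scale:
  # the n-th best planted pair must land at >= 0.9 before clamping, and a
  # zero latent match (the typical triple) at 0.05
  dd <- pair_sets[["Dr-Dz"]]
  raw_t <- unname(rowSums(R[rep("T", nrow(dd)), , drop = FALSE] *
                          E[dd$head, , drop = FALSE] *
                          E[dd$tail, , drop = FALSE]))
  n_plant <- min(config$n_planted_indications, nrow(dd))
  anchor_hi <- if (n_plant > 0) sort(raw_t, decreasing = TRUE)[n_plant]
               else stats::quantile(raw, 0.99)
  if (anchor_hi <= 0)
    stop("degenerate latent structure: planted scores are zero")
  b_true <- 0.05
  w_true <- (0.92 - b_true) / anchor_hi

  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  keep <- stats::runif(nrow(cand)) < config$edge_density
  tr <- cand[keep, , drop = FALSE]

  planted <- gold_standard()
  if (n_plant > 0) {
    top <- order(raw_t, decreasing = TRUE)[seq_len(n_plant)]
    planted <- gold_standard(dd$head[top], dd$tail[top])
    forced <- data.frame(head = dd$head[top], theme = "T",
                         tail = dd$tail[top])
    have <- paste(tr$head, tr$theme, tr$tail)
    forced <- forced[!paste(forced$head, forced$theme, forced$tail) %in%
                       have, , drop = FALSE]
    tr <- rbind(tr, forced)
  }
  score <- w_true * unname(rowSums(R[tr$theme, , drop = FALSE] *
                                   E[tr$head, , drop = FALSE] *
                                   E[tr$tail, , drop = FALSE])) + b_true
  tr$support <- clamp01(score + stats::rnorm(nrow(tr), 0, config$noise_sd))
  rownames(tr) <- NULL

  if (!any(type_pair_category(ent[tr$head], ent[tr$tail]) == "Dr-Dz"))
    stop("edge density too low: no drug-disease edges generated")
  if (n_plant > 0) {
    plant_free <- clamp01(w_true * sort(raw_t, decreasing = TRUE)[n_plant] +
                            b_true)
    if (plant_free < 0.9)
      warning("planted pairs have noise-free treatment support below 0.9")
  }

  kg <- knowledge_graph(ent, tr, themes)
  list(kg = kg,
       truth = list(entity_vectors = E, relation_vectors = R,
                    w_true = w_true, b_true = b_true,
                    planted_pairs = planted))
}

#' Write the generator's ground truth as sidecar TSV files
#'
#' @param truth the `truth` element of [generate_kg()]'s return value.
#' @param prefix path prefix; writes `<prefix>_entity_vectors.tsv`,
#'   `<prefix>_relation_vectors.tsv`, `<prefix>_planted_pairs.tsv` and
#'   `<prefix>_scalars.tsv`.
#' @export
write_truth <- function(truth, prefix) {
  wv <- function(m, path) {
    df <- data.frame(id = rownames(m), m, check.names = FALSE)
    names(df) <- c("id", paste0("v", seq_len(ncol(m))))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wv(truth$entity_vectors, paste0(prefix, "_entity_vectors.tsv"))
  wv(truth$relation_vectors, paste0(prefix, "_relation_vectors.tsv"))
  write_gold_standard(truth$planted_pairs,
                      paste0(prefix, "_planted_pairs.tsv"))
  utils::write.table(
    data.frame(key = c("w_true", "b_true"),
               value = c(truth$w_true, truth$b_true)),
    paste0(prefix, "_scalars.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(prefix)
}

#' Generate a fixture for the network-proximity permutation test
#'
#' Draws a random protein embedding and two gene sets. With `effect = 0`
#' the sets are drawn with replacement from all proteins — exactly the
#' resampling scheme of the permutation null, so the resulting p-value is
#' uniform by exchangeability. With `effect > 0` the member proteins of
#' both sets are relocated near a common latent direction (`effect` times
#' a unit vector plus standard Gaussian noise), so their median cosine
#' similarity exceeds the null.
#'
#' @param n_proteins,dim embedding shape (`dim >= 2`).
#' @param effect nonnegative shift magnitude.
#' @param set_sizes integer vector (|A|, |B|), each <= `n_proteins`.
#' @param seed integer seed.
#' @return list: `embedding` (numeric matrix, protein ids as rownames),
#'   `set_a`, `set_b` (character id vectors; may contain duplicates).
#' @export
generate_proximity_fixture <- function(n_proteins = 200, dim = 16,
                                       effect = 0, set_sizes = c(10, 10),
                                       seed = 1L) {
  if (dim < 2) stop("dim must be >= 2")
  stopifnot(all(set_sizes >= 1), all(set_sizes <= n_proteins), effect >= 0)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  ids <- sprintf("prot%04d", seq_len(n_proteins))
  V <- matrix(stats::rnorm(n_proteins * dim), n_proteins, dim,
              dimnames = list(ids, NULL))
  if (effect > 0) {
    u <- stats::rnorm(dim); u <- u / sqrt(sum(u^2))
    members <- sample(n_proteins, sum(set_sizes))
    V[members, ] <- matrix(rep(effect * u, each = length(members)),
                           nrow = length(members)) +
      matrix(stats::rnorm(length(members) * dim), ncol = dim)
    set_a <- ids[members[seq_len(set_sizes[1])]]
    set_b <- ids[members[set_sizes[1] + seq_len(set_sizes[2])]]
  } else {
    set_a <- sample(ids, set_sizes[1], replace = TRUE)
    set_b <- sample(ids, set_sizes[2], replace = TRUE)
  }
  list(embedding = V, set_a = set_a, set_b = set_b)
}
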