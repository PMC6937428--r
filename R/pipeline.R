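#' Read a flat key=value run configuration file
#'
#' One `key = value` pair per line; `#` comments and blank lines ignored.
#' Values that parse as numbers become numeric; `true`/`false` become
#' logical.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  raw <- readLines(path)
  raw <- raw[!grepl("^\\s*(#|$)", raw)]
  kv <- regmatches(raw, regexec("^\\s*([^=\\s]+)\\s*=\\s*(.*?)\\s*$", raw,
                                perl = TRUE))
  bad <- lengths(kv) != 3
  if (any(bad)) stop("cannot parse config line: ", raw[bad][1])
  vals <- lapply(kv, function(m) {
    v <- m[3]
    if (tolower(v) %in% c("true", "false")) return(as.logical(v))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(vals, vapply(kv, `[`, character(1), 2))
}

config_hash <- function(config) {
  # hash the scientific settings, not where the artifacts land
  config <- config[setdiff(names(config), "out_dir")]
  keys <- sort(names(config))
  dump <- paste(keys, vapply(config[keys], function(v)
    paste(format(v, digits = 15), collapse = ","), character(1)),
    sep = "=", collapse = "\n")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(dump, tf)
  unname(tools::md5sum(tf))
}

provenance_header <- function(command, config) {
  c(paste0("# kgrepurpose ",
           as.character(utils::packageVersion("kgrepurpose"))),
    paste0("# command: ", command),
    paste0("# seed: ", cfg_get(config, "seed", 1L)),
    paste0("# config-md5: ", config_hash(config)))
}

cfg_get <- function(config, key, default = NULL) {
  if (!is.null(config[[key]])) config[[key]] else default
}

write_artifact <- function(df, path, header, tracker) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tracker$files <- c(tracker$files, path)
  invisible(path)
}

#' Run one pipeline stage
#'
#' Orchestrates the package end to end from a flat configuration. Every
#' artifact is a TSV carrying a provenance header (`#` lines: package
#' version, command, seed, config hash); on error, partial outputs of the
#' failed run are removed.
#'
#' Commands and their main config keys (all paths; `seed` everywhere):
#' \describe{
#'   \item{simulate}{[synthetic_config()] fields -> `graph.tsv`,
#'     `gold.tsv` (planted pairs), `truth_*` sidecars in `out_dir`.}
#'   \item{train}{`graph`, optional `gold`, `variant` (submodel),
#'     [train_config()] fields, optional `tune_lr` -> model sidecars under
#'     `out_dir/model_*`, `training_log.tsv`.}
#'   \item{evaluate}{`model` (prefix), `gold`, `n_negatives`, optional
#'     `graph` + `baseline=true` (score by direct treatment support
#'     instead of the embedding) -> `metrics.tsv`, `roc_points.tsv`,
#'     `pr_points.tsv`.}
#'   \item{predict}{`model` (prefix), `graph`, optional `exclude` (gold
#'     TSV), `top_k` -> `candidates.tsv`.}
#'   \item{explain}{`graph`, `drug`, `disease`, `top_k` ->
#'     `explanations.tsv`.}
#'   \item{proximity}{`embedding`, `drug_targets`, `disease_genes`,
#'     `pairs`, `n_perm`, `alpha` -> `proximity_report.tsv`.}
#' }
#'
#' @param command one of `simulate`, `train`, `evaluate`, `predict`,
#'   `explain`, `proximity`.
#' @param config named list (see [read_run_config()]).
#' @return invisibly, a character vector of artifact paths written.
#' @export
run_pipeline <- function(command = c("simulate", "train", "evaluate",
                                     "predict", "explain", "proximity"),
                         config = list()) {
  command <- match.arg(command)
  out_dir <- cfg_get(config, "out_dir", ".")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tracker <- new.env()
  tracker$files <- character(0)
  hdr <- provenance_header(command, config)
  seed <- as.integer(cfg_get(config, "seed", 1L))
  ok <- FALSE
  on.exit(if (!ok) unlink(tracker$files))

  runner <- switch(command,
    simulate = function() {
      cfg <- synthetic_config(
        n_drugs = cfg_get(config, "n_drugs", 20),
        n_diseases = cfg_get(config, "n_diseases", 20),
        n_genes = cfg_get(config, "n_genes", 50),
        latent_dim = cfg_get(config, "latent_dim", 8),
        n_themes_per_category = cfg_get(config, "n_themes_per_category",
                                        c(4, 4, 4, 4)),
        edge_density = cfg_get(config, "edge_density", 0.2),
        noise_sd = cfg_get(config, "noise_sd", 0.05),
        n_planted_indications = cfg_get(config, "n_planted_indications",
                                        20),
        seed = seed)
      sim <- generate_kg(cfg)
      gp <- file.path(out_dir, "graph.tsv")
      write_kg(sim$kg, gp)
      # prepend provenance to the written graph
      writeLines(c(hdr, readLines(gp)), gp)
      tracker$files <- c(tracker$files, gp)
      write_artifact(as.data.frame(sim$truth$planted_pairs),
                     file.path(out_dir, "gold.tsv"), hdr, tracker)
      write_truth(sim$truth, file.path(out_dir, "truth"))
      tracker$files <- c(tracker$files,
                         file.path(out_dir, paste0("truth_",
                           c("entity_vectors", "relation_vectors",
                             "planted_pairs", "scalars"), ".tsv")))
    },
    train = function() {
      kg <- read_kg(cfg_get(config, "graph"))
      kg <- build_submodel(kg, cfg_get(config, "variant", "full"))
      gold <- if (!is.null(config$gold)) read_gold_standard(config$gold)
              else gold_standard()
      split <- split_triples(kg, gold, seed = seed)
      tc <- train_config(
        d = as.integer(cfg_get(config, "d", 32)),
        epochs = as.integer(cfg_get(config, "epochs", 100)),
        batch_size = as.integer(cfg_get(config, "batch_size", 1024)),
        learning_rate = cfg_get(config, "learning_rate", 0.01),
        seed = seed)
      if (isTRUE(cfg_get(config, "tune_lr", FALSE)))
        tc <- tune_learning_rate(split, tc, names(kg$entities),
                                 tune_epochs = cfg_get(config,
                                                       "tune_epochs", 20))
      fit <- ukge_train(split, tc, names(kg$entities))
      prefix <- file.path(out_dir, "model")
      write_ukge_model(fit$model, prefix,
                       extra = list(seed = seed,
                                    learning_rate = tc$learning_rate,
                                    config_md5 = config_hash(config)))
      tracker$files <- c(tracker$files,
                         paste0(prefix, c("_meta", "_entities",
                                          "_relations"), ".tsv"))
      write_artifact(fit$log, file.path(out_dir, "training_log.tsv"),
                     hdr, tracker)
    },
    evaluate = function() {
      gold <- read_gold_standard(cfg_get(config, "gold"))
      n_neg <- as.integer(cfg_get(config, "n_negatives", nrow(gold)))
      neg <- sample_negative_pairs(gold, n_neg, seed = seed)
      if (isTRUE(cfg_get(config, "baseline", FALSE))) {
        kg <- read_kg(cfg_get(config, "graph"))
        sp <- baseline_treatment_support(kg, gold$drug, gold$disease)
        sn <- baseline_treatment_support(kg, neg$drug, neg$disease)
      } else {
        model <- read_ukge_model(cfg_get(config, "model"))
        sp <- test_score(model, gold$drug, "T", gold$disease)
        sn <- test_score(model, neg$drug, "T", neg$disease)
      }
      ev <- evaluate_gold_standard(sp, sn)
      write_artifact(data.frame(metric = c("auroc", "aupr", "n_pos",
                                           "n_neg"),
                                value = c(ev$auroc, ev$aupr, ev$n_pos,
                                          ev$n_neg)),
                     file.path(out_dir, "metrics.tsv"), hdr, tracker)
      write_artifact(ev$roc_points, file.path(out_dir, "roc_points.tsv"),
                     hdr, tracker)
      write_artifact(ev$pr_points, file.path(out_dir, "pr_points.tsv"),
                     hdr, tracker)
    },
    predict = function() {
      model <- read_ukge_model(cfg_get(config, "model"))
      kg <- read_kg(cfg_get(config, "graph"))
      excl <- if (!is.null(config$exclude))
        read_gold_standard(config$exclude) else NULL
      cand <- score_treatment_candidates(
        model,
        drugs = names(kg$entities)[kg$entities == "drug"],
        diseases = names(kg$entities)[kg$entities == "disease"],
        exclude = excl)
      cand <- utils::head(cand, as.integer(cfg_get(config, "top_k", 30)))
      write_artifact(cand, file.path(out_dir, "candidates.tsv"), hdr,
                     tracker)
    },
    explain = function() {
      kg <- read_kg(cfg_get(config, "graph"))
      ex <- explain_prediction(kg, cfg_get(config, "drug"),
                               cfg_get(config, "disease"),
                               top_k = as.integer(cfg_get(config, "top_k",
                                                          100)))
      df <- data.frame(
        drug = cfg_get(config, "drug"),
        disease = cfg_get(config, "disease"),
        rank = seq_along(ex),
        score = vapply(ex, `[[`, numeric(1), "score"),
        motif = vapply(ex, function(p)
          if (is.na(p$motif)) "other" else p$motif, character(1)),
        nodes = vapply(ex, function(p) paste(p$nodes, collapse = "|"),
                       character(1)),
        edges = vapply(ex, function(p)
          paste(paste0(p$edges$theme, ":",
                       format_support(p$edges$support)),
                collapse = "|"), character(1)))
      write_artifact(df, file.path(out_dir, "explanations.tsv"), hdr,
                     tracker)
    },
    proximity = function() {
      emb <- read_protein_embedding(cfg_get(config, "embedding"))
      targets <- read_gene_sets(cfg_get(config, "drug_targets"))
      dz_genes <- read_gene_sets(cfg_get(config, "disease_genes"))
      pairs <- utils::read.delim(cfg_get(config, "pairs"),
                                 comment.char = "#",
                                 colClasses = "character")
      n_perm <- as.integer(cfg_get(config, "n_perm", 10000))
      res <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
        proximity_test(emb,
                       targets[[pairs$drug[i]]] %||% character(0),
                       dz_genes[[pairs$disease[i]]] %||% character(0),
                       n_perm = n_perm, seed = seed + i - 1L,
                       drug = pairs$drug[i], disease = pairs$disease[i])
      }))
      res <- bonferroni_flag(res, alpha = cfg_get(config, "alpha", 0.05))
      res$significant <- ifelse(is.na(res$p_value), "N/A",
                                ifelse(res$significant, "yes", "no"))
      write_artifact(res, file.path(out_dir, "proximity_report.tsv"),
                     hdr, tracker)
    })
  runner()
  ok <- TRUE
  invisible(tracker$files)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
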