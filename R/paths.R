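adjacency_list <- function(kg) {
  # collapse multi-edges and orientations to one undirected edge
  ed <- unique(data.frame(a = pmin(kg$triples$head, kg$triples$tail),
                          b = pmax(kg$triples$head, kg$triples$tail)))
  both <- data.frame(a = c(ed$a, ed$b), b = c(ed$b, ed$a))
  split(both$b, factor(both$a, levels = names(kg$entities)))
}

#' Enumerate simple paths between two nodes
#'
#' All simple undirected paths from `source` to `target` with between 2
#' and `max_nodes` nodes inclusive (so at most `max_nodes - 1` edges),
#' found by depth-first search over the collapsed (theme-free) edge set.
#'
#' @param kg a [knowledge_graph()].
#' @param source,target distinct entity ids present in the graph.
#' @param max_nodes maximum path length in nodes (default 4).
#' @param max_paths safety cap; enumeration aborts with an error if more
#'   paths exist (hub nodes make unbounded enumeration infeasible on
#'   literature-scale graphs).
#' @return list of character vectors (node sequences, source first).
#' @export
enumerate_paths <- function(kg, source, target, max_nodes = 4,
                            max_paths = 1e6) {
  ids <- names(kg$entities)
  if (!source %in% ids) stop("node absent from graph: ", source)
  if (!target %in% ids) stop("node absent from graph: ", target)
  if (source == target) stop("source and target must differ")
  adj <- adjacency_list(kg)
  out <- vector("list", 256L)
  n_out <- 0L
  path <- character(max_nodes)
  path[1] <- source
  dfs <- function(node, depth) {
    for (nb in adj[[node]]) {
      if (nb == target) {
        if (n_out == max_paths)
          stop("more than ", max_paths, " paths; raise max_paths")
        n_out <<- n_out + 1L
        if (n_out > length(out)) length(out) <<- 2L * n_out
        out[[n_out]] <<- c(path[seq_len(depth)], target)
      } else if (depth < max_nodes - 1 && !nb %in% path[seq_len(depth)]) {
        path[depth + 1L] <<- nb
        dfs(nb, depth + 1L)
      }
    }
  }
  dfs(source, 1L)
  out[seq_len(n_out)]
}

#' Best-supported theme between two adjacent nodes
#'
#' Over all triples linking `u` and `v` in either orientation, returns the
#' theme with the maximum support; ties break alphabetically by theme
#' code.
#'
#' @param kg a [knowledge_graph()].
#' @param u,v entity ids with at least one triple between them.
#' @return list with `theme` and `support`.
#' @export
best_theme <- function(kg, u, v) {
  tr <- kg$triples
  hit <- (tr$head == u & tr$tail == v) | (tr$head == v & tr$tail == u)
  if (!any(hit)) stop("no edge between ", u, " and ", v)
  tr <- tr[hit, , drop = FALSE]
  tr <- tr[order(-tr$support, tr$theme), , drop = FALSE]
  list(theme = tr$theme[1], support = tr$support[1])
}

#' Classify the metapath motif of an explanation path
#'
#' Four-node drug-to-disease paths fall into three motifs by the types of
#' their two interior nodes: drug-disease-gene-disease (`DzG`, shared
#' genetic mechanism), drug-disease-drug-disease (`DzDr`, shared
#' treatment), and drug-gene-gene-disease (`GG`, interacting-gene
#' mechanism). Two-node paths are `direct`; any other shape is `other`.
#'
#' @param nodes character vector of node ids along the path (or an
#'   `explanation_path`).
#' @param types named character vector id -> entity type.
#' @return one of `"DzG"`, `"DzDr"`, `"GG"`, `"direct"`, `"other"`.
#' @export
classify_motif <- function(nodes, types) {
  if (inherits(nodes, "explanation_path")) nodes <- nodes$nodes
  ty <- unname(types[nodes])
  n <- length(nodes)
  if (ty[1] != "drug" || ty[n] != "disease")
    stop("path endpoints must be a drug and a disease, got ",
         ty[1], " -> ", ty[n])
  if (n == 2) return("direct")
  if (n == 4) {
    inner <- paste(ty[2], ty[3])
    if (inner == "disease gene") return("DzG")
    if (inner == "disease drug") return("DzDr")
    if (inner == "gene gene") return("GG")
  }
  "other"
}

#' Score a path by its weakest best-theme support
#'
#' Each step is reduced to its highest-supported theme ([best_theme()]);
#' the path score is the minimum of these supports, so a path is only as
#' strong as its weakest literature link.
#'
#' @param nodes character vector of node ids forming a valid path.
#' @param kg a [knowledge_graph()].
#' @return object of class `explanation_path`: list with `nodes`, `edges`
#'   (data.frame: theme, support per step), `score`, and `motif` (`NA` if
#'   the endpoints are not a drug and a disease).
#' @export
score_path <- function(nodes, kg) {
  stopifnot(length(nodes) >= 2)
  steps <- lapply(seq_len(length(nodes) - 1), function(i)
    best_theme(kg, nodes[i], nodes[i + 1]))
  edges <- data.frame(theme = vapply(steps, `[[`, character(1), "theme"),
                      support = vapply(steps, `[[`, numeric(1), "support"))
  motif <- tryCatch(classify_motif(nodes, kg$entities),
                    error = function(e) NA_character_)
  structure(list(nodes = nodes, edges = edges,
                 score = min(edges$support), motif = motif),
            class = "explanation_path")
}

#' @export
print.explanation_path <- function(x, ...) {
  cat(paste0("(", x$nodes[1], ")"))
  for (i in seq_len(nrow(x$edges)))
    cat(paste0(" - [", x$edges$theme[i], " (",
               format(x$edges$support[i], digits = 3), ")] - (",
               x$nodes[i + 1], ")"))
  cat("\n  score", format(x$score, digits = 3), "| motif",
      if (is.na(x$motif)) "-" else x$motif, "\n")
  invisible(x)
}

#' Rank explanation paths for a candidate pair
#'
#' Enumerates all simple paths of up to `max_nodes` nodes between the drug
#' and the disease, scores each ([score_path()]), sorts by descending
#' score (ties: shorter path first, then lexicographic node sequence), and
#' truncates to `top_k`.
#'
#' @param kg a [knowledge_graph()].
#' @param drug,disease entity ids in the graph.
#' @param top_k maximum number of paths returned.
#' @param max_nodes,max_paths passed to [enumerate_paths()].
#' @return list of `explanation_path` objects (possibly empty).
#' @export
explain_prediction <- function(kg, drug, disease, top_k = 100,
                               max_nodes = 4, max_paths = 1e6) {
  paths <- enumerate_paths(kg, drug, disease, max_nodes = max_nodes,
                           max_paths = max_paths)
  if (!length(paths)) return(list())
  scored <- lapply(paths, score_path, kg = kg)
  key <- vapply(scored, function(p) paste(p$nodes, collapse = "|"),
                character(1))
  o <- order(-vapply(scored, `[[`, numeric(1), "score"),
             lengths(paths), key)
  scored[o][seq_len(min(top_k, length(scored)))]
}

#' Interior gene nodes of top-ranked explanation paths
#'
#' The potential mediators of a prediction: gene nodes appearing strictly
#' inside the top-ranked paths, in order of first appearance.
#'
#' @param explanations list of `explanation_path` objects.
#' @param types named character vector id -> entity type.
#' @param n_top number of mediators to return.
#' @export
potential_mediators <- function(explanations, types, n_top = 3) {
  inner <- unlist(lapply(explanations, function(p)
    p$nodes[-c(1, length(p$nodes))]))
  genes <- unique(inner[types[inner] == "gene"])
  utils::head(genes, n_top)
}

#' Motif counts across assessment categories
#'
#' Tallies metapath motifs over each candidate pair's top-k explanation
#' paths, aggregated by the pair's assessment category.
#'
#' @param explanations named list (one element per pair) of
#'   `explanation_path` lists.
#' @param categories named character vector mapping the same pair names to
#'   assessment labels.
#' @param top_k count at most this many paths per pair.
#' @return data.frame of counts, motifs x categories (class
#'   `motif_distribution`).
#' @export
motif_distribution <- function(explanations, categories, top_k = 100) {
  motifs <- c("DzG", "DzDr", "GG", "direct", "other")
  cats <- sort(unique(unname(categories)))
  counts <- matrix(0L, length(motifs), length(cats),
                   dimnames = list(motifs, cats))
  for (pair in names(explanations)) {
    ex <- utils::head(explanations[[pair]], top_k)
    cat_lab <- categories[[pair]]
    for (p in ex) {
      m <- if (is.na(p$motif)) "other" else p$motif
      counts[m, cat_lab] <- counts[m, cat_lab] + 1L
    }
  }
  structure(as.data.frame(counts), class = c("motif_distribution",
                                             "data.frame"))
}
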