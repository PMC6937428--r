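kg_igraph <- function(kg) {
  ed <- unique(kg$triples[c("head", "tail")])
  igraph::graph_from_data_frame(
    ed, directed = FALSE,
    vertices = data.frame(name = names(kg$entities),
                          type = unname(kg$entities)))
}

induced_kg <- function(kg, keep_ids) {
  keep_ids <- intersect(names(kg$entities), keep_ids)
  tr <- kg$triples
  tr <- tr[tr$head %in% keep_ids & tr$tail %in% keep_ids, , drop = FALSE]
  knowledge_graph(kg$entities[keep_ids], tr, kg$themes)
}

#' Largest connected component
#'
#' Induced subgraph on the largest component, treating all themed edges as
#' a single undirected edge set. Isolated entities count as singleton
#' components. Ties in component size are broken deterministically toward
#' the component containing the lexicographically smallest entity id.
#'
#' @param kg a [knowledge_graph()].
#' @return The induced [knowledge_graph()] on the largest component.
#' @export
largest_connected_component <- function(kg) {
  if (!length(kg$entities)) stop("empty graph: no entities")
  comp <- igraph::components(kg_igraph(kg))
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # smallest entity id among members decides
    firsts <- vapply(best, function(k)
      min(names(comp$membership)[comp$membership == k]), character(1))
    best <- best[order(firsts)][1]
  }
  induced_kg(kg, names(comp$membership)[comp$membership == best])
}

#' Filter a graph down to the repurposing-relevant core
#'
#' Keeps only nodes that are (1) genes, (2) high-priority disease nodes, or
#' (3) drug/disease nodes appearing in a known indication, then takes the
#' largest connected component of what remains.
#'
#' @param kg a [knowledge_graph()].
#' @param priority_diseases character vector of disease ids to keep.
#' @param indication_nodes character vector of drug/disease ids appearing
#'   in known indications.
#' @return Filtered [knowledge_graph()].
#' @export
filter_for_repurposing <- function(kg, priority_diseases = character(0),
                                   indication_nodes = character(0)) {
  ent <- kg$entities
  ids <- names(ent)
  keep <- ent == "gene" |
    (ent == "disease" & ids %in% priority_diseases) |
    (ent %in% c("drug", "disease") & ids %in% indication_nodes)
  if (!any(keep)) stop("filter removed every node")
  largest_connected_component(induced_kg(kg, ids[keep]))
}

# category of each triple, from its endpoint types
triple_categories <- function(kg) {
  type_pair_category(kg$entities[kg$triples$head],
                     kg$entities[kg$triples$tail])
}

#' Build an ablation submodel of the graph
#'
#' Variants used to probe which parts of the network carry the treatment
#' signal:
#' \describe{
#'   \item{`full`}{the graph unchanged.}
#'   \item{`treatment_only_drdz`}{drop drug-disease triples whose theme is
#'     not `"T"`; all other categories kept.}
#'   \item{`no_genes`}{drop every triple touching a gene, then take the
#'     largest connected component of the drug-disease bipartite
#'     remainder.}
#'   \item{`treatment_edges_only`}{keep only (drug, `"T"`, disease)
#'     triples — the no-embedding baseline scored directly by support.}
#' }
#'
#' @param kg a [knowledge_graph()].
#' @param variant one of the four variant names.
#' @return A [knowledge_graph()].
#' @export
build_submodel <- function(kg, variant = c("full", "treatment_only_drdz",
                                           "no_genes",
                                           "treatment_edges_only")) {
  variant <- match.arg(variant)
  if (variant == "full") return(kg)
  cats <- triple_categories(kg)
  tr <- kg$triples
  if (variant == "treatment_only_drdz") {
    keep <- cats != "Dr-Dz" | tr$theme == "T"
    return(knowledge_graph(kg$entities, tr[keep, , drop = FALSE],
                           kg$themes))
  }
  if (variant == "no_genes") {
    is_gene <- kg$entities == "gene"
    touches <- is_gene[tr$head] | is_gene[tr$tail]
    ent <- kg$entities[kg$entities != "gene"]
    sub <- knowledge_graph(ent, tr[!touches, , drop = FALSE], kg$themes)
    return(largest_connected_component(sub))
  }
  # treatment_edges_only
  keep <- cats == "Dr-Dz" & tr$theme == "T"
  tr <- tr[keep, , drop = FALSE]
  knowledge_graph(kg$entities[names(kg$entities) %in% c(tr$head, tr$tail)],
                  tr, kg$themes)
}
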