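#' Construct a support-scored heterogeneous knowledge graph
#'
#' The central container: typed entities (drug, disease, gene) linked by
#' themed multi-edges, each carrying a literature support score in [0, 1].
#' Several themes may link the same entity pair (multi-edges); connectivity
#' is always taken undirected.
#'
#' @param entities named character vector mapping entity id to one of
#'   `"drug"`, `"disease"`, `"gene"`.
#' @param triples data.frame with columns `head`, `theme`, `tail`,
#'   `support`.
#' @param themes theme vocabulary data.frame (default [gnbr_themes()]).
#' @return An object of class `knowledge_graph`: a list with elements
#'   `entities`, `triples`, `themes`.
#' @examples
#' kg <- knowledge_graph(
#'   c(metformin = "drug", t2d = "disease"),
#'   data.frame(head = "metformin", theme = "T", tail = "t2d",
#'              support = 0.999))
#' kg
#' @export
knowledge_graph <- function(entities, triples, themes = gnbr_themes()) {
  stopifnot(is.character(entities), !is.null(names(entities)))
  triples <- as.data.frame(triples)[, c("head", "theme", "tail", "support")]
  triples$head <- as.character(triples$head)
  triples$theme <- as.character(triples$theme)
  triples$tail <- as.character(triples$tail)
  triples$support <- as.numeric(triples$support)
  rownames(triples) <- NULL
  kg <- structure(list(entities = entities, triples = triples,
                       themes = themes),
                  class = "knowledge_graph")
  validate_kg(kg)
}

entity_types <- function() c("drug", "disease", "gene")

validate_kg <- function(kg) {
  ent <- kg$entities
  tr <- kg$triples
  if (any(!ent %in% entity_types()))
    stop("unknown entity type: ",
         paste(unique(setdiff(ent, entity_types())), collapse = ", "))
  if (anyDuplicated(names(ent))) stop("duplicate entity ids")
  validate_themes(kg$themes)
  if (nrow(tr)) {
    miss <- setdiff(c(tr$head, tr$tail), names(ent))
    if (length(miss))
      stop("triple endpoint not in entities: ",
           paste(utils::head(miss, 5), collapse = ", "))
    if (any(tr$head == tr$tail)) stop("self-loop triples are not allowed")
    bad <- is.na(tr$support) | tr$support < 0 | tr$support > 1
    if (any(bad))
      stop("support outside [0,1] in ", sum(bad), " triple(s)")
    cat_of <- type_pair_category(ent[tr$head], ent[tr$tail])
    key <- paste(tr$theme, cat_of)
    ok <- key %in% paste(kg$themes$code, kg$themes$category)
    if (any(!ok))
      stop("theme/category incompatible with endpoint types for triple(s): ",
           paste(utils::head(paste0("(", tr$head[!ok], ", ", tr$theme[!ok],
                                    ", ", tr$tail[!ok], ")"), 3),
                 collapse = " "))
  }
  kg
}

#' @export
print.knowledge_graph <- function(x, ...) {
  tt <- table(factor(x$entities, levels = entity_types()))
  cat("knowledge_graph:", length(x$entities), "entities (",
      paste(paste(tt, names(tt)), collapse = ", "), "),",
      nrow(x$triples), "triples,",
      nrow(x$themes), "themes\n")
  invisible(x)
}

# shortest decimal string that parses back to exactly x
format_support <- function(x) {
  s <- sprintf("%.15g", x)
  exact <- as.numeric(s) == x
  s[!exact] <- sprintf("%.17g", x[!exact])
  s
}

graph_columns <- function()
  c("head", "head_type", "theme", "tail", "tail_type", "support")

#' Read a knowledge graph from a themed edge-list TSV
#'
#' Expected columns: `head`, `head_type`, `theme`, `tail`, `tail_type`,
#' `support` (tab-separated, UTF-8). Lines starting with `#` are ignored.
#' Malformed rows — unknown entity type or theme code, support outside
#' [0, 1] — raise an error naming the offending file line.
#'
#' @param path file path.
#' @param vocabulary theme vocabulary data.frame (default [gnbr_themes()]).
#' @return A [knowledge_graph()].
#' @export
read_kg <- function(path, vocabulary = gnbr_themes()) {
  if (!file.exists(path)) stop("graph file not found: ", path)
  raw <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", raw)
  lineno <- which(keep)
  rows <- strsplit(raw[keep], "\t", fixed = TRUE)
  if (!length(rows)) stop("empty graph file: ", path)
  header <- rows[[1]]
  if (!identical(header, graph_columns()))
    stop("bad header in ", path, "; expected: ",
         paste(graph_columns(), collapse = "\t"))
  rows <- rows[-1]
  lineno <- lineno[-1]
  if (length(rows)) {
    nf <- lengths(rows) != 6L
    if (any(nf))
      stop("line ", lineno[which(nf)[1]], ": expected 6 tab-separated fields")
    m <- matrix(unlist(rows), ncol = 6, byrow = TRUE)
    bad_t <- !(m[, 2] %in% entity_types()) | !(m[, 5] %in% entity_types())
    if (any(bad_t))
      stop("line ", lineno[which(bad_t)[1]], ": unknown entity type")
    supp <- suppressWarnings(as.numeric(m[, 6]))
    bad_s <- is.na(supp) | supp < 0 | supp > 1
    if (any(bad_s))
      stop("line ", lineno[which(bad_s)[1]],
           ": support must be a number in [0,1], got '", m[bad_s, 6][1], "'")
    cat_of <- type_pair_category(m[, 2], m[, 5])
    ok <- paste(m[, 3], cat_of) %in%
      paste(vocabulary$code, vocabulary$category)
    if (any(!ok))
      stop("line ", lineno[which(!ok)[1]], ": unknown theme code '",
           m[!ok, 3][1], "' for entity types (", m[!ok, 2][1], ", ",
           m[!ok, 5][1], ")")
    ids <- c(m[, 1], m[, 4])
    typ <- c(m[, 2], m[, 5])
    confl <- tapply(typ, ids, function(v) length(unique(v)))
    if (any(confl > 1))
      stop("entity with conflicting types: ",
           names(confl)[which(confl > 1)[1]])
    ent <- stats::setNames(typ, ids)[!duplicated(ids)]
    tr <- data.frame(head = m[, 1], theme = m[, 3], tail = m[, 4],
                     support = supp, stringsAsFactors = FALSE)
  } else {
    ent <- stats::setNames(character(0), character(0))
    tr <- data.frame(head = character(0), theme = character(0),
                     tail = character(0), support = numeric(0))
  }
  knowledge_graph(ent, tr, vocabulary)
}

#' Write a knowledge graph as a themed edge-list TSV
#'
#' Rows are sorted by (head, theme, tail) so output is deterministic;
#' supports are serialized with enough digits to round-trip exactly.
#'
#' @param kg a [knowledge_graph()].
#' @param path output file path.
#' @export
write_kg <- function(kg, path) {
  tr <- kg$triples
  o <- order(tr$head, tr$theme, tr$tail)
  tr <- tr[o, , drop = FALSE]
  lines <- paste(graph_columns(), collapse = "\t")
  if (nrow(tr)) {
    body <- paste(tr$head, kg$entities[tr$head], tr$theme,
                  tr$tail, kg$entities[tr$tail],
                  format_support(tr$support), sep = "\t")
    lines <- c(lines, body)
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a gold-standard indication list
#'
#' @param path two-column TSV with columns `drug`, `disease`; `#` lines
#'   ignored.
#' @return data.frame with columns `drug`, `disease`, duplicates removed.
#' @export
read_gold_standard <- function(path) {
  g <- utils::read.delim(path, comment.char = "#",
                         colClasses = "character")
  if (!all(c("drug", "disease") %in% names(g)))
    stop("gold standard must have columns drug, disease")
  gold_standard(g$drug, g$disease)
}

#' Construct a gold-standard indication set
#'
#' @param drug,disease character vectors of equal length.
#' @return data.frame of unique (drug, disease) pairs with class
#'   `gold_standard`.
#' @export
gold_standard <- function(drug = character(0), disease = character(0)) {
  g <- unique(data.frame(drug = as.character(drug),
                         disease = as.character(disease),
                         stringsAsFactors = FALSE))
  rownames(g) <- NULL
  class(g) <- c("gold_standard", "data.frame")
  g
}

#' @export
write_gold_standard <- function(gold, path) {
  utils::write.table(as.data.frame(gold)[c("drug", "disease")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# unordered pair keys, used to match indications against triples
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
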