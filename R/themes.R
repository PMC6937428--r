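#' Default theme vocabulary
#'
#' The 32 high-level semantic themes used by literature-mined graphs in the
#' GNBR schema, organised into four categories by the entity types they
#' connect: drug-disease (`Dr-Dz`), drug-gene (`Dr-G`), disease-gene
#' (`Dz-G`) and gene-gene (`G-G`). Codes are unique within a category but a
#' code may belong to several categories (e.g. `E+` is both a drug-gene and
#' a gene-gene theme, `J` both drug-disease and disease-gene).
#'
#' @return A data.frame with columns `code`, `category` and `description`,
#'   one row per (code, category) combination (32 rows).
#' @examples
#' head(gnbr_themes())
#' @export
gnbr_themes <- function() {
  th <- rbind(
    data.frame(
      code = c("T", "C", "Sa", "Pr", "Pa", "J"),
      category = "Dr-Dz",
      description = c(
        "treatment/therapy (including investigatory)",
        "inhibits cell growth (esp. cancers)",
        "side effect/adverse event",
        "prevents, suppresses",
        "alleviates, reduces",
        "role in disease pathogenesis")),
    data.frame(
      code = c("A+", "A-", "B", "E+", "E-", "E", "N"),
      category = "Dr-G",
      description = c(
        "agonism, activation",
        "antagonism, blocking",
        "binding, ligand (esp. receptors)",
        "increases expression/production",
        "decreases expression/production",
        "affects expression/production (neutral)",
        "inhibits")),
    data.frame(
      code = c("U", "Ud", "D", "J", "Te", "Y", "G", "Md", "X", "L"),
      category = "Dz-G",
      description = c(
        "causal mutations",
        "mutations affecting disease course",
        "drug targets",
        "role in pathogenesis",
        "possible therapeutic effect",
        "polymorphisms alter risk",
        "promotes progression",
        "biomarkers (diagnostic)",
        "overexpression in disease",
        "improper regulation linked to disease")),
    data.frame(
      code = c("B", "W", "V+", "E+", "E", "I", "H", "Rg", "Q"),
      category = "G-G",
      description = c(
        "binding, ligand (esp. receptors)",
        "enhances response",
        "activates, stimulates",
        "increases expression/production",
        "affects expression/production",
        "signaling pathway",
        "same protein or complex",
        "regulation",
        "production by cell population"))
  )
  rownames(th) <- NULL
  th
}

#' Read a theme vocabulary from a TSV file
#'
#' @param path TSV with columns `code`, `category`, `description`; `#` lines
#'   are ignored.
#' @return Theme data.frame as [gnbr_themes()].
#' @export
read_themes <- function(path) {
  th <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("code", "category", "description")
  if (!all(need %in% names(th)))
    stop("theme vocabulary must have columns: ", paste(need, collapse = ", "))
  validate_themes(th[need])
  th[need]
}

theme_categories <- function() c("Dr-Dz", "Dr-G", "Dz-G", "G-G")

validate_themes <- function(themes) {
  if (any(!themes$category %in% theme_categories()))
    stop("unknown theme category: ",
         paste(unique(setdiff(themes$category, theme_categories())),
               collapse = ", "))
  if (anyDuplicated(themes[c("code", "category")]))
    stop("duplicate theme code within a category")
  invisible(themes)
}

# unordered entity-type pair -> category label, or NA if no category exists
type_pair_category <- function(type_a, type_b) {
  key <- paste(pmin(type_a, type_b), pmax(type_a, type_b))
  lut <- c("disease drug" = "Dr-Dz", "drug gene" = "Dr-G",
           "disease gene" = "Dz-G", "gene gene" = "G-G")
  unname(lut[key])
}
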