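test_that("graph TSV round-trips exactly and minimal files parse", {
  tf <- withr::local_tempfile(fileext = ".tsv")

  writeLines(c("head\thead_type\ttheme\ttail\ttail_type\tsupport",
               "metformin\tdrug\tT\tt2d\tdisease\t0.999"), tf)
  kg <- read_kg(tf)
  expect_length(kg$entities, 2)
  expect_equal(nrow(kg$triples), 1)
  expect_equal(kg$triples$support, 0.999)

  # empty graph -> header-only file
  empty <- knowledge_graph(stats::setNames(character(0), character(0)),
                           data.frame(head = character(0),
                                      theme = character(0),
                                      tail = character(0),
                                      support = numeric(0)))
  write_kg(empty, tf)
  expect_length(readLines(tf), 1)

  # round trip on random graphs preserves triples exactly
  for (s in 1:5) {
    kg <- random_kg(seed = s, n_triples = 40)
    kg$triples$support <- runif(40)  # full-precision doubles
    write_kg(kg, tf)
    kg2 <- read_kg(tf)
    o1 <- with(kg$triples, order(head, theme, tail, support))
    expect_equal(kg2$triples, kg$triples[o1, ], ignore_attr = TRUE)
    # entities carried by triples survive (isolated nodes have no row in
    # an edge-list serialization)
    touched <- unique(c(kg$triples$head, kg$triples$tail))
    expect_setequal(names(kg2$entities), touched)
    expect_identical(kg2$entities[touched], kg$entities[touched])
  }
})

test_that("malformed graph rows are rejected with the line number", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# a comment",
               "head\thead_type\ttheme\ttail\ttail_type\tsupport",
               "a\tdrug\tT\tb\tdisease\t0.5",
               "a\tdrug\tT\tc\tdisease\t1.2"), tf)
  expect_error(read_kg(tf), "line 4.*support")

  writeLines(c("head\thead_type\ttheme\ttail\ttail_type\tsupport",
               "a\tpotato\tT\tb\tdisease\t0.5"), tf)
  expect_error(read_kg(tf), "line 2.*entity type")

  writeLines(c("head\thead_type\ttheme\ttail\ttail_type\tsupport",
               "a\tdrug\tZZ\tb\tdisease\t0.5"), tf)
  expect_error(read_kg(tf), "line 2.*theme")

  # theme valid in another category but incompatible with these types
  writeLines(c("head\thead_type\ttheme\ttail\ttail_type\tsupport",
               "a\tdrug\tU\tb\tdisease\t0.5"), tf)
  expect_error(read_kg(tf), "theme")
})

test_that("knowledge_graph validates type/theme/support invariants", {
  expect_error(knowledge_graph(c(a = "drug", b = "disease"),
                               data.frame(head = "a", theme = "T",
                                          tail = "b", support = 1.5)),
               "support")
  expect_error(knowledge_graph(c(a = "drug", b = "disease"),
                               data.frame(head = "a", theme = "T",
                                          tail = "a", support = 0.5)),
               "self-loop")
  expect_error(knowledge_graph(c(a = "drug"),
                               data.frame(head = "a", theme = "T",
                                          tail = "b", support = 0.5)),
               "not in entities")
  # 32-theme default vocabulary with multi-category codes
  th <- gnbr_themes()
  expect_equal(nrow(th), 32)
  expect_true(all(table(th$code, th$category) <= 1))
  expect_setequal(th$category[th$code == "E+"], c("Dr-G", "G-G"))
  expect_setequal(th$category[th$code == "J"], c("Dr-Dz", "Dz-G"))
})

test_that("largest connected component matches a BFS oracle", {
  # two components, sizes 3 and 2
  kg <- knowledge_graph(
    c(a = "drug", b = "disease", g1 = "gene", c = "drug", d = "disease"),
    data.frame(head = c("a", "b", "c"), theme = c("T", "U", "T"),
               tail = c("b", "g1", "d"), support = 0.5))
  lcc <- largest_connected_component(kg)
  expect_setequal(names(lcc$entities), c("a", "b", "g1"))

  # connected graph is unchanged
  tri <- knowledge_graph(
    c(a = "drug", b = "disease", g1 = "gene"),
    data.frame(head = c("a", "b", "a"), theme = c("T", "U", "B"),
               tail = c("b", "g1", "g1"), support = 0.5))
  expect_setequal(names(largest_connected_component(tri)$entities),
                  c("a", "b", "g1"))

  expect_error(largest_connected_component(
    knowledge_graph(stats::setNames(character(0), character(0)),
                    data.frame(head = character(0), theme = character(0),
                               tail = character(0),
                               support = numeric(0)))), "empty")

  # random graphs vs BFS labelling, including isolated nodes
  for (s in 1:20) {
    kg <- random_kg(seed = s, n_triples = 15)
    comp <- bfs_components(names(kg$entities), kg$triples$head,
                           kg$triples$tail)
    sizes <- table(comp)
    big <- names(sizes)[sizes == max(sizes)]
    # tie-break: smallest entity id
    firsts <- vapply(big, function(k) min(names(comp)[comp == k]),
                     character(1))
    want <- names(comp)[comp == as.integer(big[order(firsts)][1])]
    expect_setequal(names(largest_connected_component(kg)$entities), want)
  }
})

test_that("repurposing filter keeps genes, priority diseases and indication nodes", {
  kg <- random_kg(seed = 3, n_triples = 60)
  types <- kg$entities
  pri <- names(types)[types == "disease"][1:2]
  ind <- c(names(types)[types == "drug"][1:2], pri[1])
  out <- filter_for_repurposing(kg, pri, ind)
  # no node outside the keep rule survives
  keep_rule <- types == "gene" |
    (types == "disease" & names(types) %in% pri) |
    (types != "gene" & names(types) %in% ind)
  expect_true(all(names(out$entities) %in% names(types)[keep_rule]))
  # a drug not in the indication set is absent
  dropped_drug <- setdiff(names(types)[types == "drug"], ind)[1]
  expect_false(dropped_drug %in% names(out$entities))
  # equals set-filter-then-LCC oracle
  sub <- kgrepurpose:::induced_kg(kg, names(types)[keep_rule])
  comp <- bfs_components(names(sub$entities), sub$triples$head,
                         sub$triples$tail)
  sizes <- table(comp)
  big <- names(sizes)[sizes == max(sizes)]
  firsts <- vapply(big, function(k) min(names(comp)[comp == k]),
                   character(1))
  want <- names(comp)[comp == as.integer(big[order(firsts)][1])]
  expect_setequal(names(out$entities), want)
})

test_that("submodel variants drop exactly the triples they should", {
  kg <- random_kg(seed = 5, n_triples = 80)
  cats <- kgrepurpose:::triple_categories(kg)

  expect_identical(build_submodel(kg, "full"), kg)

  tod <- build_submodel(kg, "treatment_only_drdz")
  keep <- cats != "Dr-Dz" | kg$triples$theme == "T"
  expect_equal(nrow(tod$triples), sum(keep))
  tcats <- kgrepurpose:::triple_categories(tod)
  expect_true(all(tod$triples$theme[tcats == "Dr-Dz"] == "T"))

  ng <- build_submodel(kg, "no_genes")
  expect_false(any(ng$entities == "gene"))
  expect_false(any(c(ng$triples$head, ng$triples$tail) %in%
                     names(kg$entities)[kg$entities == "gene"]))

  teo <- build_submodel(kg, "treatment_edges_only")
  expect_true(all(teo$triples$theme == "T"))
  expect_true(all(kgrepurpose:::triple_categories(teo) == "Dr-Dz"))
  # treatment_edges_only is the Dr-Dz restriction of treatment_only_drdz
  key <- function(g) paste(g$triples$head, g$triples$theme, g$triples$tail)
  expect_true(all(key(teo) %in% key(tod)))
  # no variant ever adds triples
  for (v in c("treatment_only_drdz", "no_genes", "treatment_edges_only"))
    expect_true(all(key(build_submodel(kg, v)) %in% key(kg)))

  expect_error(build_submodel(kg, "bogus"))
})

test_that("stratified split respects fractions, determinism and partition", {
  # 1000 triples, 100 indication-containing
  kg <- random_kg(n_drugs = 12, n_diseases = 12, n_genes = 20,
                  n_triples = 1000, seed = 9)
  tr <- kg$triples
  cats <- kgrepurpose:::triple_categories(kg)
  dd <- unique(tr[cats == "Dr-Dz", c("head", "tail")])
  # choose pairs covering ~100 triples
  keys <- kgrepurpose:::pair_key(tr$head, tr$tail)
  cnt <- table(keys)
  pk <- kgrepurpose:::pair_key(dd$head, dd$tail)
  ord <- order(-cnt[pk])
  pick <- c(); tot <- 0
  for (i in ord) {
    if (tot >= 100) break
    pick <- c(pick, i); tot <- tot + cnt[pk[i]]
  }
  heads <- dd$head[pick]; tails <- dd$tail[pick]
  is_drug <- kg$entities[heads] == "drug"
  gold <- gold_standard(ifelse(is_drug, heads, tails),
                        ifelse(is_drug, tails, heads))
  n_ind <- sum(keys %in% kgrepurpose:::pair_key(gold$drug, gold$disease))

  sp <- split_triples(kg, gold, seed = 42)
  # partition
  allk <- function(x) paste(x$head, x$theme, x$tail, x$support)
  got <- c(allk(sp$train), allk(sp$validation), allk(sp$test))
  expect_equal(sort(got), sort(allk(tr)))
  expect_equal(anyDuplicated(got), 0)
  # strata sizes within 1 of the floor allocation
  gk <- kgrepurpose:::pair_key(gold$drug, gold$disease)
  n_ind_fold <- function(f)
    sum(kgrepurpose:::pair_key(f$head, f$tail) %in% gk)
  expect_equal(n_ind_fold(sp$validation), floor(0.2 * n_ind))
  expect_equal(n_ind_fold(sp$test), floor(0.2 * n_ind))
  n_bg <- nrow(tr) - n_ind
  expect_equal(nrow(sp$validation) - n_ind_fold(sp$validation),
               floor(0.05 * n_bg))
  # determinism
  sp2 <- split_triples(kg, gold, seed = 42)
  expect_identical(sp, sp2)
  sp3 <- split_triples(kg, gold, seed = 43)
  expect_false(identical(sp$train, sp3$train))

  # empty gold: everything goes 90/5/5
  spe <- split_triples(kg, gold_standard(), seed = 1)
  expect_equal(nrow(spe$validation), floor(0.05 * nrow(tr)))
  expect_equal(nrow(spe$test), floor(0.05 * nrow(tr)))

  # tiny nonempty stratum errors
  kg2 <- random_kg(seed = 2, n_triples = 12)
  cats2 <- kgrepurpose:::triple_categories(kg2)
  one <- kg2$triples[which(cats2 == "Dr-Dz")[1], ]
  if (!is.na(one$head)) {
    is_d <- kg2$entities[one$head] == "drug"
    g1 <- gold_standard(if (is_d) one$head else one$tail,
                        if (is_d) one$tail else one$head)
    expect_error(split_triples(kg2, g1, seed = 1), "fewer than 3")
  }
})

test_that("per-pair split keeps all triples of a pair in one fold", {
  kg <- random_kg(n_drugs = 6, n_diseases = 6, n_genes = 8,
                  n_triples = 300, seed = 4)
  sp <- split_triples(kg, gold_standard(), seed = 5, by_pair = TRUE)
  fold_of <- new.env()
  ok <- TRUE
  for (f in c("train", "validation", "test")) {
    k <- kgrepurpose:::pair_key(sp[[f]]$head, sp[[f]]$tail)
    for (kk in unique(k)) {
      prev <- fold_of[[kk]]
      if (!is.null(prev) && prev != f) ok <- FALSE
      fold_of[[kk]] <- f
    }
  }
  expect_true(ok)
})
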