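test_that("candidate scoring ranks all non-excluded pairs by test score", {
  m <- random_model(entities = c(paste0("d", 1:5), paste0("z", 1:5)),
                    themes = c("T", "Sa"), d = 8, seed = 2)
  drugs <- paste0("d", 1:5); dis <- paste0("z", 1:5)

  one <- score_treatment_candidates(m, "d1", "z1")
  expect_equal(nrow(one), 1)
  expect_equal(one$rank, 1)
  expect_equal(one$score, test_score(m, "d1", "T", "z1"))

  # all pairs excluded -> empty
  allg <- expand.grid(drug = drugs, disease = dis,
                      stringsAsFactors = FALSE)
  excl <- gold_standard(allg$drug, allg$disease)
  expect_equal(nrow(score_treatment_candidates(m, drugs, dis, excl)), 0)

  # 5x5 grid matches an exhaustive sort oracle
  got <- score_treatment_candidates(m, drugs, dis)
  want <- allg
  want$score <- test_score(m, want$drug, "T", want$disease)
  want <- want[order(-want$score, want$drug, want$disease), ]
  expect_equal(got$drug, want$drug)
  expect_equal(got$score, want$score)
  expect_equal(got$rank, 1:25)

  m_noT <- random_model(themes = c("Sa", "U"), seed = 1)
  expect_error(score_treatment_candidates(m_noT, "e01", "e02"),
               "\"T\" absent")
})

test_that("baseline treatment support looks up the T edge or returns 0", {
  kg <- knowledge_graph(
    c(metformin = "drug", t2d = "disease", other = "disease"),
    data.frame(head = c("metformin", "metformin"),
               theme = c("T", "Sa"),
               tail = c("t2d", "other"),
               support = c(0.999, 0.4)))
  expect_equal(baseline_treatment_support(kg, "metformin", "t2d"), 0.999)
  # pair absent, and pair present under a non-treatment theme only -> 0
  expect_equal(baseline_treatment_support(kg, "metformin", "other"), 0)

  # linear-scan oracle on random graphs
  for (s in 1:20) {
    kg <- random_kg(seed = s, n_triples = 50)
    drugs <- names(kg$entities)[kg$entities == "drug"]
    dis <- names(kg$entities)[kg$entities == "disease"]
    for (i in 1:10) {
      d <- sample(drugs, 1); z <- sample(dis, 1)
      tr <- kg$triples
      hit <- tr$theme == "T" &
        ((tr$head == d & tr$tail == z) | (tr$head == z & tr$tail == d))
      want <- if (any(hit)) max(tr$support[hit]) else 0
      expect_equal(baseline_treatment_support(kg, d, z), want)
    }
  }
})

test_that("AUROC equals pairwise concordance and curves behave", {
  # perfect separation
  ev <- evaluate_gold_standard(c(3, 4, 5), c(0, 1, 2))
  expect_equal(ev$auroc, 1)
  expect_equal(ev$aupr, 1)
  # constant scores: all ties, half credit
  ev <- evaluate_gold_standard(rep(1, 10), rep(1, 15))
  expect_equal(ev$auroc, 0.5)

  for (s in 1:100) {
    set.seed(s)
    pos <- round(rnorm(30), 1)  # rounding forces ties across lists
    neg <- round(rnorm(30, -0.3), 1)
    ev <- evaluate_gold_standard(pos, neg)
    expect_equal(ev$auroc, auroc_pairwise(pos, neg), tolerance = 1e-12)
    # trapezoid under the returned ROC points equals the same number
    roc <- ev$roc_points
    trap <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                   utils::tail(roc$tpr, -1)) / 2)
    expect_equal(trap, ev$auroc, tolerance = 1e-12)
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
    expect_equal(utils::tail(roc$tpr, 1), 1)
    expect_true(ev$aupr >= 0 && ev$aupr <= 1)
  }

  # independent library cross-check of the AUROC
  set.seed(17)
  pos <- rnorm(50); neg <- rnorm(50, -0.4)
  got <- evaluate_gold_standard(pos, neg)$auroc
  ref <- suppressMessages(pROC::auc(
    response = rep(c(1, 0), each = 50), predictor = c(pos, neg),
    direction = "<"))
  expect_equal(got, as.numeric(ref), tolerance = 1e-12)

  # invariance under strictly monotone transforms
  set.seed(9)
  pos <- rnorm(40); neg <- rnorm(40, -0.5)
  a <- evaluate_gold_standard(pos, neg)$auroc
  b <- evaluate_gold_standard(exp(pos), exp(neg))$auroc
  expect_equal(a, b)

  expect_error(evaluate_gold_standard(numeric(0), 1), "nonempty")
})

test_that("negative pair sampling avoids gold pairs and is uniform", {
  gold <- gold_standard(rep(paste0("d", 1:4), each = 2),
                        rep(paste0("z", 1:2), 4))
  # every (drug, disease) combination is a known indication -> no negatives
  expect_error(sample_negative_pairs(gold, 1), "valid negative")

  gold <- gold_standard(paste0("d", 1:5), paste0("z", 1:5))  # diagonal
  neg <- sample_negative_pairs(gold, 15, seed = 3)
  expect_equal(nrow(neg), 15)
  expect_false(any(paste(neg$drug, neg$disease) %in%
                     paste(gold$drug, gold$disease)))
  expect_equal(anyDuplicated(paste(neg$drug, neg$disease)), 0)
  # determinism
  expect_identical(neg, sample_negative_pairs(gold, 15, seed = 3))

  # marginal uniformity over the universes (drawn without the no-dup
  # constraint binding: ask for few pairs from a large universe)
  gold2 <- gold_standard(paste0("d", 1:10), paste0("z", 1:10))
  counts_d <- integer(10); names(counts_d) <- paste0("d", 1:10)
  for (s in 1:2000) {
    n1 <- sample_negative_pairs(gold2, 5, seed = s)
    tt <- table(factor(n1$drug, levels = names(counts_d)))
    counts_d <- counts_d + as.integer(tt)
  }
  expect_gt(stats::chisq.test(counts_d)$p.value, 0.01)
})

test_that("theme similarity clusters planted groups and flags zero norms", {
  # two planted clusters of theme vectors
  base1 <- c(1, 0.2, 0, 0); base2 <- c(0, 0, 1, -0.4)
  R <- rbind("T" = base1 + 0.01, "C" = base1 * 2 + 0.02,
             "U" = base2 - 0.01, "Y" = base2 * 3)
  m <- ukge_model(matrix(rnorm(8), 2, 4,
                         dimnames = list(c("a", "b"), NULL)), R)
  ts <- theme_similarity(m)
  expect_equal(diag(ts$matrix), rep(1, 4), ignore_attr = TRUE)
  expect_equal(ts$matrix, t(ts$matrix))
  expect_equal(ts$matrix["T", "T"], 1)
  expect_lt(abs(ts$matrix["T", "U"]), 0.3)
  # clustering separates the two groups: cut at k=2
  grp <- stats::cutree(ts$hclust, k = 2)
  expect_equal(grp[["T"]], grp[["C"]])
  expect_equal(grp[["U"]], grp[["Y"]])
  expect_false(grp[["T"]] == grp[["U"]])
  # leaf order keeps cluster members adjacent
  pos <- match(c("T", "C", "U", "Y"), ts$order)
  expect_equal(abs(pos[1] - pos[2]), 1)
  expect_equal(abs(pos[3] - pos[4]), 1)

  # orthogonal singleton similarity
  R2 <- rbind("T" = c(1, 0), "U" = c(0, 1))
  m2 <- ukge_model(matrix(rnorm(4), 2, 2,
                          dimnames = list(c("a", "b"), NULL)), R2)
  expect_equal(theme_similarity(m2)$matrix["T", "U"], 0)

  R3 <- rbind("T" = c(1, 0), "U" = c(0, 0))
  m3 <- ukge_model(m2$entities, R3)
  expect_error(theme_similarity(m3), "U")
})

test_that("per-theme precision at recall matches hand enumeration", {
  # perfectly ranked: precision 1 at all recall levels for theme T
  ents <- c(paste0("d", 1:3), paste0("z", 1:2))
  m <- random_model(entities = ents, themes = c("T", "Sa"), d = 4,
                    seed = 5)
  pairs <- expand.grid(drug = paste0("d", 1:3), disease = paste0("z", 1:2),
                       stringsAsFactors = FALSE)
  sc <- test_score(m, pairs$drug, "T", pairs$disease)
  labels <- sc >= stats::median(sc)  # top half are the positives
  pr <- per_theme_precision_at_recall(m, pairs, labels,
                                      recall_levels = c(0.5, 1))
  expect_equal(unname(pr["T", ]), c(1, 1))

  # hand-enumerated 6-pair case via a stub model is awkward; check the
  # internal curve routine directly against hand values instead
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  labels <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE)
  # descending: TP at thresholds: 1,1,2,3,3,3 ; sets of size 1..6
  got <- kgrepurpose:::precision_at_recall_one(
    scores, labels, c(1 / 3, 2 / 3, 1))
  expect_equal(got, c(1, 2 / 3, 3 / 4))
  # unreachable level marked NA, not an error
  expect_true(is.na(kgrepurpose:::precision_at_recall_one(
    scores, labels, 1.5)))

  # label-independent scores at recall 1 give precision = prevalence
  set.seed(8)
  sc <- rnorm(400)
  lab <- rep(c(TRUE, FALSE), 200)
  # the qualifying set ends at the last-ranked positive, so precision is
  # only approximately the prevalence
  got <- kgrepurpose:::precision_at_recall_one(sc, lab, 1)
  expect_equal(got, 0.5, tolerance = 0.05)
})
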