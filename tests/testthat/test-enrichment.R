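# Over-representation analysis and DAG-based redundancy pruning.

.toy_annotation <- function() {
  ann <- data.frame(
    term = c("T1", "T1", "T1", "T1", "T2", "T2", "T3"),
    gene = c("a", "b", "b", "c", "b", "d", "e"),
    evidence = c("IDA", "IEA", "IDA", "EXP", "IEA", "IMP", "IEA")
  )
  dag <- data.frame(child = c("T2", "T3"), parent = c("T1", "T1"))
  annotation_set(ann, dag)
}

test_that("evidence filtering keeps pairs with at least one experimental code", {
  x <- .toy_annotation()
  y <- filter_evidence(x)
  kept <- unique(y$annotations[, c("term", "gene")])
  # (T1,b) survives through IDA despite its IEA row; IEA-only pairs vanish
  expect_setequal(paste(kept$term, kept$gene),
                  c("T1 a", "T1 b", "T1 c", "T2 d"))
  empty <- filter_evidence(x, allowed = character())
  expect_equal(nrow(empty$annotations), 0L)
  bad <- annotation_set(data.frame(term = "T1", gene = "a",
                                   evidence = "BOGUS"))
  expect_warning(filter_evidence(bad), "unknown evidence")
})

test_that("Fisher enrichment p-values match exhaustive fixed-margin enumeration", {
  # the 2x2 table (3,1 / 1,3): one-sided tail = 17/70
  ann <- annotation_set(data.frame(term = "T", gene = letters[1:4],
                                   evidence = "EXP"))
  res <- fisher_enrichment(study = letters[1:4],
                           background = letters[1:8], ann)
  # k=4 study genes in term of n=4, K=4, N=8: p = 1/C(8,4)
  expect_equal(res$p, 1 / choose(8, 4), tolerance = 1e-12)
  res2 <- fisher_enrichment(study = c("a", "b", "c", "e"),
                            background = letters[1:8], ann)
  expect_equal(res2$p, 17 / 70, tolerance = 1e-12)
  expect_equal(res2$p, oracle_fisher(3, 4, 4, 8, "greater"),
               tolerance = 1e-12)
  # a term containing the whole background can never be enriched
  res3 <- fisher_enrichment(study = c("a", "b"),
                            background = letters[1:4], ann)
  expect_equal(res3$p, 1)
})

test_that("enrichment on random tables agrees with the enumeration oracle", {
  withr::with_seed(61, {
    for (rep in 1:50) {
      N <- sample(8:30, 1)
      K <- sample(2:(N - 2), 1)
      n <- sample(2:(N - 2), 1)
      bg <- sprintf("g%02d", seq_len(N))
      study <- sample(bg, K)
      term_genes <- sample(bg, N - n)  # complement defines the term
      term_genes <- setdiff(bg, term_genes)[seq_len(n)]
      k <- length(intersect(study, term_genes))
      if (k == 0) next
      ann <- annotation_set(data.frame(term = "T", gene = term_genes,
                                       evidence = "EXP"))
      got <- fisher_enrichment(study, bg, ann)
      expect_equal(got$p, oracle_fisher(k, K, n, N, "greater"),
                   tolerance = 1e-12)
      expect_equal(got$k, k)
    }
  })
})

test_that("enrichment is invariant to gene-list order and validates the universe", {
  ann <- .toy_annotation()
  bg <- c("a", "b", "c", "d", "e", "f")
  r1 <- fisher_enrichment(c("a", "b", "d"), bg, ann)
  r2 <- fisher_enrichment(c("d", "a", "b"), rev(bg), ann)
  expect_equal(r1, r2)
  expect_error(fisher_enrichment(c("a", "zz"), bg, ann), "subset")
})

test_that("literal child-discarding keeps the ancestor of a significant chain", {
  recs <- data.frame(term = c("T1", "T2", "T3"),
                     significant = c(TRUE, TRUE, FALSE))
  dag <- data.frame(child = c("T2", "T3"), parent = c("T1", "T1"))
  out <- discard_child_terms(recs, dag)
  expect_setequal(out$term, c("T1", "T3"))      # child T2 dropped, T1 kept
  out2 <- discard_child_terms(recs, dag, mode = "drop_ancestors")
  expect_setequal(out2$term, c("T2", "T3"))     # ancestor T1 dropped
  # unrelated significant terms both survive
  recs3 <- data.frame(term = c("A", "B"), significant = c(TRUE, TRUE))
  expect_equal(nrow(discard_child_terms(recs3, dag)), 2L)
  cyc <- data.frame(child = c("X", "Y"), parent = c("Y", "X"))
  expect_error(discard_child_terms(recs3, cyc), "cycle")
})

test_that("surviving significant terms form an antichain on random DAGs", {
  withr::with_seed(62, {
    for (rep in 1:20) {
      nterm <- sample(5:12, 1)
      terms <- sprintf("T%02d", seq_len(nterm))
      # random DAG: edges only from higher to lower index (acyclic)
      pairs <- t(utils::combn(nterm, 2))
      take <- stats::runif(nrow(pairs)) < 0.3
      dag <- data.frame(child = terms[pairs[take, 2]],
                        parent = terms[pairs[take, 1]])
      recs <- data.frame(term = terms,
                         significant = stats::runif(nterm) < 0.5)
      if (nrow(dag) == 0 || !any(recs$significant)) next
      out <- discard_child_terms(recs, dag)
      surv <- out$term[out$significant]
      # transitive-closure oracle: no surviving term is an ancestor of another
      g <- igraph::graph_from_data_frame(dag, directed = TRUE,
                                         vertices = terms)
      d <- igraph::distances(g, mode = "out")
      for (a in surv) for (b in surv)
        if (a != b) expect_false(is.finite(d[a, b]))
      # every dropped significant term has a surviving significant ancestor
      dropped <- setdiff(recs$term[recs$significant], surv)
      sig <- recs$term[recs$significant]
      for (t in dropped)
        expect_true(any(is.finite(d[t, setdiff(sig, t)])))
    }
  })
})
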