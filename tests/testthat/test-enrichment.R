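# independent oracle: enumerate all tables with fixed margins from
# binomial coefficients (no dhyper), minimum-likelihood two-sided rule
enum_fisher_p <- function(k, n, K, N) {
  kk <- max(0, n + K - N):min(n, K)
  lp <- lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)
  probs <- exp(lp)
  min(1, sum(probs[probs <= probs[kk == k] * (1 + 1e-7)]))
}

test_that("fisher p matches stats::fisher.test on random tables", {
  set.seed(91)
  for (i in 1:200) {
    N <- sample(10:200, 1)
    n <- sample(1:(N - 1), 1)
    K <- sample(1:(N - 1), 1)
    k <- sample(max(0, n + K - N):min(n, K), 1)
    tab <- matrix(c(k, n - k, K - k, N - n - K + k), 2)
    expect_equal(fisher_exact_p(k, n, K, N),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-12)
  }
})

test_that("fisher p agrees with exhaustive enumeration and handles edge cases", {
  expect_equal(fisher_exact_p(5, 10, 10, 100), enum_fisher_p(5, 10, 10, 100))
  # equal proportions: the observed table is modal, two-sided p = 1
  expect_equal(fisher_exact_p(1, 10, 10, 100), 1.0)
  expect_equal(fisher_exact_p(2, 10, 20, 100), 1.0)
  expect_error(fisher_exact_p(11, 10, 10, 100), "impossible")
})

test_that("per-margin p vector matches per-table calls", {
  p_vec <- fisher_p_margin(8, 12, 40)
  kk <- max(0, 8 + 12 - 40):min(8, 12)
  expect_equal(p_vec, vapply(kk, function(k) enum_fisher_p(k, 8, 12, 40),
                             numeric(1)))
})

make_ann <- function(df) {
  df$term_name <- paste("name of", df$term_id)
  tibble::as_tibble(df)
}

test_that("enrichment builds correct 2x2 tables and skips empty terms", {
  background <- paste0("p", 1:100)
  diff <- paste0("p", 1:10)
  ann <- make_ann(data.frame(
    protein_id = c(paste0("p", 1:5), paste0("p", 50:54),   # T1: k=5, K=10
                   paste0("p", 60:69)),                    # T2: k=0
    namespace = "KEGG",
    term_id = rep(c("T1", "T2"), each = 10)))
  res <- fisher_enrich(diff, background, ann, "KEGG")
  expect_equal(nrow(res), 1)   # T2 skipped, no differential carrier
  expect_equal(res$k, 5); expect_equal(res$K, 10)
  expect_equal(res$n, 10); expect_equal(res$N, 100)
  expect_equal(res$fold_enrichment, (5 / 10) / (10 / 100))
  expect_equal(res$p_value, enum_fisher_p(5, 10, 10, 100))
  expect_true(res$significant)
  expect_error(fisher_enrich(c(diff, "absent"), background, ann, "KEGG"),
               "subset")
})

test_that("BH adjustment preserves the p-value ordering", {
  set.seed(5)
  background <- paste0("p", 1:80)
  diff <- paste0("p", 1:15)
  ann <- make_ann(data.frame(
    protein_id = sample(background, 300, replace = TRUE),
    namespace = "GO-BP",
    term_id = sample(paste0("T", 1:12), 300, replace = TRUE)))
  ann <- ann[!duplicated(ann[c("protein_id", "term_id")]), ]
  res <- fisher_enrich(diff, background, ann, "GO-BP")
  expect_equal(order(res$p_value), order(res$p_adj))
  expect_true(all(res$p_adj >= res$p_value))
})

test_that("label permutation keeps the false-positive rate controlled", {
  # with planted structure destroyed, terms significant at raw p < 0.05
  # should not exceed the nominal rate (Fisher is conservative when discrete)
  set.seed(17)
  background <- paste0("p", 1:100)
  ann <- make_ann(data.frame(
    protein_id = rep(background, each = 3),
    namespace = "GO-BP",
    term_id = as.vector(replicate(100, sample(paste0("T", 1:20), 3)))))
  ann <- ann[!duplicated(ann[c("protein_id", "term_id")]), ]
  n_sig <- 0L; n_terms <- 0L
  for (perm in 1:200) {
    diff <- sample(background, 15)
    res <- fisher_enrich(diff, background, ann, "GO-BP")
    n_sig <- n_sig + sum(res$significant)
    n_terms <- n_terms + nrow(res)
  }
  rate <- n_sig / n_terms
  se <- sqrt(0.05 * 0.95 / n_terms)
  expect_lte(rate, 0.05 + 2 * se)
})

test_that("Q-group enrichment matrix is clustered and keeps planted terms on top", {
  set.seed(23)
  n_prot <- 60
  prots <- paste0("p", 1:n_prot)
  q1 <- prots[1:20]
  records <- tibble::tibble(
    site_id = paste0(prots, "_K1"), protein_id = prots,
    fc = ifelse(prots %in% q1, 0.3, 1), cv = 0.01,
    regulation = ifelse(prots %in% q1, "DOWN", "NS"),
    q_group = ifelse(prots %in% q1, "Q1", "NONE"))
  # planted: 80% of Q1 proteins carry TPLANT vs 10% of the rest
  carriers <- c(q1[runif(20) < 0.8], setdiff(prots, q1)[runif(40) < 0.1])
  ann <- make_ann(data.frame(
    protein_id = c(carriers, sample(prots, 30, replace = TRUE)),
    namespace = "GO-BP",
    term_id = rep(c("TPLANT", "TOTHER"), c(length(carriers), 30))))
  ann <- ann[!duplicated(ann[c("protein_id", "term_id")]), ]
  out <- q_group_enrichment(records, ann, "GO-BP")
  expect_equal(colnames(out$matrix), "Q1")
  top_term <- rownames(out$matrix)[which.max(out$matrix[, "Q1"])]
  expect_equal(top_term, "TPLANT")
  expect_true(all(out$matrix >= 0, na.rm = TRUE))
  # identical groups give identical columns
  rec2 <- records; rec2$q_group[rec2$q_group == "Q1"] <- "Q2"
  both <- rbind(records[records$q_group == "Q1", ], rec2[rec2$q_group == "Q2", ])
  both <- rbind(both, records[records$regulation == "NS", ])
  out2 <- q_group_enrichment(both, ann, "GO-BP")
  expect_equal(out2$matrix[, "Q1"], out2$matrix[, "Q2"])
})

test_that("category summary counts multi-label proteins once per term", {
  ann <- make_ann(data.frame(
    protein_id = c("p1", "p2", "p3", "p4", "p5", "p1"),
    namespace = "COMPARTMENT",
    term_id = c(rep("cytoplasm", 5), "nucleus")))
  out <- category_summary(paste0("p", 1:10), ann, "COMPARTMENT")
  expect_equal(out$count[out$term_id == "cytoplasm"], 5)
  expect_equal(out$percent[out$term_id == "cytoplasm"], 50)
  expect_equal(out$count[out$term_id == "nucleus"], 1)
  expect_equal(sum(out$count), 6)  # p1 counted in both terms
  empty <- category_summary(paste0("p", 1:10),
                            ann[0, ], "COMPARTMENT")
  expect_equal(nrow(empty), 0)
})
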