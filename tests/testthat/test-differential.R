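rel <- function(values) {
  m <- matrix(values, ncol = 4, byrow = TRUE,
              dimnames = list(paste0("s", seq_len(length(values) / 4)),
                              c("C1", "C2", "SA1", "SA2")))
  m
}
A <- c("SA1", "SA2"); B <- c("C1", "C2")

test_that("fold change is the ratio of group means of observed values", {
  m <- rel(c(5, 5, 10, 20,      # fc 15/5 = 3
             2, 2, 2, 2,        # identity
             4, NA, 6, NA))     # observed-only means: 6/4
  fc <- fold_change(m, A, B)
  expect_equal(unname(fc), c(3, 1, 1.5))
})

test_that("fold change matches a brute-force mean-ratio oracle", {
  set.seed(11)
  m <- random_rel_matrix(20, seed = 11, missing_rate = 0.15)
  fc <- fold_change(m, A, B)
  for (i in seq_len(nrow(m))) {
    xa <- c(); xb <- c()
    for (s in A) if (!is.na(m[i, s])) xa <- c(xa, m[i, s])
    for (s in B) if (!is.na(m[i, s])) xb <- c(xb, m[i, s])
    expected <- if (!length(xa) || !length(xb)) NA_real_
                else (sum(xa) / length(xa)) / (sum(xb) / length(xb))
    expect_equal(unname(fc[i]), expected)
  }
})

test_that("fold change is antisymmetric on complete data", {
  m <- random_rel_matrix(50, seed = 3)
  expect_equal(unname(fold_change(m, A, B) * fold_change(m, B, A)),
               rep(1, 50))
})

test_that("CV of paired replicate ratios follows the n-1 formula", {
  m <- rel(c(1, 1, 2, 2,      # ratios [2,2] -> cv 0
             1, 1, 1, 3,      # ratios [1,3]: mean 2, sd sqrt(2)
             2, 2, 4, 6))     # ratios [2,3]: mean 2.5, sd 1/sqrt(2)
  cv <- cv_statistic(m, A, B)$cv
  expect_equal(unname(cv), c(0, sqrt(2) / 2, (1 / sqrt(2)) / 2.5))
  expect_equal(unname(cv[2]), 0.70711, tolerance = 1e-5)
  expect_equal(unname(cv[3]), 0.28284, tolerance = 1e-5)
})

test_that("CV needs two complete pairs and is scale invariant", {
  m <- rel(c(1, NA, 2, 2))    # only the (C1, SA1) pair is complete
  expect_true(is.na(cv_statistic(m, A, B)$cv))
  expect_equal(cv_statistic(m, A, B)$n_pairs[[1]], 1)

  m2 <- random_rel_matrix(20, seed = 5)
  base <- cv_statistic(m2, A, B)$cv
  m2[, c(A, B)] <- m2[, c(A, B)] * 7.3   # common factor cancels in ratios
  expect_equal(cv_statistic(m2, A, B)$cv, base)
})

test_that("t-test requires three observations per group, handles degeneracy", {
  # duplicate designs give no p-value
  expect_true(all(is.na(site_t_test(random_rel_matrix(5), A, B))))

  m6 <- matrix(c(1, 1.1, 0.9, 1, 1.1, 0.9), 1,
               dimnames = list("s1", paste0("x", 1:6)))
  p <- site_t_test(m6, paste0("x", 1:3), paste0("x", 4:6))
  expect_equal(unname(p), 1)   # identical groups: t = 0
  flat <- matrix(2, 1, 6, dimnames = dimnames(m6))
  expect_equal(unname(site_t_test(flat, paste0("x", 1:3), paste0("x", 4:6))), 1)
})

test_that("a planted log2 shift of 2 at sigma 0.1 is detected with n=3", {
  set.seed(21)
  hits <- 0L
  n_sim <- 500L
  for (i in seq_len(n_sim)) {
    a <- 2^rnorm(3, 2, 0.1); b <- 2^rnorm(3, 0, 0.1)
    m <- matrix(c(b, a), 1, dimnames = list("s1", paste0("x", 1:6)))
    p <- site_t_test(m, paste0("x", 4:6), paste0("x", 1:3))
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_sim, 0.99)
})

test_that("regulation calls follow the fc/cv/p gates", {
  # CV route (no p-value, duplicate design)
  expect_equal(call_regulation(1.6, cv = 0.05), "UP")
  expect_equal(call_regulation(0.5, cv = 0.05), "DOWN")
  expect_equal(call_regulation(1.6, cv = 0.5), "NS")     # irreproducible
  expect_equal(call_regulation(1.5, cv = 0.05), "NS")    # threshold is strict
  expect_equal(call_regulation(1 / 1.5, cv = 0.05), "NS")
  # p-value route takes precedence when defined
  expect_equal(call_regulation(1.6, cv = 0.5, p = 0.01), "UP")
  expect_equal(call_regulation(1.6, cv = 0.05, p = 0.5), "NS")
  # undefined everything
  expect_equal(call_regulation(2), "NS")
})

test_that("Q groups bin regulated sites by fold-change magnitude", {
  expect_equal(assign_q_group(0.4, "DOWN"), "Q1")
  expect_equal(assign_q_group(0.6, "DOWN"), "Q2")
  expect_equal(assign_q_group(1.8, "UP"), "Q3")
  expect_equal(assign_q_group(2.5, "UP"), "Q4")
  expect_equal(assign_q_group(1.2, "NS"), "NONE")
  expect_equal(assign_q_group(0.5, "DOWN"), "Q1")   # boundary fc = 1/2
  expect_equal(assign_q_group(2, "UP"), "Q3")       # boundary fc = 2
})

test_that("swapping groups mirrors regulation and Q groups", {
  set.seed(13)
  m <- random_rel_matrix(200, seed = 13)
  fc_ab <- fold_change(m, A, B); fc_ba <- fold_change(m, B, A)
  cv_ab <- cv_statistic(m, A, B)$cv; cv_ba <- cv_statistic(m, B, A)$cv
  reg_ab <- call_regulation(fc_ab, cv_ab)
  reg_ba <- call_regulation(fc_ba, cv_ba)
  # the CV of reciprocal ratios differs, so mirror only reproducible sites
  both <- cv_ab < 0.1 & cv_ba < 0.1
  expect_equal(reg_ab[both] == "UP", reg_ba[both] == "DOWN")
  q_ab <- assign_q_group(fc_ab, reg_ab)
  q_ba <- assign_q_group(fc_ba, reg_ba)
  map <- c(Q1 = "Q4", Q2 = "Q3", Q3 = "Q2", Q4 = "Q1", NONE = "NONE")
  expect_equal(unname(map[q_ab[both]]), unname(q_ba[both]))
})

test_that("heatmap completeness filter applies the 2/3-of-samples rule", {
  m <- rel(c(5, 5, 10, 20,
             5, NA, 10, 20,
             5, NA, NA, 20))
  rec <- tibble::tibble(site_id = paste0("s", 1:3),
                        regulation = c("UP", "UP", "UP"))
  kept <- heatmap_filter(rec, m)          # need ceil(8/3) = 3 of 4
  expect_equal(kept$site_ids, c("s1", "s2"))
  expect_equal(dim(kept$matrix), c(2, 4))
  # non-significant sites never enter the heatmap
  rec$regulation[1] <- "NS"
  expect_equal(heatmap_filter(rec, m)$site_ids, "s2")
})

test_that("top sites rank by |log2 fc| with cv then id tie-breaks", {
  rec <- tibble::tibble(site_id = c("a", "b", "c"),
                        fc = c(4, 0.2, 1.6), cv = c(0.01, 0.01, 0.01),
                        regulation = "UP")
  expect_equal(top_n_sites(rec, 2)$site_id, c("b", "a"))
  expect_equal(nrow(top_n_sites(rec, 10)), 3)      # n beyond record count
  tie <- tibble::tibble(site_id = c("x", "y"), fc = c(2, 0.5),
                        cv = c(0.08, 0.02), regulation = c("UP", "DOWN"))
  expect_equal(top_n_sites(tie, 2)$site_id, c("y", "x"))
})

test_that("planted UP sites are recovered and null sites stay quiet", {
  up_hit <- 0L; up_tot <- 0L; false_calls <- 0L; null_tot <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    n <- 200L
    truth_up <- seq_len(50)
    fc_true <- rep(1, n); fc_true[truth_up] <- 3
    noise <- function(k) 2^rnorm(k, 0, 0.05)
    m <- cbind(C1 = noise(n), C2 = noise(n),
               SA1 = fc_true * noise(n), SA2 = fc_true * noise(n))
    rownames(m) <- paste0("s", 1:n)
    r <- centralize(m)
    fc <- fold_change(r, A, B); cv <- cv_statistic(r, A, B)$cv
    reg <- call_regulation(fc, cv)
    up_hit <- up_hit + sum(reg[truth_up] == "UP")
    up_tot <- up_tot + length(truth_up)
    false_calls <- false_calls + sum(reg[-truth_up] != "NS")
    null_tot <- null_tot + (n - length(truth_up))
  }
  expect_gte(up_hit / up_tot, 0.95)
  expect_lte(false_calls / null_tot, 0.05)
})
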