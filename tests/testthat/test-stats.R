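test_that("identical groups give H = 0 and exact permutation p = 1", {
  res <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)), p_method = "exact")
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)
})

test_that("fully separated tiny groups recover the enumeration p-values", {
  # [1,2,3] vs [4,5,6]: the extreme rank split occurs twice in C(6,3) = 20
  res <- kruskal_wallis(list(1:3, 4:6), p_method = "exact")
  expect_equal(res$p.value, 2 / 20)
  # n = 6 per group, complete separation: 2 / C(12,6)
  res6 <- kruskal_wallis(list(1:6, 11:16), p_method = "exact")
  expect_equal(res6$p.value, 2 / choose(12, 6))
})

test_that("H matches both the textbook rank-ANOVA oracle and stats::kruskal.test", {
  set.seed(41)
  for (i in 1:60) {
    k <- sample(2:4, 1)
    samples <- lapply(seq_len(k), function(j) {
      n <- sample(2:6, 1)
      # integer draws force ties often
      sample(1:8, n, replace = TRUE)
    })
    if (length(unique(unlist(samples))) < 2) next
    res <- kruskal_wallis(samples)
    expect_equal(res$statistic, kw_h_oracle(samples), tolerance = 1e-12)
    ref <- stats::kruskal.test(unlist(samples),
                               factor(rep(seq_len(k), lengths(samples))))
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p.value, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("two-group exact permutation p matches the exact Wilcoxon rank-sum", {
  # on tie-free data the two-group H is a monotone function of the
  # rank-sum distance from its null mean, and the null rank-sum
  # distribution is symmetric, so the two-sided exact Wilcoxon p equals
  # the H-enumeration p
  set.seed(17)
  for (i in 1:40) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- sample(seq(0.1, 50, by = 0.1), n1 + n2)  # distinct values
    res <- kruskal_wallis(list(x[1:n1], x[-(1:n1)]), p_method = "exact")
    ref <- stats::wilcox.test(x[1:n1], x[-(1:n1)], exact = TRUE)
    expect_equal(res$p.value, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("degenerate all-equal input warns and returns H = 0, p = 1", {
  expect_warning(res <- kruskal_wallis(list(c(5, 5), c(5, 5, 5))),
                 "degenerate")
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)
  expect_error(kruskal_wallis(list(numeric(0), 1:3)), ">= 1 observation")
  expect_error(kruskal_wallis(list(1:3)), ">= 2 groups")
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(9)
  samples <- list(rnorm(8), rnorm(5, 1), rnorm(6, -1))
  h1 <- kruskal_wallis(samples)$statistic
  h2 <- kruskal_wallis(lapply(samples, function(x) exp(x / 3)))$statistic
  h3 <- kruskal_wallis(lapply(samples, function(x) x^3))$statistic
  expect_equal(h1, h2, tolerance = 1e-12)
  expect_equal(h1, h3, tolerance = 1e-12)
})

test_that("Monte-Carlo permutation p approximates the exact one", {
  x <- list(c(1.2, 3.4, 2.2, 5.1, 0.4), c(4.4, 6.2, 5.9, 8.0, 3.3))
  pe <- kruskal_wallis(x, p_method = "exact")$p.value
  pm <- kruskal_wallis(x, p_method = "montecarlo", n_perm = 4000,
                       seed = 2)$p.value
  expect_lt(abs(pe - pm), 0.03)
  expect_error(kruskal_wallis(list(1:3, 4:6, 7:9), p_method = "exact"),
               "two groups")
})

test_that("pairwise matrices are symmetric with flags matching alpha", {
  specs <- default_study_specs()[c("untreated mice", "white soft paraffin",
                                   "celecoxib 2%")]
  tab <- generate_study(specs, seed = 6)
  pw <- pairwise_comparisons(tab, "orthokeratosis", unit = "animal")
  expect_equal(pw$p, t(pw$p))
  expect_identical(pw$flags, t(pw$flags))
  off <- !is.na(pw$p)
  expect_true(all(pw$p[off] > 0 & pw$p[off] <= 1))
  expect_identical(pw$flags[off], ifelse(pw$p[off] <= pw$alpha, "S", "N"))
  expect_true(all(is.na(diag(pw$p))))
  expect_equal(nrow(pw$long), choose(3, 2))
  # an overwhelming effect at n = 6 per group hits the enumeration floor
  expect_equal(pw$p["untreated mice", "celecoxib 2%"], 2 / choose(12, 6))
})

test_that("pairwise endpoint/unit aggregation and guards behave", {
  specs <- default_study_specs()[c("white soft paraffin", "celecoxib 2%")]
  tab <- generate_study(specs, seed = 13)
  for (ep in c("orthokeratosis", "thickness")) {
    for (un in c("animal", "scale", "reading")) {
      pw <- pairwise_comparisons(tab, ep, unit = un, exact = FALSE)
      expect_equal(dim(pw$p), c(2L, 2L))
    }
  }
  one_animal <- tab[tab$group == "white soft paraffin" & tab$animal == 1 |
                      tab$group == "celecoxib 2%", ]
  expect_error(pairwise_comparisons(one_animal, unit = "animal"),
               "white soft paraffin")
})

test_that("identical zero-variance groups yield a degenerate non-significant pair", {
  sp <- group_spec("a", 30, 0, 25, 0)
  sp2 <- group_spec("b", 30, 0, 25, 0)
  tab <- rbind(generate_measurements(sp, 1), generate_measurements(sp2, 2))
  pw <- pairwise_comparisons(tab, "orthokeratosis", unit = "animal")
  expect_equal(pw$p["a", "b"], 1)
  expect_identical(pw$flags["a", "b"], "N")
})

test_that("multiple-testing adjustment never decreases p-values", {
  specs <- default_study_specs()[c("untreated mice", "diclofenac 1%",
                                   "celecoxib 2%")]
  tab <- generate_study(specs, seed = 19)
  p0 <- pairwise_comparisons(tab, "orthokeratosis")$long$p
  for (adj in c("holm", "BH")) {
    pa <- pairwise_comparisons(tab, "orthokeratosis", adjust = adj)$long$p
    expect_true(all(pa >= p0 - 1e-12))
  }
})

test_that("pairwise rendering carries the S/N footnote and long CSV layout", {
  specs <- default_study_specs()[c("white soft paraffin", "celecoxib 2%")]
  tab <- generate_study(specs, seed = 2)
  pw <- pairwise_comparisons(tab, "orthokeratosis")
  md <- format_pairwise_table(pw)
  expect_match(md[length(md)], "S = statistically significant")
  f <- tempfile(fileext = ".csv")
  write_pairwise(pw, f)
  back <- read.csv(f)
  expect_named(back, c("group_a", "group_b", "p", "flag"))
})
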