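test_that("the hypergeometric tail reproduces the enumerable textbook case", {
  # N=10, K=4, n=5, k=3: [C(4,3)C(6,2) + C(4,4)C(6,1)] / C(10,5) = 66/252
  universe <- letters[1:10]
  term <- letters[1:4]
  query <- c("a", "b", "c", "e", "f")
  expect_equal(term_test(query, term, universe, "fisher"), 66 / 252,
               tolerance = 1e-12)

  # no overlap -> the upper tail is certain
  expect_equal(term_test(c("e", "f"), term, universe, "fisher"), 1)

  # query = universe forces full overlap with probability one
  expect_equal(term_test(universe, term, universe, "fisher"), 1)

  expect_error(term_test("a", "a", character(0)), "empty")
})

test_that("EASE is never more significant than Fisher for k >= 1", {
  for (seed in 1:30) {
    set.seed(seed)
    N <- sample(5:15, 1)
    universe <- sprintf("u%02d", 1:N)
    term <- sample(universe, sample(1:N, 1))
    query <- sample(universe, sample(1:N, 1))
    pf <- term_test(query, term, universe, "fisher")
    pe <- term_test(query, term, universe, "ease")
    expect_gte(pe, pf - 1e-15)
  }
})

test_that("p-values equal the exhaustive enumeration oracle for all small configurations", {
  n_cases <- 0
  for (N in c(4, 6, 9, 12)) {
    universe <- sprintf("u%02d", 1:N)
    for (K in 0:N) {
      term <- universe[seq_len(K)]
      for (n in 1:N) {
        for (k in 0:min(K, n)) {
          if (n - k > N - K) next
          query <- c(universe[seq_len(k)],
                     if (n > k) universe[K + seq_len(n - k)])
          expect_equal(term_test(query, term, universe, "fisher"),
                       oracle_hyper_enum(N, K, n, k), tolerance = 1e-12)
          expect_equal(term_test(query, term, universe, "ease"),
                       oracle_hyper_enum(N, K, n, max(k - 1, 0)),
                       tolerance = 1e-12)
          n_cases <- n_cases + 1
        }
      }
    }
  }
  expect_gt(n_cases, 300)
})

test_that("Bonferroni correction and reporting gates behave as specified", {
  universe <- sprintf("u%02d", 1:20)
  ann <- term_map(
    tibble::tibble(
      term_id = rep(c("T1", "T2", "T3"), times = c(6, 5, 4)),
      accession = c(universe[1:6], universe[7:11], universe[12:15])),
    universe = universe)

  # single overlapping term -> m = 1 -> p_corrected = p_raw
  q1 <- universe[1:3]
  out1 <- enrich_terms(q1, ann, variant = "fisher", all_terms = TRUE)
  t1 <- out1[out1$term_id == "T1", ]
  expect_equal(t1$p_corrected, t1$p_raw)

  # a term with count 1 is never reported however small its p
  ann2 <- term_map(tibble::tibble(term_id = "T1", accession = universe[1]),
                   universe = universe)
  out2 <- enrich_terms(universe[1], ann2, variant = "fisher")
  expect_equal(nrow(tibble::as_tibble(out2)), 0)

  # correcting over all terms multiplies by the full term count
  q3 <- universe[1:6]
  m_all <- enrich_terms(q3, ann, variant = "fisher", correct_over = "all",
                        all_terms = TRUE)
  m_ovl <- enrich_terms(q3, ann, variant = "fisher", all_terms = TRUE)
  expect_equal(attr(m_all, "m_tests"), 3)
  expect_equal(attr(m_ovl, "m_tests"), sum(m_ovl$count >= 1))
})

test_that("enrichment output equals a brute-force reimplementation on random maps", {
  for (seed in 1:40) {
    set.seed(seed)
    N <- sample(6:12, 1)
    universe <- sprintf("u%02d", 1:N)
    n_terms <- sample(2:4, 1)
    ann_tab <- dplyr::bind_rows(lapply(seq_len(n_terms), function(i) {
      tibble::tibble(term_id = paste0("T", i),
                     accession = sample(universe, sample(2:N, 1)))
    }))
    ann <- term_map(ann_tab, universe = universe)
    query <- sample(universe, sample(2:N, 1))
    got <- enrich_terms(query, ann, variant = "fisher", all_terms = TRUE)

    # brute force: enumeration-based p per term, Bonferroni over overlapping
    members <- split(ann$annotation$accession, ann$annotation$term_id)
    p_raw <- vapply(members, function(acc) {
      acc <- unique(acc)
      K <- length(acc); n <- length(query)
      k <- length(intersect(acc, query))
      # enumeration on relabelled universe with term first
      oracle_hyper_enum(N, K, n, k)
    }, numeric(1))
    m <- sum(vapply(members, function(acc)
      length(intersect(unique(acc), query)) >= 1, logical(1)))
    for (id in names(members)) {
      row <- got[got$term_id == id, ]
      expect_equal(row$p_raw, unname(p_raw[id]), tolerance = 1e-12)
      expect_equal(row$p_corrected, min(1, unname(p_raw[id]) * max(m, 1)),
                   tolerance = 1e-12)
    }
  }
})

test_that("random queries are approximately calibrated under the null", {
  set.seed(99)
  N <- 60
  universe <- sprintf("u%02d", 1:N)
  ann <- term_map(
    dplyr::bind_rows(lapply(1:8, function(i) {
      tibble::tibble(term_id = paste0("T", i),
                     accession = sample(universe, 12))
    })),
    universe = universe)
  members <- split(ann$annotation$accession, ann$annotation$term_id)
  hits <- 0; total <- 0
  for (i in 1:1000) {
    query <- sample(universe, 10)
    p <- vapply(members, term_test, numeric(1),
                query = query, universe = universe, variant = "fisher")
    hits <- hits + sum(p < 0.05)
    total <- total + length(p)
  }
  expect_lte(hits / total, 0.07)
})
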