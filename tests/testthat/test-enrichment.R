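toy_counts <- function(sc, mw, runs_tbl) {
  acc <- names(mw)
  spectral_counts(
    counts = tibble::tibble(
      accession = rep(acc, times = nrow(runs_tbl)),
      run_id = rep(runs_tbl$run_id, each = length(acc)),
      count = as.integer(sc)),
    proteins = tibble::tibble(accession = acc, molecular_weight = unname(mw)),
    runs = runs_tbl)
}

one_run <- tibble::tibble(run_id = "treatment_A", condition = "treatment")

test_that("NSAF reproduces hand arithmetic and basic invariances", {
  x <- toy_counts(c(8, 2), c(A = 50, B = 100), one_run)
  n <- nsaf(x)
  expect_equal(n$nsaf[n$accession == "A"], 0.16 / 0.18)
  expect_equal(n$nsaf[n$accession == "B"], 0.02 / 0.18)

  # single protein: NSAF = 1 whatever the counts
  x1 <- toy_counts(7, c(A = 123), one_run)
  expect_equal(nsaf(x1)$nsaf, 1)

  # scaling a run's counts leaves NSAF unchanged
  x10 <- toy_counts(c(80, 20), c(A = 50, B = 100), one_run)
  expect_equal(nsaf(x10)$nsaf, n$nsaf)

  # an all-zero run cannot be normalized
  x0 <- toy_counts(c(0, 0), c(A = 50, B = 100), one_run)
  expect_error(nsaf(x0), "treatment_A")
})

two_by_two <- tibble::tibble(
  run_id = c("treatment_A", "treatment_B", "control_A", "control_B"),
  condition = rep(c("treatment", "control"), each = 2))

test_that("protein fold changes follow the mean-ratio definition", {
  # identical counts in all runs -> FC 1 everywhere
  x <- toy_counts(rep(c(4, 6), 4), c(A = 50, B = 80), two_by_two)
  fc <- protein_fold_changes(x)
  expect_equal(fc$fold_change, c(1, 1))

  # control-absent -> +Inf, flagged
  sc <- c(5, 3, 5, 3, 0, 3, 0, 3)  # A: treatment only
  x2 <- toy_counts(sc, c(A = 50, B = 80), two_by_two)
  fc2 <- protein_fold_changes(x2)
  a <- fc2[fc2$accession == "A", ]
  expect_equal(a$fold_change, Inf)
  expect_true(a$control_absent)
})

test_that("the protein filter applies inclusive twofold and six-spectra gates", {
  pol <- threshold_policy()
  # protein A: exactly FC 2 on NSAF and exactly 6 treatment spectra -> passes
  res <- tibble::tibble(
    accession = c("A", "B", "C"),
    mean_treatment = c(0.2, 0.5, 0.1),
    mean_control = c(0.1, 0.05, 0.1),
    fold_change = c(2, 10, 1),
    total_treatment_spectra = c(6L, 5L, 50L),
    control_absent = FALSE)
  out <- filter_proteins(res, pol)
  expect_true(out$passes[out$accession == "A"])
  expect_equal(out$fail_reason[out$accession == "B"], "below_abundance")
  expect_equal(out$fail_reason[out$accession == "C"], "below_fold")
})

test_that("protein pass sets equal the brute-force oracle on random toy tables", {
  for (seed in 1:60) {
    fx <- rand_sc_fixture(seed)
    got <- passing_accessions(suppressMessages(filter_proteins(fx$counts)))
    want <- oracle_protein_pass(fx$mat, fx$mw, fx$cond)
    expect_setequal(got, want)
  }
})

test_that("the adaptive site threshold matches hand arithmetic", {
  pol <- threshold_policy(site_fold_rule = "mean_plus_2sd")
  fcs <- c(2, 2, 2, 2, 2, 20)
  expect_equal(site_fold_threshold(fcs, pol), 5 + 2 * sqrt(54))

  # all equal -> sd 0 -> threshold = the common value
  expect_equal(site_fold_threshold(rep(3, 5), pol), 3)

  # infinite fold changes are excluded from the distribution
  expect_equal(site_fold_threshold(c(fcs, Inf, Inf), pol), 5 + 2 * sqrt(54))

  # fixed rule ignores the data
  expect_equal(site_fold_threshold(c(1, 100), threshold_policy()), 9)

  expect_error(site_fold_threshold(c(2, Inf), pol), "at least 2 finite")
})

test_that("the site filter honours the ninefold and two-spectra gates", {
  runs <- tibble::tibble(run_id = c("treatment_A", "control_A"),
                         condition = c("treatment", "control"))
  win <- function(r) paste0(strrep("A", 7), r, strrep("A", 7))
  tab <- tibble::tibble(
    accession = c("P1", "P2", "P3"), position = c(10L, 20L, 30L),
    residue = "S", window = win("S"),
    localization_score = NA_real_, identification_score = NA_real_,
    treatment_A = c(2L, 89L, 9L), control_A = c(0L, 10L, 1L))
  sites <- phosphosite_table(tab, runs)
  out <- filter_sites(sites, policy = threshold_policy())
  # P1: control-absent with 2 spectra -> passes
  expect_true(out$passes[out$accession == "P1"])
  # P2: FC 8.9 under the fixed ninefold rule -> fails
  expect_false(out$passes[out$accession == "P2"])
  expect_equal(out$fail_reason[out$accession == "P2"], "below_fold")
  # P3: FC 9 exactly -> inclusive boundary passes
  expect_true(out$passes[out$accession == "P3"])
})

test_that("increasing a protein's treatment counts never flips pass to fail", {
  for (seed in 1:20) {
    fx <- rand_sc_fixture(seed, n_prot = 5)
    base <- suppressMessages(filter_proteins(fx$counts))
    target <- base$accession[1]
    m2 <- fx$mat
    m2[target, fx$cond == "treatment"] <- m2[target, fx$cond == "treatment"] + 5L
    x2 <- spectral_counts(
      counts = tibble::tibble(
        accession = rep(rownames(m2), times = ncol(m2)),
        run_id = rep(colnames(m2), each = nrow(m2)),
        count = as.integer(m2)),
      proteins = fx$counts$proteins, runs = fx$counts$runs)
    bumped <- suppressMessages(filter_proteins(x2))
    if (base$passes[base$accession == target]) {
      expect_true(bumped$passes[bumped$accession == target])
    }
  }
})

test_that("glance summarises an enrichment result", {
  fx <- rand_sc_fixture(4)
  res <- suppressMessages(filter_proteins(fx$counts))
  g <- glance(res)
  expect_equal(g$level, "protein")
  expect_equal(g$n_pass, sum(res$passes))
  expect_equal(g$fold_threshold, 2)
})
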