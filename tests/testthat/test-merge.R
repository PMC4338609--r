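mk_sites <- function(acc, residues = NULL, pos = NULL) {
  n <- length(acc)
  if (is.null(residues)) residues <- rep("S", n)
  if (is.null(pos)) pos <- seq_len(n) * 10L
  tibble::tibble(accession = acc, position = pos, residue = residues)
}

test_that("catalogue merging follows set arithmetic", {
  cat1 <- merge_catalogues(c("A", "B", "C"), mk_sites(c("B", "C", "D")))
  expect_equal(cat1$total, 4)
  expect_equal(cat1$phospho_only, "D")
  expect_equal(sort(cat1$both), c("B", "C"))
  expect_equal(cat1$pct_increase, 100 / 3)

  # identical sets -> no increase
  cat2 <- merge_catalogues(c("A", "B"), mk_sites(c("A", "B")))
  expect_equal(cat2$pct_increase, 0)
  expect_equal(cat2$total, 2)

  # disjoint sets of size n and m -> total n + m
  cat3 <- merge_catalogues(c("A", "B", "C"), mk_sites(c("X", "Y")))
  expect_equal(cat3$total, 5)

  g <- glance(cat1)
  expect_equal(g$n_proteomic, 3)
  expect_equal(g$n_phospho, 3)
})

test_that("Venn compartments stay disjoint and conserve the total on random inputs", {
  for (seed in 1:25) {
    set.seed(seed)
    prot <- sample(LETTERS, sample(3:15, 1))
    phos <- sample(LETTERS, sample(3:15, 1))
    cat <- merge_catalogues(prot, mk_sites(phos))
    expect_equal(cat$total,
                 length(cat$proteomic_only) + length(cat$both) +
                   length(cat$phospho_only))
    expect_length(intersect(cat$proteomic_only, cat$phospho_only), 0)
    expect_length(intersect(cat$proteomic_only, cat$both), 0)
    expect_length(intersect(cat$phospho_only, cat$both), 0)
    expect_setequal(catalogue_accessions(cat), union(prot, phos))
  }
})

test_that("adhesome cross-referencing tallies compartments and site counts", {
  ann <- tibble::tibble(accession = c("A", "D", "E"), is_adhesome = TRUE,
                        category = c("adaptor", "kinase", "receptor"))
  # D phospho-only with 16 sites; A proteomic-only adhesome member
  sites <- mk_sites(rep("D", 16), pos = seq_len(16) * 7L)
  cat <- merge_catalogues(c("A", "B"), sites)
  x <- crossref_adhesome(cat, ann)
  expect_equal(x$max_sites_per_protein, 16)
  expect_equal(x$n_adhesome_detected, 2)
  expect_equal(x$n_adhesome_phospho, 1)
  byc <- x$by_compartment
  expect_equal(byc$n_adhesome[byc$compartment == "phospho_only"], 1)

  # no adhesome members detected -> zero tallies
  x0 <- crossref_adhesome(merge_catalogues("Q", mk_sites("R")), ann)
  expect_equal(x0$n_adhesome_detected, 0)
  expect_equal(x0$max_sites_per_protein, 0)
})

test_that("adhesome tallies equal a brute-force recount on random catalogues", {
  for (seed in 1:25) {
    set.seed(seed)
    prot <- sample(LETTERS, 8)
    phos_acc <- sample(LETTERS, 20, replace = TRUE)
    members <- sample(LETTERS, 10)
    ann <- tibble::tibble(accession = members, is_adhesome = TRUE,
                          category = sample(c("adaptor", "kinase"), 10, TRUE))
    cat <- merge_catalogues(prot, mk_sites(phos_acc,
                                           pos = seq_along(phos_acc) * 3L))
    x <- crossref_adhesome(cat, ann)
    detected <- union(prot, unique(phos_acc))
    expect_equal(x$n_adhesome_detected, length(intersect(detected, members)))
    expect_equal(x$n_adhesome_phospho,
                 length(intersect(unique(phos_acc), members)))
    for (a in intersect(unique(phos_acc), members)) {
      expect_equal(x$sites_per_protein$n_sites[x$sites_per_protein$accession == a],
                   sum(phos_acc == a))
    }
  }
})

test_that("residue composition counts, percentages and edge cases", {
  sites <- mk_sites(c("A", "A", "B", "C"), residues = c("S", "S", "T", "Y"))
  comp <- residue_composition(sites)
  expect_equal(comp$n, c(2L, 1L, 1L))
  expect_equal(comp$pct, c(50, 25, 25))

  y <- residue_composition(mk_sites(c("A", "B"), residues = c("Y", "Y")))
  expect_equal(y$pct, c(0, 0, 100))

  empty <- residue_composition(sites, subset = character(0))
  expect_true(attr(empty, "undefined"))
  expect_equal(empty$n, c(0L, 0L, 0L))

  # permutation invariance
  perm <- sites[c(3, 1, 4, 2), ]
  expect_equal(tibble::as_tibble(residue_composition(perm)),
               tibble::as_tibble(comp))

  # percentages sum to 100 within rounding for random mixes
  for (seed in 1:10) {
    set.seed(seed)
    s <- mk_sites(LETTERS[1:7], residues = sample(c("S", "T", "Y"), 7, TRUE))
    expect_lt(abs(sum(residue_composition(s)$pct) - 100), 0.11)
  }
})

test_that("simulated composition at the canonical profile is recovered", {
  edges <- simulate_interactome(150, seed = 21)
  d <- simulation_design(
    n_proteins = 150L, n_sites = 1000L, motif_fraction = 0,
    residue_profile_by_hop = tibble::tibble(hop = 1:5, pS = 0.82, pT = 0.11,
                                            pY = 0.07),
    seed = 21L)
  out <- simulate_phosphosites(d, edges, "P00001")
  comp <- residue_composition(out$sites)
  n <- sum(comp$n)
  for (i in 1:3) {
    p <- c(0.82, 0.11, 0.07)[i]
    ci <- qbinom(c(0.005, 0.995), n, p)
    expect_gte(comp$n[i], ci[1])
    expect_lte(comp$n[i], ci[2])
  }
})
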