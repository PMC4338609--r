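# Independent brute-force oracles and random-fixture builders. These are
# deliberately written in plain base R (loops, combn, matrices) so they share
# no code path with the package implementation they check.

# --- subtractive-filter oracle ---------------------------------------------

# counts_mat: proteins x runs integer matrix with rownames; cond: per-run
# condition vector. Returns accessions passing the protein filter.
oracle_protein_pass <- function(counts_mat, mw, cond, min_fold = 2,
                                min_spectra = 6) {
  saf <- counts_mat / mw
  nsafm <- saf
  for (j in seq_len(ncol(saf))) nsafm[, j] <- saf[, j] / sum(saf[, j])
  pass <- character(0)
  for (i in seq_len(nrow(counts_mat))) {
    mt <- mean(nsafm[i, cond == "treatment"])
    mc <- mean(nsafm[i, cond == "control"])
    if (mt == 0 && mc == 0) next
    fc <- if (mc > 0) mt / mc else Inf
    tot <- sum(counts_mat[i, cond == "treatment"])
    if (fc >= min_fold && tot >= min_spectra) {
      pass <- c(pass, rownames(counts_mat)[i])
    }
  }
  pass
}

# site filter on raw mean counts at a given fold threshold
oracle_site_pass <- function(counts_mat, cond, fold_threshold, min_spectra = 2) {
  pass <- character(0)
  for (i in seq_len(nrow(counts_mat))) {
    mt <- mean(counts_mat[i, cond == "treatment"])
    mc <- mean(counts_mat[i, cond == "control"])
    if (mt == 0 && mc == 0) next
    fc <- if (mc > 0) mt / mc else Inf
    tot <- sum(counts_mat[i, cond == "treatment"])
    if (fc >= fold_threshold && tot >= min_spectra) {
      pass <- c(pass, rownames(counts_mat)[i])
    }
  }
  pass
}

# --- hypergeometric upper tail by exhaustive enumeration --------------------

# P(|query & term| >= k) enumerating every n-subset of an N-universe whose
# first K elements carry the term.
oracle_hyper_enum <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  subs <- utils::combn(N, n)
  overlaps <- colSums(subs <= K)
  mean(overlaps >= k)
}

# --- all-pairs shortest paths (Floyd-Warshall) ------------------------------

oracle_apsp <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n, dimnames = dimnames(adj))
  d[adj > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], `+`)
    d <- pmin(d, dk)
  }
  d
}

# --- random fixtures --------------------------------------------------------

rand_sc_fixture <- function(seed, n_prot = NULL, n_rep = 2L) {
  set.seed(seed)
  if (is.null(n_prot)) n_prot <- sample(2:10, 1)
  acc <- sprintf("X%03d", seq_len(n_prot))
  reps <- LETTERS[seq_len(n_rep)]
  run_id <- c(paste0("treatment_", reps), paste0("control_", reps))
  cond <- rep(c("treatment", "control"), each = n_rep)
  m <- matrix(rpois(n_prot * length(run_id), lambda = sample(1:8, 1)),
              nrow = n_prot, dimnames = list(acc, run_id))
  # guarantee normalizable runs
  m[1, ] <- m[1, ] + 1L
  mw <- runif(n_prot, 10, 200)
  list(mat = m, mw = mw, cond = cond,
       counts = spectral_counts(
         counts = tibble::tibble(
           accession = rep(acc, times = length(run_id)),
           run_id = rep(run_id, each = n_prot),
           count = as.integer(m)),
         proteins = tibble::tibble(accession = acc, molecular_weight = mw),
         runs = tibble::tibble(run_id = run_id, condition = cond,
                               replicate = rep(reps, 2))))
}

rand_window <- function(n, centre) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  vapply(seq_len(n), function(i) {
    w <- sample(aa, 15, replace = TRUE)
    w[8] <- centre[(i - 1) %% length(centre) + 1]
    paste(w, collapse = "")
  }, character(1))
}

rand_site_fixture <- function(seed, n_sites = NULL, n_rep = 2L) {
  set.seed(seed)
  if (is.null(n_sites)) n_sites <- sample(3:10, 1)
  reps <- LETTERS[seq_len(n_rep)]
  run_id <- c(paste0("treatment_", reps), paste0("control_", reps))
  cond <- rep(c("treatment", "control"), each = n_rep)
  res <- sample(c("S", "T", "Y"), n_sites, replace = TRUE)
  m <- matrix(rpois(n_sites * length(run_id), lambda = 2),
              nrow = n_sites)
  m[1, 1] <- m[1, 1] + 1L
  colnames(m) <- run_id
  tab <- tibble::tibble(
    accession = sprintf("X%03d", sample(seq_len(max(2, n_sites %/% 2)),
                                        n_sites, replace = TRUE)),
    position = seq_len(n_sites) * 11L,
    residue = res,
    window = rand_window(n_sites, res),
    localization_score = NA_real_, identification_score = NA_real_
  )
  tab <- dplyr::bind_cols(tab, tibble::as_tibble(m))
  rownames(m) <- paste(tab$accession, tab$position)
  runs <- tibble::tibble(run_id = run_id, condition = cond,
                         replicate = rep(reps, 2))
  list(tab = tab, mat = m, cond = cond, runs = runs,
       sites = phosphosite_table(tab, runs))
}
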