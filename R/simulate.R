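# Ground-truth-bearing synthetic data: overdispersed spectral-count
# replicates with a designed enriched subset, scale-free interactomes, and
# phosphosite tables with hop-structured residue composition and planted
# kinase motifs. Everything is a pure function of (design, seed).

# approximate human proteome amino-acid frequencies (UniProt statistics)
AA_FREQ <- c(
  A = 0.070, R = 0.056, N = 0.036, D = 0.047, C = 0.023,
  Q = 0.048, E = 0.071, G = 0.066, H = 0.026, I = 0.043,
  L = 0.100, K = 0.057, M = 0.021, F = 0.037, P = 0.063,
  S = 0.083, T = 0.053, W = 0.012, Y = 0.027, V = 0.060
)

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulation design for synthetic experiments
#'
#' Encodes the study conditions the generators emulate: a two-condition
#' (treatment = adhesion-complex isolation, control) experiment with three
#' biological replicates per condition, negative-binomial spectral counts, a
#' designed enriched protein subset, hop-structured phospho-residue
#' profiles, and planted kinase motifs.
#'
#' @param n_proteins number of simulated proteins
#' @param n_enriched number of truly treatment-enriched proteins (default
#'   10% of the proteome)
#' @param enrichment_factor multiplicative treatment effect (> 1) on the
#'   mean count of enriched proteins
#' @param baseline_mean expected spectra per protein per run
#' @param dispersion negative-binomial overdispersion (variance =
#'   mean + dispersion * mean^2); 0 gives the Poisson limit. The default
#'   0.02 (BCV ~ 0.14) reflects replicate isolations from one cell line
#'   under a controlled workflow
#' @param n_replicates_per_condition biological replicates per condition
#' @param mw_range molecular-weight range in kDa, sampled uniformly
#' @param phospho_fraction fraction of proteins eligible to carry sites
#' @param residue_profile_by_hop tibble `hop`, `pS`, `pT`, `pY` (rows sum
#'   to 1): acceptor-residue probabilities by hop distance from the seed
#' @param n_sites number of phosphosites to simulate
#' @param motif_fraction fraction of sites carrying a planted kinase motif
#' @param motif_mutation_prob per-position mutation probability applied to
#'   planted substrate windows (centre never mutated)
#' @param site_treatment_mean,site_control_mean expected site spectra per
#'   treatment/control run (control-absent-dominated by default)
#' @param seed integer RNG seed; all generators are pure in (design, seed)
#' @return a `simulation_design` list
#' @export
simulation_design <- function(n_proteins = 2000L,
                              n_enriched = round(0.1 * n_proteins),
                              enrichment_factor = 8,
                              baseline_mean = 10,
                              dispersion = 0.02,
                              n_replicates_per_condition = 3L,
                              mw_range = c(10, 300),
                              phospho_fraction = 0.4,
                              residue_profile_by_hop = NULL,
                              n_sites = 1000L,
                              motif_fraction = 0.3,
                              motif_mutation_prob = 0.1,
                              site_treatment_mean = 3,
                              site_control_mean = 0.1,
                              seed = 1L) {
  if (n_proteins < 1) abort("Degenerate design: n_proteins must be >= 1.")
  if (n_enriched > n_proteins) abort("n_enriched cannot exceed n_proteins.")
  if (enrichment_factor < 1) abort("enrichment_factor must be >= 1.")
  if (baseline_mean <= 0 || dispersion < 0) {
    abort("baseline_mean must be > 0 and dispersion >= 0.")
  }
  if (is.null(residue_profile_by_hop)) {
    # flat profile at the canonical adhesion-complex composition
    residue_profile_by_hop <- tibble(hop = 0:3, pS = 0.82, pT = 0.11, pY = 0.07)
  }
  residue_profile_by_hop <- tibble::as_tibble(residue_profile_by_hop)
  sums <- with(residue_profile_by_hop, pS + pT + pY)
  if (any(abs(sums - 1) > 1e-9)) {
    abort("Residue profile rows must sum to 1 (+/- 1e-9).")
  }
  structure(
    list(n_proteins = as.integer(n_proteins), n_enriched = as.integer(n_enriched),
         enrichment_factor = enrichment_factor, baseline_mean = baseline_mean,
         dispersion = dispersion,
         n_replicates_per_condition = as.integer(n_replicates_per_condition),
         mw_range = mw_range, phospho_fraction = phospho_fraction,
         residue_profile_by_hop = residue_profile_by_hop,
         n_sites = as.integer(n_sites), motif_fraction = motif_fraction,
         motif_mutation_prob = motif_mutation_prob,
         site_treatment_mean = site_treatment_mean,
         site_control_mean = site_control_mean,
         seed = as.integer(seed)),
    class = "simulation_design"
  )
}

design_runs <- function(design) {
  reps <- LETTERS[seq_len(design$n_replicates_per_condition)]
  tibble(
    run_id = c(paste0("treatment_", reps), paste0("control_", reps)),
    condition = rep(c("treatment", "control"), each = length(reps)),
    replicate = rep(reps, 2)
  )
}

rcounts <- function(n, mu, dispersion) {
  if (dispersion == 0) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate a spectral-count experiment with known enriched proteins
#'
#' Counts are negative-binomial with per-protein mean `baseline_mean`, times
#' `enrichment_factor` for enriched proteins in treatment runs. Non-enriched
#' proteins behave identically in both conditions, supplying realistic
#' contaminant-style negatives for the subtractive filter.
#'
#' @param design a [simulation_design]
#' @return list with `counts` (a [spectral_counts]) and `truth` (list with
#'   `enriched_accessions`)
#' @export
simulate_counts <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  with_seed(design$seed, {
    acc <- sprintf("P%05d", seq_len(design$n_proteins))
    enriched <- sort(sample(acc, design$n_enriched))
    mw <- runif(design$n_proteins, design$mw_range[1], design$mw_range[2])
    runs <- design_runs(design)
    mu <- outer(
      ifelse(acc %in% enriched, design$enrichment_factor, 1),
      ifelse(runs$condition == "treatment", 1, NA)
    )
    mu[is.na(mu)] <- 1                       # control runs: baseline for all
    mu <- mu * design$baseline_mean
    cnt <- base::matrix(
      rcounts(length(mu), as.vector(mu), design$dispersion),
      nrow = design$n_proteins, dimnames = list(acc, runs$run_id)
    )
    long <- tibble(
      accession = rep(acc, times = nrow(runs)),
      run_id = rep(runs$run_id, each = length(acc)),
      count = as.integer(cnt)
    )
    list(
      counts = spectral_counts(long,
                               proteins = tibble(accession = acc,
                                                 molecular_weight = mw),
                               runs = runs),
      truth = list(enriched_accessions = enriched)
    )
  })
}

#' Simulate a connected scale-free interactome
#'
#' Preferential-attachment (Barabasi-Albert) growth with `edges_per_node`
#' links per new node yields a connected simple graph with a heavy-tailed
#' degree distribution (hub-containing), the shape PPI networks show.
#'
#' @param n_nodes number of proteins (>= 2)
#' @param attachment_parameter preferential-attachment power (1 = linear)
#' @param seed RNG seed
#' @param node_names accession names; defaults to `P00001`...
#' @param edges_per_node edges added per new node (default 2)
#' @return edge tibble (`from`, `to`) of a simple connected graph
#' @export
simulate_interactome <- function(n_nodes, attachment_parameter = 1, seed = 1L,
                                 node_names = NULL, edges_per_node = 2) {
  if (n_nodes < 2) abort("An interactome needs at least 2 nodes.")
  if (is.null(node_names)) node_names <- sprintf("P%05d", seq_len(n_nodes))
  stopifnot(length(node_names) == n_nodes)
  with_seed(seed, {
    g <- igraph::sample_pa(n_nodes, power = attachment_parameter,
                           m = edges_per_node, directed = FALSE)
    g <- igraph::simplify(g)
    el <- igraph::as_edgelist(g)
    clean_edges(tibble(from = node_names[as.integer(el[, 1])],
                       to = node_names[as.integer(el[, 2])]))
  })
}

random_windows <- function(n, centres, freqs = AA_FREQ) {
  flank <- base::matrix(
    sample(names(freqs), n * (WINDOW_WIDTH - 1), replace = TRUE, prob = freqs),
    nrow = n
  )
  apply(cbind(flank[, 1:(WINDOW_CENTRE - 1), drop = FALSE], centres,
              flank[, WINDOW_CENTRE:(WINDOW_WIDTH - 1), drop = FALSE]),
        1, paste, collapse = "")
}

#' Simulated background windows for threshold calibration
#'
#' Random 15-mers with flanks drawn from human proteome amino-acid
#' frequencies and the central residue drawn from the stated acceptor class.
#'
#' @param n number of windows
#' @param residue_class `"ST"` or `"Y"`
#' @param seed RNG seed
#' @return character vector of 15-mer windows
#' @export
simulate_background_windows <- function(n, residue_class = c("ST", "Y"),
                                        seed = 1L) {
  residue_class <- match.arg(residue_class)
  with_seed(seed, {
    centres <- if (residue_class == "Y") rep("Y", n) else {
      sample(c("S", "T"), n, replace = TRUE,
             prob = AA_FREQ[c("S", "T")] / sum(AA_FREQ[c("S", "T")]))
    }
    random_windows(n, centres)
  })
}

mutate_window <- function(window, prob) {
  ch <- strsplit(window, "", fixed = TRUE)[[1]]
  idx <- setdiff(seq_along(ch), WINDOW_CENTRE)
  hit <- idx[runif(length(idx)) < prob & ch[idx] != GAP_SYMBOL]
  for (i in hit) ch[i] <- sample(setdiff(AMINO_ACIDS, ch[i]), 1)
  paste(ch, collapse = "")
}

#' Simulate phosphosites with hop-structured residue composition
#'
#' Sites are placed on proteins within the hop range covered by the design's
#' `residue_profile_by_hop` (distances measured from `seed_node` on
#' `network`); each site's acceptor residue is drawn from the profile at its
#' protein's hop. A `motif_fraction` of sites copy a substrate window of a
#' randomly chosen kinase model, mutated per position with probability
#' `motif_mutation_prob` (centre untouched). Per-run counts follow the
#' control-absent-dominated pattern of subtractive phosphoproteomics.
#'
#' @param design a [simulation_design]
#' @param network edge tibble (e.g. from [simulate_interactome()])
#' @param seed_node accession to measure hop distances from
#' @param kinases optional list of [kinase_model]s supplying motifs
#' @return list with `sites` (aggregated site tibble) and `truth` (tibble
#'   `accession`, `position`, `hop`, `residue`, `kinase`)
#' @export
simulate_phosphosites <- function(design, network, seed_node, kinases = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  g <- igraph::graph_from_data_frame(network, directed = FALSE)
  if (!seed_node %in% igraph::V(g)$name) {
    abort(paste0("Seed node '", seed_node, "' is not in the network."))
  }
  prof <- design$residue_profile_by_hop
  decomp <- hop_distances(g, seed_node)
  occurring <- decomp[decomp$hop > 0 & is.finite(decomp$hop) &
                        decomp$hop <= max(prof$hop), , drop = FALSE]
  gap <- setdiff(unique(occurring$hop), prof$hop)
  if (length(gap) > 0) {
    abort(paste0("No residue profile for occurring hop distance(s): ",
                 paste(gap, collapse = ", ")))
  }
  if (nrow(occurring) == 0) abort("No proteins within the profiled hop range.")

  with_seed(design$seed + 1L, {
    pick <- sample(nrow(occurring), design$n_sites, replace = TRUE)
    acc <- occurring$accession[pick]
    hop <- occurring$hop[pick]
    # unique ascending positions per protein
    position <- stats::ave(seq_along(acc), acc, FUN = seq_along) * 17L + 8L

    pmat <- as.matrix(prof[match(hop, prof$hop), c("pS", "pT", "pY")])
    u <- runif(length(acc))
    residue <- ifelse(u < pmat[, 1], "S",
                      ifelse(u < pmat[, 1] + pmat[, 2], "T", "Y"))
    window <- random_windows(length(acc), residue)
    kinase <- rep(NA_character_, length(acc))

    if (!is.null(kinases) && design$motif_fraction > 0) {
      is_motif <- runif(length(acc)) < design$motif_fraction
      for (i in which(is_motif)) {
        m <- kinases[[sample(length(kinases), 1)]]
        sub <- sample(m$substrates, 1)
        window[i] <- mutate_window(sub, design$motif_mutation_prob)
        residue[i] <- substr(sub, WINDOW_CENTRE, WINDOW_CENTRE)
        kinase[i] <- m$kinase_id
      }
    }

    runs <- design_runs(design)
    n <- length(acc)
    cnt <- cbind(
      base::matrix(rcounts(n * design$n_replicates_per_condition,
                           design$site_treatment_mean, design$dispersion),
                   nrow = n),
      base::matrix(rcounts(n * design$n_replicates_per_condition,
                           design$site_control_mean, design$dispersion),
                   nrow = n)
    )
    colnames(cnt) <- runs$run_id
    tab <- tibble(
      accession = acc, position = position, residue = residue, window = window,
      localization_score = ifelse(runif(n) < 0.2, -1, round(runif(n, 20, 60), 1)),
      identification_score = round(runif(n, 20, 80), 1)
    )
    tab <- dplyr::bind_cols(tab, tibble::as_tibble(cnt))
    sites <- phosphosite_table(tab, runs)
    truth <- tibble(accession = acc, position = position, hop = hop,
                    residue = residue, kinase = kinase)
    list(sites = sites, truth = truth)
  })
}

#' A small built-in kinase substrate library
#'
#' Five kinase models with synthetic consensus-style substrate windows:
#' a proline-directed CMGC kinase (CDK1-like, S-P-x-x-K), a basophilic AGC
#' kinase (PKA-like, R-R-x-S), an acidophilic kinase (CK2-like, S-D/E), and
#' two tyrosine kinases of the same group (SRC-like and ABL-like) so that
#' family-level validation credit is exercised. Substrate windows are
#' synthetic, built around published consensus motifs — not curated
#' phosphosite data.
#'
#' @return named list of [kinase_model]s
#' @export
example_kinase_library <- function() {
  lib <- list(
    kinase_model("CDK1", "CMGC", "ST", c(
      "KVEKIGESPLKVDKL",
      "HSTPPKKSPRKVLFG",
      "APTKRVRSPEKAKEG"
    )),
    kinase_model("PKA", "AGC", "ST", c(
      "TGNLRRASLGAAPVA",
      "ELKRRQISIRGIVQA",
      "GSGRRVSSAEGLDKM"
    )),
    kinase_model("CK2", "other", "ST", c(
      "ADGSEDESDDEGHAE",
      "QEWSDDESDEELDKM",
      "VLASEDSSEDDEDFI"
    )),
    kinase_model("SRC", "TK", "Y", c(
      "TAEPDNGYALEGRNP",
      "GEDNEEIYGEFFAKK",
      "EPVGDNIYQVPSGAL"
    )),
    kinase_model("ABL", "TK", "Y", c(
      "APAVENVYAAPFAKK",
      "AEAIHKVYAAPVTAG",
      "ADSLNAVYAKPEASF"
    ))
  )
  setNames(lib, vapply(lib, `[[`, character(1), "kinase_id"))
}
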