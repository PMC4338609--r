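# End-to-end orchestration: a declarative config, a synthetic demo fixture
# generator, and run_pipeline() chaining normalize -> filter -> merge ->
# network -> term enrichment -> kinase prediction with a JSON manifest.

#' Pipeline configuration
#'
#' A single declarative object naming every input and threshold, so a run is
#' fully reproducible from (config, seed). All referenced paths are checked
#' at validation time, before any stage runs.
#'
#' @param counts_path spectral-count TSV
#' @param sites_path phosphosite TSV
#' @param edges_path interactome edge-list TSV
#' @param adhesome_path adhesome annotation TSV
#' @param terms_path term-annotation TSV (term_id, accession)
#' @param term_names_path optional term-name TSV
#' @param universe_path optional one-accession-per-line background list
#' @param kinase_library_path kinase substrate library TSV
#' @param matrix_path substitution-matrix TSV (default bundled BLOSUM62)
#' @param policy a [threshold_policy]
#' @param seed_node seed protein for the hop decomposition
#' @param max_hop largest hop band (default 3)
#' @param restrict `"detected"` or `"full"` graph for distances
#' @param alpha,min_count,variant term-enrichment options
#' @param target_fpr_st,target_fpr_y kinase calibration FPRs (0.02 / 0.04)
#' @param n_background background windows per residue class for calibration
#' @param seed integer seed for every stochastic step
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(counts_path, sites_path, edges_path,
                            adhesome_path, terms_path,
                            term_names_path = NULL, universe_path = NULL,
                            kinase_library_path,
                            matrix_path = NULL,
                            policy = threshold_policy(),
                            seed_node, max_hop = 3,
                            restrict = c("detected", "full"),
                            alpha = 0.05, min_count = 2L,
                            variant = c("ease", "fisher"),
                            target_fpr_st = 0.02, target_fpr_y = 0.04,
                            n_background = 1000L,
                            seed = 1L) {
  restrict <- match.arg(restrict)
  variant <- match.arg(variant)
  paths <- c(counts_path, sites_path, edges_path, adhesome_path, terms_path,
             term_names_path, universe_path, kinase_library_path, matrix_path)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(c("Pipeline input path(s) do not exist:",
            x = paste(missing, collapse = ", ")))
  }
  structure(
    list(counts_path = counts_path, sites_path = sites_path,
         edges_path = edges_path, adhesome_path = adhesome_path,
         terms_path = terms_path, term_names_path = term_names_path,
         universe_path = universe_path,
         kinase_library_path = kinase_library_path,
         matrix_path = matrix_path, policy = policy,
         seed_node = seed_node, max_hop = max_hop, restrict = restrict,
         alpha = alpha, min_count = as.integer(min_count), variant = variant,
         target_fpr_st = target_fpr_st, target_fpr_y = target_fpr_y,
         n_background = as.integer(n_background), seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("Stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full subtractive phospho-adhesome pipeline
#'
#' Executes normalize -> protein filter -> site filter -> merge ->
#' adhesome cross-reference -> hop-network analysis -> term enrichment ->
#' kinase calibration and prediction, writing one TSV per stage plus a JSON
#' run manifest (seed, thresholds, config hash) and a plain-text summary to
#' `out_dir`. Outputs contain no timestamps, so two runs with the same
#' (config, seed) are byte-identical.
#'
#' @param config a [pipeline_config]
#' @param out_dir output directory (created if needed)
#' @return (invisibly) a list of all stage results and output paths
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(out_dir, f)
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  counts <- run_stage("read_inputs", read_spectral_counts(config$counts_path))
  sites <- run_stage("read_inputs", read_phosphosites(config$sites_path))
  edges <- run_stage("read_inputs", read_edge_list(config$edges_path))
  adhesome <- run_stage("read_inputs", read_adhesome(config$adhesome_path))
  terms <- run_stage("read_inputs", read_term_map(
    config$terms_path, config$term_names_path,
    universe = if (!is.null(config$universe_path)) {
      readr::read_lines(config$universe_path, progress = FALSE)
    } else NULL))
  kinases <- run_stage("read_inputs", read_kinase_library(config$kinase_library_path))
  submat <- read_substitution_matrix(config$matrix_path)
  note("inputs: ", nrow(counts$proteins), " proteins, ", nrow(sites),
       " sites, ", nrow(edges), " interactions")

  prot <- run_stage("filter_proteins",
                    filter_proteins(counts, config$policy))
  write_enrichment_result(prot, out("protein_enrichment.tsv"))
  note("protein filter: ", nrow(prot), " in -> ", sum(prot$passes), " pass")

  site_res <- run_stage("filter_sites",
                        filter_sites(sites, policy = config$policy))
  write_enrichment_result(site_res, out("site_enrichment.tsv"))
  note("site filter: ", nrow(site_res), " in -> ", sum(site_res$passes),
       " pass (fold threshold ", signif(attr(site_res, "fold_threshold"), 4), ")")

  pass_sites <- sites |>
    dplyr::semi_join(tidy(site_res) |> dplyr::filter(.data$passes),
                     by = c("accession", "position"))
  catalogue <- run_stage("merge", merge_catalogues(prot, site_res))
  readr::write_tsv(tidy(catalogue), out("merged_catalogue.tsv"), progress = FALSE)
  note("merged catalogue: ", catalogue$total, " proteins (",
       length(catalogue$phospho_only), " phospho-only, +",
       sprintf("%.1f%%", catalogue$pct_increase), ")")

  xref <- run_stage("crossref_adhesome", crossref_adhesome(catalogue, adhesome))
  readr::write_tsv(xref$by_category, out("adhesome_by_category.tsv"),
                   progress = FALSE)
  comp_all <- residue_composition(pass_sites)
  readr::write_tsv(tibble::as_tibble(comp_all), out("residue_composition.tsv"),
                   progress = FALSE)

  # the seed protein anchors the neighbourhood; keep it even if filtered out
  graph <- run_stage("network", build_graph(
    edges, detected = union(catalogue_accessions(catalogue), config$seed_node),
    sites = pass_sites, annotation = adhesome, restrict = config$restrict))
  if (!config$seed_node %in% igraph::V(graph)$name) {
    abort(paste0("Stage 'network' failed: seed node '", config$seed_node,
                 "' absent from the ", config$restrict, " graph."))
  }
  decomp <- run_stage("network", hop_distances(graph, config$seed_node))
  hopcomp <- run_stage("network",
                       hop_composition(decomp, pass_sites, config$max_hop))
  readr::write_tsv(tidy(decomp), out("hop_distances.tsv"), progress = FALSE)
  readr::write_tsv(hopcomp, out("hop_composition.tsv"), progress = FALSE)
  export_graph(graph, out("network.graphml"), "graphml", decomp = decomp)
  export_graph(graph, out("network.sif"), "sif")
  note("network: ", igraph::vcount(graph), " nodes, ",
       igraph::ecount(graph), " edges; ",
       length(neighbourhood(decomp, 2)), " within 2 hops of ", config$seed_node)

  enr <- run_stage("term_enrichment", enrich_terms(
    intersect(catalogue_accessions(catalogue), terms$universe), terms,
    alpha = config$alpha, min_count = config$min_count,
    variant = config$variant, all_terms = TRUE))
  write_enriched_terms(enr, out("term_enrichment.tsv"))
  note("term enrichment: ", sum(enr$significant), " significant term(s) of ",
       nrow(enr))

  kin <- run_stage("kinase_prediction", {
    bg_st <- c(simulate_background_windows(config$n_background, "ST",
                                           seed = config$seed + 101L))
    bg_y <- c(simulate_background_windows(config$n_background, "Y",
                                          seed = config$seed + 102L))
    models <- lapply(kinases, function(m) {
      fpr <- if (m$residue_class == "ST") config$target_fpr_st else config$target_fpr_y
      bg <- if (m$residue_class == "ST") bg_st else bg_y
      calibrate_threshold(m, bg, fpr, submat)
    })
    list(models = models,
         predictions = predict_kinases(pass_sites, models, submat))
  })
  readr::write_tsv(kin$predictions, out("kinase_predictions.tsv"),
                   progress = FALSE)
  n_sites_pred <- dplyr::n_distinct(kin$predictions[, c("accession", "position")])
  note("kinase prediction: ", n_sites_pred, " of ", nrow(pass_sites),
       " passing sites assigned >= 1 kinase")

  manifest <- list(
    package = "adhesiomics",
    version = as.character(utils::packageVersion("adhesiomics")),
    seed = config$seed,
    config_hash = rlang::hash(config),
    thresholds = unclass(config$policy),
    site_fold_threshold = attr(site_res, "fold_threshold"),
    stages = c("read_inputs", "filter_proteins", "filter_sites", "merge",
               "network", "term_enrichment", "kinase_prediction"),
    outputs = list.files(out_dir)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  readr::write_lines(c("# adhesiomics pipeline summary",
                       paste0("seed: ", config$seed), log),
                     out("summary.txt"))

  invisible(list(
    proteins = prot, sites = site_res, catalogue = catalogue,
    adhesome = xref, graph = graph, decomp = decomp,
    hop_composition = hopcomp, terms = enr, kinases = kin,
    manifest = manifest, out_dir = out_dir, log = log
  ))
}

#' Generate a complete synthetic demo input set
#'
#' Calls the synthetic-data generators to write every input the pipeline
#' reads (counts, sites, interactome, adhesome annotation, term map, kinase
#' library) plus a `ground_truth.json`, all derived deterministically from
#' `seed`.
#'
#' @param dir output directory
#' @param seed integer seed
#' @param design optional [simulation_design]; default is a compact demo
#'   design (800 proteins, 80 enriched, 400 sites)
#' @return (invisibly) list with the fixture paths, the design and the
#'   ground truth
#' @export
make_demo <- function(dir, seed = 1L, design = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(design)) {
    design <- simulation_design(
      n_proteins = 800L, n_enriched = 80L, n_sites = 400L,
      residue_profile_by_hop = tibble(
        hop = 0:3,
        pY = c(0.30, 0.25, 0.15, 0.05),
        pT = 0.11, pS = 1 - 0.11 - c(0.30, 0.25, 0.15, 0.05)
      ),
      seed = seed
    )
  }
  sim <- simulate_counts(design)
  acc <- sim$counts$proteins$accession
  seed_node <- acc[1]

  edges <- simulate_interactome(design$n_proteins, seed = design$seed + 2L,
                                node_names = acc)
  kinases <- example_kinase_library()
  phos <- simulate_phosphosites(design, edges, seed_node, kinases)

  paths <- list(
    counts_path = file.path(dir, "counts.tsv"),
    sites_path = file.path(dir, "sites.tsv"),
    edges_path = file.path(dir, "edges.tsv"),
    adhesome_path = file.path(dir, "adhesome.tsv"),
    terms_path = file.path(dir, "terms.tsv"),
    term_names_path = file.path(dir, "term_names.tsv"),
    universe_path = file.path(dir, "universe.txt"),
    kinase_library_path = file.path(dir, "kinase_library.tsv")
  )
  write_spectral_counts(sim$counts, paths$counts_path)
  write_phosphosites(phos$sites, paths$sites_path)
  write_edge_list(edges, paths$edges_path)

  with_seed(design$seed + 3L, {
    adh_n <- min(40L, design$n_proteins)
    adh <- tibble(
      accession = sort(sample(acc, adh_n)),
      category = sample(ADHESOME_CATEGORIES, adh_n, replace = TRUE)
    )
    readr::write_tsv(adh, paths$adhesome_path, progress = FALSE)

    # one term concentrated in the true enriched set, the rest random
    enriched <- sim$truth$enriched_accessions
    term_tabs <- list(
      tibble(term_id = "T0001",
             accession = sample(enriched, min(15, length(enriched))))
    )
    for (i in 2:20) {
      term_tabs[[i]] <- tibble(term_id = sprintf("T%04d", i),
                               accession = sample(acc, sample(5:25, 1)))
    }
    ann <- dplyr::distinct(dplyr::bind_rows(term_tabs))
    readr::write_tsv(ann, paths$terms_path, progress = FALSE)
    readr::write_tsv(tibble(term_id = sprintf("T%04d", 1:20),
                            name = c("adhesion-enriched module",
                                     sprintf("random module %d", 2:20))),
                     paths$term_names_path, progress = FALSE)
    readr::write_lines(acc, paths$universe_path)
  })
  write_kinase_library(kinases, paths$kinase_library_path)

  truth <- list(
    seed = seed, seed_node = seed_node,
    enriched_accessions = sim$truth$enriched_accessions,
    site_truth = phos$truth
  )
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(c(paths, list(design = design, truth = truth,
                          seed_node = seed_node, dir = dir)))
}
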