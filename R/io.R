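# Readers and writers for the tabular and graph formats the pipeline consumes:
# spectral-count matrices, phosphosite tables, edge lists, adhesome and term
# annotations. All readers validate; all writers round-trip.

#' Construct a spectral-count experiment
#'
#' The central container for label-free quantification: one non-negative
#' integer spectral count per (protein, run), protein molecular weights in
#' kDa, and run metadata assigning each run to the treatment (adhesion-complex
#' isolation) or control condition.
#'
#' @param counts long tibble with columns `accession`, `run_id`, `count`
#' @param proteins tibble with columns `accession`, `molecular_weight` (kDa)
#' @param runs tibble with columns `run_id`, `condition`
#'   (`"treatment"`/`"control"`) and optionally `replicate`
#' @return an object of class `spectral_counts`
#' @export
spectral_counts <- function(counts, proteins, runs) {
  counts <- tibble::as_tibble(counts)
  proteins <- tibble::as_tibble(proteins)
  runs <- validate_runs(runs)

  if (anyDuplicated(proteins$accession)) {
    dup <- proteins$accession[duplicated(proteins$accession)]
    abort(paste0("Duplicate accession(s): ", paste(unique(dup), collapse = ", ")))
  }
  if (!"molecular_weight" %in% names(proteins)) {
    abort("`proteins` must carry a molecular_weight column (kDa).")
  }
  no_mw <- proteins$accession[is.na(proteins$molecular_weight)]
  if (length(no_mw) > 0) {
    abort(paste0("Missing molecular weight for: ", paste(no_mw, collapse = ", ")))
  }
  if (any(proteins$molecular_weight <= 0)) {
    abort("Molecular weights must be strictly positive (kDa).")
  }
  bad <- !is_wholenumber(counts$count) | counts$count < 0
  if (any(bad)) {
    cells <- counts[bad, , drop = FALSE]
    abort(c(
      "Spectral counts must be non-negative integers.",
      x = paste0("Offending cell(s): ",
                 paste(utils::head(paste0("(", cells$accession, ", ", cells$run_id, ") = ",
                                          cells$count), 5), collapse = "; "))
    ))
  }

  # complete the (protein, run) grid; absent pairs are zero counts
  counts <- tidyr::complete(
    counts,
    accession = proteins$accession,
    run_id = runs$run_id,
    fill = list(count = 0L)
  )
  counts$count <- as.integer(round(counts$count))

  structure(
    list(counts = counts, proteins = proteins, runs = runs),
    class = "spectral_counts"
  )
}

#' @export
print.spectral_counts <- function(x, ...) {
  cat("<spectral_counts> ", nrow(x$proteins), " proteins x ", nrow(x$runs),
      " runs (", sum(x$runs$condition == "treatment"), " treatment, ",
      sum(x$runs$condition == "control"), " control); total spectra ",
      sum(x$counts$count), "\n", sep = "")
  invisible(x)
}

#' Read a spectral-count matrix from TSV/CSV
#'
#' Expects a header row with `accession`, `molecular_weight` and one column
#' per run. Run conditions are parsed from run column names of the form
#' `<condition>_<replicate>` unless `runs` is given.
#'
#' @param path file path
#' @param format `"tsv"` (default) or `"csv"`
#' @param runs optional run-metadata tibble (`run_id`, `condition`, `replicate`)
#' @return a [spectral_counts] object; row order of the file is preserved
#' @export
read_spectral_counts <- function(path, format = c("tsv", "csv"), runs = NULL) {
  format <- match.arg(format)
  reader <- if (format == "tsv") readr::read_tsv else readr::read_csv
  tab <- reader(path, show_col_types = FALSE, progress = FALSE)
  need <- c("accession", "molecular_weight")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    abort(paste0("Missing required column(s) in ", path, ": ",
                 paste(miss, collapse = ", ")))
  }
  run_cols <- setdiff(names(tab), need)
  if (length(run_cols) == 0) abort("No run columns found.")
  if (is.null(runs)) runs <- runs_from_names(run_cols)

  long <- tidyr::pivot_longer(tab, cols = dplyr::all_of(run_cols),
                              names_to = "run_id", values_to = "count")
  spectral_counts(
    counts = long[, c("accession", "run_id", "count")],
    proteins = dplyr::distinct(tab[, need]),
    runs = runs
  )
}

#' Write a spectral-count matrix
#'
#' Inverse of [read_spectral_counts()]: `read(write(x))` reproduces `x`
#' field for field when run ids follow the `<condition>_<replicate>`
#' convention.
#'
#' @param x a [spectral_counts] object
#' @param path output path
#' @param format `"tsv"` or `"csv"`
#' @export
write_spectral_counts <- function(x, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  wide <- tidyr::pivot_wider(x$counts, names_from = "run_id",
                             values_from = "count")
  wide <- dplyr::left_join(x$proteins, wide, by = "accession")
  wide <- wide[match(x$proteins$accession, wide$accession),
               c("accession", "molecular_weight", x$runs$run_id)]
  writer <- if (format == "tsv") readr::write_tsv else readr::write_csv
  writer(wide, path, progress = FALSE)
  invisible(path)
}

#' Read a phosphosite table from TSV/CSV
#'
#' Site-level records: accession, 1-based `position`, acceptor `residue`
#' (S/T/Y), a 15-mer sequence `window` centred on the site (gap symbol `-`
#' padding protein termini), optional `localization_score` and
#' `identification_score` (the value -1 encodes infinite confidence), and one
#' spectral-count column per run. Peptide-level rows covering the same
#' (accession, position) are aggregated by summing counts per run; for the
#' scores the most confident value is kept (-1 beats any finite score).
#'
#' @inheritParams read_spectral_counts
#' @return a tibble of unique (accession, position) site records with a
#'   `runs` attribute carrying run metadata
#' @export
read_phosphosites <- function(path, format = c("tsv", "csv"), runs = NULL) {
  format <- match.arg(format)
  reader <- if (format == "tsv") readr::read_tsv else readr::read_csv
  tab <- reader(path, show_col_types = FALSE, progress = FALSE)
  need <- c("accession", "position", "residue", "window")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    abort(paste0("Missing required column(s) in ", path, ": ",
                 paste(miss, collapse = ", ")))
  }
  if (!"localization_score" %in% names(tab)) tab$localization_score <- NA_real_
  if (!"identification_score" %in% names(tab)) tab$identification_score <- NA_real_
  run_cols <- setdiff(names(tab), SITE_CORE_COLS)
  if (is.null(runs)) runs <- runs_from_names(run_cols)
  phosphosite_table(tab, runs = runs)
}

#' Validate and aggregate a phosphosite table
#'
#' @param tab tibble of peptide- or site-level records (see
#'   [read_phosphosites()] for columns)
#' @param runs run metadata tibble
#' @return aggregated site-level tibble, one row per (accession, position)
#' @export
phosphosite_table <- function(tab, runs) {
  tab <- tibble::as_tibble(tab)
  runs <- validate_runs(runs)
  bad_res <- setdiff(unique(tab$residue), RESIDUES)
  if (length(bad_res) > 0) {
    abort(paste0("Phospho-acceptor residue must be S, T or Y; found: ",
                 paste(bad_res, collapse = ", ")))
  }
  bad_win <- nchar(tab$window) != WINDOW_WIDTH
  if (any(bad_win)) {
    abort(paste0("Sequence windows must be exactly ", WINDOW_WIDTH,
                 " characters (site at index ", WINDOW_CENTRE, "); ",
                 sum(bad_win), " row(s) violate this."))
  }
  centre <- substr(tab$window, WINDOW_CENTRE, WINDOW_CENTRE)
  if (any(centre != tab$residue)) {
    abort("Window centre residue must equal the annotated acceptor residue.")
  }
  run_cols <- runs$run_id
  miss <- setdiff(run_cols, names(tab))
  if (length(miss) > 0) {
    abort(paste0("Missing run count column(s): ", paste(miss, collapse = ", ")))
  }
  cnt <- as.matrix(tab[, run_cols, drop = FALSE])
  if (any(!is_wholenumber(cnt) | cnt < 0)) {
    abort("Per-run site spectral counts must be non-negative integers.")
  }

  best_score <- function(s) {
    s <- s[!is.na(s)]
    if (length(s) == 0) return(NA_real_)
    if (any(s == -1)) return(-1)   # -1 encodes infinite confidence
    max(s)
  }
  out <- tab |>
    dplyr::group_by(.data$accession, .data$position) |>
    dplyr::summarise(
      residue = dplyr::first(.data$residue),
      window = dplyr::first(.data$window),
      localization_score = best_score(.data$localization_score),
      identification_score = best_score(.data$identification_score),
      dplyr::across(dplyr::all_of(run_cols), ~ as.integer(sum(.x))),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$accession, .data$position)
  attr(out, "runs") <- runs
  out
}

#' Write a phosphosite table
#' @param sites site tibble (as returned by [read_phosphosites()])
#' @param path output path
#' @param format `"tsv"` or `"csv"`
#' @export
write_phosphosites <- function(sites, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  writer <- if (format == "tsv") readr::write_tsv else readr::write_csv
  writer(as.data.frame(sites), path, progress = FALSE)
  invisible(path)
}

#' Run metadata attached to a site table
#' @param sites site tibble
#' @return the `runs` tibble (inferred from count column names if absent)
#' @export
site_runs <- function(sites) {
  attr(sites, "runs") %||%
    runs_from_names(setdiff(names(sites), SITE_CORE_COLS))
}

#' Read an undirected edge list
#'
#' Two-column TSV without header. Self-loops are dropped (with a message
#' giving the count) and duplicate edges collapsed, so the result is a simple
#' undirected graph.
#'
#' @param path file path
#' @return tibble with columns `from`, `to`; one row per unordered pair
#' @export
read_edge_list <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warn(paste0("Edge list ", path, " is empty; returning an empty graph."))
    return(tibble(from = character(), to = character()))
  }
  parts <- stringr::str_split(lines, "\t")
  nf <- lengths(parts)
  if (any(nf < 2)) {
    abort(paste0("Malformed edge list line ", which(nf < 2)[1], " in ", path,
                 " (expected two tab-separated columns)."))
  }
  edges <- tibble(
    from = purrr::map_chr(parts, 1),
    to = purrr::map_chr(parts, 2)
  )
  clean_edges(edges)
}

#' Reduce an edge table to a simple undirected graph
#' @param edges tibble/data frame with columns `from`, `to`
#' @return deduplicated tibble of unordered non-loop pairs
#' @export
clean_edges <- function(edges) {
  edges <- tibble::as_tibble(edges)[, c("from", "to")]
  loops <- edges$from == edges$to
  if (any(loops)) {
    inform(paste0("Dropped ", sum(loops), " self-loop(s)."))
    edges <- edges[!loops, , drop = FALSE]
  }
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  dplyr::distinct(tibble(from = a, to = b))
}

#' Write an edge list (two-column TSV, no header)
#' @param edges edge tibble
#' @param path output path
#' @export
write_edge_list <- function(edges, path) {
  readr::write_tsv(edges[, c("from", "to")], path, col_names = FALSE,
                   progress = FALSE)
  invisible(path)
}

#' Read an adhesome membership annotation
#'
#' TSV with header columns `accession` and `category` (one of the closed set
#' receptor, adaptor, actin_regulator, actin, GEF, GAP, kinase, phosphatase,
#' other). Listed accessions are adhesome members; anything absent from the
#' file defaults to non-member.
#'
#' @param path file path
#' @return tibble `accession`, `is_adhesome`, `category`
#' @export
read_adhesome <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c("accession", "category"), names(tab))
  if (length(miss) > 0) {
    abort(paste0("Adhesome annotation missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  bad <- setdiff(unique(tab$category), ADHESOME_CATEGORIES)
  if (length(bad) > 0) {
    abort(paste0("Unknown adhesome categor(ies): ", paste(bad, collapse = ", ")))
  }
  tibble(accession = tab$accession, is_adhesome = TRUE, category = tab$category)
}

#' Read a term-annotation map
#'
#' Two-column TSV with header (`term_id`, `accession`) mapping terms to member
#' proteins, plus an optional term-name table and an explicit background
#' universe. Members must be a subset of the universe.
#'
#' @param path annotation TSV (term_id, accession)
#' @param names_path optional TSV (term_id, name)
#' @param universe optional character vector; defaults to the union of members
#' @return a `term_map` list: `annotation` tibble, `term_names` tibble,
#'   `universe` character vector
#' @export
read_term_map <- function(path, names_path = NULL, universe = NULL) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c("term_id", "accession"), names(ann))
  if (length(miss) > 0) {
    abort(paste0("Term annotation missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  nm <- if (!is.null(names_path)) {
    readr::read_tsv(names_path, show_col_types = FALSE, progress = FALSE)
  } else {
    tibble(term_id = unique(ann$term_id), name = unique(ann$term_id))
  }
  term_map(ann, term_names = nm, universe = universe)
}

#' Construct a term-annotation map
#' @param annotation tibble (`term_id`, `accession`)
#' @param term_names optional tibble (`term_id`, `name`)
#' @param universe background accession set; defaults to the union of members
#' @return a `term_map` object
#' @export
term_map <- function(annotation, term_names = NULL, universe = NULL) {
  annotation <- dplyr::distinct(tibble::as_tibble(annotation)[, c("term_id", "accession")])
  if (is.null(universe)) universe <- unique(annotation$accession)
  stray <- setdiff(annotation$accession, universe)
  if (length(stray) > 0) {
    abort(paste0("Term members outside the universe: ",
                 paste(utils::head(stray, 5), collapse = ", ")))
  }
  if (is.null(term_names)) {
    term_names <- tibble(term_id = unique(annotation$term_id),
                         name = unique(annotation$term_id))
  }
  structure(
    list(annotation = annotation,
         term_names = tibble::as_tibble(term_names),
         universe = unique(universe)),
    class = "term_map"
  )
}

#' @export
print.term_map <- function(x, ...) {
  cat("<term_map> ", length(unique(x$annotation$term_id)), " terms over a ",
      length(x$universe), "-protein universe\n", sep = "")
  invisible(x)
}
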