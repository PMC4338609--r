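# Merging of the proteomic and phosphoproteomic pass sets, adhesome
# cross-referencing, and phospho-residue composition summaries.

#' Merge proteomic and phosphoproteomic catalogues
#'
#' A "phosphoprotein" is any accession carrying at least one passing
#' phosphosite, regardless of proteomic detection. The merged catalogue
#' partitions the union into proteins found only proteomically, only
#' phosphoproteomically, or in both, and reports the percentage increase of
#' the catalogue contributed by phospho-only identifications relative to the
#' proteomic set.
#'
#' @param proteomic_pass character vector of accessions passing the protein
#'   filter (or an `enrichment_result` at protein level)
#' @param site_pass site-level `enrichment_result`, or a tibble of passing
#'   sites with `accession` and `residue` columns
#' @return a `merged_catalogue` object
#' @export
merge_catalogues <- function(proteomic_pass, site_pass) {
  if (inherits(proteomic_pass, "enrichment_result")) {
    proteomic_pass <- passing_accessions(proteomic_pass)
  }
  sites <- if (inherits(site_pass, "enrichment_result")) {
    tidy(site_pass) |> dplyr::filter(.data$passes)
  } else {
    tibble::as_tibble(site_pass)
  }
  prot <- unique(proteomic_pass)
  phos <- unique(sites$accession)
  both <- intersect(prot, phos)
  res <- structure(
    list(
      proteomic_only = sort(setdiff(prot, phos)),
      phospho_only = sort(setdiff(phos, prot)),
      both = sort(both),
      total = length(union(prot, phos)),
      pct_increase = if (length(prot) > 0) {
        100 * length(setdiff(phos, prot)) / length(prot)
      } else NA_real_,
      sites = sites[, intersect(c("accession", "position", "residue"),
                                names(sites)), drop = FALSE]
    ),
    class = "merged_catalogue"
  )
  res
}

#' @export
print.merged_catalogue <- function(x, ...) {
  cat("<merged_catalogue> total ", x$total, ": proteomic-only ",
      length(x$proteomic_only), ", both ", length(x$both),
      ", phospho-only ", length(x$phospho_only),
      sprintf(" (catalogue increase %.1f%%)", x$pct_increase), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.merged_catalogue <- function(x, ...) {
  dplyr::bind_rows(
    tibble(accession = x$proteomic_only, compartment = "proteomic_only"),
    tibble(accession = x$both, compartment = "both"),
    tibble(accession = x$phospho_only, compartment = "phospho_only")
  )
}

#' @export
glance.merged_catalogue <- function(x, ...) {
  tibble(
    total = x$total,
    n_proteomic_only = length(x$proteomic_only),
    n_both = length(x$both),
    n_phospho_only = length(x$phospho_only),
    n_proteomic = length(x$proteomic_only) + length(x$both),
    n_phospho = length(x$phospho_only) + length(x$both),
    pct_increase = x$pct_increase
  )
}

#' All accessions in a merged catalogue
#' @param x a `merged_catalogue`
#' @return character vector (union of the three compartments)
#' @export
catalogue_accessions <- function(x) {
  c(x$proteomic_only, x$both, x$phospho_only)
}

#' Cross-reference a merged catalogue with the adhesome
#'
#' Counts adhesome members in each catalogue compartment, tallies
#' phosphorylated vs non-phosphorylated adhesome members per functional
#' category, and reports phosphosite counts per adhesome protein (the node
#' sizes of an adhesome network figure).
#'
#' @param catalogue a `merged_catalogue`
#' @param annotation adhesome tibble from [read_adhesome()]
#' @return list with `by_compartment`, `by_category` and `sites_per_protein`
#'   tibbles plus scalar `n_adhesome_detected`, `n_adhesome_phospho` and
#'   `max_sites_per_protein`
#' @export
crossref_adhesome <- function(catalogue, annotation) {
  stopifnot(inherits(catalogue, "merged_catalogue"))
  ann <- tibble::as_tibble(annotation)
  members <- ann$accession[ann$is_adhesome]
  compart <- tidy(catalogue)

  by_compartment <- compart |>
    dplyr::group_by(.data$compartment) |>
    dplyr::summarise(n = dplyr::n(),
                     n_adhesome = sum(.data$accession %in% members),
                     .groups = "drop")

  phospho_acc <- unique(catalogue$sites$accession)
  detected_adh <- intersect(catalogue_accessions(catalogue), members)

  sites_per_protein <- catalogue$sites |>
    dplyr::filter(.data$accession %in% members) |>
    dplyr::count(.data$accession, name = "n_sites")

  by_category <- ann |>
    dplyr::filter(.data$accession %in% detected_adh) |>
    dplyr::mutate(phosphorylated = .data$accession %in% phospho_acc) |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(n_detected = dplyr::n(),
                     n_phosphorylated = sum(.data$phosphorylated),
                     .groups = "drop")

  list(
    by_compartment = by_compartment,
    by_category = by_category,
    sites_per_protein = sites_per_protein,
    n_adhesome_detected = length(detected_adh),
    n_adhesome_phospho = length(intersect(phospho_acc, detected_adh)),
    max_sites_per_protein = if (nrow(sites_per_protein) > 0) {
      max(sites_per_protein$n_sites)
    } else 0L
  )
}

#' Phospho-residue composition of a protein subset
#'
#' Counts and percentages of serine, threonine and tyrosine phosphosites
#' among sites on proteins in `subset`. Percentages are reported to one
#' decimal (rounding half away from zero reproduces integer summaries); an
#' empty subset yields zero counts flagged `undefined`.
#'
#' @param sites site tibble with `accession` and `residue`
#' @param subset accessions to restrict to; `NULL` (default) uses all sites
#' @return a `residue_composition` tibble: one row per residue with `n` and
#'   `pct`
#' @export
residue_composition <- function(sites, subset = NULL) {
  sites <- tibble::as_tibble(sites)
  if (!is.null(subset)) sites <- sites[sites$accession %in% subset, , drop = FALSE]
  n <- setNames(integer(3), RESIDUES)
  tallied <- table(factor(sites$residue, levels = RESIDUES))
  n[names(tallied)] <- as.integer(tallied)
  total <- sum(n)
  pct <- if (total > 0) round_half_up(100 * unname(n) / total, 1) else rep(NA_real_, 3)
  structure(
    tibble(residue = RESIDUES, n = as.integer(unname(n)), pct = pct),
    class = c("residue_composition", class(tibble())),
    total = total, undefined = total == 0
  )
}

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
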