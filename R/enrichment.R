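# The subtractive comparison: NSAF normalization, replicate-mean fold
# changes, and the two pass/fail filters (proteins: fold >= 2 and >= 6 total
# treatment spectra; phosphosites: fold >= 9 or mean + k*sd, and >= 2
# treatment spectra).

#' Threshold policy for the subtractive filters
#'
#' Defaults follow the original subtractive analysis: proteins require at
#' least a twofold enrichment of mean NSAF and a minimum of six spectral
#' counts summed over treatment runs; phosphosites require at least a
#' ninefold enrichment of mean raw counts (or, under the `mean_plus_2sd`
#' rule, mean + `sd_multiplier` sample standard deviations of the finite
#' fold-change distribution) and a minimum of two treatment spectra. All
#' comparisons are inclusive ("at least"). `pseudocount` (off by default)
#' adds a constant to both condition means before the ratio.
#'
#' @param protein_min_fold minimum protein fold change (default 2)
#' @param protein_min_spectra minimum summed treatment spectra per protein (6)
#' @param site_min_spectra minimum summed treatment spectra per site (2)
#' @param site_fold_rule `"fixed"` (default) or `"mean_plus_2sd"`
#' @param site_fixed_fold fixed site fold threshold (9)
#' @param sd_multiplier s.d. multiplier for the adaptive rule (2)
#' @param sd_log_scale compute the adaptive threshold on log2 fold changes
#'   and back-transform (default FALSE: linear scale)
#' @param pseudocount constant added to both means before the ratio (0)
#' @return a `threshold_policy` list
#' @export
threshold_policy <- function(protein_min_fold = 2,
                             protein_min_spectra = 6L,
                             site_min_spectra = 2L,
                             site_fold_rule = c("fixed", "mean_plus_2sd"),
                             site_fixed_fold = 9,
                             sd_multiplier = 2,
                             sd_log_scale = FALSE,
                             pseudocount = 0) {
  site_fold_rule <- match.arg(site_fold_rule)
  vals <- c(protein_min_fold, protein_min_spectra, site_min_spectra,
            site_fixed_fold, sd_multiplier)
  if (any(vals <= 0)) abort("All thresholds must be strictly positive.")
  structure(
    list(protein_min_fold = protein_min_fold,
         protein_min_spectra = as.integer(protein_min_spectra),
         site_min_spectra = as.integer(site_min_spectra),
         site_fold_rule = site_fold_rule,
         site_fixed_fold = site_fixed_fold,
         sd_multiplier = sd_multiplier,
         sd_log_scale = sd_log_scale,
         pseudocount = pseudocount),
    class = "threshold_policy"
  )
}

#' @export
print.threshold_policy <- function(x, ...) {
  cat("<threshold_policy> protein: fold >= ", x$protein_min_fold,
      ", treatment spectra >= ", x$protein_min_spectra,
      "; site: rule ", x$site_fold_rule,
      " (fixed fold ", x$site_fixed_fold, ", sd x ", x$sd_multiplier,
      "), treatment spectra >= ", x$site_min_spectra, "\n", sep = "")
  invisible(x)
}

#' Normalized spectral abundance factors (NSAF)
#'
#' For protein p in run r, `NSAF = (SC/MW) / sum_q(SC_q/MW_q)`: spectral
#' counts divided by molecular weight, normalized to the run total so each
#' run's NSAF values sum to 1. This is the "normalized to total number of
#' IDs and molecular weight" abundance index used for the protein-level
#' subtractive comparison.
#'
#' @param x a [spectral_counts] object
#' @return tibble `accession`, `run_id`, `nsaf`; per-run values sum to 1
#' @export
nsaf <- function(x) {
  stopifnot(inherits(x, "spectral_counts"))
  tab <- dplyr::left_join(x$counts, x$proteins, by = "accession") |>
    dplyr::mutate(saf = .data$count / .data$molecular_weight) |>
    dplyr::group_by(.data$run_id) |>
    dplyr::mutate(run_total = sum(.data$saf)) |>
    dplyr::ungroup()
  dead <- unique(tab$run_id[tab$run_total == 0])
  if (length(dead) > 0) {
    abort(paste0("Run(s) with no spectra cannot be normalized: ",
                 paste(dead, collapse = ", ")))
  }
  tab |>
    dplyr::transmute(.data$accession, .data$run_id,
                     nsaf = .data$saf / .data$run_total)
}

# ratio of condition means with the infinite-fold convention
fold_from_means <- function(mean_treatment, mean_control, pseudocount = 0) {
  mt <- mean_treatment + pseudocount
  mc <- mean_control + pseudocount
  dplyr::case_when(
    mc > 0 ~ mt / mc,
    mt > 0 ~ Inf,
    TRUE ~ NaN  # both zero; callers drop these
  )
}

#' Protein-level fold changes on mean NSAF
#'
#' Mean NSAF per condition across replicate runs, fold change
#' treatment/control (`Inf` when control-absent), and total raw treatment
#' spectra (the abundance gate operates on raw counts). Proteins absent from
#' every run of both conditions are dropped with a message.
#'
#' @param x a [spectral_counts] object
#' @param policy a [threshold_policy] (only `pseudocount` is used here)
#' @return tibble: `accession`, `mean_treatment`, `mean_control`,
#'   `fold_change`, `total_treatment_spectra`, `control_absent`
#' @export
protein_fold_changes <- function(x, policy = threshold_policy()) {
  stopifnot(inherits(x, "spectral_counts"))
  if (!all(c("treatment", "control") %in% x$runs$condition)) {
    abort("Both conditions must be present for a subtractive comparison.")
  }
  norm <- nsaf(x)
  cond <- setNames(x$runs$condition, x$runs$run_id)

  means <- norm |>
    dplyr::mutate(condition = cond[.data$run_id]) |>
    dplyr::group_by(.data$accession, .data$condition) |>
    dplyr::summarise(m = mean(.data$nsaf), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "m",
                       names_prefix = "mean_")

  spectra <- x$counts |>
    dplyr::mutate(condition = cond[.data$run_id]) |>
    dplyr::filter(.data$condition == "treatment") |>
    dplyr::group_by(.data$accession) |>
    dplyr::summarise(total_treatment_spectra = sum(.data$count), .groups = "drop")

  res <- dplyr::left_join(means, spectra, by = "accession") |>
    dplyr::mutate(
      fold_change = fold_from_means(.data$mean_treatment, .data$mean_control,
                                    policy$pseudocount),
      control_absent = .data$mean_control == 0 & .data$mean_treatment > 0
    )
  dropped <- sum(is.nan(res$fold_change))
  if (dropped > 0) {
    inform(paste0("Dropped ", dropped,
                  " protein(s) with no spectra in either condition."))
    res <- res[!is.nan(res$fold_change), , drop = FALSE]
  }
  res[, c("accession", "mean_treatment", "mean_control", "fold_change",
          "total_treatment_spectra", "control_absent")]
}

apply_filter <- function(res, min_fold, min_spectra) {
  res |>
    dplyr::mutate(
      passes = .data$fold_change >= min_fold &
        .data$total_treatment_spectra >= min_spectra,
      fail_reason = dplyr::case_when(
        .data$fold_change < min_fold ~ "below_fold",
        .data$total_treatment_spectra < min_spectra ~ "below_abundance",
        TRUE ~ "none"
      )
    )
}

#' Subtractive protein filter
#'
#' A protein passes iff its NSAF fold change is at least
#' `policy$protein_min_fold` (infinite fold changes pass) AND its summed raw
#' treatment spectra reach `policy$protein_min_spectra`. When both gates
#' fail, the fold gate is reported as the reason.
#'
#' @param results output of [protein_fold_changes()], or a [spectral_counts]
#'   object (fold changes are computed first)
#' @param policy a [threshold_policy]
#' @return `enrichment_result` tibble with `passes` and `fail_reason`
#'   (`below_fold` / `below_abundance` / `none`) columns
#' @export
filter_proteins <- function(results, policy = threshold_policy()) {
  if (inherits(results, "spectral_counts")) {
    results <- protein_fold_changes(results, policy)
  }
  out <- apply_filter(results, policy$protein_min_fold, policy$protein_min_spectra)
  new_enrichment_result(out, level = "protein", policy = policy,
                        fold_threshold = policy$protein_min_fold)
}

#' Site-level fold changes on mean raw spectral counts
#'
#' Phosphosites are compared on mean raw spectral counts per condition (no
#' molecular-weight normalization applies at site level). Sites with no
#' spectra in either condition are dropped with a message.
#'
#' @param sites site tibble (see [read_phosphosites()])
#' @param runs run metadata; defaults to the table's `runs` attribute
#' @param policy a [threshold_policy] (only `pseudocount` is used here)
#' @return tibble keyed by (`accession`, `position`) with means, fold change
#'   and `total_treatment_spectra`
#' @export
site_fold_changes <- function(sites, runs = site_runs(sites),
                              policy = threshold_policy()) {
  runs <- validate_runs(runs)
  if (!all(c("treatment", "control") %in% runs$condition)) {
    abort("Both conditions must be present for a subtractive comparison.")
  }
  tr <- runs$run_id[runs$condition == "treatment"]
  ct <- runs$run_id[runs$condition == "control"]
  cnt_tr <- as.matrix(sites[, tr, drop = FALSE])
  cnt_ct <- as.matrix(sites[, ct, drop = FALSE])
  res <- tibble(
    accession = sites$accession,
    position = sites$position,
    residue = sites$residue,
    mean_treatment = rowMeans(cnt_tr),
    mean_control = rowMeans(cnt_ct),
    total_treatment_spectra = as.integer(rowSums(cnt_tr))
  ) |>
    dplyr::mutate(
      fold_change = fold_from_means(.data$mean_treatment, .data$mean_control,
                                    policy$pseudocount),
      control_absent = .data$mean_control == 0 & .data$mean_treatment > 0
    )
  dropped <- sum(is.nan(res$fold_change))
  if (dropped > 0) {
    inform(paste0("Dropped ", dropped,
                  " site(s) with no spectra in either condition."))
    res <- res[!is.nan(res$fold_change), , drop = FALSE]
  }
  res
}

#' Adaptive site fold-change threshold (mean + k s.d.)
#'
#' The threshold is computed over the finite fold changes only (control-
#' absent sites have infinite fold change, are excluded from the
#' distribution, and automatically satisfy the fold criterion). Sample
#' standard deviation uses the n-1 denominator. With
#' `policy$sd_log_scale = TRUE` the mean and s.d. are taken on log2 fold
#' changes and the threshold back-transformed.
#'
#' @param fold_changes numeric vector of fold changes (may contain `Inf`)
#' @param policy a [threshold_policy]
#' @return the fold-change threshold (a single number)
#' @export
site_fold_threshold <- function(fold_changes, policy = threshold_policy()) {
  if (policy$site_fold_rule == "fixed") return(policy$site_fixed_fold)
  fc <- fold_changes[is.finite(fold_changes)]
  if (length(fc) < 2) {
    abort(c(
      "Need at least 2 finite fold changes for the mean_plus_2sd rule.",
      i = "Use the fixed rule (site_fold_rule = \"fixed\") instead."
    ))
  }
  if (policy$sd_log_scale) {
    lf <- log2(fc[fc > 0])
    2^(mean(lf) + policy$sd_multiplier * stats::sd(lf))
  } else {
    mean(fc) + policy$sd_multiplier * stats::sd(fc)
  }
}

#' Subtractive phosphosite filter
#'
#' A site passes iff its raw-count fold change reaches the site threshold
#' (fixed ninefold by default, or mean + k s.d. of the finite fold-change
#' distribution) AND its summed treatment spectra reach
#' `policy$site_min_spectra`.
#'
#' @param sites site tibble, or the output of [site_fold_changes()]
#' @param runs run metadata (ignored when `sites` is already a fold-change
#'   table)
#' @param policy a [threshold_policy]
#' @return `enrichment_result` tibble; the applied fold threshold is stored
#'   in the `fold_threshold` attribute
#' @export
filter_sites <- function(sites, runs = NULL, policy = threshold_policy()) {
  res <- if ("fold_change" %in% names(sites)) {
    tibble::as_tibble(sites)
  } else {
    site_fold_changes(sites, runs %||% site_runs(sites), policy)
  }
  thr <- site_fold_threshold(res$fold_change, policy)
  out <- apply_filter(res, thr, policy$site_min_spectra)
  new_enrichment_result(out, level = "site", policy = policy,
                        fold_threshold = thr)
}

new_enrichment_result <- function(tab, level, policy, fold_threshold) {
  structure(
    tab,
    class = c("enrichment_result", class(tibble::as_tibble(tab))),
    level = level, policy = policy, fold_threshold = fold_threshold
  )
}

#' Accessions (or site keys) passing an enrichment filter
#' @param result an `enrichment_result`
#' @return character vector of passing accessions (proteins) or unique
#'   passing accessions (sites)
#' @export
passing_accessions <- function(result) {
  unique(result$accession[result$passes])
}

#' @export
tidy.enrichment_result <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "enrichment_result")
  out
}

#' @export
glance.enrichment_result <- function(x, ...) {
  pol <- attr(x, "policy")
  tibble(
    level = attr(x, "level"),
    n = nrow(x),
    n_pass = sum(x$passes),
    n_control_absent = sum(x$control_absent),
    fold_threshold = attr(x, "fold_threshold"),
    min_spectra = if (attr(x, "level") == "protein") pol$protein_min_spectra
                  else pol$site_min_spectra
  )
}

#' Write an enrichment result as TSV
#'
#' Infinite fold changes are serialized as the token `Inf`.
#' @param result an `enrichment_result`
#' @param path output path
#' @export
write_enrichment_result <- function(result, path) {
  readr::write_tsv(tidy(result), path, progress = FALSE)
  invisible(path)
}
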