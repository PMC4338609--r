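# Group-based kinase-substrate prediction: a site's 15-mer window is scored
# by mean substitution-matrix similarity to a kinase's known substrate
# windows; per-kinase cutoffs are calibrated to a target empirical
# false-positive rate on background windows (high stringency: 2% for S/T
# kinases, 4% for Y kinases).

#' Construct a kinase model
#'
#' @param kinase_id kinase (or group/family) name
#' @param group kinase group, e.g. CMGC, AGC, TK, CAMK, STE, CK1, TKL, other
#' @param residue_class `"ST"` (serine/threonine kinase) or `"Y"` (tyrosine
#'   kinase)
#' @param substrates character vector of known substrate 15-mer windows
#'   (site at position 8)
#' @param threshold score cutoff (set by [calibrate_threshold()])
#' @param calibrated_fpr realized background FPR at `threshold`
#' @return a `kinase_model` object
#' @export
kinase_model <- function(kinase_id, group, residue_class = c("ST", "Y"),
                         substrates, threshold = NA_real_,
                         calibrated_fpr = NA_real_) {
  residue_class <- match.arg(residue_class)
  if (length(substrates) == 0) abort("A kinase model needs >= 1 substrate window.")
  if (any(nchar(substrates) != WINDOW_WIDTH)) {
    abort(paste0("Substrate windows must be ", WINDOW_WIDTH, "-mers."))
  }
  centre <- substr(substrates, WINDOW_CENTRE, WINDOW_CENTRE)
  ok <- if (residue_class == "ST") centre %in% c("S", "T") else centre == "Y"
  if (!all(ok)) {
    abort(paste0("Substrate centre residues must match residue class ",
                 residue_class, "."))
  }
  structure(
    list(kinase_id = kinase_id, group = group, residue_class = residue_class,
         substrates = substrates, threshold = threshold,
         calibrated_fpr = calibrated_fpr),
    class = "kinase_model"
  )
}

#' @export
print.kinase_model <- function(x, ...) {
  cat("<kinase_model> ", x$kinase_id, " (", x$group, ", ", x$residue_class,
      "): ", length(x$substrates), " substrate window(s); threshold ",
      ifelse(is.na(x$threshold), "uncalibrated",
             sprintf("%.2f (FPR %.3f)", x$threshold, x$calibrated_fpr)),
      "\n", sep = "")
  invisible(x)
}

#' @export
glance.kinase_model <- function(x, ...) {
  tibble(kinase_id = x$kinase_id, group = x$group,
         residue_class = x$residue_class,
         n_substrates = length(x$substrates),
         threshold = x$threshold, calibrated_fpr = x$calibrated_fpr)
}

#' Read a substitution matrix from a TSV table
#'
#' First column `aa` holds row names; remaining columns are amino acids.
#' The bundled default is BLOSUM62
#' (`system.file("extdata", "blosum62.tsv", package = "adhesiomics")`).
#'
#' @param path TSV path; default the bundled BLOSUM62
#' @return a symmetric numeric matrix with amino-acid dimnames
#' @export
read_substitution_matrix <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "blosum62.tsv", package = "adhesiomics")
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  m
}

# expand a substitution matrix with zero-scoring rows/cols for the gap
# symbol and any residue code it lacks
scoring_lookup <- function(matrix, extra = GAP_SYMBOL) {
  syms <- union(rownames(matrix), extra)
  full <- base::matrix(0, length(syms), length(syms), dimnames = list(syms, syms))
  full[rownames(matrix), colnames(matrix)] <- matrix
  full[extra, ] <- 0
  full[, extra] <- 0
  full
}

windows_to_char <- function(windows) {
  do.call(rbind, strsplit(windows, "", fixed = TRUE))
}

#' Score windows against a kinase model
#'
#' The score of a window is the mean, over the model's substrate windows, of
#' the summed position-wise substitution-matrix similarity. The terminal gap
#' symbol `-` contributes 0 at its positions (in the window or in the
#' substrate).
#'
#' @param windows character vector of 15-mer windows
#' @param model a [kinase_model]
#' @param matrix substitution matrix (default bundled BLOSUM62)
#' @return numeric vector of scores, one per window
#' @export
score_windows <- function(windows, model, matrix = read_substitution_matrix()) {
  if (length(windows) == 0) return(numeric(0))
  if (any(nchar(windows) != WINDOW_WIDTH)) {
    abort(paste0("Windows must be ", WINDOW_WIDTH, "-mers."))
  }
  lk <- scoring_lookup(matrix)
  unknown <- setdiff(unique(unlist(strsplit(c(windows, model$substrates), ""))),
                     rownames(lk))
  if (length(unknown) > 0) lk <- scoring_lookup(matrix, c(GAP_SYMBOL, unknown))
  wch <- windows_to_char(windows)
  per_substrate <- vapply(model$substrates, function(s) {
    sch <- strsplit(s, "", fixed = TRUE)[[1]]
    sims <- lk[cbind(as.vector(wch), rep(sch, each = nrow(wch)))]
    rowSums(base::matrix(sims, nrow = nrow(wch)))
  }, numeric(nrow(wch)))
  rowMeans(base::matrix(per_substrate, nrow = nrow(wch)))
}

#' Score one window (scalar convenience wrapper)
#'
#' Returns `NA` with a message when the window's central residue is
#' incompatible with the model's residue class (such sites are skipped).
#'
#' @inheritParams score_windows
#' @param window a single 15-mer
#' @return a single score, or `NA_real_` if incompatible
#' @export
score_window <- function(window, model, matrix = read_substitution_matrix()) {
  centre <- substr(window, WINDOW_CENTRE, WINDOW_CENTRE)
  ok <- if (model$residue_class == "ST") centre %in% c("S", "T") else centre == "Y"
  if (!ok) {
    inform(paste0("Window centre '", centre, "' incompatible with ",
                  model$residue_class, " kinase ", model$kinase_id,
                  "; site skipped."))
    return(NA_real_)
  }
  score_windows(window, model, matrix)
}

#' Calibrate a kinase score threshold to a target false-positive rate
#'
#' The threshold is the smallest background score t such that the fraction
#' of background windows scoring strictly above t is at most `target_fpr`
#' (empirical quantile, ties broken upward — conservative). `target_fpr = 0`
#' yields the background maximum; `target_fpr = 1` yields `-Inf` (everything
#' passes). At least 100 background windows of the model's residue class are
#' required.
#'
#' @param model a [kinase_model]
#' @param background_windows character vector of 15-mer windows
#' @param target_fpr target empirical FPR (2% is the stringent convention
#'   for S/T kinases, 4% for Y kinases)
#' @param matrix substitution matrix
#' @return the model with `threshold` and `calibrated_fpr` filled in
#' @export
calibrate_threshold <- function(model, background_windows, target_fpr,
                                matrix = read_substitution_matrix()) {
  centre <- substr(background_windows, WINDOW_CENTRE, WINDOW_CENTRE)
  keep <- if (model$residue_class == "ST") centre %in% c("S", "T") else centre == "Y"
  bg <- background_windows[keep]
  if (length(bg) < 100) {
    abort(paste0("Calibration needs >= 100 background windows of class ",
                 model$residue_class, "; got ", length(bg), "."))
  }
  s <- sort(score_windows(bg, model, matrix))
  n <- length(s)
  allowed <- floor(target_fpr * n)
  thr <- if (allowed >= n) -Inf else s[n - allowed]
  model$threshold <- thr
  model$calibrated_fpr <- mean(s > thr)
  model
}

#' Predict kinases for phosphosites
#'
#' Every compatible (site, kinase) pair is scored; a prediction passes when
#' its score strictly exceeds the kinase's calibrated threshold (ties at the
#' cutoff do not pass). Multiple kinases may be assigned to one site;
#' passing predictions are ranked per site by score minus threshold. S/T
#' kinases never see tyrosine-centred windows and vice versa.
#'
#' @param sites site tibble with `accession`, `position`, `residue`, `window`
#' @param models list of calibrated [kinase_model]s
#' @param matrix substitution matrix
#' @param keep_all also return non-passing scored pairs (default FALSE)
#' @return tibble: `accession`, `position`, `residue`, `kinase_id`, `group`,
#'   `score`, `threshold`, `margin`, `passes`, `rank` (per-site rank among
#'   passing predictions)
#' @export
predict_kinases <- function(sites, models, matrix = read_substitution_matrix(),
                            keep_all = FALSE) {
  sites <- tibble::as_tibble(sites)
  if (any(vapply(models, function(m) is.na(m$threshold), logical(1)))) {
    abort("All kinase models must be calibrated before prediction.")
  }
  scored <- purrr::map_dfr(models, function(m) {
    compat <- if (m$residue_class == "ST") sites$residue %in% c("S", "T")
              else sites$residue == "Y"
    sub <- sites[compat, , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    tibble(
      accession = sub$accession, position = sub$position,
      residue = sub$residue,
      kinase_id = m$kinase_id, group = m$group,
      score = score_windows(sub$window, m, matrix),
      threshold = m$threshold
    )
  })
  if (nrow(scored) == 0) {
    return(tibble(accession = character(), position = integer(),
                  residue = character(), kinase_id = character(),
                  group = character(), score = numeric(),
                  threshold = numeric(), margin = numeric(),
                  passes = logical(), rank = integer()))
  }
  scored <- scored |>
    dplyr::mutate(margin = .data$score - .data$threshold,
                  passes = .data$score > .data$threshold)
  if (!keep_all) scored <- scored[scored$passes, , drop = FALSE]
  scored |>
    dplyr::group_by(.data$accession, .data$position) |>
    dplyr::arrange(dplyr::desc(.data$margin), .by_group = TRUE) |>
    dplyr::mutate(rank = ifelse(.data$passes, cumsum(.data$passes), NA_integer_)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$accession, .data$position, .data$rank)
}

#' Validate predictions against known kinase-substrate pairs
#'
#' Each known (site, kinase) pair is classified as: `correct` (the known
#' kinase is among the site's passing predictions), `different_family_member`
#' (not the kinase itself, but a passing prediction from the same group —
#' only with `family_credit = TRUE`), `kinase_not_in_tool` (the known kinase
#' has no model), or `no_prediction` (no passing prediction matches the
#' known kinase or, under family credit, its group).
#'
#' @param predictions output of [predict_kinases()]
#' @param known_pairs tibble `accession`, `position`, `kinase_id`
#' @param models the model list used for prediction
#' @param family_credit award the intermediate category to same-group
#'   predictions (default TRUE)
#' @return a `kinase_validation` tibble (one row per known pair, with
#'   `category`); `glance()` reports category counts and fraction correct
#' @export
validate_known <- function(predictions, known_pairs, models,
                           family_credit = TRUE) {
  known_pairs <- tibble::as_tibble(known_pairs)
  model_ids <- vapply(models, `[[`, character(1), "kinase_id")
  model_groups <- setNames(vapply(models, `[[`, character(1), "group"), model_ids)
  pass <- predictions[predictions$passes, , drop = FALSE]
  classify <- function(acc, pos, kin) {
    if (!kin %in% model_ids) return("kinase_not_in_tool")
    hits <- pass[pass$accession == acc & pass$position == pos, , drop = FALSE]
    if (kin %in% hits$kinase_id) return("correct")
    if (family_credit && any(hits$group == model_groups[[kin]])) {
      return("different_family_member")
    }
    "no_prediction"
  }
  out <- known_pairs |>
    dplyr::mutate(category = purrr::pmap_chr(
      list(.data$accession, .data$position, .data$kinase_id), classify))
  structure(out, class = c("kinase_validation", class(tibble())))
}

#' @export
glance.kinase_validation <- function(x, ...) {
  tab <- table(factor(x$category, levels = c("correct", "different_family_member",
                                             "kinase_not_in_tool", "no_prediction")))
  tibble(
    n_known = nrow(tibble::as_tibble(x)),
    n_correct = as.integer(tab[["correct"]]),
    n_different_family_member = as.integer(tab[["different_family_member"]]),
    n_kinase_not_in_tool = as.integer(tab[["kinase_not_in_tool"]]),
    n_no_prediction = as.integer(tab[["no_prediction"]]),
    fraction_correct = as.integer(tab[["correct"]]) / max(nrow(x), 1L)
  )
}

#' Read a kinase substrate library
#'
#' TSV with header `kinase_id`, `group`, `residue_class`, `substrate_window`;
#' one row per substrate window, grouped into one model per kinase.
#'
#' @param path TSV path
#' @return named list of [kinase_model]s
#' @export
read_kinase_library <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("kinase_id", "group", "residue_class", "substrate_window")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    abort(paste0("Kinase library missing column(s): ", paste(miss, collapse = ", ")))
  }
  tab |>
    dplyr::group_by(.data$kinase_id) |>
    dplyr::group_map(function(g, key) {
      kinase_model(key$kinase_id, g$group[1], g$residue_class[1],
                   g$substrate_window)
    }) |>
    (\(ms) setNames(ms, vapply(ms, `[[`, character(1), "kinase_id")))()
}

#' Write a kinase substrate library
#' @param models list of [kinase_model]s
#' @param path TSV path
#' @export
write_kinase_library <- function(models, path) {
  tab <- purrr::map_dfr(models, function(m) {
    tibble(kinase_id = m$kinase_id, group = m$group,
           residue_class = m$residue_class, substrate_window = m$substrates)
  })
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}
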