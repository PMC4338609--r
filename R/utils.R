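# Shared vocabulary of the data model.

#' Phospho-acceptor residues
#' @keywords internal
RESIDUES <- c("S", "T", "Y")

#' Closed set of adhesome functional categories
#' @keywords internal
ADHESOME_CATEGORIES <- c(
  "receptor", "adaptor", "actin_regulator", "actin",
  "GEF", "GAP", "kinase", "phosphatase", "other"
)

# 20 standard amino acids, one-letter code
AMINO_ACIDS <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

GAP_SYMBOL <- "-"
WINDOW_WIDTH <- 15L
WINDOW_CENTRE <- 8L

SITE_CORE_COLS <- c(
  "accession", "position", "residue", "window",
  "localization_score", "identification_score"
)

#' Split run identifiers of the form "<condition>_<replicate>"
#'
#' File headers carry one column per MS run; by convention the run id encodes
#' its condition ("treatment" or "control") and a replicate label, e.g.
#' `treatment_A`. Used whenever run metadata is not supplied explicitly.
#'
#' @param run_ids character vector of run identifiers
#' @return a tibble with columns `run_id`, `condition`, `replicate`
#' @export
runs_from_names <- function(run_ids) {
  m <- stringr::str_match(run_ids, "^(treatment|control)_(.+)$")
  bad <- run_ids[is.na(m[, 1])]
  if (length(bad) > 0) {
    abort(c(
      "Cannot infer run conditions from run ids; expected '<condition>_<replicate>'.",
      x = paste("Offending run ids:", paste(bad, collapse = ", ")),
      i = "Pass a `runs` tibble (run_id, condition, replicate) explicitly."
    ))
  }
  tibble(run_id = run_ids, condition = m[, 2], replicate = m[, 3])
}

validate_runs <- function(runs) {
  stopifnot(is.data.frame(runs))
  need <- c("run_id", "condition")
  miss <- setdiff(need, names(runs))
  if (length(miss) > 0) {
    abort(paste0("`runs` is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(runs$run_id)) {
    abort("Run ids must be unique within an experiment.")
  }
  bad <- setdiff(unique(runs$condition), c("treatment", "control"))
  if (length(bad) > 0) {
    abort(paste0("Unknown condition(s): ", paste(bad, collapse = ", "),
                 " (allowed: treatment, control)"))
  }
  if (!"replicate" %in% names(runs)) runs$replicate <- runs$run_id
  tibble::as_tibble(runs)
}

# TRUE where x is a whole number (tolerating float representation of integers)
is_wholenumber <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}

# split "P1|12" style keys are avoided; site keys are built with this helper
site_key <- function(accession, position) paste(accession, position, sep = "@")
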