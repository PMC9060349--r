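#' Assemble a single-perturbation steady-state dataset
#'
#' Bundles the basal (unperturbed) steady-state activity vector of `n`
#' modules (genes) with the `n` steady-state vectors observed under the
#' elementary perturbation of each single module. Column `k` of `perturbed`
#' holds the full activity profile measured when module `k` alone was
#' perturbed (knocked out or knocked down), so the perturbation-to-module
#' map is the identity on `module_ids`.
#'
#' @param module_ids character vector of unique module (gene) identifiers.
#' @param basal numeric vector of basal activity levels, one per module.
#' @param perturbed numeric `n x n` matrix; column `k` is the steady state
#'   under perturbation of module `k`. Dimnames, if present, must agree with
#'   `module_ids`.
#' @param value_scale `"positive_abundance"` for non-negative expression
#'   levels (counts, intensities) or `"signed_zscore"` for consensus
#'   signatures already normalized to a signed z-score scale.
#' @return An object of class `"perturbation_dataset"`: a list with elements
#'   `module_ids`, `basal`, `perturbed`, `value_scale`.
#' @seealso [global_response()] to turn the dataset into a relative-change
#'   matrix, [simulate_perturbations()] to generate one from a model network.
#' @export
perturbation_dataset <- function(module_ids, basal, perturbed,
                                 value_scale = c("positive_abundance",
                                                 "signed_zscore")) {
  value_scale <- match.arg(value_scale)
  module_ids <- as.character(module_ids)
  n <- length(module_ids)
  if (n < 1L) stop("at least one module is required")
  if (anyDuplicated(module_ids)) stop("module identifiers must be unique")
  basal <- as.numeric(basal)
  if (length(basal) != n) stop("'basal' must have one entry per module")
  perturbed <- as.matrix(perturbed)
  if (!is.numeric(perturbed)) stop("'perturbed' must be numeric")
  if (nrow(perturbed) != n || ncol(perturbed) != n)
    stop("'perturbed' must be an n x n matrix with one column per perturbed module")
  if (!is.null(rownames(perturbed)) && !identical(rownames(perturbed), module_ids))
    stop("row names of 'perturbed' disagree with 'module_ids'")
  if (!is.null(colnames(perturbed)) && !identical(colnames(perturbed), module_ids))
    stop("column names of 'perturbed' disagree with 'module_ids'")
  if (any(!is.finite(basal)) || any(!is.finite(perturbed)))
    stop("activity values must be finite")
  if (value_scale == "positive_abundance" &&
      (any(basal < 0) || any(perturbed < 0)))
    stop("negative activity is not allowed on the positive_abundance scale")
  dimnames(perturbed) <- list(module_ids, module_ids)
  names(basal) <- module_ids
  structure(list(module_ids = module_ids, basal = basal,
                 perturbed = perturbed, value_scale = value_scale),
            class = "perturbation_dataset")
}

#' @export
print.perturbation_dataset <- function(x, ...) {
  cat("Single-perturbation steady-state dataset\n")
  cat(sprintf("  modules: %d (%s%s)\n", length(x$module_ids),
              paste(utils::head(x$module_ids, 4L), collapse = ", "),
              if (length(x$module_ids) > 4L) ", ..." else ""))
  cat(sprintf("  value scale: %s\n", x$value_scale))
  invisible(x)
}

#' Expression matrix across all conditions of a perturbation dataset
#'
#' Returns the `n x (n + 1)` matrix whose first column is the basal profile
#' and whose remaining columns are the perturbed profiles. This is the
#' sample set handed to the mutual-information baselines, which treat the
#' perturbation panel as their collection of transcriptomes.
#'
#' @param data a [perturbation_dataset()].
#' @param basal_label column name used for the basal profile.
#' @return numeric matrix with modules as rows and conditions as columns.
#' @export
condition_matrix <- function(data, basal_label = "basal") {
  stopifnot(inherits(data, "perturbation_dataset"))
  out <- cbind(data$basal, data$perturbed)
  colnames(out) <- c(basal_label, data$module_ids)
  out
}

# shared validator for labeled square matrices (R, r, MI, Z)
check_square_named <- function(M, what = "matrix") {
  if (!is.matrix(M) || !is.numeric(M)) stop(sprintf("'%s' must be a numeric matrix", what))
  if (nrow(M) != ncol(M)) stop(sprintf("'%s' must be square", what))
  if (any(!is.finite(M))) stop(sprintf("'%s' contains non-finite entries", what))
  if (is.null(rownames(M))) {
    ids <- paste0("M", seq_len(nrow(M)))
    dimnames(M) <- list(ids, ids)
  } else if (!identical(rownames(M), colnames(M))) {
    stop(sprintf("row and column names of '%s' must agree", what))
  }
  M
}
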