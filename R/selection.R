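#' Select the top fraction (or count) of individuals by breeding value
#'
#' Ties at the cutoff are broken by id sort order (a message is emitted so
#' the arbitrary choice is visible).
#'
#' @param bvs named numeric vector of breeding values (names are ids), or a
#'   data.frame with columns `id` and `value`.
#' @param fraction fraction of the population to select.
#' @param count absolute number selected (overrides `fraction`).
#' @return character vector of selected ids.
#' @export
select_top <- function(bvs, fraction = 0.05, count = NULL) {
  if (is.data.frame(bvs)) bvs <- stats::setNames(bvs$value, bvs$id)
  if (length(bvs) == 0L) stop("empty breeding-value set")
  n_sel <- if (!is.null(count)) as.integer(count)
  else max(1L, round(fraction * length(bvs)))
  if (n_sel > length(bvs)) stop("selection count exceeds population size")
  ord <- order(-bvs, names(bvs))
  cut_val <- bvs[ord][n_sel]
  if (sum(bvs == cut_val) > 1 && n_sel < length(bvs) &&
      bvs[ord][min(n_sel + 1L, length(bvs))] == cut_val)
    message("ties at the selection cutoff broken by id order")
  names(bvs)[ord][seq_len(n_sel)]
}

#' Status number of a selected set
#'
#' \eqn{N_s = 1 / (2\theta)} where the group coancestry \eqn{\theta} is the
#' mean over all ordered pairs (self-pairs included) of the pairwise
#' coancestry, i.e. half the additive relationship (self-coancestry is half
#' the matrix diagonal). A set of N unrelated non-inbred trees has
#' \eqn{N_s = N}; relatedness or inbreeding shrinks it.
#'
#' @param rel additive relationship matrix or a pedigree data.frame
#'   (`id`, `mother`, `father`), from which A is built.
#' @param ids members of the selected set.
#' @return the status number (scalar).
#' @export
status_number <- function(rel, ids) {
  if (is.data.frame(rel)) rel <- A_additive(rel)
  missing_ids <- setdiff(ids, rownames(rel))
  if (length(missing_ids))
    stop("ids not covered by the relationship source: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  a <- unclass(rel)[ids, ids, drop = FALSE]
  theta <- mean(a) / 2
  if (theta <= 0) stop("group coancestry is zero: status number undefined")
  1 / (2 * theta)
}

#' Expected genetic gain from a selected set
#'
#' Gain is expressed as the mean breeding value of the selected trees as a
#' percentage of the population phenotypic mean on the modeling scale.
#'
#' @param bvs named numeric vector (or `id`/`value` data.frame) of breeding
#'   values.
#' @param selected ids of the selected set.
#' @param population_mean phenotypic mean on the analysis scale.
#' @return gain in percent.
#' @export
expected_gain <- function(bvs, selected, population_mean) {
  if (is.data.frame(bvs)) bvs <- stats::setNames(bvs$value, bvs$id)
  if (!all(selected %in% names(bvs))) stop("selected ids missing from bvs")
  if (population_mean == 0) stop("zero population mean: gain undefined")
  100 * mean(bvs[selected]) / population_mean
}

#' Cross-model corrected gain and selection overlap
#'
#' Re-scores the set selected under one model with a reference model's
#' breeding values (the paper's device for quantifying gain overestimation
#' by unreliable pedigree models): corrected mean BV, corrected gain,
#' percent overlap with the reference model's own selection, and the
#' percent overestimation of the nominal gain relative to the corrected one.
#'
#' @param bvs_model breeding values of the evaluated model (named vector or
#'   `id`/`value` data.frame).
#' @param bvs_reference breeding values of the reference model (same
#'   individuals).
#' @param selected_model,selected_reference the two selected id sets.
#' @param population_mean phenotypic mean on the analysis scale.
#' @return list `corrected_mean_bv`, `corrected_gain_percent`,
#'   `overlap_percent`, `nominal_gain_percent`, `overestimation_percent`.
#' @export
corrected_gain <- function(bvs_model, bvs_reference, selected_model,
                           selected_reference, population_mean) {
  if (is.data.frame(bvs_model))
    bvs_model <- stats::setNames(bvs_model$value, bvs_model$id)
  if (is.data.frame(bvs_reference))
    bvs_reference <- stats::setNames(bvs_reference$value, bvs_reference$id)
  if (!setequal(names(bvs_model), names(bvs_reference)))
    stop("models score different individuals")
  nominal <- expected_gain(bvs_model, selected_model, population_mean)
  corr_bv <- mean(bvs_reference[selected_model])
  corr_gain <- 100 * corr_bv / population_mean
  overlap <- 100 * length(intersect(selected_model, selected_reference)) /
    length(selected_reference)
  over <- if (corr_gain != 0) 100 * (nominal - corr_gain) / corr_gain
  else NA_real_
  list(corrected_mean_bv = corr_bv, corrected_gain_percent = corr_gain,
       overlap_percent = overlap, nominal_gain_percent = nominal,
       overestimation_percent = over)
}

#' Selection report for one model
#'
#' Bundles top-fraction selection, gain, and diversity accounting (and the
#' cross-model correction when a reference model is supplied) into one
#' record.
#'
#' @param bvs breeding values (named vector or `id`/`value` data.frame).
#' @param rel relationship source for [status_number()] (pedigree data.frame
#'   or additive matrix).
#' @param population_mean phenotypic mean on the analysis scale.
#' @param fraction selected fraction.
#' @param model_label label recorded in the report.
#' @param reference optional list with `bvs` and `selected` of the
#'   reference model.
#' @return list mirroring the per-model selection summary: selected ids,
#'   census size, mean BV, gain, status number, and corrected quantities.
#' @export
selection_report <- function(bvs, rel, population_mean, fraction = 0.05,
                             model_label = "model", reference = NULL) {
  if (is.data.frame(bvs)) bvs <- stats::setNames(bvs$value, bvs$id)
  sel <- select_top(bvs, fraction)
  out <- list(model_label = model_label, selected_ids = sel,
              census = length(sel), mean_bv = mean(bvs[sel]),
              gain_percent = expected_gain(bvs, sel, population_mean),
              status_number = status_number(rel, sel))
  if (!is.null(reference)) {
    cg <- corrected_gain(bvs, reference$bvs, sel, reference$selected,
                         population_mean)
    out <- c(out, cg)
  }
  out
}
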