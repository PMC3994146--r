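#' Analysis configuration
#'
#' Collects every tunable of the pipeline in one validated list. Defaults
#' follow the study design: significance at alpha = 0.05, the HIGH/LOW
#' activity cutoff at 50% of the maximum HCE, and 1000 tip-label reshuffles
#' for the phylogenetic-signal null.
#'
#' @param alpha significance level for the enrichment t-test, the ANCOVA and
#'   the post-hoc pairwise tests. Default 0.05.
#' @param activity_cutoff_fraction fraction of the maximum reference-treatment
#'   HCE above which a taxon is classed HIGH activity. Default 0.5.
#' @param activity_reference treatment whose HCE ranks activity. Default "H".
#' @param n_reshuffles permutations for the parsimony null. Default 1000.
#' @param rng_seed integer master seed recorded in the run summary.
#' @param min_spots minimum probe spots per regression. Default 3 (slope SE
#'   needs residual df >= 1).
#' @param posthoc_adjust p-adjustment across the three pairwise ANCOVAs:
#'   "none" (as in the original procedure) or "holm".
#' @param ancova_model "interaction" fits delta ~ fluorescence * treatment and
#'   tests all treatment terms jointly (intercept shifts and slope
#'   differences); "intercept" fits the classic common-slope ANCOVA
#'   delta ~ fluorescence + treatment.
#' @param enrichment_alpha alpha for the one-sided slope>0 enrichment test;
#'   defaults to \code{alpha}.
#' @param treatment_concentrations named molar concentrations, default
#'   c(H = 5e-6, M = 5e-7, L = 5e-8).
#' @return object of class \code{chipsip_config} (a named list).
#' @export
analysis_config <- function(alpha = 0.05,
                            activity_cutoff_fraction = 0.5,
                            activity_reference = "H",
                            n_reshuffles = 1000L,
                            rng_seed = 1L,
                            min_spots = 3L,
                            posthoc_adjust = c("none", "holm"),
                            ancova_model = c("interaction", "intercept"),
                            enrichment_alpha = NULL,
                            treatment_concentrations =
                              c(H = 5e-6, M = 5e-7, L = 5e-8)) {
  posthoc_adjust <- match.arg(posthoc_adjust)
  ancova_model <- match.arg(ancova_model)
  if (is.null(enrichment_alpha)) enrichment_alpha <- alpha
  stopifnot(alpha > 0, alpha < 1,
            enrichment_alpha > 0, enrichment_alpha < 1,
            activity_cutoff_fraction > 0, activity_cutoff_fraction <= 1,
            activity_reference %in% TREATMENTS,
            n_reshuffles >= 1, min_spots >= 3)
  if (!all(TREATMENTS %in% names(treatment_concentrations))) {
    stop("treatment_concentrations must name H, M and L", call. = FALSE)
  }
  structure(list(
    alpha = alpha,
    activity_cutoff_fraction = activity_cutoff_fraction,
    activity_reference = activity_reference,
    n_reshuffles = as.integer(n_reshuffles),
    rng_seed = as.integer(rng_seed),
    min_spots = as.integer(min_spots),
    posthoc_adjust = posthoc_adjust,
    ancova_model = ancova_model,
    enrichment_alpha = enrichment_alpha,
    treatment_concentrations = treatment_concentrations[TREATMENTS]
  ), class = "chipsip_config")
}

#' Read / write a configuration as JSON
#'
#' @param path file path.
#' @return \code{read_config} returns a \code{chipsip_config}.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$treatment_concentrations)) {
    raw$treatment_concentrations <- unlist(raw$treatment_concentrations)
  }
  do.call(analysis_config, raw)
}

#' @rdname read_config
#' @param config a \code{chipsip_config}.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "chipsip_config"))
  out <- unclass(config)
  # named vectors must serialize as JSON objects, not bare arrays
  out$treatment_concentrations <- as.list(out$treatment_concentrations)
  jsonlite::write_json(out, path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
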