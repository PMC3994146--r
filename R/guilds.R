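#' Rank taxa by single-concentration HCE and split HIGH vs LOW activity
#'
#' Activity is defined by the HCE at one reference concentration (default H).
#' HCEs are ranked high to low, the percent change between successive ranked
#' values is reported (the diagnostic used to place the cutoff), and taxa at
#' or above \code{cutoff_fraction} of the maximum HCE among enriched taxa are
#' classed HIGH. The 50%-of-maximum default corresponded to a local high in
#' that percent-change series in the original dataset.
#'
#' @param hces HCE estimates (rows of \code{\link{fit_all_hce}}) at a single
#'   treatment.
#' @param cutoff_fraction fraction of the maximum enriched HCE (default 0.5).
#' @return list with \code{classes} (taxon, hce_reference, enriched, rank,
#'   pct_change, class), \code{cutoff} and \code{max_hce}; empty classes with
#'   a warning when no taxon is enriched.
#' @export
rank_activity <- function(hces, cutoff_fraction = 0.5) {
  stopifnot(length(unique(hces$treatment)) <= 1)
  if (!any(hces$enriched)) {
    warning("no enriched taxa at the reference treatment; ",
            "no activity classes assigned", call. = FALSE)
    return(list(classes = data.frame(taxon = character(0),
                                     hce_reference = numeric(0),
                                     enriched = logical(0),
                                     rank = integer(0),
                                     pct_change = numeric(0),
                                     class = character(0)),
                cutoff = NA_real_, max_hce = NA_real_))
  }
  ord <- order(hces$slope, decreasing = TRUE)
  ranked <- hces[ord, , drop = FALSE]
  max_hce <- max(ranked$slope[ranked$enriched])
  cutoff <- cutoff_fraction * max_hce
  v <- ranked$slope
  pct <- c(100 * (v[-length(v)] - v[-1]) / abs(v[-1]), NA_real_)
  list(
    classes = data.frame(
      taxon = ranked$taxon,
      hce_reference = v,
      enriched = ranked$enriched,
      rank = seq_along(v),
      pct_change = pct,
      class = ifelse(v >= cutoff, "HIGH", "LOW"),
      stringsAsFactors = FALSE
    ),
    cutoff = cutoff,
    max_hce = max_hce
  )
}

#' ANCOVA test for a concentration effect on isotopic enrichment
#'
#' For one taxon's spots across treatments, fits a least-squares model of
#' delta on fluorescence and treatment and tests all treatment terms jointly
#' with a partial F-test against the fluorescence-only model. The default
#' "interaction" model (delta ~ fluorescence * treatment) captures both a
#' shifted intercept (overall enrichment) and a changed slope (HCE) per
#' treatment; "intercept" drops the interaction for the classic common-slope
#' ANCOVA.
#'
#' @param spots probe rows for one taxon, all available treatments, with
#'   delta values.
#' @param config \code{\link{analysis_config}}.
#' @return list: \code{p_value}, \code{model} (the full \code{lm}),
#'   \code{treatments} present, \code{partial} (TRUE when a level is
#'   missing), \code{n}.
#' @export
ancova_concentration_effect <- function(spots, config = analysis_config()) {
  spots <- droplevels(spots)
  levs <- levels(spots$treatment)
  partial <- length(levs) < 3
  if (length(levs) < 2) {
    stop("ANCOVA needs >= 2 treatment levels, got ",
         paste(levs, collapse = ","), call. = FALSE)
  }
  counts <- table(spots$treatment)
  if (any(counts < config$min_spots)) {
    stop("treatment level(s) below min_spots: ",
         paste(names(counts)[counts < config$min_spots], collapse = ","),
         call. = FALSE)
  }
  full <- if (config$ancova_model == "interaction") {
    lm(delta ~ fluor * treatment, data = spots)
  } else {
    lm(delta ~ fluor + treatment, data = spots)
  }
  reduced <- lm(delta ~ fluor, data = spots)
  # partial F computed from the two RSS directly: anova() returns NaN on
  # (near-)perfect fits, where 0/0 arises; decide those cases by the size of
  # the RSS drop relative to the response scale
  rss_r <- sum(stats::residuals(reduced)^2)
  rss_f <- sum(stats::residuals(full)^2)
  df_num <- stats::df.residual(reduced) - stats::df.residual(full)
  df_den <- stats::df.residual(full)
  tss <- sum((spots$delta - mean(spots$delta))^2)
  eps <- 1e-9 * max(tss, 1)
  p <- if (rss_r - rss_f <= eps) {
    1  # treatment terms explain nothing beyond fluorescence
  } else if (rss_f <= eps || df_den < 1) {
    0  # a real treatment effect with an (essentially) exact full fit
  } else {
    f <- ((rss_r - rss_f) / df_num) / (rss_f / df_den)
    pf(f, df_num, df_den, lower.tail = FALSE)
  }
  list(p_value = p, model = full, treatments = levs,
       partial = partial, n = nrow(spots))
}

#' Post-hoc pairwise concentration comparisons
#'
#' Given a significant overall ANCOVA, runs the same two-group ANCOVA for
#' each pair (H,M), (H,L), (M,L). A pair is reported significant only when
#' its pairwise p-value clears alpha (optionally Holm-adjusted across the
#' three pairs) AND the higher-concentration HCE exceeds the lower — lower
#' substrate availability should not drive higher isotope incorporation, so
#' a significant reversal is recorded separately (and routes the taxon to
#' OTHER).
#'
#' @param spots one taxon's spots across treatments.
#' @param overall_p the joint ANCOVA p-value; when >= alpha the set is empty
#'   by construction.
#' @param config \code{\link{analysis_config}}.
#' @return list: \code{significant} (character vector among "HM","HL","ML"),
#'   \code{reversed} (significant but direction-violating pairs),
#'   \code{p_values} (named, all three pairs), \code{slopes} (per-treatment
#'   OLS slopes).
#' @export
posthoc_pairs <- function(spots, overall_p, config = analysis_config()) {
  pairs <- list(HM = c("H", "M"), HL = c("H", "L"), ML = c("M", "L"))
  slopes <- vapply(TREATMENTS, function(t) {
    sub <- spots[spots$treatment == t, , drop = FALSE]
    if (nrow(sub) < 2 || length(unique(sub$fluor)) < 2) return(NA_real_)
    unname(coef(lm(delta ~ fluor, data = sub))["fluor"])
  }, numeric(1))
  present <- levels(droplevels(spots)$treatment)
  pvals <- setNames(rep(NA_real_, 3), names(pairs))
  for (nm in names(pairs)) {
    pr <- pairs[[nm]]
    if (!all(pr %in% present)) next
    sub <- droplevels(spots[spots$treatment %in% pr, , drop = FALSE])
    res <- tryCatch(ancova_concentration_effect(sub, config),
                    error = function(e) NULL)
    if (!is.null(res)) pvals[nm] <- res$p_value
  }
  if (!is.finite(overall_p) || overall_p >= config$alpha) {
    return(list(significant = character(0), reversed = character(0),
                p_values = pvals, slopes = slopes))
  }
  adj <- if (config$posthoc_adjust == "holm") {
    p.adjust(pvals, method = "holm")
  } else pvals
  sig <- names(adj)[!is.na(adj) & adj < config$alpha]
  direction_ok <- vapply(sig, function(nm) {
    pr <- pairs[[nm]]
    isTRUE(slopes[pr[1]] > slopes[pr[2]])
  }, logical(1))
  list(significant = sig[direction_ok],
       reversed = sig[!direction_ok],
       p_values = pvals,
       slopes = slopes)
}

#' Map an ANCOVA result to a trophic guild
#'
#' Pure decision table over the overall p-value and the set of significant
#' directed pairs:
#' \itemize{
#'   \item overall p >= alpha: NULL_HML (no concentration effect, H~M~L);
#'   \item (H,M) and (M,L) significant: COPIOTROPH (H>M>L — unsaturated
#'     response throughout);
#'   \item (M,L) or (H,L) significant without (H,M): INTERMEDIATE (H~M>L —
#'     saturated only at the highest concentration);
#'   \item anything else — (H,M) alone (the unobserved H>M~L pattern) or any
#'     significant direction reversal: OTHER.
#' }
#' Every (p, pairs) combination maps to exactly one label.
#'
#' @param overall_p joint ANCOVA p-value.
#' @param posthoc result of \code{\link{posthoc_pairs}} (or a list with
#'   \code{significant} and \code{reversed} character vectors).
#' @param alpha significance level.
#' @return guild label: one of "NULL_HML", "INTERMEDIATE", "COPIOTROPH",
#'   "OTHER".
#' @export
classify_guild <- function(overall_p, posthoc, alpha = 0.05) {
  if (!is.finite(overall_p)) return("OTHER")
  if (overall_p >= alpha) return("NULL_HML")
  sig <- posthoc$significant
  if (length(posthoc$reversed)) return("OTHER")
  if (all(c("HM", "ML") %in% sig)) return("COPIOTROPH")
  if (any(c("ML", "HL") %in% sig) && !("HM" %in% sig)) return("INTERMEDIATE")
  "OTHER"
}

#' Classify every taxon in a probe table
#'
#' Runs the full two-procedure classification: the joint ANCOVA and post-hoc
#' pairwise tests for the trophic guild. Taxa whose ANCOVA cannot be fit
#' (missing levels below the two-level minimum, insufficient spots) are
#' labelled OTHER and flagged.
#'
#' @param spots validated probe table with delta values.
#' @param config \code{\link{analysis_config}}.
#' @return data.frame: taxon, ancova_p, sig_pairs, reversed_pairs, partial,
#'   guild.
#' @export
classify_taxa <- function(spots, config = analysis_config()) {
  taxa <- split(spots, spots$taxon, drop = TRUE)
  rows <- lapply(taxa, function(tx) {
    res <- tryCatch(ancova_concentration_effect(tx, config),
                    error = function(e) NULL)
    if (is.null(res)) {
      return(data.frame(taxon = as.character(tx$taxon[1]),
                        ancova_p = NA_real_, sig_pairs = "",
                        reversed_pairs = "", partial = TRUE,
                        guild = "OTHER", stringsAsFactors = FALSE))
    }
    ph <- posthoc_pairs(tx, res$p_value, config)
    data.frame(
      taxon = as.character(tx$taxon[1]),
      ancova_p = res$p_value,
      sig_pairs = paste(ph$significant, collapse = "+"),
      reversed_pairs = paste(ph$reversed, collapse = "+"),
      partial = res$partial,
      guild = classify_guild(res$p_value, ph, config$alpha),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$taxon), , drop = FALSE]
}

#' Tally guild and activity assignments
#'
#' @param guilds data.frame from \code{\link{classify_taxa}}.
#' @param activity optional \code{classes} data.frame from
#'   \code{\link{rank_activity}}.
#' @return named list of counts (NULL_HML, INTERMEDIATE, COPIOTROPH, OTHER,
#'   HIGH, n_taxa).
#' @export
guild_tally <- function(guilds, activity = NULL) {
  tally <- as.list(table(factor(guilds$guild, levels = names(GUILDS))))
  tally$HIGH <- if (!is.null(activity) && nrow(activity)) {
    sum(activity$class == "HIGH")
  } else NA_integer_
  tally$n_taxa <- nrow(guilds)
  lapply(tally, as.integer)
}
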