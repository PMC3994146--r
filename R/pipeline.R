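#' Run the full Chip-SIP trophic-strategy analysis
#'
#' Executes every stage in order: delta conversion from ion counts (when
#' needed), per-taxon/treatment HCE regressions, enrichment flags, activity
#' classes at the reference concentration, ANCOVA trophic-guild
#' classification, ternary normalization, and — when a tree is supplied —
#' the per-guild phylogenetic-signal permutation tests. Excluded taxa are
#' reported with reasons; without a tree the signal stage is skipped with a
#' warning and everything else still runs.
#'
#' @param spots probe table (data.frame or path to a TSV readable by
#'   \code{\link{read_probe_table}}).
#' @param tree optional \code{ape::phylo} or Newick path.
#' @param config \code{\link{analysis_config}}.
#' @param r_standard standard 15N/14N ratio, required only when rows carry
#'   ion counts without delta values.
#' @param out_dir optional directory; when given, writes results.tsv,
#'   summary.json, ternary plot and per-guild null histograms.
#' @return list of class \code{chipsip_run}: hces, activity (+ cutoff),
#'   guilds, ternary, signal, results (per-taxon table), summary.
#' @export
run_pipeline <- function(spots, tree = NULL, config = analysis_config(),
                         r_standard = NULL, out_dir = NULL) {
  if (is.character(spots)) spots <- read_probe_table(spots)
  spots <- validate_probe_table(spots)
  if (is.character(tree)) tree <- read_taxon_tree(tree)

  needs_delta <- !"delta" %in% names(spots) || anyNA(spots$delta) ||
    any(!is.finite(spots$delta))
  if (needs_delta) {
    if (is.null(r_standard)) {
      stop("rows carry ion counts; supply r_standard to convert to delta",
           call. = FALSE)
    }
    spots <- add_delta(spots, r_standard)
  }

  hces <- fit_all_hce(spots, config)
  ref <- hces[hces$treatment == config$activity_reference, , drop = FALSE]
  activity <- rank_activity(ref, config$activity_cutoff_fraction)
  guilds <- classify_taxa(spots, config)
  ternary <- ternary_coordinates(hces, guilds)

  signal <- NULL
  if (!is.null(tree)) {
    signal <- tryCatch(phylo_signal_all(tree, guilds, config),
                       error = function(e) {
                         warning("phylo-signal stage failed: ",
                                 conditionMessage(e), call. = FALSE)
                         NULL
                       })
  } else {
    warning("no tree supplied; phylogenetic-signal stage skipped",
            call. = FALSE)
  }

  results <- summarize_taxa(hces, activity$classes, guilds, ternary)
  summary <- run_summary(guilds, activity, signal, config)
  run <- structure(list(hces = hces, activity = activity, guilds = guilds,
                        ternary = ternary, signal = signal,
                        results = results, summary = summary),
                   class = "chipsip_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' Per-taxon results table
#'
#' One row per taxon joining the HCE estimates (slope and SE per treatment),
#' enrichment flags, activity class, trophic guild with its ANCOVA p-value,
#' and ternary coordinates.
#'
#' @param hces long HCE table.
#' @param activity activity classes data.frame (or NULL).
#' @param guilds guild assignments (or NULL).
#' @param ternary ternary coordinates (or NULL).
#' @return data.frame, one row per taxon.
#' @export
summarize_taxa <- function(hces, activity = NULL, guilds = NULL,
                           ternary = NULL) {
  out <- hce_wide(hces)
  grab <- function(tbl, col, default = NA) {
    if (is.null(tbl) || !nrow(tbl)) return(rep(default, nrow(out)))
    tbl[[col]][match(out$taxon, tbl$taxon)]
  }
  out$activity <- grab(activity, "class", NA_character_)
  out$guild <- grab(guilds, "guild", NA_character_)
  out$ancova_p <- grab(guilds, "ancova_p", NA_real_)
  out$sig_pairs <- grab(guilds, "sig_pairs", NA_character_)
  out$w_H <- grab(ternary, "w_H", NA_real_)
  out$w_M <- grab(ternary, "w_M", NA_real_)
  out$w_L <- grab(ternary, "w_L", NA_real_)
  out
}

run_summary <- function(guilds, activity, signal, config) {
  tally <- guild_tally(guilds, activity$classes)
  sig <- NULL
  if (!is.null(signal)) {
    sig <- lapply(signal$per_guild, function(s) {
      list(observed_score = s$observed_score, null_mean = s$null_mean,
           null_sd = s$null_sd, p_empirical = s$p_empirical,
           p_ftest = s$p_ftest)
    })
  }
  list(
    counts = tally,
    activity_cutoff = activity$cutoff,
    phylo_signal = sig,
    config = unclass(config),
    package_version = as.character(utils::packageVersion("chipsip")),
    rng_seed = config$rng_seed
  )
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_results(run$results, file.path(out_dir, "results.tsv"))
  jsonlite::write_json(run$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  if (!is.null(run$ternary) && nrow(run$ternary)) {
    render_ternary(run$ternary, file.path(out_dir, "ternary.svg"))
  }
  if (!is.null(run$signal)) {
    for (g in names(run$signal$per_guild)) {
      plot_signal_histogram(run$signal$per_guild[[g]],
                            file.path(out_dir, paste0("null_", g, ".svg")),
                            main = paste("Guild", GUILDS[g]))
    }
  }
  invisible(out_dir)
}

#' @export
print.chipsip_run <- function(x, ...) {
  cat("Chip-SIP trophic-strategy run\n")
  n <- x$summary$counts
  cat(sprintf("  taxa: %d | H~M~L %d, H~M>L %d, H>M>L %d, OTHER %d\n",
              n$n_taxa, n$NULL_HML, n$INTERMEDIATE, n$COPIOTROPH, n$OTHER))
  if (!is.na(n$HIGH)) {
    cat(sprintf("  highly active (>= %.0f%% of max HCE): %d\n",
                100 * x$summary$config$activity_cutoff_fraction, n$HIGH))
  }
  if (!is.null(x$summary$phylo_signal)) {
    for (g in names(x$summary$phylo_signal)) {
      s <- x$summary$phylo_signal[[g]]
      cat(sprintf("  signal %s: score %d vs null %.1f +/- %.1f, p = %.4g\n",
                  GUILDS[g], s$observed_score, s$null_mean, s$null_sd,
                  s$p_empirical))
    }
  }
  invisible(x)
}
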