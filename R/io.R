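#' Default probe-table column mapping
#'
#' Maps the internal field names to the column headers expected in delimited
#' probe tables. Override entries to adapt foreign tables (e.g. converted GEO
#' supplementary matrices) without editing them.
#'
#' @param ... overrides, e.g. \code{taxon = "OTU_ID"}.
#' @return named character vector.
#' @export
probe_columns <- function(...) {
  map <- c(probe = "probe", taxon = "taxon", treatment = "treatment",
           fluor = "fluor", delta = "delta", c14n = "c14n", c15n = "c15n")
  dots <- c(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(map))
    if (length(unknown)) {
      stop("unknown probe-table field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    map[names(dots)] <- dots
  }
  map
}

#' Read a probe-spot table
#'
#' One row per array spot: probe id, taxon id, treatment (H/M/L),
#' fluorescence, and either a delta-permil value or raw 12C14N-/12C15N- ion
#' counts (converted downstream with \code{\link{add_delta}}). The reader is
#' total: any malformed row fails validation with its row number; no partial
#' table is ever returned silently.
#'
#' @param path delimited text file.
#' @param sep field separator; default tab, use "," for CSV.
#' @param columns column mapping from \code{\link{probe_columns}}.
#' @return validated \code{data.frame} with columns probe, taxon, treatment
#'   (factor H/M/L), fluor, and delta and/or c14n + c15n.
#' @export
read_probe_table <- function(path, sep = "\t", columns = probe_columns()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
  required <- columns[c("probe", "taxon", "treatment", "fluor")]
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("probe table ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    probe = as.character(raw[[columns["probe"]]]),
    taxon = as.character(raw[[columns["taxon"]]]),
    treatment = as.character(raw[[columns["treatment"]]]),
    fluor = as.numeric(raw[[columns["fluor"]]]),
    stringsAsFactors = FALSE
  )
  for (f in c("delta", "c14n", "c15n")) {
    if (columns[f] %in% names(raw)) out[[f]] <- as.numeric(raw[[columns[f]]])
  }
  validate_probe_table(out, context = path)
}

#' Validate a probe-spot table
#'
#' Enforces the table invariants: treatments in {H,M,L}; nonnegative
#' fluorescence; every row carries either a delta value or both ion counts;
#' counts nonnegative integers; probe ids unique within (taxon, treatment).
#' Violations are reported with 1-based row numbers.
#'
#' @param spots data.frame as returned by \code{\link{read_probe_table}}.
#' @param context label used in error messages.
#' @return the table, with \code{treatment} as an H/M/L factor.
#' @export
validate_probe_table <- function(spots, context = "probe table") {
  stopifnot(is.data.frame(spots))
  need <- c("probe", "taxon", "treatment", "fluor")
  missing <- setdiff(need, names(spots))
  if (length(missing)) {
    stop(context, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  problems <- character(0)
  flag <- function(bad, what) {
    if (any(bad)) {
      rows <- which(bad)
      shown <- paste(head(rows, 10), collapse = ", ")
      if (length(rows) > 10) shown <- paste0(shown, ", ...")
      problems <<- c(problems, sprintf("%s (row %s)", what, shown))
    }
  }
  flag(is.na(spots$treatment) | !(spots$treatment %in% TREATMENTS),
       "treatment not one of H/M/L")
  flag(!is.finite(spots$fluor) | spots$fluor < 0,
       "fluorescence missing or negative")
  has_delta <- if ("delta" %in% names(spots)) is.finite(spots$delta)
               else rep(FALSE, nrow(spots))
  has_counts <- if (all(c("c14n", "c15n") %in% names(spots))) {
    is.finite(spots$c14n) & is.finite(spots$c15n)
  } else rep(FALSE, nrow(spots))
  flag(!has_delta & !has_counts,
       "neither delta nor both ion counts present")
  if (all(c("c14n", "c15n") %in% names(spots))) {
    ok <- !has_counts |
      (spots$c14n >= 0 & spots$c15n >= 0 &
         spots$c14n == round(spots$c14n) & spots$c15n == round(spots$c15n))
    flag(!ok, "ion counts must be nonnegative integers")
  }
  key <- paste(spots$taxon, spots$treatment, spots$probe, sep = "\r")
  flag(duplicated(key), "duplicate probe id within (taxon, treatment)")
  if (length(problems)) {
    stop("invalid ", context, ":\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  spots$treatment <- treatment_factor(spots$treatment)
  spots
}

#' Write a probe-spot table as TSV
#'
#' @param spots probe table.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_probe_table <- function(spots, path) {
  write.table(spots, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a taxon tree from a Newick file
#'
#' Thin wrapper over \code{ape::read.tree} adding the validation the
#' downstream parsimony machinery relies on: unique leaf labels. Branch
#' lengths are accepted but ignored by parsimony; the tree is treated as
#' unrooted.
#'
#' @param path Newick file.
#' @return an \code{ape::phylo}.
#' @export
read_taxon_tree <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse error in ", path,
                                            ": ", conditionMessage(e),
                                            call. = FALSE))
  if (is.null(tree)) stop("Newick parse error in ", path, call. = FALSE)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    stop("duplicate leaf label(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  tree
}

#' Write the per-taxon results table
#'
#' One row per taxon: the three HCE estimates with standard errors,
#' enrichment flags, activity class, trophic guild, ANCOVA p-value and the
#' normalized ternary coordinates — the tabular mirror of the study's
#' per-OTU strategy summary.
#'
#' @param results per-taxon results data.frame from
#'   \code{\link{summarize_taxa}}.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_results <- function(results, path) {
  num <- vapply(results, is.numeric, logical(1))
  out <- results
  out[num] <- lapply(out[num], function(x) signif(x, 10))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read back a results table written by \code{\link{write_results}}
#' @param path TSV path.
#' @return data.frame.
#' @export
read_results <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
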