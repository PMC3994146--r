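#' Normalize a three-treatment HCE profile to barycentric coordinates
#'
#' Each enriched taxon's (HCE_H, HCE_M, HCE_L) triplet is normalized to its
#' sum so the three weights lie on the 2-simplex. Negative HCEs — possible
#' from regression noise — are floored to zero first, since barycentric
#' coordinates require nonnegative components. Taxa with no positive
#' component cannot be placed and are excluded with a warning.
#'
#' @param hce_h,hce_m,hce_l HCE values (vectorized).
#' @return data.frame w_H, w_M, w_L with rows summing to 1, or NA for
#'   excluded triplets.
#' @export
normalize_hce <- function(hce_h, hce_m, hce_l) {
  m <- cbind(w_H = pmax(hce_h, 0), w_M = pmax(hce_m, 0),
             w_L = pmax(hce_l, 0))
  tot <- rowSums(m)
  bad <- !is.finite(tot) | tot <= 0
  if (any(bad)) {
    warning(sum(bad), " triplet(s) with no positive HCE component excluded ",
            "from ternary normalization", call. = FALSE)
    m[bad, ] <- NA_real_
    tot[bad] <- 1
  }
  as.data.frame(m / tot)
}

#' Ternary coordinates for all enriched taxa
#'
#' @param hces HCE table from \code{\link{fit_all_hce}}.
#' @param guilds optional guild assignments from \code{\link{classify_taxa}}
#'   carried through for plotting.
#' @return data.frame: taxon, w_H, w_M, w_L, guild; taxa not enriched in any
#'   treatment are dropped (they were not plotted in the original analysis).
#' @export
ternary_coordinates <- function(hces, guilds = NULL) {
  wide <- hce_wide(hces)
  keep <- wide$enriched_H | wide$enriched_M | wide$enriched_L
  wide <- wide[keep, , drop = FALSE]
  coords <- normalize_hce(wide$hce_H, wide$hce_M, wide$hce_L)
  out <- cbind(data.frame(taxon = wide$taxon, stringsAsFactors = FALSE),
               coords)
  out$guild <- if (!is.null(guilds)) {
    guilds$guild[match(out$taxon, guilds$taxon)]
  } else NA_character_
  ok <- is.finite(out$w_H)
  out[ok, , drop = FALSE]
}

#' Reshape an HCE table to one row per taxon
#'
#' @param hces long HCE table.
#' @return data.frame with hce_/se_/enriched_ columns per treatment; missing
#'   cells are NA (enriched_ FALSE).
#' @export
hce_wide <- function(hces) {
  taxa <- sort(unique(hces$taxon))
  out <- data.frame(taxon = taxa, stringsAsFactors = FALSE)
  for (t in TREATMENTS) {
    sub <- hces[hces$treatment == t, , drop = FALSE]
    i <- match(taxa, sub$taxon)
    out[[paste0("hce_", t)]] <- sub$slope[i]
    out[[paste0("se_", t)]] <- sub$slope_se[i]
    out[[paste0("enriched_", t)]] <- !is.na(i) & sub$enriched[i]
  }
  out
}

#' Barycentric-to-Cartesian transform
#'
#' Vertex convention: H at the apex, M bottom-left, L bottom-right, on an
#' equilateral triangle with unit side: x = w_L + w_H/2, y = (sqrt(3)/2) w_H.
#' The orientation is arbitrary in principle and fixed here so plots and
#' tests are deterministic.
#'
#' @param w_H,w_M,w_L barycentric weights summing to 1.
#' @return data.frame x, y.
#' @export
ternary_xy <- function(w_H, w_M, w_L) {
  data.frame(x = w_L + w_H / 2, y = sqrt(3) / 2 * w_H)
}

#' Render the ternary diagram of normalized HCE profiles
#'
#' Equilateral triangle with corners labelled H (top), M (bottom-left) and
#' L (bottom-right); one marker per enriched taxon, colored by trophic guild.
#' Copiotroph-like taxa (H>M>L) pull toward the H corner; concentration-
#' saturated taxa (H~M~L) sit near the centroid.
#'
#' @param points data.frame from \code{\link{ternary_coordinates}}.
#' @param path output file; ".svg" or ".pdf" decide the device.
#' @param main plot title.
#' @return the path invisibly, or NULL (with a warning) for empty input.
#' @export
render_ternary <- function(points, path, main = "Normalized HCE profile") {
  if (is.null(points) || nrow(points) == 0) {
    warning("no ternary points to plot", call. = FALSE)
    return(invisible(NULL))
  }
  open_device(path, width = 6, height = 5.5)
  op <- graphics::par(mar = c(1, 1, 2, 1))
  # restore par while the device is still open, then close it
  on.exit({ graphics::par(op); grDevices::dev.off() })
  corners <- ternary_xy(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  graphics::plot(NA, xlim = c(-0.08, 1.08), ylim = c(-0.08, 0.95),
                 asp = 1, axes = FALSE, xlab = "", ylab = "", main = main)
  graphics::polygon(corners$x, corners$y, border = "grey30")
  graphics::text(corners$x, corners$y, labels = c("H", "M", "L"),
                 pos = c(3, 2, 4), font = 2)
  guild <- ifelse(is.na(points$guild), "OTHER", points$guild)
  cols <- c(NULL_HML = "#1b9e77", INTERMEDIATE = "#7570b3",
            COPIOTROPH = "#d95f02", OTHER = "grey50")
  xy <- ternary_xy(points$w_H, points$w_M, points$w_L)
  graphics::points(xy$x, xy$y, pch = 21, bg = cols[guild], col = "black",
                   cex = 1.1)
  present <- intersect(names(cols), unique(guild))
  graphics::legend("topright", legend = GUILDS[present], pt.bg = cols[present],
                   pch = 21, bty = "n", cex = 0.8)
  invisible(path)
}

open_device <- function(path, width, height) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (grepl("\\.svg$", path)) {
    ok <- tryCatch({ grDevices::svg(path, width = width, height = height)
                     TRUE }, error = function(e) FALSE)
    if (ok) return(invisible(path))
    path <- sub("\\.svg$", ".pdf", path)
  }
  grDevices::pdf(path, width = width, height = height)
  invisible(path)
}
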