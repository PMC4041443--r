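# Survey statistics: contact totals, per-structure distributions, frequency
# tables by residue/category/edge class, and tilt/distance histograms.

#' Half-open histogram
#'
#' Bins `[lo, lo + w)` covering the domain; the last bin is closed so the
#' domain maximum is counted.
#'
#' @param values numeric vector.
#' @param bin_width positive bin width.
#' @param domain length-2 numeric; values outside raise an error listing the
#'   offenders.
#' @return data.frame `lower`, `upper`, `count`.
#' @export
survey_histogram <- function(values, bin_width, domain) {
  stopifnot(bin_width > 0, length(domain) == 2L, domain[1L] < domain[2L])
  bad <- values[values < domain[1L] | values > domain[2L]]
  if (length(bad))
    stop("values outside domain [", domain[1L], ", ", domain[2L], "]: ",
         paste(signif(bad, 6), collapse = ", "))
  n_bins <- max(1L, ceiling((domain[2L] - domain[1L]) / bin_width - 1e-9))
  lower <- domain[1L] + bin_width * (seq_len(n_bins) - 1L)
  upper <- lower + bin_width
  idx <- pmin(findInterval(values, lower), length(lower))
  count <- tabulate(idx, nbins = length(lower))
  data.frame(lower = lower, upper = upper, count = count)
}

freq_table <- function(x, levels = NULL) {
  tab <- if (is.null(levels)) table(x) else table(factor(x, levels = levels))
  n <- sum(tab)
  data.frame(key = names(tab), count = as.integer(tab),
             pct = if (n > 0) round(100 * as.integer(tab) / n, 4) else
             rep(0, length(tab)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Aggregate contact tables into a survey report
#'
#' Computes the survey statistics from the scanned contact tables: how many
#' structures carry each contact family, contact totals, per-structure
#' count distributions, frequency tables by base / amino acid / category /
#' edge role / sugar edge class and atom labels, a 5-degree tilt histogram
#' and a 0.1 Angstrom closest-distance histogram. Only validated contacts
#' are counted. An optional manifest with a `protein_class` column adds a
#' protein-class breakdown.
#'
#' @param scan result of [scan_structures()] (or a list with `pi_pi`,
#'   `sugar_pi`, `n_structures`).
#' @param manifest optional data.frame with `entry_id` and `protein_class`.
#' @return object of class `survey_report`.
#' @export
aggregate_contacts <- function(scan, manifest = NULL) {
  pp <- scan$pi_pi[scan$pi_pi$valid, , drop = FALSE]
  sp <- scan$sugar_pi[scan$sugar_pi$valid, , drop = FALSE]
  n_struct <- if (!is.null(scan$n_structures)) scan$n_structures else
    length(unique(c(scan$pi_pi$entry_id, scan$sugar_pi$entry_id)))
  ids_pp <- unique(pp$entry_id); ids_sp <- unique(sp$entry_id)
  per_structure <- function(df, all_ids)
    as.data.frame(table(entry_id = df$entry_id), stringsAsFactors = FALSE)
  rep_ <- list(
    n_structures_searched = n_struct,
    n_with_pi_pi = length(ids_pp),
    n_with_sugar_pi = length(ids_sp),
    n_with_none = n_struct - length(union(ids_pp, ids_sp)),
    total_pi_pi = nrow(pp),
    total_sugar_pi = nrow(sp),
    per_structure_pi_pi = per_structure(pp),
    per_structure_sugar_pi = per_structure(sp),
    by_base = freq_table(pp$base, NUCLEOTIDES),
    by_aa = freq_table(pp$aa, AROMATIC_AA),
    by_base_aa = freq_table(paste(pp$base, pp$aa, sep = ":")),
    by_category = freq_table(pp$category,
                             c("stacked", "inclined", "t_shaped")),
    by_edge_role = freq_table(pp$edge_role,
                              c("face_face", "nucleobase_edge",
                                "amino_acid_edge")),
    sugar_by_aa = freq_table(sp$aa, AROMATIC_AA),
    sugar_by_class = freq_table(sp$edge_class, SUGAR_CLASSES),
    sugar_by_labels = freq_table(sp$atom_labels),
    tilt_histogram = survey_histogram(pp$omega_deg, 5, c(0, 90)),
    distance_histogram = survey_histogram(
      c(pp$d_min_angstrom, sp$d_min_angstrom), 0.1, c(0, 8)))
  if (!is.null(manifest) && "protein_class" %in% names(manifest)) {
    cls <- manifest$protein_class[match(c(pp$entry_id, sp$entry_id),
                                        manifest$entry_id)]
    rep_$by_protein_class <- freq_table(cls[!is.na(cls)])
  }
  structure(rep_, class = "survey_report")
}

#' @export
print.survey_report <- function(x, ...) {
  cat("DNA-protein pi-interaction survey report\n")
  cat(sprintf("  structures searched: %d\n", x$n_structures_searched))
  cat(sprintf("  with pi-pi contacts: %d (%.0f%%); total pi-pi: %d\n",
              x$n_with_pi_pi,
              100 * x$n_with_pi_pi / max(1, x$n_structures_searched),
              x$total_pi_pi))
  cat(sprintf("  with sugar-pi contacts: %d (%.0f%%); total sugar-pi: %d\n",
              x$n_with_sugar_pi,
              100 * x$n_with_sugar_pi / max(1, x$n_structures_searched),
              x$total_sugar_pi))
  cat(sprintf("  without any contact: %d\n", x$n_with_none))
  show_tab <- function(tt, title) {
    keep <- tt$count > 0
    if (!any(keep)) return(invisible())
    cat(" ", title, ": ",
        paste(sprintf("%s %d (%.1f%%)", tt$key[keep], tt$count[keep],
                      tt$pct[keep]), collapse = ", "), "\n", sep = "")
  }
  show_tab(x$by_category, "pi-pi tilt categories")
  show_tab(x$by_edge_role, "edge roles")
  show_tab(x$sugar_by_class, "sugar edges")
  invisible(x)
}

#' Plot survey histograms
#'
#' Barplots of the tilt-angle and closest-distance distributions.
#'
#' @param x a `survey_report`.
#' @param which `"tilt"` or `"distance"`.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the bin counts plotted.
#' @export
plot.survey_report <- function(x, which = c("tilt", "distance"), ...) {
  which <- match.arg(which)
  h <- if (which == "tilt") x$tilt_histogram else x$distance_histogram
  lab <- if (which == "tilt") "tilt (degrees)" else "closest distance (A)"
  graphics::barplot(h$count, names.arg = sprintf("%g", h$lower),
                    xlab = lab, ylab = "contacts", ...)
  invisible(h$count)
}

#' Write a survey report to disk
#'
#' Emits `report.json` (the full report) and per-table CSV files.
#'
#' @param report a `survey_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  for (nm in names(report)) {
    if (is.data.frame(report[[nm]]))
      utils::write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  invisible(dir)
}
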