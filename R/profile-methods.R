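#' @export
print.rop_profile <- function(x, ...) {
  cat("<rop_profile>", x$sample_id, "-", x$total_reads, "reads\n")
  nz <- x$categories[x$categories$count > 0, ]
  for (i in seq_len(nrow(nz))) {
    cat(sprintf("  %-20s %8d  %6.2f%%\n", nz$category[i], nz$count[i],
                nz$percentage[i]))
  }
  invisible(x)
}

#' @export
print.rop_result <- function(x, ...) {
  cat("<rop_result>\n")
  print(x$profile)
  invisible(x)
}

#' Tidy a protocol profile into a category table
#'
#' @param x An `rop_profile`.
#' @param ... Unused.
#' @return Tibble with `sample_id`, `category`, `count`, `percentage`.
#' @method tidy rop_profile
#' @export
tidy.rop_profile <- function(x, ...) {
  dplyr::mutate(x$categories, sample_id = x$sample_id, .before = 1)
}

#' Tidy a protocol run into the per-read assignment table
#'
#' @param x An `rop_result`.
#' @param ... Unused.
#' @return The assignment tibble (one row per input read).
#' @method tidy rop_result
#' @export
tidy.rop_result <- function(x, ...) {
  x$assignments
}

#' One-row summary of a protocol run
#'
#' @param x An `rop_result`.
#' @param ... Unused.
#' @return Tibble with totals, mapped/unmapped splits and the unaccounted
#'   percentage.
#' @method glance rop_result
#' @export
glance.rop_result <- function(x, ...) {
  cts <- stats::setNames(x$profile$categories$count,
                         x$profile$categories$category)
  mapped <- sum(cts[c("mapped_genomic", "mapped_repeat",
                      "mapped_immune_locus")])
  tibble::tibble(
    sample_id = x$profile$sample_id,
    total_reads = x$profile$total_reads,
    mapped = mapped,
    pct_mapped = if (x$profile$total_reads > 0)
      100 * mapped / x$profile$total_reads else 0,
    unaccounted = unname(cts["unaccounted"]),
    pct_unaccounted = if (x$profile$total_reads > 0)
      100 * cts[["unaccounted"]] / x$profile$total_reads else 0,
    n_ncl_events = nrow(x$ncl_events),
    n_vj_events = if (is.null(x$vj_events)) 0L else nrow(x$vj_events),
    microbial_load = unname(cts["microbial"])
  )
}

#' Bar plot of the category accounting
#'
#' @param object An `rop_profile` (or `rop_result`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rop_profile
#' @export
autoplot.rop_profile <- function(object, ...) {
  d <- object$categories
  d$category <- factor(d$category, levels = rev(ROP_CATEGORIES))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$percentage,
                                  y = .data$category)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "% of total reads", y = NULL,
                  title = paste("Read origin profile -", object$sample_id)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.rop_profile
#' @method autoplot rop_result
#' @export
autoplot.rop_result <- function(object, ...) {
  autoplot(object$profile, ...)
}

#' Write the machine- and human-readable report
#'
#' Emits `profile.tsv` (one row per category with count and percentage),
#' `profile.json` (the full profile with subcategory tables, VJ matrix and
#' taxon profile), `ncl_events.tsv` and `vj_events.tsv`.  Output is
#' byte-deterministic for identical runs.
#'
#' @param result An `rop_result`.
#' @param dir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
rop_report <- function(result, dir) {
  stopifnot(inherits(result, "rop_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- result$profile
  paths <- character()
  tsv <- file.path(dir, "profile.tsv")
  cat_tbl <- p$categories
  cat_tbl$percentage <- sprintf("%.4f", cat_tbl$percentage)
  utils::write.table(cat_tbl, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, tsv)
  js <- file.path(dir, "profile.json")
  payload <- list(
    sample_id = p$sample_id,
    total_reads = p$total_reads,
    categories = p$categories,
    genomic_subcategories = p$genomic_subcategories,
    repeat_counts = p$repeat_counts,
    immune_locus_counts = p$immune_locus_counts,
    ncl_subtype_counts = p$ncl_subtype_counts,
    vj_counts = p$vj_matrix$counts,
    taxon_profile = p$taxon_profile
  )
  writeLines(jsonlite::toJSON(payload, digits = 8, auto_unbox = TRUE,
                              na = "null"), js)
  paths <- c(paths, js)
  ncl <- file.path(dir, "ncl_events.tsv")
  utils::write.table(result$ncl_events, ncl, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, ncl)
  vj <- file.path(dir, "vj_events.tsv")
  ev <- result$vj_events
  if (is.null(ev)) {
    ev <- tibble::tibble(read_id = character(), locus = character(),
                         v_gene = character(), j_gene = character())
  }
  utils::write.table(ev, vj, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, vj)
  invisible(paths)
}

#' Round-trip a profile through its JSON report
#'
#' @param path Path to a `profile.json` written by [rop_report()].
#' @return The parsed profile payload (tibbles for the tables).
#' @export
read_profile_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  for (nm in names(x)) {
    if (is.data.frame(x[[nm]])) x[[nm]] <- tibble::as_tibble(x[[nm]])
  }
  x
}
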