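TABLE1_MD5 <- "d3916c1dec502a492d51ffd2bfd63330"

#' Load the packaged published reference-correlation table
#'
#' The package ships, as a plain-text fixture, the published table of
#' per-reference correlation summaries: for each of 120 candidate reference
#' regions (116 AAL regions plus midbrain, pons, medulla and whole grey
#' matter) the strongest (most negative) and the median Pearson correlation
#' with age over the 120 target regions, for a conventional and a digital
#' PET system, at full printed precision.
#'
#' @return A data.frame of class `table1_fixture` with columns `region`,
#'   `strongest_conv`, `median_conv`, `strongest_dig`, `median_dig`
#'   (120 rows).
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_reference_correlations.tsv",
                      package = "petref", mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, TABLE1_MD5)) {
    stop_("packaged fixture checksum mismatch: %s", md5)
  }
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
  stopifnot(nrow(tab) == 120L,
            identical(names(tab), c("region", "strongest_conv", "median_conv",
                                    "strongest_dig", "median_dig")))
  class(tab) <- c("table1_fixture", "data.frame")
  tab
}

#' Per-system summary view of the packaged fixture
#'
#' Reshapes the fixture into the `normalization_summary` layout that
#' [select_references()] and [rank_references()] consume.
#'
#' @param fixture A [load_table1_fixture()] result.
#' @param system `"conventional"` or `"digital"`.
#' @return A `normalization_summary` data.frame (`region`, `strongest_r`,
#'   `median_r`).
#' @export
fixture_summary <- function(fixture, system = c("conventional", "digital")) {
  system <- match.arg(system)
  cols <- if (system == "conventional") {
    c("strongest_conv", "median_conv")
  } else {
    c("strongest_dig", "median_dig")
  }
  out <- data.frame(region = fixture$region,
                    strongest_r = fixture[[cols[1L]]],
                    median_r = fixture[[cols[2L]]])
  attr(out, "system_label") <- system
  class(out) <- c("normalization_summary", "data.frame")
  out
}

#' Select candidate reference regions by the median criterion
#'
#' A region qualifies as a candidate reference when the median of its
#' correlation grid row is strictly below the threshold (default -0.5): a
#' reference that makes most target regions appear to decline with age is
#' itself metabolically stable. Selected regions are also grouped into
#' anatomical structures via [map_to_structure()].
#'
#' @param summary A `normalization_summary` (from [summarize_reference()] or
#'   [fixture_summary()]).
#' @param threshold Selection threshold on the median correlation (strict
#'   `<`; a median exactly at the threshold is not selected).
#' @param atlas Optional [parcellation_atlas()] supplying the grouping map;
#'   defaults to the name-based [map_to_structure()] rule.
#' @return An object of class `selection_result`: list with `threshold`,
#'   `selected_regions`, `selected_structures` (deduplicated, in ranking
#'   order) and `ranking` (all references by ascending `median_r`,
#'   lexicographic tie-break).
#' @export
select_references <- function(summary, threshold = -0.5, atlas = NULL) {
  stopifnot(nrow(summary) >= 1L)
  ranking <- rank_references(summary)
  sel <- ranking$region[ranking$median_r < threshold]
  structures <- unique(vapply(sel, map_to_structure, character(1L),
                              atlas = atlas))
  structure(list(threshold = threshold,
                 selected_regions = sel,
                 selected_structures = structures,
                 ranking = ranking),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: %d region(s) with median r < %s\n",
              length(x$selected_regions), format(x$threshold)))
  if (length(x$selected_regions)) {
    cat("  regions:   ", paste(x$selected_regions, collapse = ", "), "\n")
    cat("  structures:", paste(x$selected_structures, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Group a selection into deduplicated structure names
#'
#' @param selection A [select_references()] result.
#' @param atlas Optional [parcellation_atlas()] for the grouping map.
#' @return Character vector of structure names, deduplicated in
#'   first-appearance order of the ranking.
#' @export
group_selected_structures <- function(selection, atlas = NULL) {
  stopifnot(inherits(selection, "selection_result"))
  if (!length(selection$selected_regions)) return(character(0))
  unique(vapply(selection$selected_regions, map_to_structure, character(1L),
                atlas = atlas))
}

#' Rank candidate references by ascending median correlation
#'
#' The best candidate reference has the most negative median correlation
#' with age. Equal medians are ordered lexicographically by region name.
#'
#' @param summary A `normalization_summary`.
#' @return The summary rows reordered (ascending `median_r`).
#' @export
rank_references <- function(summary) {
  stopifnot(nrow(summary) >= 1L)
  df <- as.data.frame(summary)
  df <- df[order(df$median_r, df$region, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}
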