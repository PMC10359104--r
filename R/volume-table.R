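#' Construct a volume table
#'
#' A volume table holds one row per animal: `animal_id`, `group` (age-group
#' factor), `tbv` (total brain volume, mm^3) and one numeric column per
#' brain region (mm^3). It is the common input of the volumetric and
#' network stages.
#'
#' @param data data.frame with columns `animal_id`, `group`, `tbv` and one
#'   column per region.
#' @param regions character vector of region column names; default every
#'   column other than `animal_id`, `group`, `tbv`.
#' @param groups ordered character vector of allowed group labels; default
#'   the order of first appearance in `data$group`.
#' @return `data` with class `volume_table`, a `regions` attribute and
#'   `group` coerced to a factor with the given level order.
#' @export
volume_table <- function(data, regions = NULL, groups = NULL) {
  stopifnot(is.data.frame(data))
  needed <- c("animal_id", "group", "tbv")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0L) {
    stop("volume table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(regions)) {
    regions <- setdiff(names(data), needed)
  }
  unknown <- setdiff(regions, names(data))
  if (length(unknown) > 0L) {
    stop("region column(s) not present: ", paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(data$animal_id)) {
    stop("duplicated animal_id values")
  }
  vol <- as.matrix(data[regions])
  if (anyNA(vol) || anyNA(data$tbv)) stop("missing cells are not allowed")
  if (any(vol <= 0)) stop("all region volumes must be positive")
  if (any(data$tbv < apply(vol, 1L, max))) {
    stop("tbv must be >= every single-region volume")
  }
  if (is.null(groups)) groups <- unique(as.character(data$group))
  bad <- setdiff(unique(as.character(data$group)), groups)
  if (length(bad) > 0L) {
    stop("group label(s) outside the configured set: ",
         paste(bad, collapse = ", "))
  }
  data$group <- factor(as.character(data$group), levels = groups)
  structure(data, regions = regions, class = c("volume_table", "data.frame"))
}

#' Region columns of a volume table
#' @param table a `volume_table`.
#' @return character vector of region names.
#' @export
regions <- function(table) {
  attr(table, "regions", exact = TRUE)
}

#' @export
print.volume_table <- function(x, ...) {
  cat(sprintf("volume_table: %d animals, %d regions, groups: %s\n",
              nrow(x), length(regions(x)),
              paste(levels(x$group), collapse = " < ")))
  print.data.frame(head(as.data.frame(x)[, seq_len(min(6L, ncol(x)))]), ...)
  invisible(x)
}

# keep attributes through row subsetting
#' @export
`[.volume_table` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("animal_id", "group", "tbv") %in% names(out))) {
    attr(out, "regions") <- intersect(regions(x), names(out))
    class(out) <- c("volume_table", "data.frame")
  }
  out
}

#' Default 32-ROI hierarchy table
#'
#' The reduced parcellation used throughout: 5 brainstem areas, 2
#' cerebellar divisions, 2 cerebral nuclei, 18 cerebral cortical areas
#' (15 isocortical plus cortical subplate, hippocampal formation and
#' olfactory areas) and 5 white matter tracts. Shipped as an identity
#' mapping (each ROI standing for itself) with a class label per ROI;
#' supply your own fine-region-to-ROI table to reduce a finer
#' parcellation.
#'
#' @return data.frame with columns `fine_region`, `roi`, `roi_class`.
#' @export
default_roi_hierarchy <- function() {
  path <- system.file("extdata", "roi_hierarchy_32.csv", package = "scnaging",
                      mustWork = TRUE)
  read_roi_hierarchy(path)
}

#' Read a region hierarchy file
#'
#' @param path delimited text with columns `fine_region`, `roi` and
#'   optionally `roi_class`.
#' @return data.frame with class `roi_hierarchy`.
#' @export
read_roi_hierarchy <- function(path) {
  h <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("fine_region", "roi") %in% names(h))) {
    stop("hierarchy file needs columns fine_region, roi: ", path)
  }
  if (anyDuplicated(h$fine_region)) {
    stop("hierarchy maps a fine region more than once")
  }
  class(h) <- c("roi_hierarchy", "data.frame")
  h
}

#' The 32 default region-of-interest names
#' @return character vector, length 32.
#' @export
default_rois <- function() {
  default_roi_hierarchy()$roi
}

#' A-priori age-sensitive regions of interest
#'
#' The three regions singled out for focused analysis on grounds of known
#' age-sensitivity and relevance to working memory: the anterior cingulate
#' area, hippocampal formation and orbital area.
#' @return character vector, length 3.
#' @export
apriori_rois <- function() {
  c("anterior cingulate area", "hippocampal formation", "orbital area")
}
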