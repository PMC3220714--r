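#' Patch density records
#'
#' A density record gives, for one surveyed patch, its landscape class
#' (percent forest cover), its area in hectares, and the number of distinct
#' individuals captured under the standardized line protocol — used as an
#' index of population density.
#'
#' @param patch_id Character vector of unique patch ids.
#' @param landscape Landscape class per patch (e.g. 50, 30, 10).
#' @param area_ha Patch area in hectares, strictly positive.
#' @param count Non-negative integer count of distinct individuals.
#' @return A data frame of class `density_records`.
#' @export
density_records <- function(patch_id, landscape, area_ha, count) {
  patch_id <- as.character(patch_id)
  if (anyDuplicated(patch_id)) stop("patch ids must be unique")
  if (any(area_ha <= 0)) stop("areas must be positive")
  if (any(count < 0) || any(count != round(count)))
    stop("counts must be non-negative integers")
  out <- data.frame(patch_id = patch_id, landscape = landscape,
                    area_ha = as.numeric(area_ha), count = as.integer(count),
                    stringsAsFactors = FALSE)
  class(out) <- c("density_records", "data.frame")
  out
}

#' Read / write density records as CSV
#'
#' Columns: patch_id, landscape, area_ha, count.
#'
#' @param x A `density_records` data frame.
#' @param path File path.
#' @return `write_density_csv` returns `path` invisibly; `read_density_csv`
#'   a `density_records` data frame.
#' @export
write_density_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_density_csv
#' @export
read_density_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  density_records(d$patch_id, d$landscape, d$area_ha, d$count)
}
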