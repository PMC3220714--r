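#' Robust-design study layout
#'
#' Describes the sampling frame of a robust-design capture-recapture study:
#' `n_primary` primary trapping sessions, each made of `n_secondary`
#' consecutive secondary occasions (trap nights), over a set of habitat
#' patches each belonging to a landscape class (percent forest cover).
#'
#' @param n_primary Number of primary sessions (T), at least 2.
#' @param n_secondary Number of secondary occasions per primary session
#'   (K), at least 2 so that within-session recaptures are possible.
#' @param patches Data frame with columns `patch_id` (unique) and
#'   `landscape` (percent forest cover class, e.g. 50, 30, 10).
#' @param interval_days Days between consecutive primary sessions
#'   (metadata only).
#' @param trap_stations Optional list with per-grid trap counts,
#'   e.g. `list(sherman = 121, pitfall = 55)`; used by [trap_nights()].
#'
#' @return An object of class `rd_design`.
#' @seealso [default_design()], [trap_nights()]
#' @export
rd_design <- function(n_primary, n_secondary, patches, interval_days = 20,
                      trap_stations = NULL) {
  stopifnot(is.numeric(n_primary), length(n_primary) == 1L, n_primary >= 2,
            is.numeric(n_secondary), length(n_secondary) == 1L, n_secondary >= 2)
  patches <- as.data.frame(patches)
  if (!all(c("patch_id", "landscape") %in% names(patches)))
    stop("`patches` must have columns `patch_id` and `landscape`")
  patches$patch_id <- as.character(patches$patch_id)
  if (anyDuplicated(patches$patch_id))
    stop("patch ids must be unique")
  structure(
    list(n_primary = as.integer(n_primary),
         n_secondary = as.integer(n_secondary),
         patches = patches[c("patch_id", "landscape")],
         interval_days = interval_days,
         trap_stations = trap_stations),
    class = "rd_design")
}

#' @export
print.rd_design <- function(x, ...) {
  cat("Robust design:", x$n_primary, "primary sessions x",
      x$n_secondary, "secondary occasions;",
      nrow(x$patches), "patches in",
      length(unique(x$patches$landscape)), "landscape(s)\n")
  invisible(x)
}

#' Default six-patch study layout
#'
#' The layout used throughout the examples and the synthetic-data module:
#' three small patches in a 50% forest-cover landscape and three in a 30%
#' landscape, five 5-day primary sessions separated by 20-day intervals,
#' each 2-ha grid carrying 121 Sherman traps and 55 pitfall traps.
#'
#' @return An `rd_design`.
#' @export
default_design <- function() {
  rd_design(
    n_primary = 5L, n_secondary = 5L,
    patches = data.frame(patch_id = paste0("P", 1:6),
                         landscape = c(50, 50, 50, 30, 30, 30)),
    interval_days = 20,
    trap_stations = list(sherman = 121L, pitfall = 55L))
}

#' Total trap nights implied by a design
#'
#' One trap night is one trap set for one secondary occasion. The total is
#' patches x (traps per grid) x primary sessions x secondary occasions.
#'
#' @param design An [rd_design()] with `trap_stations` metadata.
#' @return Integer total number of trap nights.
#' @export
trap_nights <- function(design) {
  stopifnot(inherits(design, "rd_design"))
  if (is.null(design$trap_stations))
    stop("design carries no `trap_stations` metadata")
  traps <- sum(unlist(design$trap_stations))
  as.integer(nrow(design$patches) * traps * design$n_primary * design$n_secondary)
}

landscapes_of <- function(design) sort(unique(design$patches$landscape),
                                       decreasing = TRUE)

patch_landscape_index <- function(design) {
  ls <- landscapes_of(design)
  match(design$patches$landscape, ls)
}
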