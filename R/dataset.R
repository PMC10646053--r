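#' Construct a growth-curve dataset
#'
#' Container for a two-group repeated-measures tumor-volume experiment:
#' one row per animal, one column per measurement time. All downstream
#' analyses (the lag-conditioned homologous test, the cross-sectional
#' t test, the per-time-point report) consume this object.
#'
#' Missing values are rejected outright: the conditional-regression
#' bookkeeping (degrees of freedom n - 4 in the combined model) assumes
#' complete pairs at every adjacent-time-point comparison, and pairwise
#' deletion would make those counts ambiguous.
#'
#' @param volumes Numeric matrix, animals x time points. No `NA`s.
#' @param group Integer vector of 0/1 treatment indicators, one per animal
#'   (0 = control/reference, 1 = treatment). Both groups must be present.
#' @param times Strictly increasing numeric measurement times (e.g. study
#'   days). Length must equal `ncol(volumes)`.
#' @param animal_ids Optional unique labels, one per animal. Defaults to
#'   `rownames(volumes)` or `"animal_1"`, ... .
#' @param scale Either `"raw"` (volumes, e.g. mm^3) or `"log"`
#'   (natural-log transformed). Recorded as metadata; no transform is
#'   applied here.
#' @return An object of class `growth_dataset`: a list with fields
#'   `volumes`, `group`, `times`, `animal_ids`, `scale`.
#' @examples
#' vol <- matrix(c(1, 2, 4, 1.1, 2.2, 4.4, 1, 2.1, 3.9, 0.9, 1.8, 3.6),
#'               nrow = 4, byrow = TRUE)
#' ds <- growth_dataset(vol, group = c(0, 0, 1, 1), times = c(3, 5, 7))
#' ds
#' @export
growth_dataset <- function(volumes, group, times, animal_ids = NULL,
                           scale = c("raw", "log")) {
  scale <- match.arg(scale)
  volumes <- as.matrix(volumes)
  if (!is.numeric(volumes)) {
    stop("'volumes' must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(volumes)) {
    bad <- which(is.na(volumes), arr.ind = TRUE)[1, ]
    stop(sprintf("missing volume for animal %d at time column %d; %s",
                 bad[1], bad[2],
                 "complete data are required (no pairwise deletion)"),
         call. = FALSE)
  }
  group <- as.integer(group)
  if (length(group) != nrow(volumes)) {
    stop("'group' must have one entry per row of 'volumes'", call. = FALSE)
  }
  if (!all(group %in% c(0L, 1L)) || anyNA(group)) {
    stop("'group' must contain only 0 and 1", call. = FALSE)
  }
  if (!all(c(0L, 1L) %in% group)) {
    stop("both groups (0 and 1) must be present", call. = FALSE)
  }
  times <- as.numeric(times)
  if (length(times) != ncol(volumes)) {
    stop("'times' must have one entry per column of 'volumes'",
         call. = FALSE)
  }
  if (anyNA(times) || any(diff(times) <= 0)) {
    stop("'times' must be strictly increasing", call. = FALSE)
  }
  if (is.null(animal_ids)) {
    animal_ids <- rownames(volumes)
    if (is.null(animal_ids)) {
      animal_ids <- paste0("animal_", seq_len(nrow(volumes)))
    }
  }
  animal_ids <- as.character(animal_ids)
  if (length(animal_ids) != nrow(volumes)) {
    stop("'animal_ids' must have one entry per animal", call. = FALSE)
  }
  if (anyDuplicated(animal_ids)) {
    stop("duplicate animal ids: ",
         paste(unique(animal_ids[duplicated(animal_ids)]), collapse = ", "),
         call. = FALSE)
  }
  dimnames(volumes) <- list(animal_ids, times)
  structure(
    list(volumes = volumes, group = group, times = times,
         animal_ids = animal_ids, scale = scale),
    class = "growth_dataset"
  )
}

#' @export
print.growth_dataset <- function(x, ...) {
  cat(sprintf("Growth-curve dataset: %d animals (%d control, %d treated), %d time points\n",
              length(x$animal_ids), sum(x$group == 0), sum(x$group == 1),
              length(x$times)))
  cat("  times:", paste(x$times, collapse = ", "), "\n")
  cat("  scale:", x$scale, "\n")
  invisible(x)
}

#' Apply a natural-log transform to a raw-scale dataset
#'
#' @param dataset A [growth_dataset()] on the raw scale with strictly
#'   positive volumes.
#' @return A `growth_dataset` with `scale = "log"`.
#' @export
log_transform <- function(dataset) {
  stopifnot(inherits(dataset, "growth_dataset"))
  if (dataset$scale == "log") {
    stop("dataset is already on the log scale", call. = FALSE)
  }
  if (any(dataset$volumes <= 0)) {
    stop("log transform requires strictly positive volumes", call. = FALSE)
  }
  growth_dataset(log(dataset$volumes), dataset$group, dataset$times,
                 dataset$animal_ids, scale = "log")
}

#' Convert a growth-curve dataset to long format
#'
#' One record per animal and time point, the layout consumed by the
#' linear-mixed-model comparator.
#'
#' @param dataset A [growth_dataset()].
#' @return A `data.frame` with columns `animal_id`, `group`, `time`,
#'   `volume`, ordered animal-major.
#' @export
growth_long <- function(dataset) {
  stopifnot(inherits(dataset, "growth_dataset"))
  m <- length(dataset$times)
  n <- length(dataset$animal_ids)
  data.frame(
    animal_id = rep(dataset$animal_ids, each = m),
    group = rep(dataset$group, each = m),
    time = rep(dataset$times, times = n),
    volume = as.vector(t(dataset$volumes)),
    stringsAsFactors = FALSE
  )
}
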