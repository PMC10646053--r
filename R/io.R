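#' Read a growth-curve CSV
#'
#' Two dialects are accepted. Wide (canonical): header
#' `animal_id,group,<t1>,<t2>,...` with one numeric time per volume
#' column and one row per animal. Long: header
#' `animal_id,group,time,volume`, one record per animal and time point,
#' pivoted to wide on load (complete panels required).
#'
#' Group labels that are not already 0/1 must be resolved with
#' `control`, which names the label mapped to group 0.
#'
#' @param path CSV file path (UTF-8, '.' decimal separator).
#' @param dialect `"wide"` (default) or `"long"`.
#' @param log_transform Apply a natural-log transform on load.
#' @param control Group label to treat as group 0 (reference) when the
#'   group column is not numeric 0/1.
#' @return A [growth_dataset()].
#' @export
read_growth_csv <- function(path, dialect = c("wide", "long"),
                            log_transform = FALSE, control = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  ds <- if (dialect == "wide") {
    parse_wide(raw, control)
  } else {
    parse_long(raw, control)
  }
  if (log_transform) ds <- log_transform(ds) else ds
}

map_group <- function(g, control) {
  if (is.numeric(g) && all(g %in% c(0, 1))) {
    return(as.integer(g))
  }
  labs <- unique(as.character(g))
  if (length(labs) != 2) {
    stop("expected exactly 2 group labels, found: ",
         paste(labs, collapse = ", "), call. = FALSE)
  }
  if (is.null(control)) {
    stop("group labels are not 0/1 (found ",
         paste(labs, collapse = ", "),
         "); supply 'control' to name the reference (group 0) label",
         call. = FALSE)
  }
  if (!control %in% labs) {
    stop("unknown control label '", control, "'; group labels are: ",
         paste(labs, collapse = ", "), call. = FALSE)
  }
  as.integer(as.character(g) != control)
}

check_volume_block <- function(vol, ids, times) {
  bad_num <- which(!vapply(vol, is.numeric, logical(1)))
  if (length(bad_num)) {
    stop("non-numeric volumes in column(s): ",
         paste(names(vol)[bad_num], collapse = ", "), call. = FALSE)
  }
  na_idx <- which(is.na(as.matrix(vol)), arr.ind = TRUE)
  if (nrow(na_idx)) {
    stop(sprintf("missing volume for animal '%s' at time %s",
                 ids[na_idx[1, 1]], times[na_idx[1, 2]]),
         call. = FALSE)
  }
}

parse_wide <- function(raw, control) {
  if (ncol(raw) < 4 || !identical(names(raw)[1:2], c("animal_id", "group"))) {
    stop("wide dialect requires header 'animal_id,group,<t1>,<t2>,...'",
         call. = FALSE)
  }
  times <- suppressWarnings(as.numeric(names(raw)[-(1:2)]))
  if (anyNA(times)) {
    stop("wide-dialect time columns must have numeric headers; found: ",
         paste(names(raw)[-(1:2)][is.na(times)], collapse = ", "),
         call. = FALSE)
  }
  ids <- as.character(raw$animal_id)
  if (anyDuplicated(ids)) {
    stop("duplicate animal ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  vol <- raw[, -(1:2), drop = FALSE]
  check_volume_block(vol, ids, times)
  ord <- order(times)
  growth_dataset(as.matrix(vol)[, ord, drop = FALSE],
                 group = map_group(raw$group, control),
                 times = times[ord], animal_ids = ids)
}

parse_long <- function(raw, control) {
  req <- c("animal_id", "group", "time", "volume")
  if (!all(req %in% names(raw))) {
    stop("long dialect requires header 'animal_id,group,time,volume'",
         call. = FALSE)
  }
  if (!is.numeric(raw$time)) {
    stop("'time' must be numeric", call. = FALSE)
  }
  if (!is.numeric(raw$volume)) {
    stop("non-numeric volumes in column: volume", call. = FALSE)
  }
  ids <- unique(as.character(raw$animal_id))
  times <- sort(unique(raw$time))
  key <- paste(raw$animal_id, raw$time)
  if (anyDuplicated(key)) {
    stop("duplicate (animal_id, time) records", call. = FALSE)
  }
  vol <- matrix(NA_real_, nrow = length(ids), ncol = length(times),
                dimnames = list(ids, times))
  vol[cbind(match(as.character(raw$animal_id), ids),
            match(raw$time, times))] <- raw$volume
  na_idx <- which(is.na(vol), arr.ind = TRUE)
  if (nrow(na_idx)) {
    stop(sprintf("missing volume for animal '%s' at time %s",
                 ids[na_idx[1, 1]], times[na_idx[1, 2]]),
         call. = FALSE)
  }
  grp <- raw$group[match(ids, as.character(raw$animal_id))]
  growth_dataset(vol, group = map_group(grp, control),
                 times = times, animal_ids = ids)
}

#' Write a growth-curve dataset to CSV
#'
#' @param dataset A [growth_dataset()].
#' @param path Output path.
#' @param dialect `"wide"` (default) or `"long"`.
#' @return `path`, invisibly.
#' @export
write_growth_csv <- function(dataset, path, dialect = c("wide", "long")) {
  stopifnot(inherits(dataset, "growth_dataset"))
  dialect <- match.arg(dialect)
  df <- if (dialect == "wide") {
    out <- data.frame(animal_id = dataset$animal_ids,
                      group = dataset$group,
                      stringsAsFactors = FALSE)
    vol <- as.data.frame(dataset$volumes)
    names(vol) <- as.character(dataset$times)
    cbind(out, vol)
  } else {
    growth_long(dataset)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
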