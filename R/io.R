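#' Construct a capture-data object
#'
#' Validates and wraps a table of detections (one row per individual x
#' occasion at which it was caught). Egg counts may only appear on records
#' whose observed size is at or above the maturity threshold, sizes must be
#' positive, and occasion times must sit on the half-month grid.
#'
#' @param records data frame with columns `id`, `site`, `occasion`,
#'   `month_offset`, `size_mm`, `eggs`.
#' @param design optional [survey_design]; if `NULL` it is reconstructed
#'   from the records (the season boundary is placed at the largest gap
#'   between consecutive occasions at each site).
#' @param truth optional [simulation_truth] kept for recovery tests.
#' @param maturity_threshold threshold used to validate egg records, mm.
#' @return A data frame of class `capture_data` with `design` (and possibly
#'   `truth`) attributes.
#' @export
capture_data <- function(records, design = NULL, truth = NULL,
                         maturity_threshold = 36) {
  req <- c("id", "site", "occasion", "month_offset", "size_mm", "eggs")
  problems <- character()
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- records[order(records$id, records$occasion), req]
  rownames(records) <- NULL
  if (nrow(records)) {
    if (any(!is.finite(records$size_mm) | records$size_mm <= 0))
      problems <- c(problems, "sizes must be positive")
    off_grid <- abs(records$month_offset / 0.5 - round(records$month_offset / 0.5)) > 1e-6
    if (any(off_grid))
      problems <- c(problems, sprintf("%d month offset(s) off the 0.5-month grid",
                                      sum(off_grid)))
    bad_occ <- tapply(records$occasion, records$id, function(o) any(diff(o) <= 0))
    if (any(unlist(bad_occ)))
      problems <- c(problems, "occasion indices must increase within individual")
    # same occasion at one site must have one time
    key <- paste(records$site, records$occasion)
    tt <- tapply(records$month_offset, key, function(v) length(unique(v)) > 1)
    if (any(unlist(tt)))
      problems <- c(problems, "inconsistent month_offset for a site/occasion pair")
    eg <- !is.na(records$eggs)
    if (any(eg & records$size_mm < maturity_threshold))
      problems <- c(problems, "egg counts recorded below the maturity threshold")
  }
  if (length(problems)) {
    stop("invalid capture data:\n  - ", paste(problems, collapse = "\n  - "))
  }
  if (is.null(design)) design <- design_from_records(records)
  structure(records, class = c("capture_data", "data.frame"),
            design = design, truth = truth)
}

design_from_records <- function(records) {
  if (!nrow(records)) stop("cannot reconstruct a design from empty records")
  occ <- unique(records[, c("site", "occasion", "month_offset")])
  occ <- occ[order(occ$site, occ$occasion), ]
  occ$season <- unlist(lapply(split(occ, occ$site), function(o) {
    if (nrow(o) < 4)
      stop("too few occasions with detections at site ", o$site[1],
           " to infer the season structure; supply a survey design")
    boundary <- which.max(diff(o$month_offset))  # summer gap
    rep(1:2, c(boundary, nrow(o) - boundary))
  }), use.names = FALSE)
  survey_design(occ, n_initial = rep(0L, length(unique(occ$site))),
                staggered_frac = 0)
}

#' @export
print.capture_data <- function(x, ...) {
  d <- attr(x, "design")
  cat(sprintf("Capture data: %d detections of %d individuals at %d site(s)\n",
              nrow(x), length(unique(x$id)), length(unique(x$site))))
  NextMethod()
}

#' Write capture data to CSV
#'
#' Plain-CSV serialization of the detection records; round-trips losslessly
#' through [read_capture_csv()].
#'
#' @param data a [capture_data] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_capture_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read capture data from CSV
#'
#' Reads a detection table written by [write_capture_csv()] (columns `id`,
#' `site`, `occasion`, `month_offset`, `size_mm`, `eggs`), validates it and
#' reconstructs the survey design unless one is supplied.
#'
#' @param path CSV file path.
#' @param design optional [survey_design] describing all occasions
#'   (needed if some surveyed occasions yielded no detections).
#' @return A [capture_data] object.
#' @export
read_capture_csv <- function(path, design = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  capture_data(df, design = design)
}

#' Prepare capture data for the joint likelihood
#'
#' Collapses the detection records into the structures the likelihood needs:
#' per-individual detection histories over the site's occasions, one mean
#' observed size per field season (the within-season average of the measured
#' sizes), egg observations (one per individual-season), and the interval
#' lengths in months. Individuals first detected in season 2 contribute no
#' growth term; individuals with a season-1 size but no season-2 size get a
#' latent season-2 size imputed during sampling.
#'
#' @param data a [capture_data] object.
#' @return A list of class `cmr_data` with elements `individuals` (data
#'   frame: `id`, `site`, `first`, `last`, `x1`, `x2`, `has_growth`,
#'   `latent_x2`), `det` (list of 0/1 detection vectors over the site's
#'   occasions), `design`, and `eggs` (data frame: `id`, `site`, `season`,
#'   `size`, `count`).
#' @export
prepare_cmr_data <- function(data) {
  stopifnot(inherits(data, "capture_data"))
  design <- attr(data, "design")
  occ_by_site <- split(design$occasions, design$occasions$site)
  ids <- unique(data$id)
  if (!length(ids)) stop("no detections in capture data")
  ind <- vector("list", length(ids))
  det <- vector("list", length(ids))
  eggs <- list()
  for (k in seq_along(ids)) {
    rec <- data[data$id == ids[k], ]
    si <- rec$site[1]
    occ <- occ_by_site[[as.character(si)]]
    seas_occ <- occ$season[match(rec$occasion, occ$occasion)]
    x1 <- if (any(seas_occ == 1)) mean(rec$size_mm[seas_occ == 1]) else NA_real_
    x2 <- if (any(seas_occ == 2)) mean(rec$size_mm[seas_occ == 2]) else NA_real_
    d <- integer(nrow(occ))
    d[match(rec$occasion, occ$occasion)] <- 1L
    det[[k]] <- d
    ind[[k]] <- data.frame(id = ids[k], site = si,
                           first = min(rec$occasion), last = max(rec$occasion),
                           x1 = x1, x2 = x2,
                           has_growth = !is.na(x1),
                           latent_x2 = !is.na(x1) & is.na(x2))
    for (s in 1:2) {
      e <- rec$eggs[seas_occ == s]
      e <- e[!is.na(e)]
      if (length(e)) {
        eggs[[length(eggs) + 1L]] <- data.frame(
          id = ids[k], site = si, season = s,
          size = if (s == 1) x1 else x2, count = e[1])
      }
    }
  }
  structure(list(
    individuals = do.call(rbind, ind),
    det = det,
    design = design,
    eggs = if (length(eggs)) do.call(rbind, eggs) else
      data.frame(id = integer(), site = integer(), season = integer(),
                 size = numeric(), count = numeric())
  ), class = "cmr_data")
}
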