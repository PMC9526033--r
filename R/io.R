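#' Read length-frequency data from CSV
#'
#' Two layouts are understood:
#' \describe{
#'   \item{raw}{columns \code{date} (ISO-8601) and \code{length_mm}; one
#'     row per measured fish. Returned as a named list of per-date length
#'     vectors (feed to \code{\link{bin_lengths}}).}
#'   \item{pre-binned}{column \code{bin_lower_mm} followed by one count
#'     column per ISO date. Returned as an \code{\link{lfq}} object;
#'     bins must be uniform.}
#' }
#'
#' @param path CSV file path.
#' @return named list of lengths, or an \code{lfq} object.
#' @export
read_lfq_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  nms <- names(df)
  if (all(c("date", "length_mm") %in% nms)) {
    bad <- which(!is.finite(df$length_mm) | df$length_mm < 0)
    if (length(bad))
      stop("invalid length_mm at line(s) ",
           paste(bad + 1L, collapse = ", "))  # +1 for the header line
    if (any(is.na(as.Date(df$date, optional = TRUE))))
      stop("unparseable date at line(s) ",
           paste(which(is.na(as.Date(df$date, optional = TRUE))) + 1L,
                 collapse = ", "))
    return(split(df$length_mm, df$date))
  }
  if (nms[1] == "bin_lower_mm") {
    counts <- as.matrix(df[, -1, drop = FALSE])
    if (any(is.na(counts)) || any(counts < 0))
      stop("pre-binned counts must be non-negative and complete")
    return(lfq(df$bin_lower_mm, nms[-1], counts))
  }
  stop("unknown LFQ schema; expected columns (date, length_mm) or ",
       "(bin_lower_mm, <ISO dates...>)")
}

#' Write raw length samples to CSV
#'
#' @param lengths named list of per-date length vectors (as produced by
#'   \code{\link{simulate_length_frequencies}}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_lfq_csv <- function(lengths, path) {
  df <- data.frame(
    date = rep(names(lengths), lengths = NULL,
               times = vapply(lengths, length, integer(1))),
    length_mm = unlist(lengths, use.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an environmental grid to long CSV
#'
#' One row per (cell, year, month) with columns lon, lat, year, month,
#' depth_m, sst_c, sss, catch_t. The annual winter catch of winter year y
#' is carried on that winter's December row (month 12); other months have
#' \code{NA} catch.
#'
#' @param grid an \code{env_grid}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  stopifnot(inherits(grid, "env_grid"))
  m <- grid$monthly
  key <- paste(m$lon, m$lat)
  cells_key <- paste(grid$cells$lon, grid$cells$lat)
  out <- data.frame(lon = m$lon, lat = m$lat, year = m$year,
                    month = m$month,
                    depth_m = grid$cells$depth_m[match(key, cells_key)],
                    sst_c = m$sst_c, sss = m$sss,
                    catch_t = NA_real_)
  if (!is.null(grid$catch)) {
    ck <- paste(grid$catch$lon, grid$catch$lat, grid$catch$year)
    dec <- which(out$month == 12L)
    out$catch_t[dec] <- grid$catch$catch_t[
      match(paste(out$lon, out$lat, out$year)[dec], ck)]
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read an environmental grid from long CSV
#'
#' Inverse of \code{\link{write_grid_csv}}. Duplicate (lon, lat, year,
#' month) rows and missing required columns are rejected.
#'
#' @param path CSV path.
#' @return an \code{env_grid}.
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("lon", "lat", "year", "month", "depth_m", "sst_c", "sss")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  key <- paste(df$lon, df$lat, df$year, df$month)
  if (anyDuplicated(key))
    stop("duplicate (lon, lat, year, month) rows in grid file")
  cells <- unique(df[, c("lon", "lat", "depth_m")])
  if (anyDuplicated(paste(cells$lon, cells$lat)))
    stop("inconsistent depth for the same cell across rows")
  cells <- cells[order(cells$lat, cells$lon), , drop = FALSE]
  rownames(cells) <- NULL
  monthly <- df[, c("lon", "lat", "year", "month", "sst_c", "sss")]
  catch <- NULL
  if ("catch_t" %in% names(df)) {
    dec <- df[df$month == 12L & !is.na(df$catch_t), , drop = FALSE]
    if (nrow(dec))
      catch <- data.frame(lon = dec$lon, lat = dec$lat, year = dec$year,
                          catch_t = dec$catch_t)
  }
  res <- if (nrow(cells) > 1) min(diff(sort(unique(cells$lon)))) else 0.5
  years <- if (!is.null(catch)) sort(unique(catch$year))
           else sort(unique(df$year[df$month == 12L]))
  structure(list(cells = cells, monthly = monthly, catch = catch,
                 resolution = res, years = years, scenario = NULL),
            class = "env_grid")
}
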