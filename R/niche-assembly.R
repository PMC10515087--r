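# Species-level analysis table assembly: averaging repeated physiological
# measurements, climatic-niche summaries from occurrence records, nearest-cell
# extraction from gridded climate surfaces, and the trait/niche join.

#' Average repeated physiological measurements per species
#'
#' Collapses raw measurement rows (one row per measurement) to one value per
#' species and trait by the arithmetic mean. Hardening labels are resolved per
#' species: a single consistent label is kept; conflicting labels collapse to
#' `"unknown"` with a warning. Conflicting group labels keep the first
#' observed, with a warning.
#'
#' @param records Data frame with columns `species`, `trait` (`"T_min"` or
#'   `"T_max"`), `value` (numeric, °C), and optionally `hardening`
#'   (`"hardened"`, `"non_hardened"`, `"unknown"`) and `group`
#'   (`"angiosperm"`, `"gymnosperm"`, `"fern"`, `"bryophyte"`).
#' @return A species-level trait table: `species`, `T_min`, `T_max` (NA when
#'   unmeasured), `hardening`, `group`. Species where `T_min >= T_max` are
#'   kept with a warning.
#' @export
average_repeated_measurements <- function(records) {
  req <- c("species", "trait", "value")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  bad_trait <- !records$trait %in% c("T_min", "T_max")
  if (any(bad_trait))
    stop("unknown trait in rows ", paste(which(bad_trait), collapse = ", "))
  val <- suppressWarnings(as.numeric(records$value))
  if (anyNA(val))
    stop("non-numeric trait value in rows ",
         paste(utils::head(which(is.na(val)), 10), collapse = ", "))
  records$value <- val
  if (is.null(records$hardening)) records$hardening <- "unknown"
  if (is.null(records$group)) records$group <- NA_character_

  agg <- stats::aggregate(value ~ species + trait, data = records, FUN = mean)
  wide <- stats::reshape(agg, idvar = "species", timevar = "trait",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  for (tr in c("T_min", "T_max"))
    if (!tr %in% names(wide)) wide[[tr]] <- NA_real_

  resolve <- function(sp) {
    rows <- records[records$species == sp, ]
    h <- unique(rows$hardening[!is.na(rows$hardening)])
    h <- setdiff(h, "unknown")
    hard <- if (length(h) == 1L) h
            else if (length(h) == 0L) "unknown"
            else { warning("conflicting hardening labels for ", sp,
                           "; set to unknown"); "unknown" }
    g <- unique(rows$group[!is.na(rows$group)])
    grp <- if (length(g) <= 1L) (if (length(g)) g else NA_character_)
           else { warning("conflicting group labels for ", sp,
                          "; keeping first"); g[1L] }
    c(hard, grp)
  }
  hg <- t(vapply(wide$species, resolve, character(2)))
  wide$hardening <- hg[, 1L]
  wide$group <- hg[, 2L]
  bad <- !is.na(wide$T_min) & !is.na(wide$T_max) & wide$T_min >= wide$T_max
  if (any(bad))
    warning("T_min >= T_max for: ", paste(wide$species[bad], collapse = ", "))
  rownames(wide) <- NULL
  wide[order(wide$species), c("species", "T_min", "T_max", "hardening",
                              "group")]
}

#' Summarize a species' climatic niche from occurrence records
#'
#' Per species: number of occurrences, arithmetic means of Bio5 (MTWM) and
#' Bio6 (MTCM), the 90th percentile of Bio5 (`upper_MTWM`) and the 10th
#' percentile of Bio6 (`lower_MTCM`). Percentiles use the linear-interpolation
#' definition (R `quantile` type 7), so results are reproducible bit-for-bit.
#' With `tail_mode = "tail_mean"` the tail summaries are instead the mean of
#' values at or above (below) the 90th (10th) percentile — the literal
#' "top 90% values" reading.
#'
#' @param occ Data frame with columns `species`, `longitude`, `latitude`,
#'   `bio5`, `bio6` (°C). Coordinates are validated: longitude in
#'   `[-180, 180]`, latitude in `[-90, 90]` (error). `bio5 < bio6` at a point
#'   triggers a warning.
#' @param species Optional subset of species; default all in `occ`.
#' @param tail_mode `"percentile"` (default) or `"tail_mean"`.
#' @return Data frame: `species`, `n_occurrences`, `mean_MTWM`, `mean_MTCM`,
#'   `upper_MTWM`, `lower_MTCM`.
#' @export
summarize_niche <- function(occ, species = NULL,
                            tail_mode = c("percentile", "tail_mean")) {
  tail_mode <- match.arg(tail_mode)
  req <- c("species", "longitude", "latitude", "bio5", "bio6")
  miss <- setdiff(req, names(occ))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(occ$longitude < -180 | occ$longitude > 180, na.rm = TRUE))
    stop("longitude outside [-180, 180]")
  if (any(occ$latitude < -90 | occ$latitude > 90, na.rm = TRUE))
    stop("latitude outside [-90, 90]")
  if (any(occ$bio5 < occ$bio6, na.rm = TRUE))
    warning("bio5 < bio6 at some occurrence points")
  if (!is.null(species)) occ <- occ[occ$species %in% species, , drop = FALSE]
  if (nrow(occ) == 0L) stop("no occurrences for the requested species")
  one <- function(d) {
    up <- if (tail_mode == "percentile")
      unname(stats::quantile(d$bio5, 0.9, type = 7))
    else mean(d$bio5[d$bio5 >= stats::quantile(d$bio5, 0.9, type = 7)])
    lo <- if (tail_mode == "percentile")
      unname(stats::quantile(d$bio6, 0.1, type = 7))
    else mean(d$bio6[d$bio6 <= stats::quantile(d$bio6, 0.1, type = 7)])
    data.frame(species = d$species[1L], n_occurrences = nrow(d),
               mean_MTWM = mean(d$bio5), mean_MTCM = mean(d$bio6),
               upper_MTWM = up, lower_MTCM = lo, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(split(occ, occ$species), one))
  rownames(out) <- NULL
  out[order(out$species), ]
}

#' Read an ESRI ASCII grid
#'
#' Plain-text raster format: a 6-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`) followed by `nrows` rows of
#' values, first row northernmost.
#'
#' @param path File path.
#' @return A list of class `climate_grid`: `values` (matrix, row 1 = north),
#'   `xll`, `yll`, `cellsize`, `ncols`, `nrows`, `nodata`.
#' @export
read_esri_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
  }
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA
  structure(list(values = m, xll = hdr$xllcorner, yll = hdr$yllcorner,
                 cellsize = hdr$cellsize, ncols = hdr$ncols,
                 nrows = hdr$nrows, nodata = hdr$nodata_value),
            class = "climate_grid")
}

#' Write an ESRI ASCII grid
#'
#' @param grid A `climate_grid` (see [read_esri_grid()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_esri_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", grid$ncols), paste("nrows", grid$nrows),
    paste("xllcorner", format(grid$xll, digits = 12)),
    paste("yllcorner", format(grid$yll, digits = 12)),
    paste("cellsize", format(grid$cellsize, digits = 12)),
    paste("NODATA_value", grid$nodata)), con)
  v <- grid$values
  v[is.na(v)] <- grid$nodata
  writeLines(apply(v, 1L, function(r)
    paste(format(r, digits = 9, trim = TRUE), collapse = " ")), con)
  invisible(path)
}

#' Build a climate grid from an analytic surface
#'
#' @param xll,yll Lower-left corner of the extent.
#' @param cellsize Cell size (degrees).
#' @param ncols,nrows Grid dimensions.
#' @param fun Function of (lon, lat) vectors evaluated at cell centers.
#' @param nodata NODATA sentinel (default -9999).
#' @return A `climate_grid`.
#' @export
make_climate_grid <- function(xll, yll, cellsize, ncols, nrows, fun,
                              nodata = -9999) {
  lon_c <- xll + (seq_len(ncols) - 0.5) * cellsize
  lat_c <- yll + (nrows - seq_len(nrows) + 0.5) * cellsize  # row 1 = north
  vals <- outer(lat_c, lon_c, function(la, lo) fun(lo, la))
  structure(list(values = vals, xll = xll, yll = yll, cellsize = cellsize,
                 ncols = ncols, nrows = nrows, nodata = nodata),
            class = "climate_grid")
}

#' Extract grid values at coordinates
#'
#' Nearest-cell lookup with cell-center registration: each point takes the
#' value of the cell containing it; a point exactly on a cell edge belongs to
#' the cell with the larger column / larger row-from-south index (i.e. east /
#' north). Points outside the extent (including the exact north/east boundary)
#' return `NA` rather than erroring.
#'
#' @param grid A `climate_grid`.
#' @param lon,lat Coordinate vectors (equal length).
#' @return Numeric vector of cell values, `NA` where out of extent or NODATA.
#' @export
extract_grid_values <- function(grid, lon, lat) {
  stopifnot(length(lon) == length(lat))
  col <- floor((lon - grid$xll) / grid$cellsize) + 1
  row_s <- floor((lat - grid$yll) / grid$cellsize) + 1  # from south
  ok <- col >= 1 & col <= grid$ncols & row_s >= 1 & row_s <= grid$nrows
  out <- rep(NA_real_, length(lon))
  r_top <- grid$nrows - row_s[ok] + 1
  out[ok] <- grid$values[cbind(r_top, col[ok])]
  out
}

#' Attach experimental-site climate to a niche table
#'
#' The "local" niche variant: extract Bio5/Bio6 at each species'
#' experimental-site coordinate.
#'
#' @param niches Niche summary table from [summarize_niche()].
#' @param sites Data frame `species`, `longitude`, `latitude`.
#' @param grid_bio5,grid_bio6 `climate_grid` surfaces.
#' @return `niches` with `local_MTWM`, `local_MTCM` columns added.
#' @export
add_local_niche <- function(niches, sites, grid_bio5, grid_bio6) {
  i <- match(niches$species, sites$species)
  niches$local_MTWM <- extract_grid_values(grid_bio5, sites$longitude[i],
                                           sites$latitude[i])
  niches$local_MTCM <- extract_grid_values(grid_bio6, sites$longitude[i],
                                           sites$latitude[i])
  niches
}

#' Assemble the species-level analysis table
#'
#' Inner join of the trait table and the niche summaries; the `MTCM`/`MTWM`
#' columns come from the chosen niche variant: `mean` (range averages),
#' `tail` (`lower_MTCM` / `upper_MTWM`), or `local` (experimental-site
#' values, requiring `local_*` columns). Join losses on either side are
#' reported with a message.
#'
#' @param traits Trait table (see [average_repeated_measurements()]).
#' @param niches Niche summary table (see [summarize_niche()]).
#' @param niche_variant `"mean"`, `"tail"`, or `"local"`.
#' @return Data frame: `species`, `T_min`, `T_max`, `MTCM`, `MTWM`,
#'   `hardening`, `group`.
#' @export
assemble_analysis_table <- function(traits, niches,
                                    niche_variant = c("mean", "tail",
                                                      "local")) {
  niche_variant <- match.arg(niche_variant)
  cols <- switch(niche_variant,
    mean = c(MTCM = "mean_MTCM", MTWM = "mean_MTWM"),
    tail = c(MTCM = "lower_MTCM", MTWM = "upper_MTWM"),
    local = c(MTCM = "local_MTCM", MTWM = "local_MTWM"))
  miss <- setdiff(cols, names(niches))
  if (length(miss))
    stop("niche table lacks columns for variant '", niche_variant, "': ",
         paste(miss, collapse = ", "))
  tab <- merge(traits, niches[, c("species", cols)], by = "species")
  lost_t <- setdiff(traits$species, tab$species)
  lost_n <- setdiff(niches$species, tab$species)
  if (length(lost_t) || length(lost_n))
    message("join dropped ", length(lost_t), " trait-only and ",
            length(lost_n), " niche-only species")
  names(tab)[match(cols, names(tab))] <- names(cols)
  if (is.null(tab$hardening)) tab$hardening <- "unknown"
  tab[order(tab$species),
      c("species", "T_min", "T_max", "MTCM", "MTWM", "hardening", "group")]
}

#' Read a delimited trait or occurrence table
#'
#' Tab-separated with a header row; plain `utils::read.delim` with
#' `stringsAsFactors = FALSE`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a delimited table
#'
#' @param x Data frame.
#' @param path File path.
#' @param digits Optional rounding applied to numeric columns (e.g. 2 to
#'   mirror published tables); `NULL` writes full precision.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path, digits = NULL) {
  if (!is.null(digits))
    x[] <- lapply(x, function(col)
      if (is.numeric(col)) round(col, digits) else col)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
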