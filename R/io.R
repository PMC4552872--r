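# CSV input/output for double-observer line-transect surveys. Files in the
# wild use arbitrary headers, so reading goes through a schema map (canonical
# field -> file column). Canonical observation fields: transect, distance
# (m), size, seen_by_1, seen_by_2, plus covariates (activity, cover, snow,
# airspeed, searchdist, flat, ...). Canonical transect fields: transect,
# length (km) and/or area (km^2), optional habitat.

#' Schema maps for survey CSV files
#'
#' A schema map is a named character vector `canonical_field = file_column`.
#' `obs_schema()` and `transect_schema()` return the identity defaults;
#' override entries to adapt arbitrary headers, e.g.
#' `obs_schema(distance = "PerpDist", size = "GroupSize")`.
#'
#' @param ... Named overrides `canonical = "file column"`.
#' @return Named character vector.
#' @export
obs_schema <- function(...) {
  base <- c(transect = "transect", distance = "distance", size = "size",
            seen_by_1 = "seen_by_1", seen_by_2 = "seen_by_2",
            activity = "activity", cover = "cover", snow = "snow",
            airspeed = "airspeed", searchdist = "searchdist", flat = "flat")
  ov <- c(...)
  base[names(ov)] <- ov
  base
}

#' @rdname obs_schema
#' @export
transect_schema <- function(...) {
  base <- c(transect = "transect", length = "length", area = "area",
            habitat = "habitat")
  ov <- c(...)
  base[names(ov)] <- ov
  base
}

# Pull mapped columns out of a raw data frame; `required` must be present.
apply_schema <- function(raw, schema, required, path) {
  found <- schema[schema %in% colnames(raw)]
  missing_req <- setdiff(required, names(found))
  if (length(missing_req))
    stop("missing required column(s) in ", path, ": ",
         paste(sprintf("%s (expected header '%s')", missing_req,
                       schema[missing_req]), collapse = ", "),
         "; found headers: ", paste(colnames(raw), collapse = ", "),
         call. = FALSE)
  out <- raw[unname(found)]
  colnames(out) <- names(found)
  # covariates outside the canonical schema pass through untouched
  extra <- setdiff(colnames(raw), unname(found))
  if (length(extra)) out <- cbind(out, raw[extra])
  out
}

#' Standard covariate transforms
#'
#' Adds the transformed covariate columns used by the detection models:
#' `cover20 = cover / 20`, `snow20 = snow / 20`, `airspeed100 =
#' airspeed / 100` (rescalings that condition the optimizer), and
#' `bin_lnsd<w>` — search distance truncated at `w`, natural-logged, and
#' binned into `n_bins` equal-width classes on the log scale (value = bin
#' midpoint), which decorrelates search distance from perpendicular
#' distance. Columns absent from the input are skipped.
#'
#' @param data Observation data frame with canonical column names.
#' @param w Right truncation distance used for the search-distance bin.
#' @param n_bins Number of log-scale search-distance bins.
#' @return `data` with the derived columns appended.
#' @export
apply_transforms <- function(data, w = 350, n_bins = 9) {
  if ("cover" %in% colnames(data)) data$cover20 <- data$cover / 20
  if ("snow" %in% colnames(data)) data$snow20 <- data$snow / 20
  if ("airspeed" %in% colnames(data)) data$airspeed100 <- data$airspeed / 100
  if ("searchdist" %in% colnames(data)) {
    sd_tr <- pmin(data$searchdist, w)
    if (any(sd_tr <= 0)) stop("search distances must be positive",
                              call. = FALSE)
    lsd <- log(sd_tr)
    lo <- min(lsd); hi <- log(w)
    if (hi <= lo) hi <- lo + 1e-6
    edges <- seq(lo, hi, length.out = n_bins + 1)
    idx <- pmin(pmax(findInterval(lsd, edges, rightmost.closed = TRUE), 1L),
                n_bins)
    mids <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
    data[[paste0("bin_lnsd", w)]] <- mids[idx]
  }
  data
}

#' Read an observation CSV
#'
#' Reads a detections table (one row per detected group), maps headers to
#' the canonical schema, validates records, and applies the standard
#' covariate transforms. Truncation to the strip is *not* applied here —
#' that is the fitting layer's job — so trimmed-detection counts can be
#' reported.
#'
#' @param path CSV file (RFC-4180, header row required).
#' @param schema Schema map from [obs_schema()].
#' @param transforms Apply [apply_transforms()]? Default `TRUE`.
#' @param w Truncation distance forwarded to [apply_transforms()].
#' @return Validated observation data frame.
#' @export
read_observations <- function(path, schema = obs_schema(),
                              transforms = TRUE, w = 350) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE)
  out <- apply_schema(raw, schema,
                      c("distance", "seen_by_1", "seen_by_2"), path)
  bad <- which(!is.finite(out$distance) | out$distance < 0)
  if (length(bad))
    stop("invalid (negative or missing) distance in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  if ("size" %in% colnames(out)) {
    bad <- which(!is.finite(out$size) | out$size < 1)
    if (length(bad))
      stop("group size must be >= 1; row(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  for (cl in c("seen_by_1", "seen_by_2")) {
    v <- out[[cl]]
    if (is.logical(v)) v <- as.integer(v)
    if (!all(v %in% 0:1))
      stop("'", cl, "' must be 0/1", call. = FALSE)
    out[[cl]] <- as.integer(v)
  }
  bad <- which(out$seen_by_1 == 0L & out$seen_by_2 == 0L)
  if (length(bad))
    stop("capture history (0,0) in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  if (transforms) out <- apply_transforms(out, w = w)
  out
}

#' Read a transect CSV
#'
#' Supports length-only (`length` in km; covered area derived from the strip
#' width) and area-only (`area` in km^2) dialects, or both.
#'
#' @param path CSV file.
#' @param schema Schema map from [transect_schema()].
#' @return Validated transect data frame.
#' @export
read_transects <- function(path, schema = transect_schema()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE)
  out <- apply_schema(raw, schema, "transect", path)
  if (!any(c("length", "area") %in% colnames(out)))
    stop("transect table needs a 'length' (km) or 'area' (km^2) column ",
         "(via the schema map); found: ",
         paste(colnames(raw), collapse = ", "), call. = FALSE)
  for (cl in intersect(c("length", "area"), colnames(out))) {
    bad <- which(!is.finite(out[[cl]]) | out[[cl]] <= 0)
    if (length(bad))
      stop("non-positive '", cl, "' in row(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  out
}

#' Write observations to CSV
#'
#' Canonical-schema companion to [read_observations()]; round-trips all
#' canonical fields.
#'
#' @param data Observation data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}
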