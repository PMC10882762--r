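# Panel data model, coordinate tables, spatial weights, packaged fixtures.

#' Construct a validated long-format indicator panel
#'
#' An indicator panel holds one numeric value per (unit, year, indicator)
#' triple, plus an orientation ("positive": more is better; "negative": less
#' is better) per indicator, consumed by the entropy-weighting stage.
#'
#' @param df data.frame with columns `unit_id`, `year`, `indicator`, `value`.
#' @param orientation named character vector mapping indicator names to
#'   `"positive"` or `"negative"`. Indicators not named default to positive.
#' @return `df` with class `indicator_panel` and an `orientation` attribute.
#' @export
indicator_panel <- function(df, orientation = NULL) {
  req <- c("unit_id", "year", "indicator", "value")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("panel schema error: missing column(s) ", paste(miss, collapse = ", "))
  df <- df[req]
  df$unit_id <- as.character(df$unit_id)
  df$indicator <- as.character(df$indicator)
  if (!is.numeric(df$year)) {
    yr <- suppressWarnings(as.integer(as.character(df$year)))
    if (anyNA(yr)) stop("parse error: non-integer year value")
    df$year <- yr
  }
  df$year <- as.integer(df$year)
  if (!is.numeric(df$value)) {
    v <- suppressWarnings(as.numeric(as.character(df$value)))
    if (anyNA(v) & !anyNA(df$value))
      stop("parse error: non-numeric value at row ",
           paste(which(is.na(v))[1]))
    df$value <- v
  }
  if (any(!is.finite(df$value)))
    stop("parse error: non-finite value at row ",
         which(!is.finite(df$value))[1])
  key <- paste(df$unit_id, df$year, df$indicator, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1, ]
    stop("duplicate record for (", d$unit_id, ", ", d$year, ", ",
         d$indicator, ")")
  }
  inds <- sort(unique(df$indicator))
  ori <- setNames(rep("positive", length(inds)), inds)
  if (!is.null(orientation)) {
    bad <- setdiff(names(orientation), inds)
    if (length(bad))
      stop("orientation given for unknown indicator(s): ",
           paste(bad, collapse = ", "))
    if (!all(orientation %in% c("positive", "negative")))
      stop("orientation must be 'positive' or 'negative'")
    ori[names(orientation)] <- orientation
  }
  structure(df, orientation = ori,
            class = c("indicator_panel", "data.frame"))
}

#' Read an indicator panel from CSV
#'
#' @param path CSV file with a header row.
#' @param schema optional named character vector mapping the canonical column
#'   names (`unit_id`, `year`, `indicator`, `value`) to the file's column
#'   names, e.g. `c(unit_id = "province")`.
#' @param orientation passed to [indicator_panel()].
#' @return an `indicator_panel`.
#' @export
read_indicator_panel <- function(path, schema = NULL, orientation = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(df))
        stop("panel schema error: missing column(s) ", schema[[canon]])
      names(df)[names(df) == schema[[canon]]] <- canon
    }
  }
  indicator_panel(df, orientation = orientation)
}

#' Extract a units x indicators value matrix for one year
#'
#' @param panel an `indicator_panel`.
#' @param indicators character vector of indicator names (column order).
#' @param year single year.
#' @return numeric matrix, rownames = unit ids sorted alphabetically.
#' @export
panel_matrix <- function(panel, indicators, year) {
  sub <- panel[panel$year == year & panel$indicator %in% indicators, ,
               drop = FALSE]
  units <- sort(unique(panel$unit_id))
  out <- matrix(NA_real_, length(units), length(indicators),
                dimnames = list(units, indicators))
  out[cbind(match(sub$unit_id, units), match(sub$indicator, indicators))] <-
    sub$value
  if (anyNA(out)) {
    gaps <- which(is.na(out), arr.ind = TRUE)
    stop("missing indicator values for year ", year, ": ",
         paste(units[gaps[, 1]], indicators[gaps[, 2]],
               sep = "/", collapse = ", "))
  }
  out
}

#' Construct a coordinate table
#'
#' @param df data.frame with `unit_id` and either `lat`/`lon` (decimal
#'   degrees) or `x`/`y` (planar, any length unit).
#' @param planar logical; if `TRUE` columns `x`,`y` are used with Euclidean
#'   distance, otherwise `lat`,`lon` with great-circle distance.
#' @return data.frame of class `coordinate_table`.
#' @export
coordinate_table <- function(df, planar = FALSE) {
  cols <- if (planar) c("x", "y") else c("lat", "lon")
  miss <- setdiff(c("unit_id", cols), names(df))
  if (length(miss))
    stop("coordinate schema error: missing column(s) ",
         paste(miss, collapse = ", "))
  df <- df[c("unit_id", cols)]
  df$unit_id <- as.character(df$unit_id)
  if (anyDuplicated(df$unit_id))
    stop("duplicate unit_id in coordinate table: ",
         df$unit_id[duplicated(df$unit_id)][1])
  for (cc in cols) df[[cc]] <- as.numeric(df[[cc]])
  if (any(!is.finite(as.matrix(df[cols])))) stop("non-finite coordinate")
  structure(df, planar = planar,
            class = c("coordinate_table", "data.frame"))
}

#' @rdname coordinate_table
#' @param path CSV file with a header row.
#' @export
read_coordinates <- function(path, planar = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  coordinate_table(read.csv(path, stringsAsFactors = FALSE), planar = planar)
}

# great-circle distance matrix in km on a 6371-km sphere
haversine_matrix <- function(lat, lon) {
  r <- 6371
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  n <- length(lat)
  dphi <- outer(phi, phi, "-")
  dlam <- outer(lam, lam, "-")
  a <- sin(dphi / 2)^2 + outer(cos(phi), cos(phi)) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * r * asin(sqrt(a))
}

#' Construct a spatial weights object
#'
#' @param matrix n x n nonnegative matrix with a zero diagonal.
#' @param ids character vector of unit ids (row/column order).
#' @param standardization `"none"` or `"row"` (each nonzero row sums to 1).
#' @param kind provenance tag: `"inverse_distance"`, `"binary_contiguity"`
#'   or `"custom"`.
#' @return list of class `spatial_weights` with elements `ids`, `matrix`,
#'   `standardization`, `kind`.
#' @export
spatial_weights <- function(matrix, ids = rownames(matrix),
                            standardization = c("none", "row"),
                            kind = "custom") {
  standardization <- match.arg(standardization)
  matrix <- as.matrix(matrix)
  n <- nrow(matrix)
  if (n != ncol(matrix)) stop("weight matrix must be square")
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (length(ids) != n) stop("ids length must match matrix dimension")
  if (any(matrix < 0)) stop("spatial weights must be nonnegative")
  if (any(diag(matrix) != 0)) stop("spatial weights diagonal must be zero")
  if (all(matrix == 0)) stop("all-zero weight matrix")
  if (standardization == "row") {
    rs <- rowSums(matrix)
    nz <- rs > 0
    matrix[nz, ] <- matrix[nz, , drop = FALSE] / rs[nz]
  }
  dimnames(matrix) <- list(ids, ids)
  structure(list(ids = as.character(ids), matrix = matrix,
                 standardization = standardization, kind = kind),
            class = "spatial_weights")
}

#' Inverse-distance spatial weights
#'
#' Off-diagonal weights are `1/d_ij` where `d_ij` is the great-circle
#' distance in km for lat/lon coordinates (6371-km sphere) or the Euclidean
#' distance for planar coordinates; nearer units get larger weights. The
#' pre-standardization matrix is symmetric.
#'
#' @param coords a `coordinate_table`.
#' @param standardization `"none"` (keep raw 1/d) or `"row"`.
#' @return a `spatial_weights` object of kind `"inverse_distance"`.
#' @export
inverse_distance_weights <- function(coords,
                                     standardization = c("none", "row")) {
  standardization <- match.arg(standardization)
  if (!inherits(coords, "coordinate_table"))
    coords <- coordinate_table(coords, planar = all(c("x", "y") %in%
                                                      names(coords)))
  if (nrow(coords) < 2) stop("need at least 2 units")
  d <- if (isTRUE(attr(coords, "planar"))) {
    as.matrix(dist(coords[c("x", "y")]))
  } else {
    haversine_matrix(coords$lat, coords$lon)
  }
  off <- d[upper.tri(d)]
  if (any(off <= 0))
    stop("coincident coordinates: infinite inverse-distance weight")
  w <- 1 / d
  diag(w) <- 0
  spatial_weights(w, ids = coords$unit_id, standardization = standardization,
                  kind = "inverse_distance")
}

#' Packaged reference tables
#'
#' Returns one of the reference tables shipped with the package, transcribed
#' at the printed 3-decimal precision from a published province-level
#' analysis of primary-health-care efficiency in China (31 provinces,
#' 2016-2020): `table2_chrdi` (comprehensive health resource density index),
#' `table4_efficiency` (traditional and bootstrap-bias-corrected DEA
#' technical efficiency), `table5_moran` (yearly global Moran's I of
#' efficiency; `p_censored = 1` marks p values printed only as an upper
#' bound).
#'
#' @param name one of `"table2_chrdi"`, `"table4_efficiency"`,
#'   `"table5_moran"`.
#' @return data.frame.
#' @export
load_fixture <- function(name) {
  avail <- c("table2_chrdi", "table4_efficiency", "table5_moran")
  if (length(name) != 1 || !name %in% avail)
    stop("unknown fixture '", name, "'; available: ",
         paste(avail, collapse = ", "))
  path <- system.file("extdata", paste0(name, ".csv"), package = "phceff",
                      mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
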