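#' Column schema for a stem table
#'
#' Maps the canonical field names used throughout the package onto the column
#' headers of a particular CSV file, and defines how treatment labels are coded.
#' Herbivores-present is coded 1 so that a negative treatment effect on the
#' log kernel mean corresponds to herbivores pulling establishment towards the
#' source.
#'
#' @param plot,treatment,transect,distance_m Column names in the CSV.
#' @param cover_native,cover_weedy,cover_bare Optional cover columns (percent
#'   aerial cover of planted natives, non-planted weeds and bare ground in the
#'   0.25 m^2 around each stem). Set to `NULL` if absent from the file.
#' @param treatment_codes Named numeric vector mapping treatment labels to
#'   {0, 1}; numeric treatment columns already coded 0/1 are used as-is.
#' @return A list of class `stem_schema`.
#' @export
stem_schema <- function(plot = "plot",
                        treatment = "treatment",
                        transect = "transect",
                        distance_m = "distance_m",
                        cover_native = "cover_native_pct",
                        cover_weedy = "cover_weedy_pct",
                        cover_bare = "cover_bare_pct",
                        treatment_codes = c(absent = 0, present = 1)) {
  structure(list(plot = plot, treatment = treatment, transect = transect,
                 distance_m = distance_m, cover_native = cover_native,
                 cover_weedy = cover_weedy, cover_bare = cover_bare,
                 treatment_codes = treatment_codes),
            class = "stem_schema")
}

cover_cols <- c("cover_native_pct", "cover_weedy_pct", "cover_bare_pct")

#' Read a stem table from CSV
#'
#' One row per established stem: plot id, herbivore treatment, transect id,
#' establishment distance in metres from the outer edge of the seeded source
#' core, and optional aerial-cover percentages. Rows are validated against the
#' field-design invariants: distances non-negative and no longer than the
#' transect, covers within \[0, 100\] (the three covers need not sum to 100
#' because canopies overlap).
#'
#' @param path CSV file with a header row.
#' @param schema A [stem_schema()] mapping canonical names to file columns.
#' @param max_distance_m Transect length; distances beyond it are rejected.
#' @return A `data.frame` with columns `plot`, `treatment` (integer 0/1),
#'   `transect`, `distance_m` and any cover columns present, in file order.
#' @export
read_stem_table <- function(path, schema = stem_schema(), max_distance_m = 10) {
  if (!file.exists(path)) stop("stem table not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("plot", "treatment", "transect", "distance_m")
  for (fld in required) {
    col <- schema[[fld]]
    if (is.null(col) || !col %in% names(raw))
      stop("schema error: required column '", col %||% fld,
           "' (", fld, ") missing from ", path)
  }
  stems <- data.frame(
    plot = as.character(raw[[schema$plot]]),
    treatment = code_treatment(raw[[schema$treatment]], schema$treatment_codes),
    transect = as.character(raw[[schema$transect]]),
    distance_m = as.numeric(raw[[schema$distance_m]]),
    stringsAsFactors = FALSE
  )
  for (fld in c("cover_native", "cover_weedy", "cover_bare")) {
    col <- schema[[fld]]
    canon <- paste0(fld, "_pct")
    if (!is.null(col) && col %in% names(raw))
      stems[[canon]] <- as.numeric(raw[[col]])
  }
  validate_stem_table(stems, max_distance_m = max_distance_m)
  stems
}

code_treatment <- function(x, codes) {
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1)))
      stop("validation error: numeric treatment values must be 0 or 1")
    return(as.integer(x))
  }
  x <- as.character(x)
  unknown <- setdiff(unique(x), names(codes))
  if (length(unknown))
    stop("validation error: unmapped treatment label(s): ",
         paste(unknown, collapse = ", "))
  as.integer(codes[x])
}

#' Validate a stem table against the design invariants
#'
#' @param stems A stem table as returned by [read_stem_table()].
#' @param max_distance_m Transect length in metres.
#' @return The table, invisibly, if valid; otherwise an error naming the
#'   offending row.
#' @export
validate_stem_table <- function(stems, max_distance_m = 10) {
  bad <- which(!is.finite(stems$distance_m) | stems$distance_m < 0)
  if (length(bad))
    stop("validation error: negative or non-finite distance at row ", bad[1])
  bad <- which(stems$distance_m > max_distance_m)
  if (length(bad))
    stop("validation error: distance exceeds transect length (",
         max_distance_m, " m) at row ", bad[1])
  if (!all(stems$treatment %in% c(0L, 1L)))
    stop("validation error: treatment must be coded 0/1")
  for (col in intersect(cover_cols, names(stems))) {
    v <- stems[[col]]
    bad <- which(!is.na(v) & (v < 0 | v > 100))
    if (length(bad))
      stop("validation error: ", col, " outside [0, 100] at row ", bad[1])
  }
  invisible(stems)
}

#' Write a stem table to CSV at full precision
#'
#' Numeric columns are written with 17 significant digits so that a
#' read/write round trip reproduces every field exactly.
#'
#' @param stems A stem table.
#' @param path Output CSV path.
#' @export
write_stem_table <- function(stems, path) {
  out <- stems
  for (col in names(out)) {
    if (is.double(out[[col]]))
      out[[col]] <- ifelse(is.na(out[[col]]), NA,
                           formatC(out[[col]], digits = 17, format = "g"))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Discretize establishment distances into per-plot kernel data
#'
#' The Poisson-gamma establishment model has integer support, so metre-scale
#' distances are floored into bins of `bin_width_m`. One summed kernel is kept
#' per plot (transects pooled), matching the census design.
#'
#' @param stems A stem table.
#' @param bin_width_m Positive bin width in metres (default 0.1 m).
#' @return A `data.frame` of class `kernel_data` with columns `plot`,
#'   `treatment` and integer `y` (binned distance), plus attribute
#'   `bin_width_m`. Empty input yields an empty table.
#' @export
discretize <- function(stems, bin_width_m = 0.1) {
  stopifnot(is.numeric(bin_width_m), length(bin_width_m) == 1, bin_width_m > 0)
  if (nrow(stems)) {
    mixed <- tapply(stems$treatment, stems$plot, function(t) length(unique(t)))
    if (any(mixed > 1))
      stop("data-integrity error: plot(s) with mixed treatment labels: ",
           paste(names(mixed)[mixed > 1], collapse = ", "))
  }
  out <- data.frame(plot = stems$plot,
                    treatment = stems$treatment,
                    y = as.integer(floor(stems$distance_m / bin_width_m)),
                    stringsAsFactors = FALSE)
  attr(out, "bin_width_m") <- bin_width_m
  class(out) <- c("kernel_data", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
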