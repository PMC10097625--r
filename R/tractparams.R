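#' @include AllClasses.R
NULL

## tractparams column dialect (this package's own schema):
##   tract_name   required, unique label
##   roi1, roi2   required, names of the two defining ROIs
##   roi1_combine, roi2_combine  optional ';'-separated extra ROI names
##                unioned into the respective defining ROI
##   roi1_dilate, roi2_dilate    optional dilation iterations (default 0)
##   select_mode  all|any (default all)
##   clean        true|false (default true)
##   max_len_sd, max_dist_sd, max_iter  cleaning parameters (4, 4, 5)
##   c2roi        true|false (default false)
##   metrics      ';'-separated metric names (default FA)

tractparamsDefaults <- list(
  roi1_combine = "", roi2_combine = "",
  roi1_dilate = 0L, roi2_dilate = 0L,
  select_mode = "all", clean = TRUE,
  max_len_sd = 4, max_dist_sd = 4, max_iter = 5L,
  c2roi = FALSE, metrics = "FA")

parseLogicalCell <- function(x, row, col) {
  v <- tolower(trimws(as.character(x)))
  if (v %in% c("true", "t", "1", "yes")) return(TRUE)
  if (v %in% c("false", "f", "0", "no")) return(FALSE)
  stop(sprintf("tractparams row %d, column '%s': cannot parse '%s' as logical",
               row, col, x))
}

parseNumericCell <- function(x, row, col) {
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v))
    stop(sprintf("tractparams row %d, column '%s': cannot parse '%s' as number",
                 row, col, x))
  v
}

#' Parse a tractparams table
#'
#' Reads the per-tract configuration table (CSV text, file path, or data
#' frame) into typed rows with documented defaults applied. Unknown columns
#' produce a warning, not an error; duplicate tract names, missing required
#' columns, negative dilation iterations and unparseable numbers are
#' errors with row/column context.
#'
#' @param x CSV file path, CSV text (with embedded newlines), or data
#'   frame.
#' @return a list of named lists, one per tract, each with all parameters
#'   resolved.
#' @export
parseTractparams <- function(x) {
  if (is.data.frame(x)) {
    df <- x
  } else {
    if (length(x) == 1L && grepl("\n", x)) x <- textConnection(x)
    df <- read.csv(x, stringsAsFactors = FALSE, check.names = FALSE)
  }
  required <- c("tract_name", "roi1", "roi2")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("tractparams missing required column(s): ",
         paste(miss, collapse = ", "))
  known <- c(required, names(tractparamsDefaults))
  unknown <- setdiff(names(df), known)
  if (length(unknown))
    warning("tractparams has unknown column(s), ignored: ",
            paste(unknown, collapse = ", "))
  if (anyDuplicated(df$tract_name))
    stop("duplicate tract_name: ",
         paste(unique(df$tract_name[duplicated(df$tract_name)]),
               collapse = ", "))
  lapply(seq_len(nrow(df)), function(r) {
    row <- df[r, ]
    getCol <- function(col) {
      if (col %in% names(df) && !is.na(row[[col]]) &&
          !identical(trimws(as.character(row[[col]])), ""))
        row[[col]]
      else tractparamsDefaults[[col]]
    }
    splitList <- function(v)
      if (identical(v, "")) character(0)
      else trimws(strsplit(as.character(v), ";", fixed = TRUE)[[1]])
    p <- list(
      tract_name = as.character(row$tract_name),
      roi1 = as.character(row$roi1),
      roi2 = as.character(row$roi2),
      roi1_combine = splitList(getCol("roi1_combine")),
      roi2_combine = splitList(getCol("roi2_combine")),
      roi1_dilate = as.integer(parseNumericCell(getCol("roi1_dilate"),
                                                r, "roi1_dilate")),
      roi2_dilate = as.integer(parseNumericCell(getCol("roi2_dilate"),
                                                r, "roi2_dilate")),
      select_mode = match.arg(as.character(getCol("select_mode")),
                              c("all", "any")),
      clean = if (is.logical(getCol("clean"))) getCol("clean")
              else parseLogicalCell(getCol("clean"), r, "clean"),
      max_len_sd = parseNumericCell(getCol("max_len_sd"), r, "max_len_sd"),
      max_dist_sd = parseNumericCell(getCol("max_dist_sd"), r,
                                     "max_dist_sd"),
      max_iter = as.integer(parseNumericCell(getCol("max_iter"), r,
                                             "max_iter")),
      c2roi = if (is.logical(getCol("c2roi"))) getCol("c2roi")
              else parseLogicalCell(getCol("c2roi"), r, "c2roi"),
      metrics = splitList(getCol("metrics")))
    if (p$roi1_dilate < 0 || p$roi2_dilate < 0)
      stop(sprintf("tractparams row %d: dilation iterations must be >= 0", r))
    if (p$max_len_sd <= 0 || p$max_dist_sd <= 0 || p$max_iter < 1)
      stop(sprintf("tractparams row %d: invalid cleaning parameters", r))
    if (!length(p$metrics))
      p$metrics <- "FA"
    p
  })
}
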