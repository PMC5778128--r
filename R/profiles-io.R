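#' Read a pore-water profile CSV into a CoreProfile
#'
#' Reads the canonical profile dialect: comma-separated, UTF-8, one header
#' row `depth_mbsf,ch4_uM,d13c_ch4_permil,so4_mM,no3_uM,mn_uM,fe_uM,state`,
#' empty string = missing value. Rows are sorted by depth; duplicate depths
#' and negative concentrations are rejected by the `CoreProfile` validator.
#'
#' @param path path to a profile CSV.
#' @param coreId core identifier (defaults to the file name without
#'   extension).
#' @param inundationAge,provenance optional metadata, see [CoreProfile()].
#' @return a [CoreProfile-class].
#' @seealso [writeCoreProfile()] for the exact inverse.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeCoreProfile(CoreProfile(data.frame(depth_mbsf = 1:3,
#'                                         ch4_uM = c(10, 20, 30))), f)
#' readCoreProfile(f)
#' @export
readCoreProfile <- function(path, coreId = NULL, inundationAge = NA_real_,
                            provenance = character()) {
  if (!file.exists(path)) stop("profile file does not exist: ", path)
  df <- read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                 na.strings = "", colClasses = "character",
                 fileEncoding = "UTF-8")
  bad <- setdiff(names(df), .profileColumns)
  missing <- setdiff(.profileColumns, names(df))
  if (length(bad) || length(missing))
    stop("malformed profile header: ",
         if (length(missing)) paste("missing column(s)",
                                    paste(missing, collapse = ", ")),
         if (length(bad) && length(missing)) "; ",
         if (length(bad)) paste("unknown column(s)",
                                paste(bad, collapse = ", ")))
  for (col in c("depth_mbsf", .analyteColumns)) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(is.na(v) & !is.na(df[[col]])))
      stop("non-numeric value in column ", col)
    df[[col]] <- v
  }
  if (is.null(coreId)) coreId <- sub("\\.[^.]*$", "", basename(path))
  CoreProfile(df, coreId = coreId, inundationAge = inundationAge,
              provenance = provenance)
}

#' Write a CoreProfile to the canonical profile CSV
#'
#' Emits the same dialect [readCoreProfile()] reads; `readCoreProfile(
#' writeCoreProfile(p, f))` reproduces `p`'s records field-for-field. Values
#' are written with full precision (up to 15 significant digits); missing
#' cells are empty strings.
#'
#' @param profile a valid [CoreProfile-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCoreProfile <- function(profile, path) {
  stopifnot(is(profile, "CoreProfile"))
  validObject(profile)
  rec <- profile@records
  out <- rec
  for (col in c("depth_mbsf", .analyteColumns)) {
    v <- vapply(rec[[col]], function(x)
      if (is.na(x)) "" else format(x, digits = 15, scientific = FALSE,
                                   trim = TRUE), character(1))
    out[[col]] <- v
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  write.csv(out, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
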