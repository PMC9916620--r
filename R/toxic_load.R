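#' Unit conversions for toxic-load estimation
#'
#' A land class's annual toxic load is the number of honey-bee contact-LD50
#' doses applied per acre: reported pounds of active ingredient are
#' converted to micrograms, divided by the chemical's contact LD50
#' (micrograms per bee) to give lethal doses, divided by the class acreage,
#' and summed over chemicals.
#'
#' @param pounds pounds of active ingredient applied (non-negative).
#' @return `pounds_to_micrograms()`: micrograms, `pounds * 453,592,370`.
#' @export
#' @examples
#' pounds_to_micrograms(1) # 453592370
#' lethal_doses(1183052498279, 0.0029) # ~4.08e14 doses
pounds_to_micrograms <- function(pounds) {
  if (any(pounds < 0)) stop("pounds must be non-negative")
  pounds * 453592370
}

#' @rdname pounds_to_micrograms
#' @param micrograms micrograms of active ingredient applied.
#' @param ld50_ug_per_bee contact LD50 in micrograms per bee (positive).
#' @return `lethal_doses()`: number of LD50 doses, `micrograms / ld50`.
#' @export
lethal_doses <- function(micrograms, ld50_ug_per_bee) {
  if (any(ld50_ug_per_bee <= 0)) stop("LD50 must be positive")
  if (any(micrograms < 0)) stop("micrograms must be non-negative")
  micrograms / ld50_ug_per_bee
}

#' @rdname pounds_to_micrograms
#' @param doses number of LD50 doses (non-negative).
#' @param acres acreage of the land class (positive).
#' @return `per_acre_load()`: LD50 doses per acre, `doses / acres`.
#' @export
per_acre_load <- function(doses, acres) {
  if (any(acres <= 0)) stop("acres must be positive")
  if (any(doses < 0)) stop("doses must be non-negative")
  doses / acres
}

#' Per-acre annual toxic load of one land class
#'
#' Sums `per_acre_load(lethal_doses(pounds_to_micrograms(pounds), ld50),
#' acres)` over every chemical applied to the class in the given year.
#' Classes present in the records but silent in a year are treated as
#' receiving no reported applications (load 0) by the table builders.
#'
#' @param records data frame of use records (`chemical`, `land_class`,
#'   `year`, `pounds`).
#' @param ld50 data frame `chemical`, `ld50_ug_per_bee`.
#' @param acreage data frame `land_class`, `acres`.
#' @param land_class,year the class and year to evaluate.
#' @return LD50 doses per acre (0 when the class has no records that year).
#' @export
class_annual_load <- function(records, ld50, acreage, land_class, year) {
  rec <- records[records$land_class == land_class & records$year == year, ,
                 drop = FALSE]
  if (nrow(rec) == 0) return(0)
  ld <- setNames(ld50$ld50_ug_per_bee, ld50$chemical)
  missing_ld <- setdiff(unique(rec$chemical), names(ld))
  if (length(missing_ld))
    stop("no contact LD50 for chemical(s): ",
         paste(missing_ld, collapse = ", "))
  ac <- setNames(acreage$acres, acreage$land_class)
  if (!land_class %in% names(ac))
    stop("no acreage for land class: ", land_class)
  sum(per_acre_load(lethal_doses(pounds_to_micrograms(rec$pounds),
                                 ld[rec$chemical]),
                    ac[[land_class]]))
}

#' Annual toxic-load table
#'
#' Per-acre toxic load for every (land class, year) combination, where the
#' class set is every class appearing in the use records (after dropping
#' excluded use categories) and the year set is every year in the records.
#' A class with records in some years but none in another gets load 0 for
#' the silent year, reflecting that absence from use reporting means no
#' reported application.
#'
#' @inheritParams class_annual_load
#' @param exclude use categories (matched against `land_class`) dropped
#'   before computation; reported structural pest control is excluded by
#'   default because its risk to pollinators is unknown.
#' @return data frame `land_class`, `year`, `doses_per_acre`.
#' @export
toxic_load_annual <- function(records, ld50, acreage,
                              exclude = "structural pest control") {
  records <- records[!tolower(records$land_class) %in% tolower(exclude), ,
                     drop = FALSE]
  if (nrow(records) == 0) stop("no usable pesticide-use records")
  classes <- sort(unique(records$land_class))
  years <- sort(unique(records$year))
  out <- expand.grid(land_class = classes, year = years,
                     stringsAsFactors = FALSE)
  out$doses_per_acre <- mapply(function(cl, yr)
    class_annual_load(records, ld50, acreage, cl, yr),
    out$land_class, out$year)
  out[order(out$land_class, out$year), c("land_class", "year",
                                         "doses_per_acre")]
}

#' Collapse three annual loads to low/medium/high scenario loads
#'
#' Interannual variation is folded into three scenarios per class: the
#' lowest, median, and highest of the three annual values.
#'
#' @param annual data frame `land_class`, `year`, `doses_per_acre` with
#'   exactly three years per class.
#' @return data frame `land_class`, `low`, `medium`, `high` with
#'   `low <= medium <= high` for every class.
#' @export
#' @examples
#' ann <- data.frame(land_class = "x", year = 1:3,
#'                   doses_per_acre = c(9, 0, 3))
#' collapse_to_scenarios(ann) # low 0, medium 3, high 9
collapse_to_scenarios <- function(annual) {
  split_by <- split(annual$doses_per_acre, annual$land_class)
  n_years <- length(unique(annual$year))
  if (n_years != 3)
    stop("scenario collapse requires exactly 3 annual values per class, ",
         "got ", n_years, " year(s)")
  bad <- names(split_by)[vapply(split_by, length, 1L) != 3]
  if (length(bad))
    stop("class(es) without exactly 3 annual values: ",
         paste(bad, collapse = ", "))
  keep <- vapply(split_by, function(v) any(v > 0), TRUE)
  if (any(!keep))
    warning("dropping class(es) with no reported applications in any year: ",
            paste(names(split_by)[!keep], collapse = ", "))
  split_by <- split_by[keep]
  out <- data.frame(
    land_class = names(split_by),
    low = vapply(split_by, min, 1),
    medium = vapply(split_by, median, 1),
    high = vapply(split_by, max, 1),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(out$land_class), ]
}
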