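#' Pesticide-use configuration for the synthetic landscape
#'
#' Defines the chemicals applied on the synthetic landscape, their honey-bee
#' contact LD50s, the per-class application intensity, and the interannual
#' variation of reported use. By default the intensity of each land class is
#' calibrated so its medium-scenario per-acre toxic load sits at the
#' magnitude implied by the packaged published resistance table (a class
#' with medium resistance R receives R/8 times the urban application
#' intensity), which keeps the synthetic loads on a realistic scale from
#' near-zero (rice) to very high (citrus).
#'
#' @param crop_classes crop class names receiving applications.
#' @param years integer vector of reporting years (three by default).
#' @param cv interannual coefficient of variation of reported pounds
#'   (lognormal year effects; `cv = 0` gives identical pounds every year).
#' @param chemicals data frame `chemical`, `ld50_ug_per_bee` (contact LD50
#'   in micrograms per bee).
#' @param mix named numeric, fraction of a class's total application
#'   intensity carried by each chemical (must cover `chemicals$chemical`).
#' @param urban_class name of the urban land class whose reported
#'   non-agricultural uses anchor the resistance scaling.
#' @param urban_intensity urban application intensity, lbs/acre/year.
#' @param intensity optional named numeric of lbs/acre/year per land class;
#'   when `NULL` it is derived from the packaged resistance table.
#' @return a list of class `pesticide_config`.
#' @export
pesticide_config <- function(crop_classes = default_crop_classes(),
                             years = 2014:2016, cv = 0.3,
                             chemicals = default_chemicals(),
                             mix = default_chemical_mix(),
                             urban_class = "Urban",
                             urban_intensity = 0.12,
                             intensity = NULL) {
  if (is.null(intensity)) {
    tab <- table1_resistance()
    med <- setNames(tab$medium, tab$land_class)
    if (!all(crop_classes %in% names(med)))
      stop("no default intensity for crop class(es): ",
           paste(setdiff(crop_classes, names(med)), collapse = ", "),
           "; supply `intensity` explicitly")
    intensity <- c(setNames(med[crop_classes] / 8 * urban_intensity,
                            crop_classes),
                   setNames(urban_intensity, urban_class))
  }
  cfg <- as.list(environment())
  class(cfg) <- "pesticide_config"
  cfg
}

#' @rdname pesticide_config
#' @export
default_chemicals <- function() {
  data.frame(
    chemical = c("Spinosad", "Chlorpyrifos", "Imidacloprid",
                 "Lambda-cyhalothrin", "Malathion", "Carbaryl"),
    ld50_ug_per_bee = c(0.0029, 0.059, 0.043, 0.038, 0.27, 1.1),
    stringsAsFactors = FALSE
  )
}

#' @rdname pesticide_config
#' @export
default_chemical_mix <- function() {
  c(Spinosad = 0.15, Chlorpyrifos = 0.20, Imidacloprid = 0.15,
    `Lambda-cyhalothrin` = 0.10, Malathion = 0.25, Carbaryl = 0.15)
}

#' Acres covered by one grid cell
#'
#' @param cell_size cell edge in metres.
#' @return acres per cell (30 m cells: 900 m2 = 0.2223948 acres).
#' @export
acres_per_cell <- function(cell_size) {
  cell_size^2 / 4046.8564224
}

#' Generate synthetic pesticide-use, LD50 and acreage tables
#'
#' Emulates the structure of public pesticide-use reporting joined to
#' toxicity databases: one record per (land class, chemical, year) with
#' pounds applied, a contact-LD50 lookup, and class acreage derived from
#' the grid. Pounds are `intensity x mix x acres` scaled by a lognormal
#' year effect with the configured coefficient of variation (mean 1), so
#' expected annual use is intensity-proportional and `cv = 0` removes all
#' interannual variation.
#'
#' @param grid a [land_grid()]; acreage is `cells x acres_per_cell`.
#' @param config a [pesticide_config()].
#' @param seed master seed; draws use `child_seed(seed, 2)`.
#' @return list with data frames `use_records` (`chemical`, `land_class`,
#'   `year`, `pounds`), `ld50` (`chemical`, `ld50_ug_per_bee`), and
#'   `acreage` (`land_class`, `acres`).
#' @export
generate_pesticide_tables <- function(grid, config = pesticide_config(),
                                      seed = 1) {
  cfg <- config
  if (nrow(cfg$chemicals) == 0)
    stop("configuration error: the chemical list is empty")
  if (!all(cfg$chemicals$chemical %in% names(cfg$mix)))
    stop("chemical mix is missing: ",
         paste(setdiff(cfg$chemicals$chemical, names(cfg$mix)),
               collapse = ", "))

  name_of <- setNames(grid$classes$name, grid$classes$code)
  counts <- table(name_of[as.character(grid$codes[!is.na(grid$codes)])])
  acreage <- data.frame(land_class = names(counts),
                        acres = as.numeric(counts) *
                          acres_per_cell(grid$cell_size),
                        stringsAsFactors = FALSE)

  treated <- intersect(names(cfg$intensity), acreage$land_class)
  if (length(treated) == 0)
    stop("no treated land class from the configuration is present on the grid")
  acres <- setNames(acreage$acres, acreage$land_class)

  sigma <- sqrt(log(1 + cfg$cv^2))
  combos <- expand.grid(year = cfg$years,
                        chemical = cfg$chemicals$chemical,
                        land_class = treated,
                        stringsAsFactors = FALSE)
  records <- withr::with_seed(child_seed(seed, 2), {
    dev <- if (cfg$cv == 0) rep(1, nrow(combos)) else
      exp(rnorm(nrow(combos), 0, sigma) - sigma^2 / 2)
    data.frame(
      chemical = combos$chemical,
      land_class = combos$land_class,
      year = combos$year,
      pounds = cfg$intensity[combos$land_class] *
        cfg$mix[combos$chemical] * acres[combos$land_class] * dev,
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  list(use_records = records, ld50 = cfg$chemicals, acreage = acreage)
}
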