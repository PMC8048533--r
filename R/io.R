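#' Input and output tables
#'
#' An instance is stored as a directory of seven delimited tables mirroring
#' the tool's workbook structure: `parameters`, `products`,
#' `center_capacities`, `demand`, `vehicle`, `distance_data` and
#' `road_condition` (all `.csv`). Units: volumes in liters, distances in km,
#' times in hours, clock times HH:MM (24 h). The distance matrix need not be
#' symmetric (one-way roads); road and vehicle conditions use the closed
#' vocabularies [ROAD_CONDITIONS] and [VEHICLE_CONDITIONS]. A center,
#' product or vehicle is entered once, in its own table, and referenced by
#' name everywhere else.
#'
#' @name instance-io
NULL

.sheet_names <- c("parameters", "products", "center_capacities", "demand",
                  "vehicle", "distance_data", "road_condition")

.read_sheet <- function(path, sheet) {
  f <- file.path(path, paste0(sheet, ".csv"))
  if (!file.exists(f))
    stop("schema error: missing input table ", sQuote(sheet), " (expected ", f, ")",
         call. = FALSE)
  utils::read.csv(f, check.names = FALSE, stringsAsFactors = FALSE)
}

.param_get <- function(tab, key, required = TRUE) {
  v <- tab$value[tab$key == key]
  if (length(v) != 1L) {
    if (required) stop("schema error: parameters table needs key ", sQuote(key),
                       call. = FALSE)
    return(NULL)
  }
  v
}

#' Read an instance from a directory of delimited tables
#'
#' @param path directory holding the seven `.csv` tables (see
#'   [instance-io]).
#' @param road_penalties,vehicle_penalties optional penalty-scale overrides.
#' @return an `lm_instance`.
#' @export
read_instance <- function(path,
                          road_penalties = .default_road_penalties,
                          vehicle_penalties = .default_vehicle_penalties) {
  if (!dir.exists(path))
    stop("input path does not exist or is not a directory: ", path, call. = FALSE)
  tabs <- lapply(.sheet_names, function(s) .read_sheet(path, s))
  names(tabs) <- .sheet_names

  pt <- tabs$parameters
  if (!all(c("key", "value") %in% names(pt)))
    stop("schema error: parameters table must have columns key,value", call. = FALSE)
  parameters <- list(
    run_description = .param_get(pt, "run_description"),
    start_location = .param_get(pt, "start_location"),
    start_time = .param_get(pt, "start_time"),
    max_route_hours = as.numeric(.param_get(pt, "max_route_hours")),
    dropoff_time = as.numeric(.param_get(pt, "dropoff_time")),
    transit_weight_raw = as.numeric(.param_get(pt, "transit_weight")),
    objective_form = .param_get(pt, "objective_form", required = FALSE))
  .parse_hhmm(parameters$start_time)  # validates the format

  need <- function(tab, cols, sheet) {
    miss <- setdiff(cols, names(tab))
    if (length(miss)) stop("schema error: table ", sQuote(sheet),
                           " lacks column(s) ", paste(miss, collapse = ", "),
                           call. = FALSE)
  }
  need(tabs$products, c("name", "unit_volume", "doses_per_vial",
                        "requires_cold", "available_supply"), "products")
  need(tabs$center_capacities, c("name", "center_type", "cold_capacity",
                                 "dry_capacity", "is_depot"), "center_capacities")
  need(tabs$vehicle, c("name", "condition_class", "velocity", "cold_capacity",
                       "dry_capacity", "fuel_consumption", "fuel_price",
                       "per_diem"), "vehicle")

  centers <- tabs$center_capacities
  centers$is_depot <- .as_flag(centers$is_depot)
  products <- tabs$products
  products$requires_cold <- .as_flag(products$requires_cold)

  to_matrix <- function(tab, sheet, names_expected, numeric = TRUE) {
    if (names(tab)[1] != "name")
      stop("schema error: first column of ", sQuote(sheet), " must be 'name'",
           call. = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab$name
    if (!identical(sort(rownames(m)), sort(names_expected)) ||
        !identical(sort(colnames(m)), sort(names_expected)))
      stop("schema error: ", sQuote(sheet),
           " rows/columns do not match the center names", call. = FALSE)
    m <- m[names_expected, names_expected, drop = FALSE]
    if (numeric) {
      mm <- suppressWarnings(matrix(as.numeric(m), nrow(m), dimnames = dimnames(m)))
      if (anyNA(mm))
        stop("value error: ", sQuote(sheet), " has blank or non-numeric cells",
             call. = FALSE)
      mm
    } else m
  }
  distance <- to_matrix(tabs$distance_data, "distance_data", centers$name)
  road_condition <- to_matrix(tabs$road_condition, "road_condition",
                              centers$name, numeric = FALSE)

  dem <- tabs$demand
  if (names(dem)[1] != "name")
    stop("schema error: first column of 'demand' must be 'name'", call. = FALSE)
  demand <- as.matrix(dem[, -1, drop = FALSE])
  rownames(demand) <- dem$name
  if (!identical(sort(rownames(demand)), sort(centers$name)) ||
      !identical(sort(colnames(demand)), sort(products$name)))
    stop("schema error: 'demand' must have one row per center and one column per product",
         call. = FALSE)
  demand <- demand[centers$name, products$name, drop = FALSE]
  storage.mode(demand) <- "numeric"

  instance(centers, products, tabs$vehicle, distance, road_condition, demand,
           parameters, road_penalties, vehicle_penalties)
}

.as_flag <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) %in% c("true", "yes", "1")
}

#' Write an instance to a directory of delimited tables
#'
#' Inverse of [read_instance()]: value-level round trips are exact.
#'
#' @param inst an `lm_instance`.
#' @param path target directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_instance <- function(inst, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  p <- inst$parameters
  wr <- function(d, sheet) utils::write.csv(
    d, file.path(path, paste0(sheet, ".csv")), row.names = FALSE)
  wr(data.frame(
    key = c("run_description", "start_location", "start_time",
            "max_route_hours", "dropoff_time", "transit_weight",
            "objective_form"),
    value = c(p$run_description, p$start_location, p$start_time,
              p$max_route_hours, p$dropoff_time, p$transit_weight_raw,
              p$objective_form)), "parameters")
  wr(inst$products[, c("name", "unit_volume", "doses_per_vial",
                       "requires_cold", "available_supply")], "products")
  wr(inst$centers[, c("name", "center_type", "cold_capacity", "dry_capacity",
                      "is_depot")], "center_capacities")
  wr(inst$vehicles[, c("name", "condition_class", "velocity", "cold_capacity",
                       "dry_capacity", "fuel_consumption", "fuel_price",
                       "per_diem")], "vehicle")
  mat <- function(m) data.frame(name = rownames(m), m, check.names = FALSE)
  wr(mat(inst$roads$distance), "distance_data")
  wr(mat(inst$roads$condition), "road_condition")
  wr(mat(inst$demand), "demand")
  invisible(path)
}

#' Write the solution report tables
#'
#' Writes the `routes` and `products` tables (see [build_report()]) as a CSV
#' pair named `<stem>_result_<YYYY-MM-DD>_routes.csv` and
#' `..._products.csv`; the run description is echoed in the routes table. A
#' numeric suffix avoids overwriting earlier results from the same day.
#'
#' @param solution an `lm_solution`.
#' @param grouped the `lm_grouped` it solves.
#' @param dir output directory (created if needed).
#' @param stem basename of the input the solution answers (default "instance").
#' @param date date stamp used in the filename.
#' @return character vector of the two file paths written.
#' @export
write_solution <- function(solution, grouped, dir, stem = "instance",
                           date = Sys.Date()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rep <- build_report(solution, grouped)
  base <- sprintf("%s_result_%s", stem, format(date, "%Y-%m-%d"))
  candidate <- base
  k <- 1L
  while (file.exists(file.path(dir, paste0(candidate, "_routes.csv")))) {
    k <- k + 1L
    candidate <- sprintf("%s-%d", base, k)
  }
  paths <- file.path(dir, paste0(candidate, c("_routes.csv", "_products.csv")))
  utils::write.csv(rep$routes, paths[1], row.names = FALSE)
  utils::write.csv(rep$products, paths[2], row.names = FALSE)
  paths
}
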