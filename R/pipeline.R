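# End-to-end entry points tying the pipeline together: simulate a colony to
# schema files, validate a file pair, build and serialize the life-history
# table, and compare two analysis-layout tables cell-wise. A thin
# command-line wrapper over these functions ships in inst/cli/lemurlife.R.

#' Simulate a colony and write its files
#'
#' Runs [simulate_colony()] and writes the animal list, weight file and a
#' ground-truth JSON sidecar into `out_dir`.
#'
#' @param params `colony_params` or list thereof.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, the list of written paths.
#' @export
run_simulate <- function(params, out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_colony(params, seed = seed)
  paths <- list(
    animals = file.path(out_dir, "animal_list.csv"),
    weights = file.path(out_dir, "weight_file.csv"),
    truth = file.path(out_dir, "ground_truth.json")
  )
  write_animal_list(sim$animals, paths$animals)
  write_weight_file(sim$weights, paths$weights)
  truth_plain <- lapply(sim$truth, function(gt) unclass(gt))
  jsonlite::write_json(truth_plain, paths$truth, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  message("simulated ", nrow(sim$animals), " animal records, ",
          nrow(sim$weights), " weight records")
  invisible(paths)
}

#' Validate a record-file pair
#'
#' @param animal_path,weight_path Input CSV paths.
#' @param registry Taxon registry.
#' @param ... Passed to [validate_colony()].
#' @return The validation report.
#' @export
run_validate <- function(animal_path, weight_path,
                         registry = default_registry(), ...) {
  animals <- read_animal_list(animal_path, registry)
  weights <- read_weight_file(weight_path, registry)
  report <- validate_colony(animals, weights, ...)
  for (src in list(animals, weights)) {
    for (issue in attr(src, "issues")) message("read issue: ", issue)
  }
  report
}

#' Build the life-history table from record files
#'
#' Reads both files, builds the 91-variable table and writes both published
#' layouts plus a validation report.
#'
#' @param animal_path,weight_path Input CSV paths.
#' @param out_dir Output directory.
#' @param registry Taxon registry.
#' @param cfg A [mass_config()].
#' @return Invisibly, a list with the built `table`, the validation
#'   `report` and the output `paths`.
#' @export
run_build_table <- function(animal_path, weight_path, out_dir,
                            registry = default_registry(),
                            cfg = mass_config()) {
  animals <- read_animal_list(animal_path, registry)
  weights <- read_weight_file(weight_path, registry)
  message("read ", nrow(animals), " animal records, ", nrow(weights),
          " weight records")
  report <- validate_colony(animals, weights)
  table <- build_life_history_table(animals, weights, registry, cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    reference = file.path(out_dir, "life_history_reference.csv"),
    analysis = file.path(out_dir, "life_history_analysis.csv"),
    validation = file.path(out_dir, "validation_report.csv")
  )
  serialize_reference(table, paths$reference)
  serialize_analysis(table, paths$analysis)
  utils::write.csv(as.data.frame(report), paths$validation,
                   row.names = FALSE)
  message("built table: ", nrow(table), " taxa x ", ncol(table) - 1,
          " variables; ", nrow(report), " validation flag(s)")
  invisible(list(table = table, report = report, paths = paths))
}

#' Compare two analysis-layout tables
#'
#' Cell-wise comparison of two life-history tables with a numeric tolerance;
#' character cells must match exactly.
#'
#' @param a,b `life_history_table` data.frames or paths to analysis-layout
#'   CSVs.
#' @param tol Absolute numeric tolerance per cell.
#' @return Data.frame of differences (`taxon`, `variable`, `a`, `b`); zero
#'   rows when the tables agree within tolerance.
#' @export
run_compare <- function(a, b, tol = 0.01) {
  if (is.character(a)) a <- read_analysis_table(a)
  if (is.character(b)) b <- read_analysis_table(b)
  if (!setequal(a$Taxon, b$Taxon) || !setequal(names(a), names(b))) {
    stop("comparison failed: tables have different taxa or variables")
  }
  b <- b[match(a$Taxon, b$Taxon), names(a), drop = FALSE]
  diffs <- list()
  for (v in setdiff(names(a), "Taxon")) {
    xa <- a[[v]]
    xb <- b[[v]]
    if (is.numeric(xa) && is.numeric(xb)) {
      bad <- xor(is.na(xa), is.na(xb)) |
        (!is.na(xa) & !is.na(xb) & abs(xa - xb) > tol)
    } else {
      ca <- as.character(xa)
      cb <- as.character(xb)
      bad <- xor(is.na(ca), is.na(cb)) |
        (!is.na(ca) & !is.na(cb) & ca != cb)
    }
    if (any(bad)) {
      diffs[[length(diffs) + 1]] <- data.frame(
        taxon = a$Taxon[bad], variable = v,
        a = as.character(xa[bad]), b = as.character(xb[bad]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(diffs) == 0) {
    data.frame(taxon = character(0), variable = character(0),
               a = character(0), b = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, diffs)
  }
}
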