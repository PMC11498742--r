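# Tabular file formats: measurement and condition tables follow the
# column naming of the PEtab ecosystem (observableId,
# simulationConditionId, preequilibrationConditionId, time, measurement),
# restricted to the subset this package supports; `time = inf` marks
# steady-state (post-equilibration) rows.

#' Read a measurement table
#'
#' Tab-separated with header columns `observableId`,
#' `simulationConditionId`, optional `preequilibrationConditionId` (empty
#' allowed), `time` (number or the literal `inf`) and `measurement`.
#'
#' @param path TSV file.
#' @return data.frame with numeric `time` (`Inf` for steady-state rows)
#'   and an attribute `preeq_map` (condition -> pre-equilibration
#'   condition) when the optional column is present.
#' @export
read_measurements <- function(path) {
  m <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("observableId", "simulationConditionId", "time", "measurement")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols))
    stop("measurement table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  known <- c(need, "preequilibrationConditionId")
  extra <- setdiff(names(m), known)
  if (length(extra))
    stop("unsupported measurement table column(s): ",
         paste(extra, collapse = ", "),
         " (full PEtab tables are not supported)")
  tm <- tolower(trimws(as.character(m$time)))
  time <- suppressWarnings(as.numeric(tm))
  time[tm %in% c("inf", "+inf", "infinity")] <- Inf
  bad <- which(is.na(time))
  if (length(bad))
    stop("unparseable time at measurement row(s): ",
         paste(bad, collapse = ", "))
  neg <- which(is.finite(time) & time < 0)
  if (length(neg))
    stop("negative time at measurement row(s): ", paste(neg, collapse = ", "))
  m$time <- time
  m$measurement <- as.numeric(m$measurement)
  if ("preequilibrationConditionId" %in% names(m)) {
    pe <- m$preequilibrationConditionId
    pe[is.na(pe) | pe == ""] <- NA_character_
    mp <- unique(data.frame(cond = m$simulationConditionId, preeq = pe,
                            stringsAsFactors = FALSE))
    if (anyDuplicated(mp$cond))
      stop("inconsistent preequilibrationConditionId within a condition")
    m$preequilibrationConditionId <- NULL
    attr(m, "preeq_map") <- stats::setNames(mp$preeq, mp$cond)
  }
  ord <- order(m$simulationConditionId, m$time)
  structure(m[ord, , drop = FALSE], row.names = seq_len(nrow(m)))
}

#' Write a measurement table
#' @param measurements data.frame as in [read_measurements()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  m <- as.data.frame(measurements)
  m$time <- ifelse(is.infinite(m$time), "inf", format(m$time, digits = 15))
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a condition table
#'
#' Tab-separated with a `conditionId` column, one column per model input,
#' and an optional `preequilibrationConditionId` column.
#'
#' @param path TSV file.
#' @param model an [ode_model()] naming the expected inputs.
#' @return list of [condition()] objects.
#' @export
read_conditions <- function(path, model) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!"conditionId" %in% names(tab))
    stop("condition table lacks a conditionId column")
  missing_u <- setdiff(model$input_names, names(tab))
  if (length(missing_u))
    stop("condition table lacks input column(s): ",
         paste(missing_u, collapse = ", "))
  has_pe <- "preequilibrationConditionId" %in% names(tab)
  lapply(seq_len(nrow(tab)), function(i) {
    pe <- if (has_pe) tab$preequilibrationConditionId[i] else NA_character_
    if (!is.na(pe) && (pe == "" )) pe <- NA_character_
    condition(tab$conditionId[i],
              stats::setNames(as.numeric(tab[i, model$input_names]),
                              model$input_names),
              preeq_condition_id = pe)
  })
}

#' Write a condition table
#' @param conditions list of [condition()] objects.
#' @param model the model (fixes the input column order).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_conditions <- function(conditions, model, path) {
  rows <- lapply(conditions, function(cn) {
    base <- data.frame(conditionId = cn$condition_id,
                       stringsAsFactors = FALSE)
    for (u in model$input_names) base[[u]] <- cn$input_values[[u]]
    base$preequilibrationConditionId <-
      if (is.na(cn$preeq_condition_id)) "" else cn$preeq_condition_id
    base
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Load a full problem (model + conditions + measurements)
#'
#' @param model_path model YAML.
#' @param conditions_path condition TSV.
#' @param measurements_path measurement TSV.
#' @return list with `model`, `deriv` and `data` (an [dataset()]).
#' @export
read_problem <- function(model_path, conditions_path, measurements_path) {
  model <- parse_model(model_path)
  conditions <- read_conditions(conditions_path, model)
  m <- read_measurements(measurements_path)
  pe_map <- attr(m, "preeq_map")
  if (!is.null(pe_map)) {
    conditions <- lapply(conditions, function(cn) {
      if (cn$condition_id %in% names(pe_map) &&
          !is.na(pe_map[[cn$condition_id]])) {
        if (!is.na(cn$preeq_condition_id) &&
            cn$preeq_condition_id != pe_map[[cn$condition_id]])
          stop("conflicting pre-equilibration references for condition '",
               cn$condition_id, "'")
        cn$preeq_condition_id <- pe_map[[cn$condition_id]]
      }
      cn
    })
  }
  list(model = model, deriv = derive(model),
       data = dataset(model, conditions, m))
}

#' Write a benchmark report to JSON and CSV
#'
#' Writes the full report as JSON plus three CSV tables: per-pair failure
#' rates (percent), pairwise gradient agreement, and a per-pair timing
#' summary.  Numeric fields round-trip losslessly through the JSON.
#'
#' @param report a [run_benchmark()] result.
#' @param path output directory.
#' @return named character vector of written files.
#' @export
write_report <- function(report, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- c(json = file.path(path, "report.json"),
             failures = file.path(path, "failure_rates.csv"),
             agreement = file.path(path, "agreement.csv"),
             timings = file.path(path, "timing_summary.csv"))
  payload <- list(
    n_samples = report$n_samples,
    seed = report$seed,
    failures = as.data.frame.matrix(report$failures),
    failure_rates = as.list(report$failure_rates),
    agreement = report$agreement,
    timing_summary = timing_summary(report))
  jsonlite::write_json(payload, files[["json"]], digits = NA, pretty = TRUE,
                       dataframe = "columns", auto_unbox = TRUE, na = "null")
  fr <- data.frame(pair = names(report$failure_rates),
                   failure_rate_percent = as.numeric(report$failure_rates))
  utils::write.csv(fr, files[["failures"]], row.names = FALSE)
  utils::write.csv(report$agreement, files[["agreement"]], row.names = FALSE)
  utils::write.csv(timing_summary(report), files[["timings"]],
                   row.names = FALSE)
  files
}

timing_summary <- function(report) {
  if (!length(report$timings))
    return(data.frame(pair = character(0), mean_total = numeric(0),
                      mean_equilibration = numeric(0),
                      mean_dynamic = numeric(0)))
  do.call(rbind, lapply(names(report$timings), function(pn) {
    tt <- report$timings[[pn]]
    data.frame(pair = pn,
               mean_total = mean(tt$total, na.rm = TRUE),
               mean_equilibration = mean(tt$equilibration, na.rm = TRUE),
               mean_dynamic = mean(tt$dynamic, na.rm = TRUE))
  }))
}

#' Read back a JSON benchmark report
#' @param path the directory or `report.json` written by [write_report()].
#' @return the parsed report payload.
#' @export
read_report <- function(path) {
  f <- if (dir.exists(path)) file.path(path, "report.json") else path
  jsonlite::read_json(f, simplifyVector = TRUE)
}
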