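#' Write a synthetic linked population to disk
#'
#' Writes each record table as UTF-8 CSV (RFC 4180 quoting, header row),
#' the shelter address list as a one-column CSV, a JSON ground-truth file
#' (`person_id`, `true_homeless`, `died_opioid_overdose`), and a JSON echo
#' of the generating configuration.
#'
#' @param population A `linked_population`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_population <- function(population, dir) {
  stopifnot(inherits(population, "linked_population"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("persons", "claims", "dmh_records", "ambulance_records",
              "prescription_records", "death_records")
  for (tab in tables) {
    readr::write_csv(population[[tab]], file.path(dir, paste0(tab, ".csv")),
                     na = "")
  }
  readr::write_csv(tibble::tibble(address = population$shelter_addresses),
                   file.path(dir, "shelter_addresses.csv"))
  truth <- population$persons[, c("person_id", "true_homeless",
                                  "died_opioid_overdose")]
  jsonlite::write_json(truth, file.path(dir, "truth.json"))
  cfg <- population$config
  cfg$predictor_spec <- as.data.frame(cfg$predictor_spec)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a linked population written by [write_population()]
#'
#' @param dir Directory containing the CSV/JSON files.
#' @return A `linked_population` (the `config` element is the JSON echo as
#'   a plain list, not a validated `sim_config`).
#' @export
read_population <- function(dir) {
  read1 <- function(name, col_types) {
    readr::read_csv(file.path(dir, paste0(name, ".csv")),
                    col_types = col_types, na = character(),
                    trim_ws = FALSE, progress = FALSE)
  }
  persons <- readr::read_csv(file.path(dir, "persons.csv"),
                             show_col_types = FALSE, progress = FALSE)
  structure(
    list(
      persons = persons,
      claims = read1("claims", "icc"),
      dmh_records = read1("dmh_records", "iic"),
      ambulance_records = read1("ambulance_records", "ic"),
      prescription_records = read1("prescription_records", "ic"),
      death_records = read1("death_records", "iccc") |>
        dplyr::mutate(underlying_cause = dplyr::na_if(.data$underlying_cause, "")),
      shelter_addresses = readr::read_csv(
        file.path(dir, "shelter_addresses.csv"), col_types = "c",
        progress = FALSE
      )$address,
      config = jsonlite::read_json(file.path(dir, "config.json"),
                                   simplifyVector = TRUE)
    ),
    class = "linked_population"
  )
}
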