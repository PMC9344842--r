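## Deterministic use-case corpus: fiber-experiment metadata records for the
## manufacture phase (core-shell hydrogel fiber fabrication) and the
## measurement phase (optical-microscopy characterization), random payloads,
## and corrupted variants that each plant exactly one known violation kind
## -- so every module is testable without external data.

#' Fiber-experiment templates
#'
#' The two packaged extensions of the Dublin Core base: `manufacture_template()`
#' adds the fabrication parameters (cell type with a controlled vocabulary,
#' collagen concentration in mg/ml, cell density in cells/ml, alginate flow
#' in ul/min, CaCl2 concentration in mM, incubation temperature in degrees C);
#' `measurement_template()` adds inner/outer fiber diameters at three points
#' along the axis (um), the optical image count and the microscope id.
#'
#' @return A resolved `metadata_template`.
#' @export
manufacture_template <- function() builtin_template("manufacture")

#' @rdname manufacture_template
#' @export
measurement_template <- function() builtin_template("measurement")

CORRUPTION_MODES <- c("drop-required", "bad-language", "off-vocabulary",
                      "bad-date", "bad-number")

## corruption mode -> the exact violation kind it must trigger
corruption_violation_kind <- function(mode) {
  c("drop-required" = "missing-required", "bad-language" = "bad-language-code",
    "off-vocabulary" = "not-in-vocabulary", "bad-date" = "bad-date",
    "bad-number" = "bad-number")[[mode]]
}

dublin_values <- function(i, phase) {
  list(
    Creator = "Tissue Engineering Group",
    Contributor = if (phase == "manufacture") "Hybrid Technology Hub" else "Sensors Group",
    Publisher = "University of Oslo",
    Title = sprintf("Fiber %s run %03d", phase, i),
    Date = sprintf("2022-03-%02d", (i - 1L) %% 28L + 1L),
    Language = "en",
    Format = "text/csv",
    Subject = "core-shell hydrogel fiber",
    Description = sprintf("%s record for engineered-living-material fiber experiment %d",
                          phase, i),
    Identifier = sprintf("fiber-%s-%03d", phase, i),
    Relation = "none",
    Source = "fiber-experiment-series-1",
    Type = "Dataset",
    Coverage = "Oslo, Norway",
    Rights = "CC-BY-4.0")
}

## A valid record for one phase; numeric values are the wet-lab parameters
## of the reference fiber protocol (4 mg/ml collagen, 1e8 cells/ml, 200
## ul/min alginate flow, 100 mM CaCl2, 37 C incubation; diameters measured
## at three points from >= 5 microscope images).
fixture_record <- function(i, phase = c("manufacture", "measurement")) {
  phase <- match.arg(phase)
  values <- dublin_values(i, phase)
  if (phase == "manufacture") {
    values <- c(values, list(
      cell_type = "HEK293",
      collagen_concentration_mg_per_ml = "4",
      cell_density_cells_per_ml = "1e8",
      alginate_flow_ul_per_min = "200",
      cacl2_concentration_mM = "100",
      incubation_temp_C = "37"))
  } else {
    inner <- sprintf("%.1f", runif(3, 90, 130))
    outer <- sprintf("%.1f", runif(3, 180, 260))
    values <- c(values, list(
      inner_diameter_um_point1 = inner[1], inner_diameter_um_point2 = inner[2],
      inner_diameter_um_point3 = inner[3],
      outer_diameter_um_point1 = outer[1], outer_diameter_um_point2 = outer[2],
      outer_diameter_um_point3 = outer[3],
      n_images = as.character(sample(5:12, 1)),
      microscope_id = "uio-phys-scope-01"))
  }
  metadata_record(phase, values)
}

corrupt_record <- function(record, mode) {
  v <- record$values
  switch(mode,
    "drop-required" = { v$Title <- "" },
    "bad-language" = { v$Language <- sample(c("e", "eng", "engl", "engli"), 1) },
    "off-vocabulary" = { v$cell_type <- "NIH3T3" },
    "bad-date" = { v$Date <- sample(c("22-03-01", "2022/03/01", "March 1"), 1) },
    "bad-number" = {
      if (record$template_id == "manufacture") v$collagen_concentration_mg_per_ml <- "four"
      else v$n_images <- "several"
    },
    stop("unknown corruption mode: ", mode))
  metadata_record(record$template_id, v)
}

#' Generate the fixture corpus
#'
#' Deterministic under `seed`: the same seed yields a byte-identical corpus.
#' Without corruption modes every record is valid. With modes, records are
#' corrupted in rotation over the given modes, and each corrupted record
#' carries the exact violation kind it must trigger (`planted_kind`),
#' enabling oracle-style assertions. Modes needing a specific template
#' (`off-vocabulary` needs the manufacture vocabulary field) force that
#' phase for the affected record.
#'
#' @param seed Integer seed.
#' @param n_records Number of records.
#' @param corruption Character vector, subset of `"drop-required"`,
#'   `"bad-language"`, `"off-vocabulary"`, `"bad-date"`, `"bad-number"`;
#'   empty (default) for an all-valid corpus.
#' @param payload_size Payload size in bytes (seeded pseudo-random bytes).
#' @param phases Phases to draw from (alternated).
#' @return A tibble: `id`, `phase`, `record` (list), `payload` (list of
#'   raw), `expected_valid`, `planted_mode`, `planted_kind`.
#' @export
generate_corpus <- function(seed = 42L, n_records = 10L, corruption = character(),
                            payload_size = 1024L,
                            phases = c("manufacture", "measurement")) {
  bad <- setdiff(corruption, CORRUPTION_MODES)
  if (length(bad)) stop("unknown corruption mode(s): ", paste(bad, collapse = ", "))
  phases <- match.arg(phases, several.ok = TRUE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  rows <- lapply(seq_len(n_records), function(i) {
    mode <- if (length(corruption)) corruption[(i - 1L) %% length(corruption) + 1L]
            else NA_character_
    phase <- if (!is.na(mode) && mode == "off-vocabulary") "manufacture"
             else phases[(i - 1L) %% length(phases) + 1L]
    rec <- fixture_record(i, phase)
    if (!is.na(mode)) rec <- corrupt_record(rec, mode)
    tibble::tibble(
      id = i, phase = phase, record = list(rec),
      payload = list(as.raw(sample(0:255, payload_size, replace = TRUE))),
      expected_valid = is.na(mode),
      planted_mode = mode,
      planted_kind = if (is.na(mode)) NA_character_ else corruption_violation_kind(mode))
  })
  do.call(rbind, rows)
}

#' Write a corpus to disk
#'
#' Emits one record JSON document and one payload file per corpus row,
#' plus a `corpus.json` index with the planted expectations.
#'
#' @param corpus A [generate_corpus()] tibble.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(corpus))) {
    rec <- corpus$record[[i]]
    writeLines(rawToChar(canonical_bytes(rec)),
               file.path(dir, sprintf("record-%03d.json", corpus$id[i])))
    writeBin(corpus$payload[[i]],
             file.path(dir, sprintf("payload-%03d.bin", corpus$id[i])))
  }
  idx <- corpus[, c("id", "phase", "expected_valid", "planted_mode", "planted_kind")]
  jsonlite::write_json(idx, file.path(dir, "corpus.json"), auto_unbox = FALSE)
  invisible(dir)
}
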